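# Small simulated fixtures shared across test files; built once per run.

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_individuals = 300, n_variants = 600,
                        n_chromosomes = 2, seed = 42,
                        n_causal_chip = 100, n_causal_subset = 50,
                        subset_specs = list(list(name = "set1", size = 100,
                                                 placement = "uniform")))
      sim <- simulate_genotypes(cfg)
      ph <- simulate_phenotypes(sim$genotypes, sim$variants, cfg, sim$subsets)
      cache <<- list(config = cfg, sim = sim, pheno = ph)
    }
    cache
  }
})

# tiny deterministic dosage matrix with ids, used for GRM and REML fixtures
tiny_genotypes <- function(n = 12, m = 30, seed = 7, maf_lo = 0.2) {
  set.seed(seed)
  repeat {
    p <- runif(m, maf_lo, 0.5)
    G <- sapply(p, function(pp) rbinom(n, 2, pp))
    f <- colMeans(G) / 2
    if (all(f > 0 & f < 1)) break
  }
  dimnames(G) <- list(sprintf("i%02d", seq_len(n)),
                      sprintf("m%02d", seq_len(m)))
  G
}
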