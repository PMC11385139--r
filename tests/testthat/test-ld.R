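# Brute-force O(m^2) pair enumeration in the test provides the oracle for
# ld_pairs(); hand-built dosage columns with exactly known correlations
# provide worked examples for the six subset metrics.

brute_pairs <- function(genotypes, variants, subset, window_bp) {
  out <- list()
  for (i in seq_len(nrow(variants) - 1)) {
    for (j in (i + 1):nrow(variants)) {
      if (variants$chromosome[i] != variants$chromosome[j]) next
      a <- if (variants$position[i] <= variants$position[j]) i else j
      b <- if (variants$position[i] <= variants$position[j]) j else i
      d <- variants$position[b] - variants$position[a]
      if (d == 0 || d > window_bp) next
      in_a <- variants$variant_id[a] %in% subset
      in_b <- variants$variant_id[b] %in% subset
      if (!in_a && !in_b) next
      out[[length(out) + 1]] <- data.frame(
        id_a = variants$variant_id[a], id_b = variants$variant_id[b],
        distance = d,
        r2 = oracle_r2(genotypes[, variants$variant_id[a]],
                       genotypes[, variants$variant_id[b]]),
        class = if (in_a && in_b) "intern" else "extern",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

test_that("ld_pairs matches brute-force enumeration on simulated data", {
  fx <- small_sim()
  G <- fx$sim$genotypes
  v <- fx$sim$variants
  subset <- sample(v$variant_id, 40)
  got <- ld_pairs(G, v, subset, window_bp = 30000)
  want <- brute_pairs(G, v, subset, window_bp = 30000)
  key <- function(d) paste(d$id_a, d$id_b)
  expect_setequal(key(got), key(want))
  want <- want[match(key(got), key(want)), ]
  expect_equal(got$r2, want$r2, tolerance = 1e-12)
  expect_equal(got$class, want$class)
  expect_equal(got$distance, want$distance)
  # every unordered pair appears exactly once, oriented by position
  expect_false(any(duplicated(key(got))))
  expect_true(all(got$pos_b > got$pos_a))
})

test_that("the pair window boundary is inclusive", {
  set.seed(4)
  G <- matrix(sample(0:2, 30, TRUE), 10, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  G[1, ] <- c(0, 0, 0); G[2, ] <- c(2, 2, 2)  # guarantee polymorphism
  v <- tibble::tibble(variant_id = c("a", "b", "c"), chromosome = "1",
                      position = c(100L, 100L + 500000L, 101L + 500000L))
  got <- ld_pairs(G, v, subset = "a", window_bp = 500000)
  expect_true(all(c("b") %in% got$id_b[got$id_a == "a"]))
  expect_false("c" %in% got$id_b[got$id_a == "a"])
})

test_that("pairs on different chromosomes are never formed", {
  set.seed(5)
  G <- matrix(sample(0:2, 40, TRUE), 10, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  G[1, ] <- 0; G[2, ] <- 2
  v <- tibble::tibble(variant_id = paste0("v", 1:4),
                      chromosome = c("1", "1", "2", "2"),
                      position = c(100L, 200L, 100L, 200L))
  got <- ld_pairs(G, v, subset = paste0("v", 1:4), window_bp = 1e6)
  expect_equal(nrow(got), 2)
  expect_setequal(paste(got$id_a, got$id_b), c("v1 v2", "v3 v4"))
})

test_that("hand-built columns give the expected decay and distribution", {
  # A and B identical (r2 = 1, near); C correlates 0.5 with A (r2 = 0.25, far)
  A <- c(0, 0, 0, 0, 2, 2, 2, 2)
  C <- c(0, 0, 2, 0, 2, 2, 0, 2)
  G <- cbind(a = A, b = A, c = C)
  v <- tibble::tibble(variant_id = c("a", "b", "c"), chromosome = "1",
                      position = c(1000L, 11000L, 131000L),
                      maf = c(0.5, 0.5, 0.5))
  pairs <- ld_pairs(G, v, subset = "a", window_bp = 500000)
  m <- ld_subset_metrics(pairs, v, subset = "a")
  val <- function(x) m$value[m$metric == x]
  expect_equal(val("decay_extern"), 0.25 / 1)
  expect_equal(val("mean_ld_extern"), mean(c(1, 0.25)))
  expect_equal(val("distribution"), 0)  # single-member subset: no intern pair
  expect_equal(val("mean_maf"), 0.5)
  expect_true(is.na(val("mean_ld_intern")))
  expect_match(m$note[m$metric == "mean_ld_intern"], "no intern")

  # subset {a, b}: a-b intern, a-c and b-c extern
  pairs2 <- ld_pairs(G, v, subset = c("a", "b"), window_bp = 500000)
  m2 <- ld_subset_metrics(pairs2, v, subset = c("a", "b"))
  expect_equal(m2$value[m2$metric == "distribution"], 1 / 3)
  expect_equal(m2$value[m2$metric == "mean_ld_intern"], 1)
})

test_that("flat LD gives decay exactly one", {
  # four copies of the same column: every r2 is 1 at every distance
  A <- c(0, 0, 1, 1, 2, 2)
  G <- cbind(a = A, b = A, c = A, d = A)
  v <- tibble::tibble(variant_id = c("a", "b", "c", "d"), chromosome = "1",
                      position = c(0L, 10000L, 150000L, 300000L),
                      maf = rep(0.5, 4))
  pairs <- ld_pairs(G, v, subset = c("a", "b", "c", "d"), window_bp = 500000)
  m <- ld_subset_metrics(pairs, v, subset = c("a", "b", "c", "d"))
  expect_equal(m$value[m$metric == "decay_intern"], 1)
  expect_equal(m$value[m$metric == "distribution"], 1)
})

test_that("strata without pairs are reported as NA with a reason", {
  A <- c(0, 0, 1, 1, 2, 2)
  G <- cbind(a = A, b = A)
  v <- tibble::tibble(variant_id = c("a", "b"), chromosome = "1",
                      position = c(0L, 10000L), maf = c(0.5, 0.5))
  pairs <- ld_pairs(G, v, subset = c("a", "b"), window_bp = 500000)
  m <- ld_subset_metrics(pairs, v, subset = c("a", "b"))
  expect_true(is.na(m$value[m$metric == "decay_intern"]))
  expect_match(m$note[m$metric == "decay_intern"], "far stratum")

  # no pairs at all: lone variant per chromosome
  v2 <- tibble::tibble(variant_id = c("a", "b"), chromosome = c("1", "2"),
                       position = c(0L, 0L), maf = c(0.5, 0.5))
  pairs2 <- ld_pairs(G, v2, subset = c("a", "b"), window_bp = 500000)
  expect_equal(nrow(pairs2), 0)
  m2 <- ld_subset_metrics(pairs2, v2, subset = c("a", "b"))
  expect_true(is.na(m2$value[m2$metric == "distribution"]))
  expect_match(m2$note[m2$metric == "distribution"], "no pairs")
})

test_that("a clustered subset is more subset-intern than a uniform one", {
  cfg <- sim_config(n_individuals = 150, n_variants = 400, n_chromosomes = 1,
                    seed = 21, n_causal_chip = 50, n_causal_subset = 20,
                    subset_specs = list(list(name = "cl", size = 80,
                                             placement = "clustered")))
  sim <- simulate_genotypes(cfg)
  G <- sim$genotypes
  v <- sim$variants
  clustered <- subset_members(sim$subsets, "cl")
  set.seed(77)
  uniform <- sample(v$variant_id, length(clustered))
  dist_of <- function(sub) {
    p <- ld_pairs(G, v, sub, window_bp = 50000)
    m <- ld_subset_metrics(p, v, sub)
    m$value[m$metric == "distribution"]
  }
  expect_gt(dist_of(clustered), dist_of(uniform))
})

test_that("metric correlations reproduce the explicit Pearson formula", {
  metrics <- tibble::tibble(
    subset = rep(c("s1", "s2", "s3", "s4", "s5"), 2),
    metric = rep(c("mean_ld_extern", "mean_maf"), each = 5),
    value = c(0.1, 0.2, 0.4, 0.3, 0.25, 0.5, 0.5, 0.5, 0.5, 0.5))
  h2 <- tibble::tibble(subset = c("s1", "s2", "s3", "s4", "s5"),
                       value = c(3e-6, 2e-6, 1e-6, 2.5e-6, 1.5e-6))
  out <- ld_metric_correlations(metrics, h2)
  x <- c(0.1, 0.2, 0.4, 0.3, 0.25)
  y <- h2$value
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r[out$metric == "mean_ld_extern"], r_hand,
               tolerance = 1e-12)
  # constant metric across subsets: undefined, with reason
  expect_true(is.na(out$r[out$metric == "mean_maf"]))
  expect_match(out$note[out$metric == "mean_maf"], "zero variance")
})

test_that("fewer than three complete subsets yields NA with a reason", {
  metrics <- tibble::tibble(subset = c("s1", "s2", "s3"),
                            metric = "mean_ld_extern",
                            value = c(0.1, NA, 0.3))
  h2 <- tibble::tibble(subset = c("s1", "s2", "s3"),
                       value = c(1e-6, 2e-6, 3e-6))
  out <- ld_metric_correlations(metrics, h2)
  expect_true(is.na(out$r))
  expect_equal(out$n, 2L)
  expect_match(out$note, "fewer than 3")
})
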