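#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic genotype/phenotype
#' generator. Genotypes follow a block-mosaic haplotype model: each chromosome
#' is tiled into blocks of `block_length_bp` base pairs, each block carries a
#' finite pool of `haplotypes_per_block` haplotypes, and every individual draws
#' two haplotypes per block. This creates strong within-block linkage
#' disequilibrium and near-zero LD between blocks. Phenotypes follow the
#' two-component additive model used by the two-GRM mixed models: a "chip"
#' polygenic component (causal variants outside the focal subset) and a
#' "subset" component (causal variants inside it), with effects drawn on
#' standardized genotypes so configured variances are on the phenotypic scale.
#'
#' Default variance settings place 30% of the phenotypic variance on the chip
#' component, 10% on the subset component and 60% on the residual, with a
#' subset-level genetic correlation of -0.5 between the two traits --
#' magnitudes typical of a production trait paired with a health trait.
#'
#' @param n_individuals Number of diploid individuals.
#' @param n_variants Total number of biallelic variants across all chromosomes.
#' @param n_chromosomes Number of autosomes to spread variants over.
#' @param block_length_bp Haplotype-block length in base pairs.
#' @param haplotypes_per_block Size of the haplotype pool within each block.
#' @param maf_floor Minimum sample minor allele frequency of emitted variants.
#' @param variant_spacing_bp Base-pair distance between adjacent variants.
#' @param subset_specs List of subset specifications; each element is a list
#'   with `name`, `size` (variant count, or proportion if < 1) and `placement`
#'   (`"uniform"` or `"clustered"`).
#' @param n_traits 1 or 2 simulated traits.
#' @param var_g_chip,var_g_subset,var_e Per-trait variances of the chip
#'   genetic, subset genetic and residual components (trait-variance units).
#' @param cov_g_chip,cov_g_subset,cov_e Between-trait covariances of the three
#'   components (used only when `n_traits = 2`).
#' @param n_causal_chip,n_causal_subset Causal variant counts per component.
#' @param causal_subset Name of the subset supplying subset-component causal
#'   variants; defaults to the first entry of `subset_specs`.
#' @param missing_rate_trait2 Proportion of trait-2 records masked as missing.
#' @param seed Integer seed; fully determines all simulator output.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 100, n_variants = 200, seed = 1)
sim_config <- function(n_individuals = 1000,
                       n_variants = 5000,
                       n_chromosomes = 5,
                       block_length_bp = 50000,
                       haplotypes_per_block = 20,
                       maf_floor = 0.05,
                       variant_spacing_bp = 1000,
                       subset_specs = list(list(name = "set1", size = 500,
                                                placement = "uniform")),
                       n_traits = 2,
                       var_g_chip = 0.30,
                       var_g_subset = 0.10,
                       var_e = 0.60,
                       cov_g_chip = -0.06,
                       cov_g_subset = -0.05,
                       cov_e = 0.12,
                       n_causal_chip = 500,
                       n_causal_subset = 100,
                       causal_subset = NULL,
                       missing_rate_trait2 = 0,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    n_chromosomes = as.integer(n_chromosomes),
    block_length_bp = as.integer(block_length_bp),
    haplotypes_per_block = as.integer(haplotypes_per_block),
    maf_floor = maf_floor,
    variant_spacing_bp = as.integer(variant_spacing_bp),
    subset_specs = subset_specs,
    n_traits = as.integer(n_traits),
    var_g_chip = var_g_chip, var_g_subset = var_g_subset, var_e = var_e,
    cov_g_chip = cov_g_chip, cov_g_subset = cov_g_subset, cov_e = cov_e,
    n_causal_chip = as.integer(n_causal_chip),
    n_causal_subset = as.integer(n_causal_subset),
    causal_subset = causal_subset %||%
      (if (length(subset_specs)) subset_specs[[1]]$name else NULL),
    missing_rate_trait2 = missing_rate_trait2,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_individuals >= 2, cfg$n_variants >= 1,
            cfg$n_chromosomes >= 1, cfg$block_length_bp >= 1,
            cfg$haplotypes_per_block >= 1,
            cfg$maf_floor >= 0, cfg$maf_floor <= 0.5,
            cfg$n_traits %in% c(1L, 2L),
            cfg$missing_rate_trait2 >= 0, cfg$missing_rate_trait2 <= 1)
  vars <- c(var_g_chip = cfg$var_g_chip, var_g_subset = cfg$var_g_subset,
            var_e = cfg$var_e)
  if (any(vars < 0)) {
    abort("all component variances must be non-negative")
  }
  covs <- c(cov_g_chip = cfg$cov_g_chip, cov_g_subset = cfg$cov_g_subset,
            cov_e = cfg$cov_e)
  for (i in seq_along(covs)) {
    if (abs(covs[i]) > vars[i] + 1e-12) {
      abort(sprintf(
        "|%s| = %g exceeds its variance bound %g (effect covariance not PSD)",
        names(covs)[i], abs(covs[i]), vars[i]))
    }
  }
  sizes <- vapply(cfg$subset_specs, function(s) {
    sz <- s$size
    if (sz < 1) round(sz * cfg$n_variants) else round(sz)
  }, numeric(1))
  if (length(sizes) && sum(sizes) > cfg$n_variants) {
    abort("subset sizes sum to more than n_variants")
  }
  invisible(cfg)
}

stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1)) + 1L
}

#' Simulate genotypes under the block-mosaic haplotype model
#'
#' Each chromosome is tiled into blocks; each block holds a pool of
#' `haplotypes_per_block` binary haplotypes, and every individual samples two
#' pool haplotypes per block (with replacement), so dosages are in
#' \{0, 1, 2\}. Variants whose sample minor allele frequency falls below
#' `maf_floor` have their pool column redrawn; if the floor cannot be met
#' after repeated redraws (e.g. a pool of one haplotype is always
#' monomorphic), the offending block is reported in the error.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `genotypes` (individuals x variants dosage
#'   matrix with individual/variant dimnames), `variants` (tibble: variant_id,
#'   chromosome, position, a1, a2, maf, dr2) and `subsets` (tibble: subset,
#'   variant_id, provenance) holding the simulated subset memberships.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 0))
  n <- config$n_individuals
  spacing <- config$variant_spacing_bp
  per_chr <- diff(round(seq(0, config$n_variants,
                            length.out = config$n_chromosomes + 1)))

  geno_cols <- vector("list", config$n_chromosomes)
  var_rows <- vector("list", config$n_chromosomes)

  for (chr in seq_len(config$n_chromosomes)) {
    m_chr <- per_chr[chr]
    if (m_chr == 0) next
    pos <- spacing * seq_len(m_chr)
    block <- (pos - 1L) %/% config$block_length_bp
    G <- matrix(0L, nrow = n, ncol = m_chr)
    for (b in unique(block)) {
      idx <- which(block == b)
      G[, idx] <- sim_block(n, length(idx), config$haplotypes_per_block,
                            config$maf_floor, chr, b)
    }
    geno_cols[[chr]] <- G
    var_rows[[chr]] <- tibble(
      variant_id = sprintf("v%d_%d", chr, pos),
      chromosome = as.character(chr),
      position = as.integer(pos))
  }

  genotypes <- do.call(cbind, geno_cols[!vapply(geno_cols, is.null, TRUE)])
  variants <- dplyr::bind_rows(var_rows)
  ids <- sprintf("id%04d", seq_len(n))
  dimnames(genotypes) <- list(ids, variants$variant_id)
  p <- colMeans(genotypes) / 2
  variants$a1 <- "A"
  variants$a2 <- "C"
  variants$maf <- pmin(p, 1 - p)
  variants$dr2 <- 1

  subsets <- place_subsets(variants, config)
  list(genotypes = genotypes, variants = variants, subsets = subsets)
}

# one haplotype block: pool draw + per-individual mosaic sampling
sim_block <- function(n, m, n_hap, maf_floor, chr, block_id) {
  draw_col <- function() {
    p <- runif(1, min(0.45, max(0.15, 2 * maf_floor)), 0.5)
    as.integer(runif(n_hap) < p)
  }
  pool <- matrix(0L, nrow = n_hap, ncol = m)
  for (j in seq_len(m)) pool[, j] <- draw_col()
  h1 <- sample.int(n_hap, n, replace = TRUE)
  h2 <- sample.int(n_hap, n, replace = TRUE)
  G <- pool[h1, , drop = FALSE] + pool[h2, , drop = FALSE]
  for (j in seq_len(m)) {
    tries <- 0L
    repeat {
      f <- mean(G[, j]) / 2
      if (min(f, 1 - f) >= maf_floor) break
      tries <- tries + 1L
      if (tries > 25L) {
        abort(sprintf(
          "cannot reach MAF floor %.3f in chromosome %s block %s (haplotype pool too small or floor infeasible)",
          maf_floor, chr, block_id))
      }
      pool[, j] <- draw_col()
      G[, j] <- pool[h1, j] + pool[h2, j]
    }
  }
  G
}

place_subsets <- function(variants, config) {
  if (!length(config$subset_specs)) {
    return(tibble(subset = character(), variant_id = character(),
                  provenance = character()))
  }
  m <- nrow(variants)
  available <- rep(TRUE, m)
  out <- vector("list", length(config$subset_specs))
  for (k in seq_along(config$subset_specs)) {
    sp <- config$subset_specs[[k]]
    size <- if (sp$size < 1) round(sp$size * m) else as.integer(round(sp$size))
    placement <- sp$placement %||% "uniform"
    if (placement == "clustered") {
      runs <- rle(available)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      ok <- which(runs$values & runs$lengths >= size)
      if (!length(ok)) {
        abort(sprintf("no free run of %d variants for clustered subset '%s'",
                      size, sp$name))
      }
      r <- ok[sample.int(length(ok), 1)]
      start <- starts[r] + sample.int(runs$lengths[r] - size + 1L, 1) - 1L
      idx <- start:(start + size - 1L)
    } else {
      free <- which(available)
      if (length(free) < size) {
        abort(sprintf("not enough free variants for subset '%s'", sp$name))
      }
      idx <- sort(sample(free, size))
    }
    available[idx] <- FALSE
    out[[k]] <- tibble(subset = sp$name,
                       variant_id = variants$variant_id[idx],
                       provenance = "simulated")
  }
  dplyr::bind_rows(out)
}

#' Simulate one or two phenotypes under the two-component polygenic model
#'
#' Draws per-variant additive effects for a "chip" component (causal variants
#' outside the focal subset) and a "subset" component (causal variants inside
#' it) from a bivariate normal whose per-variant covariance matches the
#' configured component (co)variances, applies them to column-standardized
#' dosages, and adds correlated residuals:
#' \deqn{y_t = g_{chip,t} + g_{set,t} + e_t.}
#' Because genotypes are standardized, configured variances equal the expected
#' variance-component values recovered by REML. Trait-2 records are masked
#' missing at `missing_rate_trait2`.
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()].
#' @param variants Variant tibble from [simulate_genotypes()].
#' @param config A [sim_config()] object.
#' @param subsets Subset membership tibble (columns subset, variant_id);
#'   defaults to none, in which case `n_causal_subset` must be 0.
#' @return A list with `phenotypes` (tibble: individual_id, y1\[, y2\]),
#'   `truth` (tibble of per-individual component values g_chip/g_set/e per
#'   trait), `realized` (tibble of realized component variances, covariances,
#'   correlations and heritabilities computed from the drawn values) and
#'   `causal` (the sampled causal variant ids per component).
#' @export
simulate_phenotypes <- function(genotypes, variants, config, subsets = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 7919L))
  n <- nrow(genotypes)
  nt <- config$n_traits

  set_ids <- character()
  if (!is.null(subsets) && !is.null(config$causal_subset)) {
    set_ids <- subsets$variant_id[subsets$subset == config$causal_subset]
  }
  chip_pool <- setdiff(colnames(genotypes), set_ids)
  if (config$n_causal_chip > length(chip_pool)) {
    abort(sprintf(
      "n_causal_chip = %d exceeds the %d variants outside the causal subset",
      config$n_causal_chip, length(chip_pool)))
  }
  if (config$n_causal_subset > length(set_ids)) {
    abort(sprintf("n_causal_subset = %d exceeds the %d members of subset '%s'",
                  config$n_causal_subset, length(set_ids),
                  config$causal_subset %||% "<none>"))
  }
  chip_causal <- sort(sample(chip_pool, config$n_causal_chip))
  set_causal <- if (config$n_causal_subset > 0) {
    sort(sample(set_ids, config$n_causal_subset))
  } else {
    character()
  }

  comp_values <- function(causal, v, cv) {
    if (!length(causal) || v == 0) return(matrix(0, n, nt))
    Xs <- scale_dosages(genotypes[, causal, drop = FALSE])
    B <- draw_effects(length(causal), v, cv, nt)
    Xs %*% B
  }
  g_chip <- comp_values(chip_causal, config$var_g_chip, config$cov_g_chip)
  g_set <- comp_values(set_causal, config$var_g_subset, config$cov_g_subset)
  e <- draw_mvn(n, config$var_e, config$cov_e, nt)

  y <- g_chip + g_set + e
  pheno <- tibble(individual_id = rownames(genotypes), y1 = y[, 1])
  if (nt == 2) {
    y2 <- y[, 2]
    if (config$missing_rate_trait2 > 0) {
      y2[runif(n) < config$missing_rate_trait2] <- NA_real_
    }
    pheno$y2 <- y2
  }

  truth <- tibble(individual_id = rownames(genotypes))
  for (t in seq_len(nt)) {
    truth[[paste0("g_chip_", t)]] <- g_chip[, t]
    truth[[paste0("g_set_", t)]] <- g_set[, t]
    truth[[paste0("e_", t)]] <- e[, t]
  }
  realized <- realized_stats(g_chip, g_set, e, y, nt)
  list(phenotypes = pheno, truth = truth, realized = realized,
       causal = list(chip = chip_causal, subset = set_causal))
}

# center and scale dosage columns to unit variance (GCTA scaling)
scale_dosages <- function(X) {
  p <- colMeans(X) / 2
  sweep(sweep(X, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
}

draw_effects <- function(m, v, cv, nt) {
  if (nt == 1) return(matrix(rnorm(m, sd = sqrt(v / m)), m, 1))
  S <- matrix(c(v, cv, cv, v), 2) / m
  draw_from_cov(m, S)
}

draw_mvn <- function(n, v, cv, nt) {
  if (nt == 1) return(matrix(rnorm(n, sd = sqrt(v)), n, 1))
  draw_from_cov(n, matrix(c(v, cv, cv, v), 2))
}

draw_from_cov <- function(n, S) {
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    abort("effect covariance matrix is not positive semidefinite")
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(S)) %*% t(ev$vectors)
  matrix(rnorm(n * nrow(S)), n) %*% L
}

realized_stats <- function(g_chip, g_set, e, y, nt) {
  comp <- list(chip = g_chip, set = g_set, residual = e)
  purrr::map_dfr(names(comp), function(nm) {
    M <- comp[[nm]]
    r <- tibble(component = nm,
                var_1 = var(M[, 1]),
                h2_1 = if (nm == "residual") NA_real_ else
                  var(M[, 1]) / var(y[, 1]))
    if (nt == 2) {
      r$var_2 <- var(M[, 2])
      r$cov_12 <- cov(M[, 1], M[, 2])
      r$cor_12 <- if (r$var_1 > 0 && r$var_2 > 0) {
        r$cov_12 / sqrt(r$var_1 * r$var_2)
      } else {
        NA_real_
      }
      r$h2_2 <- if (nm == "residual") NA_real_ else var(M[, 2]) / var(y[, 2])
    }
    r
  })
}

#' Write/read a PLINK- and GCTA-style phenotype file
#'
#' Whitespace-delimited `FID IID y1 [y2]` with `NA` for missing values; family
#' ID is taken equal to the individual ID.
#'
#' @param phenotypes Tibble with `individual_id` and trait columns.
#' @param path Output file path.
#' @return `write_phenotypes()` returns `path` invisibly; `read_phenotypes()`
#'   returns a tibble with `individual_id` and `y1`\[, `y2`\] columns.
#' @export
write_phenotypes <- function(phenotypes, path) {
  traits <- setdiff(names(phenotypes), "individual_id")
  df <- data.frame(FID = phenotypes$individual_id,
                   IID = phenotypes$individual_id,
                   phenotypes[traits], check.names = FALSE)
  write.table(df, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  nt <- ncol(df) - 2L
  stopifnot(nt >= 1)
  out <- tibble(individual_id = as.character(df[[2]]))
  for (t in seq_len(nt)) out[[paste0("y", t)]] <- as.numeric(df[[2 + t]])
  out
}
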