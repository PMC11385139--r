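# Synthetic fit objects with known components and sampling covariance let
# every derived statistic be checked against hand arithmetic and against a
# Monte-Carlo standard-error oracle that never touches the delta method.

make_uni_fit <- function(est, vcov, terms) {
  nm <- names(est)
  dimnames(vcov) <- list(nm, nm)
  structure(list(components = tibble::tibble(term = nm,
                                             estimate = unname(est),
                                             se = sqrt(diag(vcov)),
                                             pinned = FALSE),
                 vcov = vcov, terms = terms, converged = TRUE,
                 loglik_trace = 0, n_iterations = 1L,
                 n_records = 10L, trait = "y1",
                 phenotypic_variance = sum(est)),
            class = "uni_fit")
}

make_bi_fit <- function(est, vcov, terms) {
  nm <- as.vector(t(outer(terms2 <- c(terms, "residual"),
                          c(":var1", ":var2", ":cov12"), paste0)))
  names(est) <- nm
  dimnames(vcov) <- list(nm, nm)
  structure(list(components = tibble::tibble(term = rep(terms2, each = 3),
                                             trait = rep(c("1", "2", "12"),
                                                         length(terms2)),
                                             estimate = unname(est),
                                             se = sqrt(diag(vcov)),
                                             pinned = FALSE,
                                             at_bound = FALSE),
                 vcov = vcov, terms = terms, converged = TRUE,
                 loglik_trace = 0, n_iterations = 1L,
                 n_records = c(trait1 = 10L, trait2 = 10L, both = 10L),
                 traits = c("y1", "y2")),
            class = "bi_fit")
}

mc_se <- function(est, vcov, fun, B = 6000, seed = 99) {
  set.seed(seed)
  L <- t(chol(vcov))
  draws <- replicate(B, fun(est + as.numeric(L %*% rnorm(length(est)))))
  sd(draws)
}

test_that("two-GRM heritabilities are the component shares of the total", {
  est <- c(set = 0.1, chip = 0.3, residual = 0.6)
  vcov <- diag(c(4e-4, 9e-4, 1e-3))
  fit <- make_uni_fit(est, vcov, c("set", "chip"))
  h2 <- heritabilities(fit)
  expect_equal(h2$statistic, c("h2_set", "h2_chip"))
  expect_equal(h2$estimate, c(0.1, 0.3))

  one <- make_uni_fit(c(g = 0.4, residual = 0.6), diag(c(1e-3, 1e-3)), "g")
  expect_equal(heritabilities(one)$estimate, 0.4)
  expect_equal(heritabilities(one)$statistic, "h2")
})

test_that("heritability delta SEs agree with a Monte-Carlo oracle", {
  est <- c(set = 0.12, chip = 0.31, residual = 0.55)
  vcov <- matrix(c(4, 1, -1, 1, 9, -2, -1, -2, 12), 3) * 1e-4
  fit <- make_uni_fit(est, vcov, c("set", "chip"))
  h2 <- heritabilities(fit)
  se_set <- mc_se(est, vcov, function(th) th[1] / sum(th))
  se_chip <- mc_se(est, vcov, function(th) th[2] / sum(th))
  expect_equal(h2$se[h2$statistic == "h2_set"], se_set, tolerance = 0.25)
  expect_equal(h2$se[h2$statistic == "h2_chip"], se_chip, tolerance = 0.25)
})

test_that("genetic correlations are the covariance over the geometric mean", {
  est <- c(0.4, 0.3, -0.17, 0.5, 0.6, 0.1)
  vcov <- diag(6) * 2e-4
  fit <- make_bi_fit(est, vcov, "g")
  rg <- genetic_correlations(fit)
  expect_equal(rg$estimate[rg$term == "g"], -0.17 / sqrt(0.4 * 0.3))
  expect_equal(rg$estimate[rg$term == "residual"], 0.1 / sqrt(0.5 * 0.6))
  expect_false(any(rg$clamped))

  se_oracle <- mc_se(est, vcov, function(th) th[3] / sqrt(th[1] * th[2]))
  expect_equal(rg$se[rg$term == "g"], se_oracle, tolerance = 0.25)
})

test_that("out-of-range and degenerate correlations are flagged, not errors", {
  est <- c(0.1, 0.1, 0.2, 0.5, 0.6, 0.1)  # |r_g| = 2
  fit <- make_bi_fit(est, diag(6) * 1e-4, "g")
  rg <- genetic_correlations(fit)
  expect_equal(rg$estimate[rg$term == "g"], 1)
  expect_true(rg$clamped[rg$term == "g"])

  est2 <- c(0, 0.1, 0.0, 0.5, 0.6, 0.1)
  fit2 <- make_bi_fit(est2, diag(6) * 1e-4, "g")
  rg2 <- genetic_correlations(fit2)
  expect_true(is.na(rg2$estimate[rg2$term == "g"]))
  expect_match(rg2$note[rg2$term == "g"], "non-positive")
})

test_that("relative covariances keep signs and their magnitudes sum to one", {
  est <- c(0.4, 0.3, -0.05, 0.2, 0.3, -0.06,
           0.5, 0.6, 0.12)
  vcov <- diag(9) * 1e-4
  fit <- make_bi_fit(est, vcov, c("set", "chip"))
  rc <- relative_covariances(fit)
  denom <- 0.05 + 0.06 + 0.12
  expect_equal(rc$estimate, c(-0.05, -0.06, 0.12) / denom)
  expect_equal(sum(abs(rc$estimate)), 1)

  # scaling every covariance by the same positive factor changes nothing
  est2 <- est
  est2[c(3, 6, 9)] <- 3 * est[c(3, 6, 9)]
  rc2 <- relative_covariances(make_bi_fit(est2, vcov, c("set", "chip")))
  expect_equal(rc2$estimate, rc$estimate)

  se_oracle <- mc_se(est, vcov, function(th) {
    th[3] / (abs(th[3]) + abs(th[6]) + abs(th[9]))
  })
  expect_equal(rc$estimate[rc$term == "set"], -0.05 / denom)
  expect_equal(rc$se[rc$term == "set"], se_oracle, tolerance = 0.25)
})

test_that("all-zero covariances give NA relative covariances with a note", {
  est <- c(0.4, 0.3, 0, 0.5, 0.6, 0)
  fit <- make_bi_fit(est, diag(6) * 1e-4, "g")
  rc <- relative_covariances(fit)
  expect_true(all(is.na(rc$estimate)))
  expect_match(rc$note[1], "zero")
})

test_that("per-variant summaries reproduce published worked examples", {
  extdata <- system.file("extdata", package = "h2part")
  chip <- read.delim(file.path(extdata, "chip_estimates.tsv"))
  sizes_tbl <- read.delim(file.path(extdata, "subset_sizes.tsv"))
  rg_ex <- read.delim(file.path(extdata, "subset_rg_examples.tsv"))
  sizes <- setNames(sizes_tbl$n_variants, sizes_tbl$subset)

  h2 <- tibble::tibble(subset = "chip", trait = chip$abbreviation,
                       h2 = chip$h2)
  rg <- tibble::tibble(subset = rg_ex$subset, trait_pair = rg_ex$trait_pair,
                       rg = rg_ex$rg)
  out <- per_variant_summary(h2 = h2, rg = rg, subset_sizes = sizes)

  across <- out$value[out$statistic == "across_trait_per_variant_h2"]
  expect_equal(across, 3.409e-06, tolerance = 1e-4)
  # and the independent recomputation: sum of the nine h2 / (9 * 44126)
  expect_equal(across, sum(chip$h2) / (9 * 44126), tolerance = 1e-12)

  pv_rg <- out[out$statistic == "per_variant_rg", ]
  expect_equal(pv_rg$value[pv_rg$subset == "chip"], -2.516e-07,
               tolerance = 1e-4)
  expect_equal(pv_rg$value[pv_rg$subset == "noncoding_related"], 2.089e-04,
               tolerance = 1e-4)
  abs_rg <- out[out$statistic == "per_variant_rg_abs", ]
  expect_equal(abs_rg$value[abs_rg$subset == "chip"], 2.516e-07,
               tolerance = 1e-4)
})

test_that("per-variant values are linear in the inverse subset size", {
  h2 <- tibble::tibble(subset = rep(c("a", "b"), each = 2),
                       trait = rep(c("t1", "t2"), 2),
                       h2 = c(0.2, 0.1, 0.2, 0.1))
  out1 <- per_variant_summary(h2 = h2, subset_sizes = c(a = 100, b = 100))
  out2 <- per_variant_summary(h2 = h2, subset_sizes = c(a = 100, b = 200))
  v1 <- out1[out1$statistic == "across_trait_per_variant_h2", ]
  v2 <- out2[out2$statistic == "across_trait_per_variant_h2", ]
  expect_equal(v1$value[v1$subset == "a"], v2$value[v2$subset == "a"])
  expect_equal(v1$value[v1$subset == "b"], 2 * v2$value[v2$subset == "b"])
  expect_equal(v1$value[v1$subset == "a"], 0.3 / (2 * 100))
})

test_that("subsets missing a trait get NA across-trait values with a note", {
  h2 <- tibble::tibble(subset = c("a", "a", "b"),
                       trait = c("t1", "t2", "t1"),
                       h2 = c(0.2, 0.1, 0.3))
  out <- per_variant_summary(h2 = h2, subset_sizes = c(a = 10, b = 10))
  across <- out[out$statistic == "across_trait_per_variant_h2", ]
  expect_false(is.na(across$value[across$subset == "a"]))
  expect_true(is.na(across$value[across$subset == "b"]))
  expect_match(across$note[across$subset == "b"], "1 of 2")
  expect_error(per_variant_summary(h2 = h2, subset_sizes = c(a = 10)),
               "missing")
  expect_error(per_variant_summary(h2 = h2, subset_sizes = c(a = 10, b = 0)),
               "positive")
})

test_that("the two-standard-error rule matches published significance calls", {
  # a clearly significant and a clearly non-significant published pair
  expect_true(significance_flag(-0.4558, 0.1070))
  expect_false(significance_flag(-0.0111, 0.0387))
  # inclusive boundary and degenerate SEs
  expect_true(significance_flag(0.2, 0.1))
  expect_false(significance_flag(0.19999, 0.1))
  expect_true(is.na(significance_flag(0.5, 0)))
  expect_true(is.na(significance_flag(0.5, NA)))
  expect_equal(significance_flag(c(1, 0.1), c(0.4, 0.4)), c(TRUE, FALSE))
})

test_that("derived statistics from a real two-GRM fit are internally consistent", {
  fx <- small_sim()
  set_ids <- subset_members(fx$sim$subsets, "set1")
  grm <- compute_grm(fx$sim$genotypes, set_ids)
  chip <- compute_grm(fx$sim$genotypes,
                      setdiff(colnames(fx$sim$genotypes), set_ids))
  fit <- fit_bivariate(fx$pheno$phenotypes, list(set = grm, chip = chip))
  comp <- fit$components
  rg <- genetic_correlations(fit)
  rc <- relative_covariances(fit)
  for (tm in c("set", "chip", "residual")) {
    v1 <- comp$estimate[comp$term == tm & comp$trait == "1"]
    v2 <- comp$estimate[comp$term == tm & comp$trait == "2"]
    c12 <- comp$estimate[comp$term == tm & comp$trait == "12"]
    expect_equal(rg$estimate[rg$term == tm],
                 max(min(c12 / sqrt(v1 * v2), 1), -1), tolerance = 1e-12)
  }
  expect_equal(sum(abs(rc$estimate)), 1, tolerance = 1e-12)

  uni <- fit_univariate(fx$pheno$phenotypes, list(set = grm, chip = chip))
  h2 <- heritabilities(uni)
  tot <- sum(uni$components$estimate)
  expect_equal(h2$estimate,
               uni$components$estimate[match(c("set", "chip"),
                                             uni$components$term)] / tot,
               tolerance = 1e-12)
})
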