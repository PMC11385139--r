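#' Heritabilities from a univariate REML fit
#'
#' For a two-GRM (subset + chip) fit the subset heritability is
#' \deqn{h^2_{set} = \sigma^2_{g,set} / (\sigma^2_{g,set} +
#'   \sigma^2_{g,50K} + \sigma^2_e)}
#' and the chip heritability the analogous ratio for the chip component; a
#' single-GRM fit returns the usual \eqn{h^2 = \sigma^2_g / (\sigma^2_g +
#' \sigma^2_e)}. Standard errors use the first-order delta method on the
#' fit's sampling covariance matrix. A non-converged fit is still summarized
#' but flagged.
#'
#' @param fit A `uni_fit` from [fit_univariate()].
#' @return A tibble with columns `statistic` (`"h2"` for one GRM, or
#'   `"h2_<term>"` per genetic term), `estimate`, `se`, `converged`.
#' @export
heritabilities <- function(fit) {
  stopifnot(inherits(fit, "uni_fit"))
  v <- fit$components$estimate
  names(v) <- fit$components$term
  total <- sum(v)
  if (total <= 0) abort("total variance is zero; heritability undefined")
  gen_terms <- fit$terms
  purrr::map_dfr(gen_terms, function(tm) {
    grad <- (as.numeric(names(v) == tm) * total - v[tm]) / total^2
    tibble(statistic = if (length(gen_terms) == 1) "h2" else paste0("h2_", tm),
           estimate = unname(v[tm] / total),
           se = delta_se(grad, fit$vcov),
           converged = fit$converged)
  })
}

#' Genetic (and residual) correlations from a bivariate REML fit
#'
#' For each random term with trait variances \eqn{\sigma^2_1, \sigma^2_2}
#' and covariance \eqn{\sigma_{12}}, the correlation is
#' \eqn{r = \sigma_{12} / \sqrt{\sigma^2_1 \sigma^2_2}} with a delta-method
#' standard error. Estimates outside \eqn{[-1, 1]} are clamped and flagged.
#' A term with a non-positive variance yields `NA` with the reason in `note`
#' rather than an error.
#'
#' @param fit A `bi_fit` from [fit_bivariate()].
#' @return A tibble with columns `term`, `estimate`, `se`, `clamped`,
#'   `note`, `converged`; genetic terms first, residual last.
#' @export
genetic_correlations <- function(fit) {
  stopifnot(inherits(fit, "bi_fit"))
  comp <- fit$components
  terms <- unique(comp$term)
  purrr::map_dfr(terms, function(tm) {
    v1 <- comp$estimate[comp$term == tm & comp$trait == "1"]
    v2 <- comp$estimate[comp$term == tm & comp$trait == "2"]
    c12 <- comp$estimate[comp$term == tm & comp$trait == "12"]
    if (v1 <= 0 || v2 <= 0) {
      return(tibble(term = tm, estimate = NA_real_, se = NA_real_,
                    clamped = FALSE,
                    note = "non-positive variance component",
                    converged = fit$converged))
    }
    r <- c12 / sqrt(v1 * v2)
    pn <- paste0(tm, c(":var1", ":var2", ":cov12"))
    grad <- setNames(numeric(nrow(comp)), rownames(fit$vcov))
    grad[pn[1]] <- -c12 / (2 * v1 * sqrt(v1 * v2))
    grad[pn[2]] <- -c12 / (2 * v2 * sqrt(v1 * v2))
    grad[pn[3]] <- 1 / sqrt(v1 * v2)
    clamped <- abs(r) > 1
    tibble(term = tm, estimate = max(min(r, 1), -1),
           se = delta_se(grad, fit$vcov),
           clamped = clamped,
           note = if (clamped) "clamped to [-1, 1]" else NA_character_,
           converged = fit$converged)
  })
}

#' Relative covariances from a bivariate REML fit
#'
#' Each between-trait covariance (per genetic term and residual) is divided
#' by the sum of the absolute values of all the covariances, keeping its own
#' sign:
#' \deqn{relcov_k = \sigma_{k,12} / \sum_l |\sigma_{l,12}|.}
#' The absolute values therefore sum to one. All covariances exactly zero
#' yields `NA` values with the reason in `note`.
#'
#' @param fit A `bi_fit` from [fit_bivariate()].
#' @return A tibble with columns `term`, `covariance`, `estimate` (the
#'   relative covariance), `se` (delta method), `note`, `converged`.
#' @export
relative_covariances <- function(fit) {
  stopifnot(inherits(fit, "bi_fit"))
  comp <- fit$components
  terms <- unique(comp$term)
  covs <- unname(vapply(terms, function(tm) {
    comp$estimate[comp$term == tm & comp$trait == "12"]
  }, numeric(1)))
  denom <- sum(abs(covs))
  if (denom == 0) {
    return(tibble(term = terms, covariance = covs, estimate = NA_real_,
                  se = NA_real_, note = "all covariances are zero",
                  converged = fit$converged))
  }
  purrr::map_dfr(seq_along(terms), function(k) {
    pn <- paste0(terms, ":cov12")
    grad <- setNames(numeric(nrow(comp)), rownames(fit$vcov))
    for (l in seq_along(terms)) {
      grad[pn[l]] <- ((l == k) * denom - covs[k] * sign(covs[l])) / denom^2
    }
    tibble(term = terms[k], covariance = covs[k],
           estimate = covs[k] / denom,
           se = delta_se(grad, fit$vcov),
           note = NA_character_, converged = fit$converged)
  })
}

delta_se <- function(grad, vcov) {
  g <- as.numeric(grad)
  sqrt(max(0, g %*% vcov %*% g))
}

#' Per-variant heritability and correlation summaries
#'
#' Scales subset-level estimates by subset size so that subsets of very
#' different variant counts become comparable:
#' * across-trait per-variant \eqn{h^2}: the sum of a subset's per-trait
#'   \eqn{h^2_{set}} estimates divided by the number of traits and the
#'   number of variants in the subset;
#' * trait-specific per-variant \eqn{h^2}: each \eqn{h^2_{set}} divided by
#'   the variant count;
#' * trait-specific per-variant \eqn{r_g}: each genetic correlation divided
#'   by the variant count, reported signed with the absolute value alongside
#'   (no across-trait version: correlations of mixed sign do not sum
#'   meaningfully).
#'
#' @param h2 Tibble of heritability estimates with columns `subset`, `trait`,
#'   `h2` (one row per subset x trait), or `NULL`.
#' @param rg Tibble of genetic correlations with columns `subset`,
#'   `trait_pair`, `rg`, or `NULL`.
#' @param subset_sizes Named numeric vector: variant count per subset.
#' @param n_traits Number of traits the across-trait average divides by
#'   (default: distinct traits present in `h2`).
#' @return A long tibble with columns `subset`, `trait` (or trait pair; `NA`
#'   for across-trait rows), `statistic`, `value`, `note`. Subsets missing a
#'   trait estimate get `NA` across-trait values with the reason in `note`.
#' @export
per_variant_summary <- function(h2 = NULL, rg = NULL, subset_sizes,
                                n_traits = NULL) {
  if (any(subset_sizes <= 0)) abort("subset sizes must be positive")
  out <- list()
  if (!is.null(h2)) {
    n_traits <- n_traits %||% dplyr::n_distinct(h2$trait)
    sizes <- unname(subset_sizes[h2$subset])
    if (anyNA(sizes)) abort("subset size missing for some h2 rows")
    out$trait_h2 <- tibble(subset = h2$subset, trait = h2$trait,
                           statistic = "per_variant_h2",
                           value = h2$h2 / sizes, note = NA_character_)
    out$across <- h2 |>
      dplyr::group_by(.data$subset) |>
      dplyr::summarise(n_est = dplyr::n(), total = sum(.data$h2),
                       .groups = "drop") |>
      dplyr::mutate(
        trait = NA_character_,
        statistic = "across_trait_per_variant_h2",
        value = ifelse(.data$n_est == n_traits,
                       .data$total /
                         (n_traits * unname(subset_sizes[.data$subset])),
                       NA_real_),
        note = ifelse(.data$n_est == n_traits, NA_character_,
                      sprintf("only %d of %d trait estimates available",
                              .data$n_est, n_traits))) |>
      dplyr::select("subset", "trait", "statistic", "value", "note")
  }
  if (!is.null(rg)) {
    sizes <- unname(subset_sizes[rg$subset])
    if (anyNA(sizes)) abort("subset size missing for some rg rows")
    out$rg <- tibble(subset = rep(rg$subset, 2),
                     trait = rep(rg$trait_pair, 2),
                     statistic = rep(c("per_variant_rg",
                                       "per_variant_rg_abs"), each = nrow(rg)),
                     value = c(rg$rg / sizes, abs(rg$rg) / sizes),
                     note = NA_character_)
  }
  dplyr::bind_rows(out)
}

#' Two-standard-error significance rule
#'
#' An estimate is flagged significant when its magnitude is at least twice
#' its standard error (inclusive boundary). A non-positive standard error
#' yields `NA` rather than an error.
#'
#' @param estimate,se Numeric vectors (recycled to common length).
#' @return Logical vector; `NA` where `se <= 0` or missing.
#' @export
#' @examples
#' significance_flag(c(-0.4558, -0.0111, 0.2), c(0.1070, 0.0387, 0.1))
significance_flag <- function(estimate, se) {
  ifelse(is.na(se) | se <= 0, NA, abs(estimate) >= 2 * se)
}
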