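#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_errorbar
#'   geom_hline geom_line labs facet_wrap position_dodge
NULL

#' @export
ggplot2::autoplot

#' Component plot of a univariate REML fit
#'
#' Variance components with approximate 2-SE error bars.
#'
#' @param object A `uni_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uni_fit <- function(object, ...) {
  d <- object$components
  ggplot(d, aes(x = .data$term, y = .data$estimate)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$estimate - 2 * .data$se,
                      ymax = .data$estimate + 2 * .data$se), width = 0.2) +
    labs(x = NULL, y = "variance component",
         title = "Univariate REML components (±2 SE)")
}

#' Component plot of a bivariate REML fit
#'
#' (Co)variance components per random term and trait pair with 2-SE bars.
#'
#' @param object A `bi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bi_fit <- function(object, ...) {
  d <- object$components
  d$trait <- factor(d$trait, levels = c("1", "2", "12"),
                    labels = c("trait 1", "trait 2", "covariance"))
  ggplot(d, aes(x = .data$term, y = .data$estimate, fill = .data$trait)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$estimate - 2 * .data$se,
                      ymax = .data$estimate + 2 * .data$se),
                  position = position_dodge(width = 0.8), width = 0.2) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    labs(x = NULL, y = "(co)variance component", fill = NULL,
         title = "Bivariate REML components (±2 SE)")
}

#' Stacked relative-covariance bars
#'
#' Shows how the between-trait covariance splits across the chip, subset and
#' residual terms (signed shares whose absolute values sum to one).
#'
#' @param relcov Output of [relative_covariances()], optionally row-bound
#'   over several fits with an extra `subset` column.
#' @return A ggplot object.
#' @export
plot_relative_covariance <- function(relcov) {
  p <- ggplot(relcov, aes(x = if ("subset" %in% names(relcov))
    .data$subset else "fit",
    y = .data$estimate, fill = .data$term)) +
    geom_col() +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    labs(x = NULL, y = "relative covariance", fill = NULL,
         title = "Covariance shares by term")
  p
}

#' LD decay curve from a pair list
#'
#' Mean r-squared in distance bins, by intern/extern pair class.
#'
#' @param pairs Output of [ld_pairs()].
#' @param bin_bp Bin width in base pairs.
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(pairs, bin_bp = 25000) {
  d <- pairs |>
    dplyr::mutate(bin = (ceiling(.data$distance / bin_bp) - 0.5) * bin_bp) |>
    dplyr::group_by(.data$class, .data$bin) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), .groups = "drop")
  ggplot(d, aes(x = .data$bin / 1000, y = .data$mean_r2,
                colour = .data$class)) +
    geom_line() + geom_point() +
    labs(x = "distance (kbp)", y = expression(mean ~ r^2), colour = NULL,
         title = "LD decay by pair class")
}
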