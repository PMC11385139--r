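#' Enumerate LD pairs around the variants of a subset
#'
#' For every subset variant, forms its pairs with all other variants on the
#' same chromosome within `window_bp` base pairs and computes the squared
#' Pearson correlation of the dosage vectors (composite, unphased LD). A
#' pair of two subset variants is classed `"intern"` and emitted once; a
#' subset/non-subset pair is classed `"extern"`.
#'
#' @param genotypes Dosage matrix whose columns match `variants$variant_id`.
#' @param variants Variant tibble (`variant_id`, `chromosome`, `position`).
#' @param subset Character vector of subset member variant ids.
#' @param window_bp Window in base pairs (default 500 kbp).
#' @return A tibble with columns `chromosome`, `id_a`, `pos_a`, `id_b`,
#'   `pos_b`, `distance`, `r2`, `class`, each unordered pair appearing once.
#' @export
ld_pairs <- function(genotypes, variants, subset, window_bp = 500000) {
  stopifnot(length(subset) >= 1, window_bp > 0)
  in_subset <- variants$variant_id %in% subset
  rows <- list()
  for (chr in unique(variants$chromosome)) {
    idx <- which(variants$chromosome == chr)
    idx <- idx[order(variants$position[idx])]
    pos <- variants$position[idx]
    ids <- variants$variant_id[idx]
    sub <- in_subset[idx]
    if (!any(sub)) next
    Xc <- scale(genotypes[, ids, drop = FALSE])
    n <- nrow(Xc)
    m <- length(idx)
    for (a in seq_len(m - 1)) {
      b_range <- which(pos > pos[a] & pos - pos[a] <= window_bp)
      if (!length(b_range)) next
      keep <- sub[a] | sub[b_range]
      b_range <- b_range[keep]
      if (!length(b_range)) next
      r <- crossprod(Xc[, a], Xc[, b_range, drop = FALSE]) / (n - 1)
      rows[[length(rows) + 1]] <- tibble(
        chromosome = chr,
        id_a = ids[a], pos_a = pos[a],
        id_b = ids[b_range], pos_b = pos[b_range],
        distance = pos[b_range] - pos[a],
        r2 = as.numeric(r)^2,
        class = ifelse(sub[a] & sub[b_range], "intern", "extern"))
    }
  }
  if (!length(rows)) {
    return(tibble(chromosome = character(), id_a = character(),
                  pos_a = integer(), id_b = character(), pos_b = integer(),
                  distance = integer(), r2 = numeric(), class = character()))
  }
  dplyr::bind_rows(rows)
}

#' Six LD/MAF/distribution parameters of a variant subset
#'
#' From the pair list of [ld_pairs()]:
#' * `mean_ld_extern` / `mean_ld_intern`: mean \eqn{r^2} over extern /
#'   intern pairs;
#' * `decay_extern` / `decay_intern`: mean \eqn{r^2} of pairs at distance in
#'   `(far_lo_bp, far_hi_bp]` divided by the mean \eqn{r^2} of pairs at
#'   distance in `(0, near_bp]` (within the same class); values above 1 are
#'   legal and indicate LD rising with distance;
#' * `distribution`: intern pair count over total pair count -- 1 when the
#'   subset has no extern pairs in the window, lower when its variants sit
#'   among many non-members;
#' * `mean_maf`: mean sample MAF of the subset members.
#'
#' Empty strata give `NA` with the reason in `note`, never a silent zero.
#'
#' @param pairs Pair tibble from [ld_pairs()].
#' @param variants Variant tibble with `maf`.
#' @param subset Character vector of subset member variant ids.
#' @param near_bp,far_lo_bp,far_hi_bp Distance strata bounds in base pairs
#'   (defaults 25 kbp and 120-500 kbp; half-open upper intervals).
#' @return A tibble with columns `metric`, `value`, `n`, `note`.
#' @export
ld_subset_metrics <- function(pairs, variants, subset, near_bp = 25000,
                              far_lo_bp = 120000, far_hi_bp = 500000) {
  mean_or_na <- function(x, what) {
    if (length(x) == 0) {
      list(value = NA_real_, n = 0L, note = paste0("no ", what))
    } else {
      list(value = mean(x), n = length(x), note = NA_character_)
    }
  }
  one_class <- function(cl) {
    r2 <- pairs$r2[pairs$class == cl]
    d <- pairs$distance[pairs$class == cl]
    m <- mean_or_na(r2, paste0(cl, " pairs"))
    near <- r2[d > 0 & d <= near_bp]
    far <- r2[d > far_lo_bp & d <= far_hi_bp]
    decay <- if (!length(near)) {
      list(value = NA_real_, n = 0L,
           note = paste0("no ", cl, " pairs in near stratum"))
    } else if (!length(far)) {
      list(value = NA_real_, n = 0L,
           note = paste0("no ", cl, " pairs in far stratum"))
    } else if (mean(near) == 0) {
      list(value = NA_real_, n = length(far),
           note = paste0("near-stratum mean r2 is zero for ", cl))
    } else {
      list(value = mean(far) / mean(near), n = length(far),
           note = NA_character_)
    }
    list(mean = m, decay = decay)
  }
  ext <- one_class("extern")
  int <- one_class("intern")
  n_int <- sum(pairs$class == "intern")
  n_tot <- nrow(pairs)
  distribution <- if (n_tot == 0) {
    list(value = NA_real_, n = 0L, note = "no pairs at all")
  } else {
    list(value = n_int / n_tot, n = n_tot, note = NA_character_)
  }
  mafs <- variants$maf[variants$variant_id %in% subset]
  maf <- mean_or_na(mafs, "subset members with MAF")

  vals <- list(mean_ld_extern = ext$mean, mean_ld_intern = int$mean,
               decay_extern = ext$decay, decay_intern = int$decay,
               distribution = distribution, mean_maf = maf)
  tibble(metric = names(vals),
         value = unname(vapply(vals, `[[`, numeric(1), "value")),
         n = unname(vapply(vals, `[[`, integer(1), "n")),
         note = unname(vapply(vals, `[[`, character(1), "note")))
}

#' Correlate subset LD parameters with per-variant heritability
#'
#' Pearson correlation, across subsets, between each of the six LD/MAF/
#' distribution parameters and the across-trait per-variant \eqn{h^2}.
#' Subsets missing either quantity are dropped per parameter; fewer than 3
#' complete subsets, or a parameter constant across subsets, yields `NA`
#' with the reason in `note`.
#'
#' @param metrics Long tibble with columns `subset`, `metric`, `value`
#'   (e.g. row-bound [ld_subset_metrics()] outputs).
#' @param per_variant_h2 Tibble with columns `subset`, `value`.
#' @return A tibble with columns `metric`, `r`, `n`, `note`.
#' @export
ld_metric_correlations <- function(metrics, per_variant_h2) {
  purrr::map_dfr(unique(metrics$metric), function(mt) {
    sub <- metrics[metrics$metric == mt, c("subset", "value")]
    joined <- dplyr::inner_join(sub, per_variant_h2, by = "subset",
                                suffix = c("_metric", "_h2"))
    joined <- joined[stats::complete.cases(joined), ]
    if (nrow(joined) < 3) {
      return(tibble(metric = mt, r = NA_real_, n = nrow(joined),
                    note = "fewer than 3 subsets with complete data"))
    }
    if (sd(joined$value_metric) == 0 || sd(joined$value_h2) == 0) {
      return(tibble(metric = mt, r = NA_real_, n = nrow(joined),
                    note = "zero variance across subsets"))
    }
    tibble(metric = mt, r = cor(joined$value_metric, joined$value_h2),
           n = nrow(joined), note = NA_character_)
  })
}
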