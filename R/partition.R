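#' Filter a variant table on MAF, imputation quality and chromosome
#'
#' Retains variants with `maf >= maf_min`, `dr2 >= dr2_min` and (optionally)
#' an autosomal chromosome label (any label that is a plain integer). Row
#' order is preserved. Counts of variants removed by each rule are reported
#' via a message and the `removals` attribute.
#'
#' @param variants Variant tibble with `maf` and optionally `dr2` (missing
#'   `dr2` is treated as 1, i.e. directly genotyped) and `chromosome`.
#' @param maf_min Minimum minor allele frequency (chip default 0.01,
#'   sequence default 0.05).
#' @param dr2_min Minimum dosage R-squared imputation quality.
#' @param autosomes_only Drop variants on non-numeric chromosome labels
#'   (X, Y, MT, ...).
#' @return The filtered tibble; errors if no variant survives.
#' @export
filter_variants <- function(variants, maf_min = 0.05, dr2_min = 0.75,
                            autosomes_only = TRUE) {
  dr2 <- variants$dr2 %||% rep(1, nrow(variants))
  dr2[is.na(dr2)] <- 1
  keep_maf <- variants$maf >= maf_min
  keep_dr2 <- dr2 >= dr2_min
  keep_chr <- if (autosomes_only) {
    grepl("^[0-9]+$", as.character(variants$chromosome))
  } else {
    rep(TRUE, nrow(variants))
  }
  removals <- c(maf = sum(!keep_maf),
                dr2 = sum(keep_maf & !keep_dr2),
                sex_chromosome = sum(keep_maf & keep_dr2 & !keep_chr))
  out <- variants[keep_maf & keep_dr2 & keep_chr, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("no variants survive filtering (check maf_min/dr2_min)")
  }
  inform(sprintf(
    "filter_variants: removed %d (MAF < %g), %d (DR2 < %g), %d (sex chromosome); %d retained",
    removals[["maf"]], maf_min, removals[["dr2"]], dr2_min,
    removals[["sex_chromosome"]], nrow(out)))
  attr(out, "removals") <- removals
  out
}

#' Windowed LD scores and variant density
#'
#' For each variant i the LD score is \eqn{1 + \sum_j r^2(i, j)} over all
#' other variants j on the same chromosome within `window_bp` base pairs
#' (inclusive boundary), where \eqn{r^2} is the squared Pearson correlation
#' of unphased dosage vectors. The self term is included, so an isolated
#' variant scores 1. `snp_num` counts the variants in the window, index
#' variant included (the variant-density measure).
#'
#' @param genotypes Dosage matrix whose columns match `variants$variant_id`.
#' @param variants Variant tibble (chromosome, position).
#' @param window_bp Window half-width in base pairs (default 50 kbp).
#' @return `variants` with `ld_score`, `snp_num` and `maf` columns filled.
#' @export
compute_ld_scores <- function(genotypes, variants, window_bp = 50000) {
  stopifnot(window_bp > 0)
  genotypes <- genotypes[, variants$variant_id, drop = FALSE]
  sds <- apply(genotypes, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance dosage column(s): %s",
                  paste(head(colnames(genotypes)[sds == 0], 5), collapse = ", ")))
  }
  ld <- rep(1, nrow(variants))
  nsnp <- rep(1L, nrow(variants))
  for (chr in unique(variants$chromosome)) {
    idx <- which(variants$chromosome == chr)
    ord <- idx[order(variants$position[idx])]
    pos <- variants$position[ord]
    Xc <- scale(genotypes[, ord, drop = FALSE])
    n <- nrow(Xc)
    for (a in seq_along(ord)) {
      nb <- which(abs(pos - pos[a]) <= window_bp)
      nb <- nb[nb != a]
      nsnp[ord[a]] <- 1L + length(nb)
      if (length(nb)) {
        r <- crossprod(Xc[, a], Xc[, nb, drop = FALSE]) / (n - 1)
        ld[ord[a]] <- 1 + sum(r^2)
      }
    }
  }
  variants$ld_score <- ld
  variants$snp_num <- nsnp
  p <- colMeans(genotypes) / 2
  variants$maf <- pmin(p, 1 - p)
  variants
}

quartile_prefix <- c(ld_score = "LD", snp_num = "VD", maf = "MAF")

#' Rank-based quartile subsets of a variant field
#'
#' Ranks variants ascending on the chosen field (ties broken by chromosome
#' then position, i.e. genome order) and splits them into four rank groups
#' whose sizes differ by at most one (larger groups come first when the
#' count is not divisible by four). Subset names are `LD1..LD4`, `VD1..VD4`
#' or `MAF1..MAF4`, quartile 1 holding the lowest values. With
#' `drop_lowest = TRUE` quartile 1 is omitted (used for the MAF split, whose
#' lowest quartile contributes little variance).
#'
#' @param variants Variant tibble with the field populated.
#' @param field One of `"ld_score"`, `"snp_num"`, `"maf"`.
#' @param drop_lowest Omit quartile 1 from the output.
#' @return Tibble with columns `subset`, `variant_id`, `provenance`.
#' @export
quartile_subsets <- function(variants, field = c("ld_score", "snp_num", "maf"),
                             drop_lowest = FALSE) {
  field <- match.arg(field)
  m <- nrow(variants)
  if (m < 4) abort("need at least 4 variants to form quartiles")
  vals <- variants[[field]]
  if (is.null(vals) || anyNA(vals)) {
    abort(sprintf("field '%s' is not populated for all variants", field))
  }
  chr_key <- suppressWarnings(as.numeric(variants$chromosome))
  chr_key[is.na(chr_key)] <- Inf
  ord <- order(vals, chr_key, variants$position)
  base <- m %/% 4L
  sizes <- base + (seq_len(4) <= m %% 4L)
  q <- rep(1:4, times = sizes)
  prefix <- quartile_prefix[[field]]
  out <- tibble(subset = paste0(prefix, q),
                variant_id = variants$variant_id[ord],
                provenance = "quartile")
  if (drop_lowest) out <- out[out$subset != paste0(prefix, 1), , drop = FALSE]
  out
}

#' Annotation- and list-based variant subsets
#'
#' Maps functional annotation categories onto named subsets (several
#' categories may merge into one subset, e.g. 5' and 3' UTR into "UTR") and
#' intersects externally supplied variant-id lists with the variant table. A
#' variant may belong to several subsets.
#'
#' @param variants Variant tibble with a `category` column (used with
#'   `category_map`).
#' @param category_map Named character vector: `category label -> subset
#'   name`. Categories absent from the map are ignored.
#' @param external_lists Named list; each element a character vector of
#'   variant ids or a path to a one-id-per-line file. Lists with zero overlap
#'   with the table raise an error; partial overlap is reported.
#' @return Tibble with columns `subset`, `variant_id`, `provenance`.
#' @export
annotation_subsets <- function(variants, category_map = NULL,
                               external_lists = NULL) {
  parts <- list()
  if (!is.null(category_map) && length(category_map)) {
    if (is.null(variants$category)) {
      abort("variants table has no 'category' column")
    }
    hit <- variants$category %in% names(category_map)
    if (any(hit)) {
      parts$anno <- tibble(
        subset = unname(category_map[variants$category[hit]]),
        variant_id = variants$variant_id[hit],
        provenance = "annotation")
    }
  }
  if (!is.null(external_lists) && length(external_lists)) {
    parts$ext <- purrr::imap_dfr(external_lists, function(lst, nm) {
      ids <- if (length(lst) == 1 && is.character(lst) && file.exists(lst)) {
        readLines(lst)
      } else {
        as.character(lst)
      }
      ids <- unique(ids[nzchar(ids)])
      present <- intersect(ids, variants$variant_id)
      if (length(present) == 0) {
        abort(sprintf("external list '%s' has no overlap with the variant table", nm))
      }
      if (length(present) < length(ids)) {
        warn(sprintf("external list '%s': %d of %d ids present in variant table",
                     nm, length(present), length(ids)))
      } else {
        inform(sprintf("external list '%s': all %d ids present", nm, length(ids)))
      }
      tibble(subset = nm, variant_id = present, provenance = "external-list")
    })
  }
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) {
    return(tibble(subset = character(), variant_id = character(),
                  provenance = character()))
  }
  dplyr::distinct(out, .data$subset, .data$variant_id, .keep_all = TRUE)
}

#' Member variant ids of one named subset
#'
#' @param subsets Long subset tibble (columns `subset`, `variant_id`).
#' @param name Subset name.
#' @return Character vector of variant ids; errors if the subset is empty.
#' @export
subset_members <- function(subsets, name) {
  ids <- subsets$variant_id[subsets$subset == name]
  if (!length(ids)) abort(sprintf("subset '%s' is empty or unknown", name))
  ids
}
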