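#' Construct a genomic relationship matrix from a variant subset
#'
#' Additive GRM with per-variant standardization: for individuals j, k and
#' subset variants m with sample allele frequency \eqn{p_m},
#' \deqn{G_{jk} = \frac{1}{M} \sum_m
#'   \frac{(x_{jm} - 2p_m)(x_{km} - 2p_m)}{2 p_m (1 - p_m)}.}
#' Allele frequencies are always taken from the analyzed sample itself.
#'
#' @param genotypes Individuals x variants dosage matrix (no missing values).
#' @param variant_subset Character vector of variant ids (column names) to
#'   use; `NULL` uses every column.
#' @return An object of class `grm`: list with `matrix` (n x n, symmetric),
#'   `individual_ids` and `n_variants`.
#' @export
#' @examples
#' G <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "v1"))
#' compute_grm(G)$matrix  # [[2, -2], [-2, 2]]
compute_grm <- function(genotypes, variant_subset = NULL) {
  if (!is.null(variant_subset)) {
    missing_ids <- setdiff(variant_subset, colnames(genotypes))
    if (length(missing_ids)) {
      abort(sprintf("subset variants absent from genotype matrix: %s",
                    paste(head(missing_ids, 5), collapse = ", ")))
    }
    X <- genotypes[, variant_subset, drop = FALSE]
  } else {
    X <- genotypes
  }
  p <- colMeans(X) / 2
  mono <- which(p <= 0 | p >= 1)
  if (length(mono)) {
    abort(sprintf("monomorphic variant(s) in subset: %s",
                  paste(head(colnames(X)[mono], 10), collapse = ", ")))
  }
  Xs <- sweep(sweep(X, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  M <- ncol(Xs)
  A <- tcrossprod(Xs) / M
  A <- (A + t(A)) / 2
  new_grm(A, rownames(genotypes) %||% as.character(seq_len(nrow(A))), M)
}

new_grm <- function(matrix, ids, n_variants) {
  dimnames(matrix) <- list(ids, ids)
  structure(list(matrix = matrix, individual_ids = ids,
                 n_variants = as.integer(n_variants)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d individuals, %d variants; mean diagonal %.4f\n",
              length(x$individual_ids), x$n_variants,
              mean(diag(x$matrix))))
  invisible(x)
}

#' @export
dim.grm <- function(x) dim(x$matrix)

#' Write / read a GRM in the GCTA binary dialect
#'
#' `<prefix>.grm.bin` holds the lower triangle (diagonal included, row by
#' row) as little-endian float32; `<prefix>.grm.N.bin` the per-pair variant
#' counts as float32; `<prefix>.grm.id` two whitespace-separated id columns
#' (family and individual id, written equal here).
#'
#' @param grm A [compute_grm()] object.
#' @param prefix Path prefix (no extension).
#' @return `write_grm_gcta()` returns `prefix` invisibly; `read_grm_gcta()`
#'   returns a `grm` (float32 round-off applies to the values).
#' @export
write_grm_gcta <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$individual_ids)
  # GCTA stores the row-major lower triangle, which for a symmetric matrix
  # equals the column-major upper triangle
  upper <- grm$matrix[upper.tri(grm$matrix, diag = TRUE)]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(upper), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_variants), n * (n + 1) / 2), con,
           size = 4, endian = "little")
  close(con)
  write.table(data.frame(grm$individual_ids, grm$individual_ids),
              paste0(prefix, ".grm.id"), quote = FALSE,
              row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' @rdname write_grm_gcta
#' @export
read_grm_gcta <- function(prefix) {
  ids <- read.table(paste0(prefix, ".grm.id"), stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  n_pairs <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric",
                  n = file.size(paste0(prefix, ".grm.bin")) / 4 + 1,
                  size = 4, endian = "little")
  if (length(vals) != n_pairs) {
    abort(sprintf(".grm.bin holds %d values but %d ids need %d",
                  length(vals), n, n_pairs))
  }
  A <- matrix(0, n, n)
  A[upper.tri(A, diag = TRUE)] <- vals
  A <- A + t(A) - diag(diag(A), n)
  nfile <- paste0(prefix, ".grm.N.bin")
  n_variants <- if (file.exists(nfile)) {
    nv <- readBin(nfile, "numeric", n = 1, size = 4, endian = "little")
    as.integer(round(nv))
  } else {
    NA_integer_
  }
  new_grm(A, as.character(ids), n_variants)
}

#' Check a GRM for symmetry and numerical positive semidefiniteness
#'
#' @param grm A `grm` object.
#' @param tol Eigenvalue tolerance; smallest eigenvalue must exceed `-tol`.
#' @return TRUE (invisibly) or an error describing the violation.
#' @export
validate_grm <- function(grm, tol = 1e-8) {
  stopifnot(inherits(grm, "grm"))
  if (max(abs(grm$matrix - t(grm$matrix))) > 1e-10) {
    abort("GRM is not symmetric")
  }
  ev <- eigen(grm$matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev)))) {
    abort(sprintf("GRM has eigenvalue %.3e below the PSD tolerance", min(ev)))
  }
  invisible(TRUE)
}
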