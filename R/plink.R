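#' Write genotypes in PLINK format
#'
#' Writes either the binary `.bed`/`.bim`/`.fam` triplet (SNP-major, two bits
#' per genotype) or the text `.ped`/`.map` pair. Dosages count copies of the
#' `a1` allele of the variant table.
#'
#' @param genotypes Individuals x variants dosage matrix in \{0, 1, 2\} (NA
#'   allowed; written as the missing genotype code).
#' @param variants Variant tibble with columns `variant_id`, `chromosome`,
#'   `position`, `a1`, `a2`.
#' @param prefix Path prefix (no extension).
#' @param format `"bed"` (binary) or `"ped"` (text).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, variants, prefix, format = c("bed", "ped")) {
  format <- match.arg(format)
  stopifnot(ncol(genotypes) == nrow(variants))
  ids <- rownames(genotypes) %||% sprintf("id%04d", seq_len(nrow(genotypes)))
  if (format == "bed") {
    write_bed_triplet(genotypes, variants, ids, prefix)
  } else {
    write_ped_pair(genotypes, variants, ids, prefix)
  }
  invisible(prefix)
}

write_bed_triplet <- function(genotypes, variants, ids, prefix) {
  n <- nrow(genotypes)
  # 2-bit codes, LSB-first within each byte: 00 hom a1, 10 het, 11 hom a2, 01 missing
  code <- matrix(3L, n, ncol(genotypes))
  code[genotypes == 2] <- 0L
  code[genotypes == 1] <- 2L
  code[is.na(genotypes)] <- 1L
  n_bytes <- ceiling(n / 4)
  pad <- n_bytes * 4 - n
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  mult <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(ncol(genotypes))) {
    v <- c(code[, j], rep(0L, pad))
    bytes <- colSums(matrix(v * mult, nrow = 4))
    writeBin(as.raw(bytes), con)
  }
  write.table(data.frame(variants$chromosome, variants$variant_id, 0,
                         variants$position, variants$a1, variants$a2),
              paste0(prefix, ".bim"), quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  write.table(data.frame(ids, ids, 0, 0, 0, -9),
              paste0(prefix, ".fam"), quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

write_ped_pair <- function(genotypes, variants, ids, prefix) {
  n <- nrow(genotypes)
  allele_cols <- matrix("", n, 2 * ncol(genotypes))
  for (j in seq_len(ncol(genotypes))) {
    a1 <- variants$a1[j]; a2 <- variants$a2[j]
    g <- genotypes[, j]
    allele_cols[, 2 * j - 1] <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
    allele_cols[, 2 * j] <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
  }
  ped <- cbind(ids, ids, "0", "0", "0", "-9", allele_cols)
  write.table(ped, paste0(prefix, ".ped"), quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(data.frame(variants$chromosome, variants$variant_id, 0,
                         variants$position),
              paste0(prefix, ".map"), quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
}

#' Read genotypes from PLINK files
#'
#' Reads a `.bed`/`.bim`/`.fam` triplet, or a `.ped`/`.map` pair when no
#' `.bed` file exists at the prefix. Missing genotypes are mean-imputed per
#' variant (replaced by twice the sample allele frequency of the non-missing
#' dosages) and the number of imputed cells is reported via a message and the
#' `n_imputed` element of the result.
#'
#' @param prefix Path prefix (no extension).
#' @return A list with `genotypes` (matrix, no missing values), `variants`
#'   (tibble with variant_id, chromosome, position, a1, a2, maf) and
#'   `n_imputed`.
#' @export
read_plink <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) {
    res <- read_bed_triplet(prefix)
  } else if (file.exists(paste0(prefix, ".ped"))) {
    res <- read_ped_pair(prefix)
  } else {
    abort(sprintf("no .bed or .ped file found at prefix '%s'", prefix))
  }
  if (anyDuplicated(res$variants$variant_id)) {
    abort("duplicate variant IDs in variant map")
  }
  G <- res$genotypes
  n_imputed <- sum(is.na(G))
  if (n_imputed > 0) {
    for (j in which(colSums(is.na(G)) > 0)) {
      g <- G[, j]
      G[is.na(g), j] <- mean(g, na.rm = TRUE)
    }
    inform(sprintf("mean-imputed %d missing genotype(s)", n_imputed))
  }
  p <- colMeans(G) / 2
  res$variants$maf <- pmin(p, 1 - p)
  res$genotypes <- G
  res$n_imputed <- n_imputed
  res
}

read_bed_triplet <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  fam <- read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = file.size(paste0(prefix, ".bed")))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("not a PLINK .bed file (magic bytes mismatch)")
  }
  if (raw[3] != as.raw(0x01)) {
    abort("only SNP-major .bed files are supported")
  }
  n_bytes <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != n_bytes * m) {
    abort(sprintf(".bed payload has %d bytes but %d individuals x %d variants need %d",
                  length(body), n, m, n_bytes * m))
  }
  # decode all 2-bit fields at once
  ints <- as.integer(body)
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  codes <- matrix(as.vector(codes), nrow = n_bytes * 4)[seq_len(n), ,
                                                        drop = FALSE]
  G <- matrix(NA_real_, n, m)
  G[codes == 0L] <- 2
  G[codes == 2L] <- 1
  G[codes == 3L] <- 0
  variants <- tibble(variant_id = as.character(bim[[2]]),
                     chromosome = as.character(bim[[1]]),
                     position = as.integer(bim[[4]]),
                     a1 = as.character(bim[[5]]),
                     a2 = as.character(bim[[6]]))
  dimnames(G) <- list(as.character(fam[[2]]), variants$variant_id)
  list(genotypes = G, variants = variants)
}

read_ped_pair <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), stringsAsFactors = FALSE)
  ped <- read.table(paste0(prefix, ".ped"), stringsAsFactors = FALSE,
                    colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) {
    abort(sprintf(".ped has %d columns; expected %d for %d variants",
                  ncol(ped), 6 + 2 * m, m))
  }
  n <- nrow(ped)
  variants <- tibble(variant_id = as.character(map[[2]]),
                     chromosome = as.character(map[[1]]),
                     position = as.integer(map[[4]]),
                     a1 = NA_character_, a2 = NA_character_)
  G <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    al1 <- ped[[6 + 2 * j - 1]]
    al2 <- ped[[6 + 2 * j]]
    obs <- sort(unique(c(al1, al2)))
    obs <- setdiff(obs, "0")
    if (length(obs) > 2) {
      abort(sprintf("variant %s has more than two alleles", variants$variant_id[j]))
    }
    # counted allele: first observed alphabetically, as a1 if present
    a1 <- obs[1] %||% NA_character_
    a2 <- if (length(obs) == 2) obs[2] else a1
    variants$a1[j] <- a1
    variants$a2[j] <- a2
    g <- (al1 == a1) + (al2 == a1)
    g[al1 == "0" | al2 == "0"] <- NA
    G[, j] <- g
  }
  dimnames(G) <- list(as.character(ped[[2]]), variants$variant_id)
  list(genotypes = G, variants = variants)
}
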