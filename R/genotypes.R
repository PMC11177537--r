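#' Genotype matrix container
#'
#' Couples a samples-by-variants dosage matrix with its variant metadata.
#' Dosages count copies of allele `a1` and take values 0, 1, 2 or `NA`
#' (missing).  Only autosomal bi-allelic variants are admitted; the
#' constructor rejects anything else.
#'
#' @param dosages integer matrix, samples in rows, variants in columns.
#'   Row names are sample ids; they are required and must be unique.
#' @param variants data frame with columns `id`, `chrom` (character,
#'   "1".."22"), `pos` (1-based base pairs), `a1`, `a2`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` and `variants`.
#' @export
genotype_matrix <- function(dosages, variants) {
  stop_if_not(is.matrix(dosages), "dosages must be a matrix")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "a1", "a2")
  stop_if_not(all(req %in% names(variants)),
              paste("variants must have columns:", paste(req, collapse = ", ")))
  stop_if_not(ncol(dosages) == nrow(variants),
              "ncol(dosages) must equal nrow(variants)")
  stop_if_not(!is.null(rownames(dosages)) && !anyDuplicated(rownames(dosages)),
              "dosages must have unique sample ids as row names")
  storage.mode(dosages) <- "integer"
  bad <- dosages[!is.na(dosages)]
  stop_if_not(all(bad %in% 0:2), "dosages must be 0, 1, 2 or NA")
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  stop_if_not(all(is_autosome(variants$chrom)),
              "non-autosomal variants are not allowed in a genotype_matrix")
  stop_if_not(all(variants$pos >= 1), "positions must be >= 1 (1-based)")
  stop_if_not(all(variants$a1 != variants$a2), "a1 and a2 must differ")
  stop_if_not(!anyDuplicated(variants$id), "variant ids must be unique")
  colnames(dosages) <- variants$id
  rownames(variants) <- NULL
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "variants\n")
  cat("  chromosomes:", paste(sort(unique(as.integer(x$variants$chrom))),
                              collapse = " "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness: %.4f\n", miss))
  invisible(x)
}

#' Sample ids of a genotype matrix
#' @param g a `genotype_matrix`.
#' @export
samples <- function(g) rownames(g$dosages)

#' Number of samples / variants
#' @rdname samples
#' @export
n_samples <- function(g) nrow(g$dosages)

#' @rdname samples
#' @export
n_variants <- function(g) ncol(g$dosages)

#' Subset a genotype matrix
#'
#' @param g a `genotype_matrix`.
#' @param sample_ids character vector of sample ids to keep (order kept as
#'   given), or `NULL` to keep all.
#' @param variant_keep logical/integer/character index over variants, or
#'   `NULL` to keep all.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(g, sample_ids = NULL, variant_keep = NULL) {
  d <- g$dosages
  v <- g$variants
  if (!is.null(sample_ids)) {
    missing_ids <- setdiff(sample_ids, rownames(d))
    stop_if_not(length(missing_ids) == 0,
                paste("unknown sample ids:", paste(head(missing_ids), collapse = ", ")))
    d <- d[sample_ids, , drop = FALSE]
  }
  if (!is.null(variant_keep)) {
    if (is.character(variant_keep)) variant_keep <- match(variant_keep, v$id)
    d <- d[, variant_keep, drop = FALSE]
    v <- v[variant_keep, , drop = FALSE]
  }
  genotype_matrix(d, v)
}

#' Allele frequency of allele a1 per variant
#'
#' @param g a `genotype_matrix`.
#' @param sample_ids samples over which to compute frequencies (default all).
#' @return numeric vector, named by variant id; `NaN` where no calls.
#' @export
allele_freq <- function(g, sample_ids = NULL) {
  d <- g$dosages
  if (!is.null(sample_ids)) d <- d[sample_ids, , drop = FALSE]
  colMeans(d, na.rm = TRUE) / 2
}

# Per-variant genotype counts (n0, n1, n2 of a1 dosage) over a sample set.
genotype_counts <- function(g, sample_ids = NULL) {
  d <- g$dosages
  if (!is.null(sample_ids)) d <- d[sample_ids, , drop = FALSE]
  n2 <- colSums(d == 2L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n0 <- colSums(d == 0L, na.rm = TRUE)
  cbind(n0 = n0, n1 = n1, n2 = n2)
}
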