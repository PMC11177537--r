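# Reference-anchored principal component analysis for ancestry.
#
# The PCA is fitted jointly on cohort founders and a labelled reference
# panel; offspring are projected with the fitted standardization and
# loadings rather than refitted, so family structure cannot distort the
# axes.  Round 1 (continental-scale contrast panels) drives inclusion;
# round 2 (sub-population panels of the retained ancestry) supplies the
# PC scores and the |PC1| loading ranking used downstream.

#' Fit a reference-anchored PCA
#'
#' Dosages are standardized per variant to mean `2p` and scale
#' `sqrt(2p(1-p))`, with `p` the allele frequency in the fitting set
#' (founders plus reference); missing calls are mean-imputed (zero after
#' standardization).  Loadings columns are unit-norm with a fixed sign
#' convention: the entry of largest magnitude in each column is
#' positive, so ranked SNP lists are reproducible across eigensolvers.
#'
#' @param g_founders [genotype_matrix()] of cohort founders.
#' @param g_reference [genotype_matrix()] of reference samples, on the
#'   same variant set (same ids, same order).
#' @param k number of components (default 20); reduced with a warning if
#'   it exceeds the rank.
#' @return object of class `pca_model`: `eigenvalues`, `scores` (fitted
#'   samples x k), `loadings` (variants x k), `center`, `scale`,
#'   `variants`, `fitted_ids`.
#' @export
fit_reference_pca <- function(g_founders, g_reference = NULL, k = 20) {
  if (!is.null(g_reference)) {
    stop_if_not(identical(g_founders$variants$id, g_reference$variants$id),
                "founders and reference must share a harmonized variant set")
    X <- rbind(g_founders$dosages, g_reference$dosages)
  } else {
    X <- g_founders$dosages
  }
  stop_if_not(!anyDuplicated(rownames(X)),
              "sample ids overlap between founders and reference")
  p <- colMeans(X, na.rm = TRUE) / 2
  ctr <- 2 * p
  scl <- sqrt(2 * p * (1 - p))
  usable <- which(scl > 0)
  Z <- sweep(X[, usable, drop = FALSE], 2, ctr[usable], "-")
  Z <- sweep(Z, 2, scl[usable], "/")
  Z[is.na(Z)] <- 0
  kmax <- min(nrow(Z) - 1L, length(usable))
  if (k > kmax) {
    warning(sprintf("k reduced from %d to %d (rank limit)", k, kmax))
    k <- kmax
  }
  sv <- svd(Z, nu = k, nv = k)
  # sign convention: largest-|entry| of each loading column positive
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  V <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  scores <- Z %*% V
  loadings <- matrix(0, ncol(X), k,
                     dimnames = list(g_founders$variants$id,
                                     paste0("PC", seq_len(k))))
  loadings[usable, ] <- V
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(eigenvalues = (sv$d[seq_len(k)]^2) / (nrow(Z) - 1),
                 scores = scores,
                 loadings = loadings,
                 center = ctr, scale = scl,
                 variants = g_founders$variants,
                 fitted_ids = rownames(X)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- ncol(x$scores)
  cat("pca_model:", length(x$fitted_ids), "fitted samples,",
      nrow(x$loadings), "variants,", k, "components\n")
  ev <- x$eigenvalues
  cat("  eigenvalues (top 5):",
      paste(sprintf("%.3f", head(ev, 5)), collapse = " "), "\n")
  invisible(x)
}

#' Project samples onto a fitted PCA
#'
#' Uses the model's standardization (fitting-set frequencies) and
#' loadings; projecting a fitted sample reproduces its fitted score.
#'
#' @param model a `pca_model`.
#' @param g [genotype_matrix()] on the model's variant set.
#' @return score matrix (samples x k).
#' @export
project_samples <- function(model, g) {
  stop_if_not(identical(g$variants$id, model$variants$id),
              "variant set differs from the fitted model")
  usable <- model$scale > 0
  Z <- sweep(g$dosages[, usable, drop = FALSE], 2, model$center[usable], "-")
  Z <- sweep(Z, 2, model$scale[usable], "/")
  Z[is.na(Z)] <- 0
  Z %*% model$loadings[usable, , drop = FALSE]
}

#' Centroid-rule ancestry assignment on (PC1, PC2)
#'
#' A sample is assigned to the target population iff, on PC1 *and* on
#' PC2 separately, its distance to the target centroid is strictly
#' smaller than its distance to every contrast centroid.  Ties exclude
#' the sample.  Centroids are per-population means of the reference
#' sample scores.
#'
#' @param scores matrix of sample scores (columns PC1, PC2, ...).
#' @param ref_scores matrix of reference sample scores.
#' @param ref_labels population label per reference sample.
#' @param target the target population label (default first label).
#' @return data frame of class `ancestry_call`: `sample_id`, `assigned`
#'   (logical), plus per-population PC1/PC2 centroid distances.
#' @export
assign_ancestry <- function(scores, ref_scores, ref_labels,
                            target = ref_labels[1]) {
  pops <- unique(ref_labels)
  stop_if_not(target %in% pops, "target label absent from reference labels")
  stop_if_not(all(table(ref_labels) > 0), "empty reference population")
  cent <- t(vapply(pops, function(p)
    colMeans(ref_scores[ref_labels == p, 1:2, drop = FALSE]), numeric(2)))
  rownames(cent) <- pops
  d1 <- abs(outer(scores[, 1], cent[, 1], "-"))   # samples x pops, PC1
  d2 <- abs(outer(scores[, 2], cent[, 2], "-"))
  contrasts <- setdiff(pops, target)
  closer1 <- rowSums(d1[, target] < d1[, contrasts, drop = FALSE]) ==
    length(contrasts)
  closer2 <- rowSums(d2[, target] < d2[, contrasts, drop = FALSE]) ==
    length(contrasts)
  out <- data.frame(sample_id = rownames(scores) %||% seq_len(nrow(scores)),
                    assigned = closer1 & closer2,
                    stringsAsFactors = FALSE)
  for (p in pops) {
    out[[paste0("d1_", p)]] <- d1[, p]
    out[[paste0("d2_", p)]] <- d2[, p]
  }
  attr(out, "target") <- target
  class(out) <- c("ancestry_call", "data.frame")
  out
}

#' Rank variants by loading magnitude
#'
#' Variants sorted by `|loading|` on the given component, descending;
#' ties broken by (chromosome, position) ascending.  The head of the
#' ranking is the ancestry-informative ("top") set, the tail the less
#' informative ("bottom") set.
#'
#' @param model a `pca_model`.
#' @param component component index (default 1, i.e. |PC1|).
#' @return data frame `id`, `chrom`, `pos`, `abs_loading` in rank order.
#' @export
rank_snps_by_loading <- function(model, component = 1) {
  stop_if_not(component <= ncol(model$loadings), "component exceeds fitted k")
  v <- model$variants
  al <- abs(model$loadings[, component])
  o <- order(-al, as.integer(v$chrom), v$pos)
  data.frame(id = v$id[o], chrom = v$chrom[o], pos = v$pos[o],
             abs_loading = al[o], stringsAsFactors = FALSE, row.names = NULL)
}
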