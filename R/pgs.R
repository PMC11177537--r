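# Polygenic scoring, the polygenic transmission disequilibrium test and
# the odd/even-chromosome estimator of score-based assortative mating.
#
# Effect sizes are consumed as given (typically shrunk by an external
# tool); this module contributes the SNP-retention filter, scoring with
# mean imputation, covariate adjustment, and the family-based tests.

#' Summary-statistic SNP retention filter
#'
#' Compares the per-SNP standard deviation implied by the summary
#' statistics (`SD_ss`) with that of the target genotypes (`SD_test`).
#' For a binary trait, `n_eff = 4 / (1/n_case + 1/n_control)` and
#' `SD_ss = 2 / (se * sqrt(n_eff))`; for a quantitative trait,
#' `SD_ss = 1 / (se * sqrt(n))`.  `SD_test = sqrt(2 AF (1 - AF))` with
#' `AF` the founder allele frequency.  A SNP is removed when any of
#' `SD_ss < 0.5 SD_test`, `SD_ss > 0.1 + SD_test`, `SD_ss < 0.1`, or
#' `SD_test < 0.05` holds.
#'
#' @param stats `summary_stats` data frame (harmonized).
#' @param founder_freq allele frequency of the scored allele among
#'   founders, aligned with `stats` rows.
#' @return logical keep mask; diagnostic columns in the
#'   `"detail"` attribute.
#' @export
sd_filter <- function(stats, founder_freq) {
  stop_if_not(length(founder_freq) == nrow(stats),
              "founder_freq must align with stats rows")
  stop_if_not(all(stats$se > 0), "se must be positive")
  binary <- all(c("n_case", "n_control") %in% names(stats)) &&
    !anyNA(stats$n_case) && !anyNA(stats$n_control)
  if (binary) {
    n_eff <- 4 / (1 / stats$n_case + 1 / stats$n_control)
    sd_ss <- 2 / (stats$se * sqrt(n_eff))
  } else {
    stop_if_not("n" %in% names(stats) && !anyNA(stats$n),
                "need n_case/n_control (binary) or n (quantitative)")
    sd_ss <- 1 / (stats$se * sqrt(stats$n))
  }
  sd_test <- sqrt(2 * founder_freq * (1 - founder_freq))
  keep <- !(sd_ss < 0.5 * sd_test | sd_ss > 0.1 + sd_test |
              sd_ss < 0.1 | sd_test < 0.05)
  attr(keep, "detail") <- data.frame(id = stats$id, sd_ss = sd_ss,
                                     sd_test = sd_test, keep = keep)
  keep
}

#' Compute polygenic scores
#'
#' Raw score per sample is the weighted sum of dosages; a missing
#' dosage contributes the founder mean dosage of that variant.  Scores
#' are standardized to mean 0, sd 1 over founders; when covariates are
#' supplied, an adjusted score (the residual of the standardized score
#' on the covariates) is added.
#'
#' @param g a [genotype_matrix()].
#' @param weights data frame with `id` and `beta` (aligned to the
#'   panel's a1 allele, e.g. via [harmonize_sumstats()]).
#' @param founders sample ids defining the standardization/imputation
#'   reference (default: all samples).
#' @param covariates optional data frame, one row per sample of `g`
#'   (matched by a `sample_id` column), whose remaining columns are the
#'   adjustment covariates (e.g. age, sex, PC1..PC10).
#' @return data frame of class `pgs_result`: `sample_id`, `raw`, `std`,
#'   and `adj` when covariates were given; `n_variants` attribute.
#' @export
score_pgs <- function(g, weights, founders = NULL, covariates = NULL) {
  founders <- founders %||% samples(g)
  idx <- match(weights$id, g$variants$id)
  ok <- !is.na(idx)
  stop_if_not(any(ok), "no overlap between weights and genotype variants")
  idx <- idx[ok]
  beta <- weights$beta[ok]
  D <- g$dosages[, idx, drop = FALSE]
  mu <- colMeans(D[founders, , drop = FALSE], na.rm = TRUE)
  miss <- is.na(D)
  if (any(miss)) D[miss] <- rep(mu, each = nrow(D))[miss]
  raw <- as.vector(D %*% beta)
  mf <- mean(raw[rownames(D) %in% founders])
  sf <- sd(raw[rownames(D) %in% founders])
  std <- if (sf > 0) (raw - mf) / sf else raw - mf
  out <- data.frame(sample_id = rownames(D), raw = raw, std = std,
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    stop_if_not("sample_id" %in% names(covariates),
                "covariates need a sample_id column")
    cv <- covariates[match(out$sample_id, covariates$sample_id), , drop = FALSE]
    X <- cv[, setdiff(names(cv), "sample_id"), drop = FALSE]
    cc <- complete.cases(X)
    adj <- rep(NA_real_, nrow(out))
    fit <- lm(out$std[cc] ~ ., data = X[cc, , drop = FALSE])
    adj[cc] <- resid(fit)
    out$adj <- adj
  }
  attr(out, "n_variants") <- length(beta)
  class(out) <- c("pgs_result", "data.frame")
  out
}

#' Polygenic transmission disequilibrium test
#'
#' Per trio, the transmission deviation is
#' `(child - midparent) / sd(midparent)`, with `midparent =
#' (father + mother)/2` and `sd(midparent)` the sample standard
#' deviation (n-1 denominator) of midparent scores across included
#' trios.  A one-sample two-sided t-test asks whether the mean
#' deviation differs from zero (over-transmission when positive).
#'
#' @param scores named numeric vector of per-sample scores, or a
#'   `pgs_result` (its `std` column is used).
#' @param pedigree pedigree data frame with `father_id`, `mother_id`,
#'   and the child column selected by `child`.
#' @param child `"proband"` or `"sibling"`.
#' @return object of class `ptdt_result`: `n`, `mean_deviation`,
#'   `t`, `p`, `conf_int`.
#' @export
ptdt <- function(scores, pedigree, child = c("proband", "sibling")) {
  child <- match.arg(child)
  if (inherits(scores, "pgs_result"))
    scores <- setNames(scores$std, scores$sample_id)
  ccol <- paste0(child, "_id")
  ids <- pedigree[, c("father_id", "mother_id", ccol)]
  ids <- ids[complete.cases(ids), , drop = FALSE]
  ok <- ids$father_id %in% names(scores) & ids$mother_id %in% names(scores) &
    ids[[ccol]] %in% names(scores)
  ids <- ids[ok, , drop = FALSE]
  n <- nrow(ids)
  stop_if_not(n >= 2, "need at least two complete trios")
  mid <- (scores[ids$father_id] + scores[ids$mother_id]) / 2
  s_mid <- sd(mid)
  stop_if_not(s_mid > 0, "midparent scores are constant; deviation undefined")
  dev <- (scores[ids[[ccol]]] - mid) / s_mid
  if (sd(dev) == 0) {
    # every child deviates identically (e.g. all equal to midparent)
    m <- mean(dev)
    tt <- list(statistic = if (m == 0) 0 else sign(m) * Inf,
               p.value = if (m == 0) 1 else 0, conf.int = c(m, m))
  } else {
    tt <- t.test(dev, mu = 0)
  }
  structure(list(n = n, child = child,
                 mean_deviation = unname(mean(dev)),
                 t = unname(tt$statistic), p = tt$p.value,
                 conf_int = unname(tt$conf.int)),
            class = "ptdt_result")
}

#' @export
print.ptdt_result <- function(x, ...) {
  cat(sprintf("pTDT (%s, n = %d trios): mean deviation %.4f [%.4f, %.4f], t = %.3f, p = %.3g\n",
              x$child, x$n, x$mean_deviation, x$conf_int[1], x$conf_int[2],
              x$t, x$p))
  invisible(x)
}

#' Odd/even-chromosome estimator of score-based assortment
#'
#' Splits the panel by chromosome parity, scores each half separately
#' (disjoint variant sets), standardizes both scores, and fits the two
#' regressions `S_odd = theta S_even + PCE_1..PCE_k` and
#' `S_even = theta S_odd + PCO_1..PCO_k`, where PCO/PCE are principal
#' components of the LD-pruned odd/even subsets.  Under assortative
#' mating on the score, the two half-genome predictors correlate
#' (theta > 0); the PC covariates absorb ancestry-driven correlation.
#' The two estimates are combined by inverse-variance weighting.
#'
#' @param g founder/parent [genotype_matrix()].
#' @param weights data frame with `id`, `beta` aligned to a1.
#' @param k number of parity PCs to adjust for (default 20; reduced
#'   with a warning if fewer are computable).
#' @param prune_r2,prune_window_bp LD-pruning parameters for the PC
#'   SNP sets (defaults r^2 > 0.1 within 1 Mb).
#' @return object of class `theta_result`: data frame `estimates` with
#'   one row per regression plus the combined row.
#' @export
odd_even_theta <- function(g, weights, k = 20,
                           prune_r2 = 0.1, prune_window_bp = 1e6) {
  chrom <- as.integer(g$variants$chrom)
  odd <- chrom %% 2L == 1L
  g_o <- subset_genotypes(g, variant_keep = odd)
  g_e <- subset_genotypes(g, variant_keep = !odd)
  stop_if_not(n_variants(g_o) > 0 && n_variants(g_e) > 0,
              "need variants on both odd and even chromosomes")
  s_o <- score_pgs(g_o, weights)$std
  s_e <- score_pgs(g_e, weights)$std

  pcs <- function(gp) {
    kept <- ld_prune(gp, r2_threshold = prune_r2, window_bp = prune_window_bp)
    m <- fit_reference_pca(subset_genotypes(gp, variant_keep = kept$id),
                           g_reference = NULL, k = k)
    m$scores
  }
  pco <- pcs(g_o)
  pce <- pcs(g_e)
  kk <- min(k, ncol(pco), ncol(pce))
  if (kk < k) warning(sprintf("using %d PCs (rank limit)", kk))

  fit_one <- function(y, x, pc) {
    df <- data.frame(y = y, x = x, pc[, seq_len(kk), drop = FALSE])
    fm <- lm(y ~ ., data = df)
    sm <- summary(fm)$coefficients["x", ]
    c(theta = unname(sm[1]), se = unname(sm[2]), p = unname(sm[4]))
  }
  r1 <- fit_one(s_o, s_e, pce)   # S_o = theta S_e + PCE
  r2 <- fit_one(s_e, s_o, pco)   # S_e = theta S_o + PCO
  w <- 1 / c(r1["se"]^2, r2["se"]^2)
  comb <- sum(w * c(r1["theta"], r2["theta"])) / sum(w)
  comb_se <- sqrt(1 / sum(w))
  comb_p <- 2 * pnorm(-abs(comb / comb_se))
  est <- data.frame(
    regression = c("odd_on_even", "even_on_odd", "combined"),
    theta = c(r1["theta"], r2["theta"], comb),
    se = c(r1["se"], r2["se"], comb_se),
    p = c(r1["p"], r2["p"], comb_p), row.names = NULL)
  structure(list(estimates = est, n = length(s_o), k = kk),
            class = "theta_result")
}

#' @export
print.theta_result <- function(x, ...) {
  cat(sprintf("odd/even-chromosome assortment (n = %d, %d PCs per parity):\n",
              x$n, x$k))
  print.data.frame(x$estimates, digits = 4)
  invisible(x)
}
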