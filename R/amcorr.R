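# Spousal-correlation estimation and comparison, variance-explained
# regressions, multiple-testing and power utilities.

#' Spousal correlation of a paired variable
#'
#' Pairs with a missing value in either spouse are dropped (pairwise
#' complete).  Pearson p-values come from the t distribution; Spearman
#' p-values are exact for n <= 10 and t-approximate otherwise.  The
#' confidence interval uses the Fisher-z transform (an approximation
#' for Spearman, labelled as such).
#'
#' @param father_values,mother_values numeric vectors paired by family.
#' @param method `"pearson"` or `"spearman"`.
#' @param variable optional variable name carried into the result.
#' @param stratum optional stratum label carried into the result.
#' @return object of class `spousal_corr`: `variable`, `method`, `r`,
#'   `n`, `conf_int`, `p`, `stratum`, `ci_approx`.
#' @export
spousal_correlation <- function(father_values, mother_values,
                                method = c("pearson", "spearman"),
                                variable = NA_character_,
                                stratum = NA_character_) {
  method <- match.arg(method)
  stop_if_not(length(father_values) == length(mother_values),
              "spousal vectors must have equal length")
  ok <- !is.na(father_values) & !is.na(mother_values)
  x <- father_values[ok]
  y <- mother_values[ok]
  n <- length(x)
  stop_if_not(n >= 3, "need at least 3 complete spouse pairs")
  if (method == "spearman") {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = n <= 10))
  } else {
    ct <- cor.test(x, y, method = "pearson")
  }
  r <- unname(ct$estimate)
  structure(list(variable = variable, method = method, r = r, n = n,
                 conf_int = fisher_z_ci(r, n), p = ct$p.value,
                 stratum = stratum, ci_approx = method == "spearman"),
            class = "spousal_corr")
}

#' @export
print.spousal_corr <- function(x, ...) {
  cat(sprintf("spousal correlation%s (%s%s): r = %.3f [%.3f, %.3f], n = %d, p = %.3g\n",
              if (is.na(x$variable)) "" else paste0(" of ", x$variable),
              x$method,
              if (is.na(x$stratum)) "" else paste0(", ", x$stratum),
              x$r, x$conf_int[1], x$conf_int[2], x$n, x$p))
  invisible(x)
}

#' Compare two independent correlations (Fisher's z-test)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal p-value.  Strata must be independent samples.
#'
#' @param c1,c2 `spousal_corr` objects, or lists with `r` and `n`.
#' @return object of class `corr_comparison`: `r1`, `n1`, `r2`, `n2`,
#'   `z`, `p`.
#' @export
compare_correlations <- function(c1, c2) {
  stop_if_not(c1$n > 3 && c2$n > 3, "both groups need n > 3")
  stop_if_not(abs(c1$r) < 1 && abs(c2$r) < 1,
              "|r| must be < 1 for the Fisher z transform")
  z <- (atanh(c1$r) - atanh(c2$r)) /
    sqrt(1 / (c1$n - 3) + 1 / (c2$n - 3))
  structure(list(r1 = c1$r, n1 = c1$n, r2 = c2$r, n2 = c2$n,
                 z = z, p = 2 * pnorm(-abs(z))),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  cat(sprintf("Fisher z comparison: r1 = %.3f (n = %d) vs r2 = %.3f (n = %d): z = %.3f, p = %.3g\n",
              x$r1, x$n1, x$r2, x$n2, x$z, x$p))
  invisible(x)
}

#' Bonferroni per-test significance threshold
#'
#' @param alpha family-wise type-I error rate.
#' @param m number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stop_if_not(m >= 1, "m must be >= 1")
  alpha / m
}

#' Minimum sample size to detect a correlation
#'
#' Fisher-z approximation: the smallest integer `n` with approximate
#' power at least `power` for a two-sided test of `r = 0` at level
#' `alpha`, i.e. `ceiling(((z_{1-alpha/2} + z_power) / atanh(r))^2 + 3)`.
#'
#' @param r true correlation (0 < r < 1).
#' @param alpha two-sided type-I error rate.
#' @param power target power.
#' @return integer sample size.
#' @export
min_n_for_power <- function(r, alpha = 0.05, power = 0.8) {
  stop_if_not(r > 0 && r < 1, "r must be in (0, 1)")
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  as.integer(ceiling((z / atanh(r))^2 + 3))
}

#' Monte-Carlo power of the Pearson correlation test
#'
#' Draws `n_reps` independent samples of `n` bivariate-normal pairs
#' with correlation `rho` and reports the fraction rejecting the null
#' of zero correlation at two-sided level `alpha`.
#'
#' @param n pairs per replicate.
#' @param rho true correlation.
#' @param alpha two-sided level.
#' @param n_reps Monte-Carlo replicates.
#' @param seed optional RNG seed.
#' @return rejection proportion in `[0, 1]`.
#' @export
empirical_power_correlation <- function(n, rho, alpha = 0.05,
                                        n_reps = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(n * n_reps), n, n_reps)
  y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(n * n_reps), n, n_reps)
  # columnwise Pearson r, then the t test statistic
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  r <- colSums(xc * yc) / sqrt(colSums(xc^2) * colSums(yc^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  crit <- qt(1 - alpha / 2, df = n - 2)
  mean(abs(tstat) > crit)
}

#' Variance explained by predictor blocks (adjusted R-squared)
#'
#' Ordinary least squares of the response on each predictor block
#' separately (univariate models; a block may hold several columns,
#' e.g. ten PCs jointly) and on all blocks together (full model), with
#' listwise deletion within each model.
#'
#' @param data data frame holding response and predictors.
#' @param response response column name.
#' @param blocks named list; each element is a character vector of
#'   predictor column names forming one block.
#' @return data frame `model`, `n`, `adj_r_squared` (one row per block
#'   plus `"full"`).
#' @export
variance_explained <- function(data, response, blocks) {
  fit_block <- function(vars, label) {
    d <- data[, c(response, vars), drop = FALSE]
    d <- d[complete.cases(d), , drop = FALSE]
    p <- sum(vapply(d[, vars, drop = FALSE], function(col)
      if (is.numeric(col)) 1L else length(unique(col)) - 1L, integer(1)))
    stop_if_not(nrow(d) > p + 1, paste("too few rows for model", label))
    fm <- lm(stats::reformulate(vars, response = response), data = d)
    data.frame(model = label, n = nrow(d),
               adj_r_squared = summary(fm)$adj.r.squared)
  }
  rows <- lapply(names(blocks), function(nm) fit_block(blocks[[nm]], nm))
  rows <- c(rows, list(fit_block(unique(unlist(blocks)), "full")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spousal correlation before and after covariate adjustment
#'
#' Residualizes the trait on a covariate block (fitted on all parents
#' jointly), recomputes the spousal correlation of the residuals, and
#' reports the fractional change `(r_raw - r_residual) / r_raw`.
#'
#' @param data per-parent data frame: `family_id`, `role` ("father" /
#'   "mother"), the trait column, covariate columns.
#' @param trait trait column name.
#' @param covariates character vector of covariate column names (the
#'   adjustment block; by convention sex is excluded here since spouses
#'   differ in sex by construction).
#' @param method correlation method, as in [spousal_correlation()].
#' @return list with `raw`, `residual` (both `spousal_corr`) and
#'   `fractional_change`.
#' @export
residualized_spousal_correlation <- function(data, trait, covariates,
                                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  d <- data[, c("family_id", "role", trait, covariates), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  fm <- lm(stats::reformulate(covariates, response = trait), data = d)
  d$.resid <- resid(fm)
  stop_if_not(sd(d$.resid) > 1e-8 * (sd(d[[trait]]) + 1e-300),
              "residuals are (near) constant; correlation undefined")
  pair <- function(col) {
    f <- d[d$role == "father", c("family_id", col)]
    m <- d[d$role == "mother", c("family_id", col)]
    mg <- merge(f, m, by = "family_id", suffixes = c("_f", "_m"))
    mg[, 2:3]
  }
  pr_raw <- pair(trait)
  pr_res <- pair(".resid")
  raw <- spousal_correlation(pr_raw[, 1], pr_raw[, 2], method,
                             variable = trait)
  res <- spousal_correlation(pr_res[, 1], pr_res[, 2], method,
                             variable = paste0(trait, "_residual"))
  list(raw = raw, residual = res,
       fractional_change = (raw$r - res$r) / raw$r)
}
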