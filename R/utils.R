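# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

AUTOSOMES <- as.character(1:22)

is_autosome <- function(chrom) as.character(chrom) %in% AUTOSOMES

# Fisher-z confidence interval for a correlation coefficient.
fisher_z_ci <- function(r, n, level = 0.95) {
  if (n <= 3 || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

# Normal scores of a vector (rank-based inverse-normal transform);
# ties broken at random under the caller's RNG state.
normal_scores <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "random")
  qnorm((r - 0.5) / n)
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
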