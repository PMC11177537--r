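# Independent oracles used across tests.  These never call the package
# code paths they are used to check.

# Exact Hardy-Weinberg p-value by direct log-factorial enumeration of
# the conditional distribution of the heterozygote count.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- (2 * n - rare - h) / 2
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# Two-locus haplotype-frequency maximum likelihood by grid search over
# the (p_AB, p_Ab, p_aB) simplex: vectorised coarse grid (step 0.01)
# followed by nested local refinement down to 5e-6.  Returns the
# maximal multinomial log-likelihood.
em_grid_oracle <- function(cnt9) {
  ll_of <- function(pAB, pAb, paB) {
    pab <- pmax(1 - pAB - pAb - paB, 0)
    pr <- cbind(pab^2, 2 * pAb * pab, pAb^2,
                2 * paB * pab, 2 * (pAB * pab + pAb * paB), 2 * pAB * pAb,
                paB^2, 2 * pAB * paB, pAB^2)
    lp <- suppressWarnings(log(pr))
    lp[!is.finite(lp)] <- -1e12
    as.vector(lp %*% cnt9)
  }
  s <- seq(0, 1, 0.01)
  gr <- expand.grid(pAB = s, pAb = s, paB = s)
  gr <- gr[gr$pAB + gr$pAb + gr$paB <= 1 + 1e-12, ]
  best <- gr[which.max(ll_of(gr$pAB, gr$pAb, gr$paB)), ]
  for (step in c(2e-3, 4e-4, 8e-5, 1.6e-5, 5e-6)) {
    s <- seq(-10, 10) * step
    g2 <- expand.grid(pAB = best$pAB + s, pAb = best$pAb + s,
                      paB = best$paB + s)
    g2 <- g2[g2$pAB >= 0 & g2$pAb >= 0 & g2$paB >= 0 &
               g2$pAB + g2$pAb + g2$paB <= 1, ]
    g2 <- rbind(g2, best)
    best <- g2[which.max(ll_of(g2$pAB, g2$pAb, g2$paB)), ]
  }
  max(ll_of(best$pAB, best$pAb, best$paB))
}

# 3x3 genotype count vector (index g1 + 3*g2 + 1) from dosage vectors.
count9 <- function(g1, g2) {
  as.vector(table(factor(g1, 0:2), factor(g2, 0:2)))
}

# Small genotype_matrix builder with evenly spaced positions.
make_geno <- function(d, chrom = NULL, pos = NULL, ids = NULL) {
  m <- ncol(d)
  if (is.null(rownames(d))) rownames(d) <- sprintf("s%03d", seq_len(nrow(d)))
  v <- data.frame(id = ids %||% sprintf("v%03d", seq_len(m)),
                  chrom = chrom %||% rep("1", m),
                  pos = pos %||% seq(1e5, by = 1e6, length.out = m),
                  a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  genotype_matrix(d, v)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
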