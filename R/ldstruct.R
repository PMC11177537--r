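# Intra-locus (Wright's F) and inter-locus (cross-chromosome D^2)
# correlation structure, with the SNP-thinning / top-vs-bottom-K
# resampling design.
#
# Positive Wright's F at a marker indicates a heterozygote deficit
# relative to Hardy-Weinberg expectation (inbreeding or pooled
# substructure, the Wahlund effect).  D^2 between unlinked markers
# measures long-range linkage disequilibrium; ancestry-based mate
# choice inflates it at ancestry-informative markers.

#' Greedy LD pruning
#'
#' Left-to-right scan per chromosome: a variant is removed when any
#' already-kept variant within `window_bp` has squared dosage
#' correlation above `r2_threshold` with it (the later member of each
#' offending pair is dropped).  Deterministic given input order.
#'
#' @param g a [genotype_matrix()] (founder samples).
#' @param r2_threshold squared-correlation threshold (default 0.1).
#' @param window_bp window size in base pairs (default 500 kb).
#' @return data frame of kept variants (`id`, `chrom`, `pos`).
#' @export
ld_prune <- function(g, r2_threshold = 0.1, window_bp = 5e5) {
  v <- g$variants
  d <- g$dosages
  keep <- logical(nrow(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    idx <- idx[order(v$pos[idx])]
    kept <- integer(0)
    kept_pos <- numeric(0)
    for (j in idx) {
      near <- kept[kept_pos >= v$pos[j] - window_bp]
      drop <- FALSE
      for (q in near) {
        r <- suppressWarnings(cor(d[, j], d[, q],
                                  use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2_threshold) { drop <- TRUE; break }
      }
      if (!drop) {
        kept <- c(kept, j)
        kept_pos <- c(kept_pos, v$pos[j])
        keep[j] <- TRUE
      }
    }
  }
  out <- v[keep, c("id", "chrom", "pos"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random distance-based SNP thinning
#'
#' Iterates the variants in a seeded random order and accepts a variant
#' iff no previously accepted variant on the same chromosome lies
#' closer than `min_gap_bp`.  Variants on different chromosomes never
#' conflict.
#'
#' @param variants variant data frame (`id`, `chrom`, `pos`).
#' @param min_gap_bp minimum pairwise distance within a chromosome
#'   (default 500 kb).
#' @param seed RNG seed for the visiting order.
#' @return the accepted subset of `variants`, in original row order.
#' @export
thin_by_distance <- function(variants, min_gap_bp = 5e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(variants)
  ord <- sample.int(n)
  acc <- logical(n)
  acc_pos <- list()
  for (i in ord) {
    ch <- variants$chrom[i]
    pos <- variants$pos[i]
    ap <- acc_pos[[ch]]
    if (is.null(ap) || all(abs(ap - pos) >= min_gap_bp)) {
      acc[i] <- TRUE
      acc_pos[[ch]] <- c(ap, pos)
    }
  }
  variants[acc, , drop = FALSE]
}

#' Wright's F from genotype counts
#'
#' `F = 1 - n_oAa / n_eAa`, the observed over the Hardy-Weinberg
#' expected heterozygote count `n_eAa = 2 p (1-p) n`.  Undefined
#' (returned as `NA`) for monomorphic markers; such markers are
#' excluded from set means downstream.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectors accepted).
#' @return numeric vector of F values.
#' @export
wrights_f <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  e <- 2 * p * (1 - p) * n
  ifelse(e > 0, 1 - n_Aa / e, NA_real_)
}

#' Two-locus EM haplotype frequencies from unphased genotypes
#'
#' Estimates the four haplotype frequencies (p_AB, p_Ab, p_aB, p_ab)
#' from paired dosages by expectation-maximization.  Only the double
#' heterozygote is phase-ambiguous; the E-step assigns it to the
#' coupling (AB/ab) phase with weight
#' `p_AB p_ab / (p_AB p_ab + p_Ab p_aB)`.  Initialization is at
#' linkage equilibrium; iteration stops when the largest absolute
#' frequency change falls below `tol`.  The implied allele frequencies
#' always equal the genotype-derived ones (the M-step preserves allele
#' counts).
#'
#' @param g1,g2 dosage vectors in `{0,1,2,NA}`; individuals missing at
#'   either locus are excluded.
#' @param tol convergence tolerance on frequencies (default 1e-10).
#' @param max_iter iteration cap (default 1000); non-convergence is
#'   flagged, not an error.
#' @return object of class `haplotype_freqs`: `p` (named length-4
#'   vector), `n`, `iterations`, `converged`, `loglik`.
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-10, max_iter = 1000) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  stop_if_not(n > 0, "no individuals with both loci observed")
  stop_if_not(all(g1 %in% 0:2) && all(g2 %in% 0:2), "dosages must be 0/1/2")
  cnt <- numeric(9)
  for (i in seq_len(n)) {
    cell <- g1[i] + 3 * g2[i] + 1
    cnt[cell] <- cnt[cell] + 1
  }
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  n11 <- cnt[1 + 3 * 1 + 1]
  base <- c(AB = 2 * cnt[2 + 3 * 2 + 1] + cnt[2 + 3 * 1 + 1] + cnt[1 + 3 * 2 + 1],
            Ab = 2 * cnt[2 + 3 * 0 + 1] + cnt[2 + 3 * 1 + 1] + cnt[1 + 3 * 0 + 1],
            aB = 2 * cnt[0 + 3 * 2 + 1] + cnt[1 + 3 * 2 + 1] + cnt[0 + 3 * 1 + 1],
            ab = 2 * cnt[0 + 3 * 0 + 1] + cnt[1 + 3 * 0 + 1] + cnt[0 + 3 * 1 + 1])
  p <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  loglik_of <- function(p) {
    pr <- c(p["ab"]^2, 2 * p["Ab"] * p["ab"], p["Ab"]^2,
            2 * p["aB"] * p["ab"], 2 * (p["AB"] * p["ab"] + p["Ab"] * p["aB"]),
            2 * p["AB"] * p["Ab"],
            p["aB"]^2, 2 * p["AB"] * p["aB"], p["AB"]^2)
    if (any(cnt > 0 & pr <= 0)) return(-Inf)
    sum(cnt[cnt > 0] * log(pr[cnt > 0]))
  }
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    coup <- p["AB"] * p["ab"]
    repl <- p["Ab"] * p["aB"]
    w <- if (coup + repl > 0) coup / (coup + repl) else 0.5
    q <- c(AB = (base["AB"] + w * n11),
           Ab = (base["Ab"] + (1 - w) * n11),
           aB = (base["aB"] + (1 - w) * n11),
           ab = (base["ab"] + w * n11)) / (2 * n)
    names(q) <- names(p)
    delta <- max(abs(q - p))
    p <- q
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(p = p, n = n, iterations = it, converged = converged,
                 loglik = unname(loglik_of(p))),
            class = "haplotype_freqs")
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat(sprintf("haplotype frequencies (n = %d, %d EM iterations%s):\n",
              x$n, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  print(round(x$p, 6))
  cat(sprintf("  D = %.6g, D^2 = %.6g, loglik = %.6f\n",
              x$p["AB"] - (x$p["AB"] + x$p["Ab"]) * (x$p["AB"] + x$p["aB"]),
              d_squared(x), x$loglik))
  invisible(x)
}

#' Squared linkage disequilibrium coefficient
#'
#' `D^2 = (p_AB - p_A p_B)^2` with `p_A = p_AB + p_Ab` and
#' `p_B = p_AB + p_aB`.  Invariant to allele relabelling at either
#' locus.
#'
#' @param h a `haplotype_freqs` object, or a length-4 numeric vector
#'   `(p_AB, p_Ab, p_aB, p_ab)`.
#' @return D-squared.
#' @export
d_squared <- function(h) {
  p <- if (inherits(h, "haplotype_freqs")) h$p else h
  pA <- p[1] + p[2]
  pB <- p[1] + p[3]
  unname((p[1] - pA * pB)^2)
}

#' Resampling comparison of ancestry-informative vs control SNPs
#'
#' The repeated-thinning design: per iteration, thin the (already
#' LD-pruned) panel to variants at least `min_gap_bp` apart using a
#' per-iteration derived seed (`seed + iteration`), rank the thinned
#' set by |PC1| loading, take the top-K and bottom-K variants, and for
#' each pedigree role compute (a) the mean Wright's F over each set
#' (undefined F excluded, contribution counts recorded) and (b) the
#' mean EM-based D^2 over all different-chromosome pairs within each
#' set, on that role's samples.  Iteration means are then compared
#' top-vs-bottom with Welch's two-sample t-test, per role and per
#' statistic.
#'
#' @param g a [genotype_matrix()] restricted to LD-pruned variants.
#' @param pedigree pedigree data frame (`father_id`, `mother_id`,
#'   `sibling_id`).
#' @param loadings named numeric vector of |PC1| loadings (or a
#'   `pca_model`, whose component-1 loadings are used), covering the
#'   variants of `g`.
#' @param n_iter number of thinning iterations (default 1000).
#' @param top_k set size (default 200).
#' @param min_gap_bp thinning distance (default 500 kb).
#' @param seed base seed; iteration i uses `seed + i`.
#' @param roles which pedigree roles to evaluate.
#' @return object of class `ld_comparison`: `iterations` (long data
#'   frame of per-iteration means) and `tests` (Welch t-test per role
#'   and statistic).
#' @export
resampling_comparison <- function(g, pedigree, loadings, n_iter = 1000,
                                  top_k = 200, min_gap_bp = 5e5, seed = 1,
                                  roles = c("father", "mother", "sibling")) {
  if (inherits(loadings, "pca_model"))
    loadings <- setNames(abs(loadings$loadings[, 1]),
                         loadings$variants$id)
  v <- g$variants
  stop_if_not(all(v$id %in% names(loadings)),
              "loadings must cover all variants of g")
  al <- abs(loadings[v$id])

  role_ids <- list()
  for (r in roles) {
    ids <- switch(r,
                  father = pedigree$father_id,
                  mother = pedigree$mother_id,
                  sibling = pedigree$sibling_id,
                  proband = pedigree$proband_id)
    ids <- intersect(unique(ids[!is.na(ids)]), samples(g))
    if (length(ids) > 0) role_ids[[r]] <- ids
  }
  stop_if_not(length(role_ids) > 0, "no pedigree roles resolvable")

  chrom_int <- as.integer(v$chrom)
  res <- vector("list", 0)
  skipped <- 0L
  for (it in seq_len(n_iter)) {
    thin <- thin_by_distance(v, min_gap_bp = min_gap_bp, seed = seed + it)
    if (nrow(thin) < 2 * top_k) {
      skipped <- skipped + 1L
      warning(sprintf("iteration %d skipped: thinned set %d < 2K", it, nrow(thin)))
      next
    }
    o <- order(-al[match(thin$id, v$id)], as.integer(thin$chrom), thin$pos)
    sets <- list(top = thin$id[o[seq_len(top_k)]],
                 bottom = thin$id[o[seq(length(o) - top_k + 1, length(o))]])
    for (set_name in names(sets)) {
      cols <- match(sets[[set_name]], v$id)
      for (r in names(role_ids)) {
        D <- g$dosages[role_ids[[r]], cols, drop = FALSE]
        n2 <- colSums(D == 2L, na.rm = TRUE)
        n1 <- colSums(D == 1L, na.rm = TRUE)
        n0 <- colSums(D == 0L, na.rm = TRUE)
        f <- wrights_f(n2, n1, n0)
        d2 <- .mean_d2_cross_cpp(D, chrom_int[cols], 1e-10, 1000L)
        res[[length(res) + 1]] <- data.frame(
          iteration = it, role = r, set = set_name,
          mean_f = mean(f, na.rm = TRUE), n_f = sum(!is.na(f)),
          mean_d2 = d2$mean_d2, n_pairs = d2$n_pairs)
      }
    }
  }
  stop_if_not(skipped <= 0.1 * n_iter,
              sprintf("%d of %d iterations skipped (> 10%%); thinned sets too small",
                      skipped, n_iter))
  iterations <- do.call(rbind, res)

  tests <- list()
  for (r in names(role_ids)) {
    for (stat in c("mean_f", "mean_d2")) {
      top <- iterations[iterations$role == r & iterations$set == "top", stat]
      bot <- iterations[iterations$role == r & iterations$set == "bottom", stat]
      tt <- t.test(top, bot)   # Welch
      tests[[length(tests) + 1]] <- data.frame(
        role = r, statistic = sub("mean_", "", stat),
        mean_top = mean(top), sd_top = sd(top),
        mean_bottom = mean(bot), sd_bottom = sd(bot),
        t = unname(tt$statistic), p = tt$p.value)
    }
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  structure(list(iterations = iterations, tests = tests,
                 n_iter = n_iter, top_k = top_k, skipped = skipped,
                 seed = seed,
                 note = "iteration means share samples; the t-test treats them as independent"),
            class = "ld_comparison")
}

#' @export
print.ld_comparison <- function(x, ...) {
  cat(sprintf("ld_comparison: %d iterations (K = %d, %d skipped)\n",
              x$n_iter, x$top_k, x$skipped))
  print.data.frame(x$tests, digits = 4)
  invisible(x)
}
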