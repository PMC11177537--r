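# Variant- and sample-level quality control.
#
# Filter chain (in order): sample missingness -> variant call rate ->
# extended-LD region exclusion -> MAF (founders) -> Hardy-Weinberg
# exact test (founders) -> Mendelian error rate.  Thresholds follow the
# usual family-cohort conventions: samples with more than 5% missing
# genotypes are removed, variants are kept with call rate >= 95% and
# MAF >= 0.01, and removed with HWE p < 1e-5 or Mendelian error > 5%.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test: the p-value is the sum of the probabilities of
#' all heterozygote counts (conditional on the observed allele counts)
#' whose probability does not exceed that of the observed count.  No
#' mid-p correction is applied.  Monomorphic markers return p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stop_if_not(all(c(n_AA, n_Aa, n_aa) >= 0), "counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  stop_if_not(n >= 1, "need at least one genotype")
  nA <- 2L * n_AA + n_Aa          # minor/major labelling is irrelevant
  na <- 2L * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  # heterozygote count shares the parity of the rare allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # relative probabilities via the standard two-way recurrence anchored at
  # the conditional mode (anchoring there avoids overflow for large n):
  #   P(h-2)/P(h) = h (h-1) / (4 (homr(h)+1)(homc(h)+1))
  #   P(h+2)/P(h) = 4 homr(h) homc(h) / ((h+2)(h+1))
  mode_h <- rare * (2 * n - rare) / (2 * n)
  k0 <- which.min(abs(hets - mode_h))
  probs <- numeric(length(hets))
  probs[k0] <- 1
  if (k0 > 1) for (k in seq(k0, 2)) {
    h <- hets[k]
    hom_r <- (rare - h) / 2          # rare-allele homozygotes at het count h
    hom_c <- (2 * n - rare - h) / 2  # common-allele homozygotes
    probs[k - 1] <- probs[k] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
  }
  if (k0 < length(hets)) for (k in seq(k0, length(hets) - 1)) {
    h <- hets[k]
    hom_r <- (rare - h) / 2
    hom_c <- (2 * n - rare - h) / 2
    probs[k + 1] <- probs[k] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

#' Per-sample missingness filter
#'
#' Removes samples whose missing-genotype fraction strictly exceeds
#' `max_missing` ("more than 5% missing" removes; exactly 5% is kept).
#'
#' @param g a [genotype_matrix()].
#' @param max_missing maximum tolerated missing fraction (default 0.05).
#' @return filtered `genotype_matrix`, sample order preserved; removed
#'   ids in the `"removed_samples"` attribute.
#' @export
sample_missingness_filter <- function(g, max_missing = 0.05) {
  frac <- rowMeans(is.na(g$dosages))
  keep <- frac <= max_missing
  out <- subset_genotypes(g, sample_ids = rownames(g$dosages)[keep])
  attr(out, "removed_samples") <- rownames(g$dosages)[!keep]
  out
}

#' Per-variant Mendelian error rate
#'
#' For each variant, the fraction of parent-parent-child trios whose
#' child genotype is impossible given both parents, among trios with all
#' three genotypes non-missing.  Variants with no informative trio get
#' `NA` (retained and flagged by the QC chain, never removed).
#'
#' @param g a [genotype_matrix()].
#' @param pedigree a pedigree data frame (see [simulate_cohort()]); the
#'   columns `father_id`, `mother_id`, `proband_id` and, when present,
#'   `sibling_id` define the trios.
#' @return numeric vector of error rates (named by variant id).
#' @export
mendel_error_rate <- function(g, pedigree) {
  d <- g$dosages
  trios <- rbind(
    cbind(pedigree$father_id, pedigree$mother_id, pedigree$proband_id),
    if ("sibling_id" %in% names(pedigree))
      cbind(pedigree$father_id, pedigree$mother_id, pedigree$sibling_id))
  trios <- trios[!is.na(trios[, 3]), , drop = FALSE]
  ids <- rownames(d)
  ok <- trios[, 1] %in% ids & trios[, 2] %in% ids & trios[, 3] %in% ids
  trios <- trios[ok, , drop = FALSE]
  stop_if_not(nrow(trios) > 0, "no trios resolvable from pedigree")
  Df <- d[trios[, 1], , drop = FALSE]
  Dm <- d[trios[, 2], , drop = FALSE]
  Dc <- d[trios[, 3], , drop = FALSE]
  informative <- !is.na(Df) & !is.na(Dm) & !is.na(Dc)
  # impossible transmissions for unlinked bi-allelic markers:
  #  - child lacks an allele a homozygous parent must transmit
  #  - child homozygous for an allele some parent cannot supply
  err <- (Df == 2 & Dc == 0) | (Df == 0 & Dc == 2) |
    (Dm == 2 & Dc == 0) | (Dm == 0 & Dc == 2) |
    (Df == 2 & Dm == 2 & Dc != 2) | (Df == 0 & Dm == 0 & Dc != 0) |
    (Df == 2 & Dm == 0 & Dc != 1) | (Df == 0 & Dm == 2 & Dc != 1)
  err[!informative] <- NA
  n_inf <- colSums(informative)
  rate <- colSums(err, na.rm = TRUE) / n_inf
  rate[n_inf == 0] <- NA_real_
  setNames(rate, colnames(d))
}

#' Apply the full variant/sample QC chain
#'
#' @param g a [genotype_matrix()].
#' @param pedigree pedigree data frame; used for founder identification
#'   (fathers and mothers) and Mendelian checks.
#' @param regions optional `ld_regions` (extended-LD exclusion list).
#' @param thresholds named list overriding any of `sample_missing`
#'   (0.05), `call_rate` (0.95), `maf` (0.01), `hwe_p` (1e-5),
#'   `mendel` (0.05).
#' @return list with `geno` (filtered matrix) and `report` (a
#'   `qc_report`: one row per step with before/removed/after counts).
#' @details MAF and the HWE exact test are computed on founders only
#'   (parents), after the sample filter, using non-missing calls;
#'   offspring of the same families are not independent draws and would
#'   distort both.  Genotypes of Mendelian-inconsistent cells are left
#'   in place; inconsistency beyond the rate threshold removes the
#'   variant, never individual calls.
#' @export
apply_qc_chain <- function(g, pedigree, regions = NULL, thresholds = list()) {
  th <- utils::modifyList(list(sample_missing = 0.05, call_rate = 0.95,
                               maf = 0.01, hwe_p = 1e-5, mendel = 0.05),
                          thresholds)
  steps <- list()
  note_step <- function(name, before, after)
    steps[[length(steps) + 1]] <<- data.frame(
      step = name, before = before, removed = before - after, after = after)

  # 1. sample missingness (counts samples, not variants)
  ns0 <- n_samples(g)
  g <- sample_missingness_filter(g, th$sample_missing)
  note_step("sample_missingness (samples)", ns0, n_samples(g))
  stop_if_not(n_samples(g) > 0, "no samples left after missingness filter")

  founders <- intersect(unique(c(pedigree$father_id, pedigree$mother_id)),
                        samples(g))
  stop_if_not(length(founders) > 0, "no founders present in genotype matrix")

  # 2. variant call rate
  m0 <- n_variants(g)
  call_rate <- 1 - colMeans(is.na(g$dosages))
  g <- subset_genotypes(g, variant_keep = call_rate >= th$call_rate)
  note_step("call_rate", m0, n_variants(g))

  # 3. extended-LD region exclusion
  m0 <- n_variants(g)
  if (!is.null(regions)) {
    inside <- variant_in_regions(g$variants, regions)
    g <- subset_genotypes(g, variant_keep = !inside)
  }
  note_step("extended_ld_regions", m0, n_variants(g))

  # 4. MAF on founders
  m0 <- n_variants(g)
  af <- allele_freq(g, founders)
  maf <- pmin(af, 1 - af)
  keep <- !is.na(maf) & maf >= th$maf
  g <- subset_genotypes(g, variant_keep = keep)
  note_step("maf", m0, n_variants(g))

  # 5. HWE exact test on founders
  m0 <- n_variants(g)
  cnt <- genotype_counts(g, founders)
  hwe_p <- vapply(seq_len(nrow(cnt)), function(i)
    hwe_exact_test(cnt[i, "n2"], cnt[i, "n1"], cnt[i, "n0"]), numeric(1))
  g <- subset_genotypes(g, variant_keep = hwe_p >= th$hwe_p)
  note_step("hwe", m0, n_variants(g))

  # 6. Mendelian error rate
  m0 <- n_variants(g)
  mer <- mendel_error_rate(g, pedigree)
  keep <- is.na(mer) | mer <= th$mendel   # undefined rate: retained, flagged
  g <- subset_genotypes(g, variant_keep = keep)
  note_step("mendel", m0, n_variants(g))
  stop_if_not(n_variants(g) > 0, "no variants left after QC chain")

  report <- do.call(rbind, steps)
  rownames(report) <- NULL
  attr(report, "thresholds") <- th
  attr(report, "flagged_no_trio") <- names(mer)[is.na(mer)]
  class(report) <- c("qc_report", "data.frame")
  list(geno = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC chain report (rows = filter steps):\n")
  print.data.frame(x)
  th <- attr(x, "thresholds")
  cat(sprintf("thresholds: sample_missing <= %g, call_rate >= %g, maf >= %g, hwe_p >= %g, mendel <= %g\n",
              th$sample_missing, th$call_rate, th$maf, th$hwe_p, th$mendel))
  invisible(x)
}
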