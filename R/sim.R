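# Forward simulator of quartet families from an admixed population
# under ancestry-related and/or trait-based assortative mating.
#
# Two ancestral subpopulations diverge under the Balding-Nichols model
# (beta-distributed subpopulation frequencies around an ancestral
# frequency, parameterized by FST).  Founders carry a continuous
# admixture proportion alpha; a founder's genotype at each marker is
# binomial with frequency alpha p1 + (1 - alpha) p2.  Mate choice is a
# Gaussian-copula coupling on ancestry ranks (and trait ranks when
# trait assortment is configured), which guarantees the target spousal
# correlation without modelling a search mechanism.  Loci are unlinked:
# the downstream analyses only use markers >= 500 kb apart or on
# different chromosomes, where background LD is negligible and
# assortment-induced LD does not require linkage.
#
# With n_generations = 2 (the default) the configured mating rule acts
# in the grandparental generation as well, so the parents of each
# quartet are themselves offspring of assortative couples.  Within a
# single generation, pairing cannot alter the parents' own genotypic
# structure (the set of fathers is invariant to who marries whom);
# ancestry-related assortment leaves its intra- and inter-locus
# signature on a generation only through that generation's ancestors.

#' Simulation configuration
#'
#' @param n_snps number of bi-allelic markers.
#' @param n_chromosomes autosome count (markers assigned round-robin).
#' @param chrom_length_bp chromosome length for uniform positions.
#' @param fst Balding-Nichols divergence of the two ancestral
#'   subpopulations (0 <= fst < 1).  The default 0.005 is a
#'   within-continent scale; no quantitative within-European divergence
#'   is established, so this is a configuration choice, not a claim.
#' @param admixture_beta shape of the symmetric Beta distribution of
#'   founder admixture proportions.  `Inf` gives the panmictic limit
#'   (every founder at alpha = 0.5, i.e. a fully mixed population with
#'   no standing ancestry variance) — the appropriate null world for
#'   type-I-error calibrations, since any population with ancestry
#'   variance carries genuine admixture LD whatever the current mating
#'   pattern.
#' @param n_families number of quartet families.
#' @param rho_ancestry target spousal correlation of admixture
#'   proportion, in `[0, 1)`.
#' @param rho_trait target spousal correlation of the quantitative
#'   trait, in `[0, 1)`; `rho_ancestry + rho_trait` must stay below 1.
#' @param n_causal causal marker count for the trait.
#' @param h2 trait heritability in `[0, 1]`.
#' @param ascertainment_quantile liability-threshold prevalence: a
#'   child is affected iff its liability exceeds the
#'   `1 - ascertainment_quantile` quantile of the parent generation.
#' @param missing_rate per-genotype missingness injected at output.
#' @param n_generations 1 = founders are the parents; 2 = founders are
#'   the grandparents and the configured mating rule acts twice.
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 2000, n_chromosomes = 22,
                       chrom_length_bp = 1e8, fst = 0.005,
                       admixture_beta = 2, n_families = 500,
                       rho_ancestry = 0.5, rho_trait = 0,
                       n_causal = 100, h2 = 0.5,
                       ascertainment_quantile = 0.02,
                       missing_rate = 0, n_generations = 2, seed = 1) {
  cfg <- list(n_snps = n_snps, n_chromosomes = n_chromosomes,
              chrom_length_bp = chrom_length_bp, fst = fst,
              admixture_beta = admixture_beta, n_families = n_families,
              rho_ancestry = rho_ancestry, rho_trait = rho_trait,
              n_causal = n_causal, h2 = h2,
              ascertainment_quantile = ascertainment_quantile,
              missing_rate = missing_rate, n_generations = n_generations,
              seed = seed)
  stop_if_not(fst >= 0 && fst < 1, "fst must be in [0, 1)")
  stop_if_not(h2 >= 0 && h2 <= 1, "h2 must be in [0, 1]")
  stop_if_not(rho_ancestry >= 0 && rho_ancestry < 1,
              "rho_ancestry must be in [0, 1)")
  stop_if_not(rho_trait >= 0 && rho_trait < 1, "rho_trait must be in [0, 1)")
  stop_if_not(rho_ancestry + rho_trait < 1,
              "rho_ancestry + rho_trait must be < 1")
  stop_if_not(n_causal <= n_snps, "n_causal must be <= n_snps")
  stop_if_not(!(h2 > 0 && n_causal == 0),
              "h2 > 0 requires at least one causal marker")
  stop_if_not(ascertainment_quantile >= 0 && ascertainment_quantile < 1,
              "ascertainment_quantile must be in [0, 1)")
  stop_if_not(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must be in [0, 1)")
  stop_if_not(n_generations %in% 1:2, "n_generations must be 1 or 2")
  class(cfg) <- "sim_config"
  cfg
}

#' Draw subpopulation allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are uniform on `[0.05, 0.95]`; the two
#' subpopulation frequencies are independent draws from
#' `Beta(p (1-fst)/fst, (1-p)(1-fst)/fst)` (degenerate at `p` when
#' `fst = 0`).  Markers are assigned round-robin to chromosomes with
#' uniform positions, then sorted by (chromosome, position).
#'
#' @param n_snps,fst,n_chromosomes,chrom_length_bp see [sim_config()].
#' @param seed optional seed (otherwise the current RNG state is used).
#' @return data frame `id`, `chrom`, `pos`, `a1`, `a2`, `p`, `p1`, `p2`.
#' @export
draw_subpop_freqs <- function(n_snps, fst, n_chromosomes = 22,
                              chrom_length_bp = 1e8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- runif(n_snps, 0.05, 0.95)
  if (fst == 0) {
    p1 <- p2 <- p
  } else {
    p1 <- rbeta(n_snps, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
    p2 <- rbeta(n_snps, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
  }
  chrom <- as.character(((seq_len(n_snps) - 1L) %% n_chromosomes) + 1L)
  pos <- sample.int(chrom_length_bp, n_snps, replace = TRUE)
  o <- order(as.integer(chrom), pos)
  out <- data.frame(id = sprintf("snp%05d", seq_len(n_snps)),
                    chrom = chrom[o], pos = pos[o],
                    a1 = "A", a2 = "G",
                    p = p[o], p1 = p1[o], p2 = p2[o],
                    stringsAsFactors = FALSE)
  # collapse the (vanishingly rare) duplicate positions
  dup <- duplicated(out[, c("chrom", "pos")])
  if (any(dup)) out$pos[dup] <- out$pos[dup] + 1L
  out
}

#' Draw admixed founders
#'
#' @param freqs frequency table from [draw_subpop_freqs()].
#' @param n founders to draw.
#' @param admixture_beta Beta shape for admixture proportions; or pass
#'   fixed `alpha`.
#' @param alpha optional fixed admixture proportion(s), recycled to n.
#' @return list with `alpha` (length n) and `dosages` (n x n_snps
#'   integer matrix, unnamed rows).
#' @export
draw_founders <- function(freqs, n, admixture_beta = 2, alpha = NULL) {
  if (is.null(alpha)) {
    alpha <- if (is.infinite(admixture_beta)) rep(0.5, n)
    else rbeta(n, admixture_beta, admixture_beta)
  }
  alpha <- rep_len(alpha, n)
  pv <- outer(alpha, freqs$p1) + outer(1 - alpha, freqs$p2)
  d <- matrix(rbinom(length(pv), 2L, pv), nrow = n)
  list(alpha = alpha, dosages = d)
}

#' Assortative pairing by Gaussian-copula coupling
#'
#' Draws bivariate-normal latent ranks with the target correlation and
#' matches males and females by sorted latent versus sorted matching
#' value.  The matching value is the normal score of the admixture
#' proportion, of the trait, or (when both correlations are requested)
#' a weighted combination calibrated so each marginal spousal
#' correlation is approximately attained.
#'
#' @param founders data frame with columns `idx`, `sex` ("male" /
#'   "female"; equal counts), `alpha`, and `trait` / `family` as needed.
#' @param rho_ancestry,rho_trait target spousal correlations.
#' @param seed optional seed.
#' @return data frame `father_idx`, `mother_idx`, one row per couple.
#'   Couples sharing a `family` value (full siblings) are broken up by
#'   swapping mothers with a neighbouring couple.
#' @export
mate_assortatively <- function(founders, rho_ancestry, rho_trait = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stop_if_not(rho_ancestry >= 0 && rho_ancestry < 1 &&
                rho_trait >= 0 && rho_trait < 1 &&
                rho_ancestry + rho_trait < 1,
              "rho values must be in [0, 1) with sum < 1")
  males <- founders[founders$sex == "male", , drop = FALSE]
  females <- founders[founders$sex == "female", , drop = FALSE]
  nc <- nrow(males)
  stop_if_not(nc == nrow(females), "need equal numbers of males and females")

  match_value <- function(df) {
    za <- normal_scores(df$alpha)
    if (rho_trait > 0) {
      stop_if_not(!is.null(df$trait), "rho_trait > 0 needs a trait column")
      zt <- normal_scores(df$trait)
      w <- rho_ancestry / (rho_ancestry + rho_trait)
      sqrt(w) * za + sqrt(1 - w) * zt
    } else za
  }
  rho_c <- rho_ancestry + rho_trait
  vm <- match_value(males)
  vf <- match_value(females)
  if (rho_c == 0) {
    father <- males$idx
    mother <- females$idx[sample.int(nc)]
  } else {
    z1 <- rnorm(nc)
    z2 <- rho_c * z1 + sqrt(1 - rho_c^2) * rnorm(nc)
    father <- males$idx[order(vm)][rank(z1, ties.method = "first")]
    mother <- females$idx[order(vf)][rank(z2, ties.method = "first")]
  }
  pairs <- data.frame(father_idx = father, mother_idx = mother)
  if (!is.null(founders$family)) {
    fam <- setNames(founders$family, as.character(founders$idx))
    same <- fam[as.character(pairs$father_idx)] ==
      fam[as.character(pairs$mother_idx)]
    for (i in which(same)) {   # swap mothers with the next couple
      j <- if (i < nc) i + 1L else 1L
      tmp <- pairs$mother_idx[i]
      pairs$mother_idx[i] <- pairs$mother_idx[j]
      pairs$mother_idx[j] <- tmp
    }
  }
  pairs
}

#' Mendelian transmission
#'
#' Each parent transmits, per marker independently, one of its two
#' alleles chosen uniformly (deterministic for homozygotes, fair coin
#' for heterozygotes).  Trios are Mendelian-consistent by construction.
#'
#' @param g_father,g_mother parent dosage matrices, couples aligned by
#'   row; no missing values (missingness is injected afterwards).
#' @param n_children children per couple.
#' @return list of `n_children` dosage matrices.
#' @export
simulate_offspring <- function(g_father, g_mother, n_children = 2) {
  stop_if_not(!anyNA(g_father) && !anyNA(g_mother),
              "parental genotypes must be non-missing at transmission time")
  stop_if_not(all(dim(g_father) == dim(g_mother)),
              "parent matrices must have identical dimensions")
  lapply(seq_len(n_children), function(i) {
    pat <- matrix(rbinom(length(g_father), 1L, g_father / 2), nrow(g_father))
    mat <- matrix(rbinom(length(g_mother), 1L, g_mother / 2), nrow(g_mother))
    pat + mat
  })
}

# Draw causal effects and return the per-column beta vector scaled so
# that var(genetic value) = h2 and residual sd = sqrt(1 - h2) in the
# reference (parent) generation.
scale_effects <- function(ref_dosages, causal_idx, raw_beta, h2) {
  beta <- numeric(ncol(ref_dosages))
  if (h2 == 0 || length(causal_idx) == 0) {
    return(list(beta = beta, sigma_e = 1))
  }
  beta[causal_idx] <- raw_beta
  gv <- as.vector(ref_dosages %*% beta)
  vg <- var(gv)
  stop_if_not(vg > 0, "genetic variance is zero; cannot scale to h2 > 0")
  beta <- beta * sqrt(h2 / vg)
  list(beta = beta, sigma_e = sqrt(1 - h2))
}

#' Trait simulation and liability-threshold ascertainment
#'
#' Causal effects are standard-normal draws rescaled so the genetic
#' variance over the parent generation equals `h2`; the trait (equal
#' to the liability) adds normal noise of variance `1 - h2`.  A child
#' is affected iff its liability exceeds the
#' `1 - ascertainment_quantile` empirical quantile of the parent
#' generation.  Families with exactly one affected child form the
#' "simplex-like" subset; the proband is the affected child (child 1
#' when none or both are affected, so every family has exactly one
#' proband).  Group labels emulating the two severity strata are an
#' independent per-family coin flip, hence exchangeable under the null
#' of equal assortment across strata.
#'
#' @param parent_dosages parent-generation dosage matrix (couples'
#'   fathers then mothers, any order; used as the scaling/threshold
#'   reference).
#' @param child_dosages list of two child dosage matrices (couples
#'   aligned by row).
#' @param config a [sim_config()].
#' @param effects optional precomputed effect list from an earlier
#'   call (fields `causal_idx`, `raw_beta`); drawn fresh otherwise.
#' @return list: `beta` (per-marker scaled effects), `sigma_e`,
#'   `threshold`, `parent_trait`, `parent_genetic`, `child_trait`
#'   (list), `child_genetic` (list), `affected` (n_families x 2
#'   logical), `group_label`, `causal_idx`.
#' @export
simulate_trait_and_ascertain <- function(parent_dosages, child_dosages,
                                         config, effects = NULL) {
  m <- ncol(parent_dosages)
  if (is.null(effects)) {
    causal_idx <- sort(sample.int(m, config$n_causal))
    raw_beta <- rnorm(config$n_causal)
  } else {
    causal_idx <- effects$causal_idx
    raw_beta <- effects$raw_beta
  }
  sc <- scale_effects(parent_dosages, causal_idx, raw_beta, config$h2)
  gv_parent <- as.vector(parent_dosages %*% sc$beta)
  trait_parent <- gv_parent + rnorm(length(gv_parent), sd = sc$sigma_e)
  threshold <- if (config$ascertainment_quantile > 0)
    quantile(trait_parent, 1 - config$ascertainment_quantile, names = FALSE)
  else Inf
  child_gv <- lapply(child_dosages, function(d) as.vector(d %*% sc$beta))
  child_trait <- lapply(child_gv, function(g)
    g + rnorm(length(g), sd = sc$sigma_e))
  affected <- vapply(child_trait, function(tr) tr > threshold,
                     logical(length(child_trait[[1]])))
  if (is.null(dim(affected)))
    affected <- matrix(affected, nrow = 1)
  group_label <- ifelse(runif(nrow(affected)) < 0.5,
                        "with_CI_ID", "without_CI_ID")
  list(beta = sc$beta, sigma_e = sc$sigma_e, threshold = threshold,
       parent_trait = trait_parent, parent_genetic = gv_parent,
       child_trait = child_trait, child_genetic = child_gv,
       affected = affected, group_label = group_label,
       causal_idx = causal_idx)
}

#' Simulate a full quartet cohort
#'
#' Runs the complete generative process: subpopulation frequencies,
#' admixed founders, assortative pairing (acting in each simulated
#' generation), Mendelian transmission, trait simulation with
#' liability-threshold ascertainment, pedigree assembly, and
#' missingness injection.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `geno` ([genotype_matrix()] of
#'   parents and children), `pedigree` (one row per family), `traits`
#'   (per-sample table with SRS-like and BAPQ-like parent scores),
#'   `alpha` (named true admixture proportions), `effects` (`id`,
#'   `beta` of causal markers, scaled), `freqs`, `threshold`, `config`.
#' @export
simulate_cohort <- function(config) {
  stop_if_not(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  nf <- config$n_families
  freqs <- draw_subpop_freqs(config$n_snps, config$fst,
                             config$n_chromosomes, config$chrom_length_bp)
  m <- nrow(freqs)

  if (config$n_generations == 2) {
    g0m <- draw_founders(freqs, nf, config$admixture_beta)
    g0f <- draw_founders(freqs, nf, config$admixture_beta)
    # grandparental traits for trait-based assortment
    founders0 <- data.frame(idx = seq_len(2 * nf),
                            sex = rep(c("male", "female"), each = nf),
                            alpha = c(g0m$alpha, g0f$alpha))
    D0 <- rbind(g0m$dosages, g0f$dosages)
    eff0 <- NULL
    if (config$rho_trait > 0) {
      causal_idx <- sort(sample.int(m, config$n_causal))
      raw_beta <- rnorm(config$n_causal)
      eff0 <- list(causal_idx = causal_idx, raw_beta = raw_beta)
      sc0 <- scale_effects(D0, causal_idx, raw_beta, config$h2)
      founders0$trait <- as.vector(D0 %*% sc0$beta) +
        rnorm(2 * nf, sd = sc0$sigma_e)
    }
    pairs0 <- mate_assortatively(founders0, config$rho_ancestry,
                                 config$rho_trait)
    Df0 <- D0[pairs0$father_idx, , drop = FALSE]
    Dm0 <- D0[pairs0$mother_idx, , drop = FALSE]
    kids <- simulate_offspring(Df0, Dm0, n_children = 2)
    alpha_mid <- (founders0$alpha[pairs0$father_idx] +
                    founders0$alpha[pairs0$mother_idx]) / 2
    # one son and one daughter per grandparental couple
    D_par <- rbind(kids[[1]], kids[[2]])
    par_alpha <- c(alpha_mid, alpha_mid)
    par_sex <- rep(c("male", "female"), each = nf)
    par_family <- c(seq_len(nf), seq_len(nf))
  } else {
    g1m <- draw_founders(freqs, nf, config$admixture_beta)
    g1f <- draw_founders(freqs, nf, config$admixture_beta)
    D_par <- rbind(g1m$dosages, g1f$dosages)
    par_alpha <- c(g1m$alpha, g1f$alpha)
    par_sex <- rep(c("male", "female"), each = nf)
    par_family <- rep(NA_integer_, 2 * nf)
    eff0 <- NULL
  }

  # parent traits (needed both for assortment and for the trait table)
  if (is.null(eff0)) {
    causal_idx <- sort(sample.int(m, config$n_causal))
    raw_beta <- rnorm(config$n_causal)
    eff0 <- list(causal_idx = causal_idx, raw_beta = raw_beta)
  }
  parents <- data.frame(idx = seq_len(2 * nf), sex = par_sex,
                        alpha = par_alpha, family = par_family)
  sc <- scale_effects(D_par, eff0$causal_idx, eff0$raw_beta, config$h2)
  parents$trait <- as.vector(D_par %*% sc$beta) +
    rnorm(2 * nf, sd = sc$sigma_e)

  pairs <- mate_assortatively(parents, config$rho_ancestry, config$rho_trait)
  Df <- D_par[pairs$father_idx, , drop = FALSE]
  Dm <- D_par[pairs$mother_idx, , drop = FALSE]
  kids <- simulate_offspring(Df, Dm, n_children = 2)

  tr <- simulate_trait_and_ascertain(D_par, kids, config, effects = eff0)
  child_sex <- matrix(ifelse(runif(2 * nf) < 0.5, "male", "female"), nf, 2)

  fam_id <- sprintf("F%04d", seq_len(nf))
  father_id <- sprintf("P%04d_f", seq_len(nf))
  mother_id <- sprintf("P%04d_m", seq_len(nf))
  child1_id <- sprintf("C%04d_1", seq_len(nf))
  child2_id <- sprintf("C%04d_2", seq_len(nf))

  aff <- tr$affected
  simplex <- xor(aff[, 1], aff[, 2])
  proband_is_1 <- aff[, 1] | !aff[, 2]   # affected child; child 1 on ties
  proband_id <- ifelse(proband_is_1, child1_id, child2_id)
  sibling_id <- ifelse(proband_is_1, child2_id, child1_id)
  pick <- function(x1, x2) ifelse(proband_is_1, x1, x2)
  pedigree <- data.frame(
    family_id = fam_id, father_id = father_id, mother_id = mother_id,
    proband_id = proband_id, sibling_id = sibling_id,
    proband_sex = pick(child_sex[, 1], child_sex[, 2]),
    sibling_sex = pick(child_sex[, 2], child_sex[, 1]),
    proband_affected = pick(aff[, 1], aff[, 2]),
    sibling_affected = pick(aff[, 2], aff[, 1]),
    group_label = tr$group_label,
    family_type = ifelse(aff[, 1] & aff[, 2], "multiplex",
                         ifelse(simplex, "simplex", "unknown")),
    retained_simplex = simplex,
    proband_carrier = FALSE, sibling_carrier = FALSE,
    stringsAsFactors = FALSE)
  class(pedigree) <- c("pedigree", "data.frame")

  all_ids <- c(father_id, mother_id, child1_id, child2_id)
  D_all <- rbind(Df, Dm, kids[[1]], kids[[2]])
  rownames(D_all) <- all_ids
  if (config$missing_rate > 0) {
    drop <- runif(length(D_all)) < config$missing_rate
    D_all[drop] <- NA_integer_
  }
  geno <- genotype_matrix(D_all, freqs[, c("id", "chrom", "pos", "a1", "a2")])

  alpha_all <- c(parents$alpha[pairs$father_idx], parents$alpha[pairs$mother_idx],
                 rep((parents$alpha[pairs$father_idx] +
                        parents$alpha[pairs$mother_idx]) / 2, 2))
  names(alpha_all) <- all_ids

  par_trait <- c(parents$trait[pairs$father_idx], parents$trait[pairs$mother_idx])
  # SRS-like (informant) and BAPQ-like (self-report) parent scores:
  # noisy transforms of the latent trait with different reliabilities
  srs <- 50 + 15 * (0.85 * par_trait + rnorm(2 * nf, sd = sqrt(1 - 0.85^2)))
  bapq <- 3 + 0.6 * (0.6 * par_trait + rnorm(2 * nf, sd = sqrt(1 - 0.6^2)))
  traits <- data.frame(
    sample_id = all_ids,
    family_id = rep(fam_id, 4),
    role = rep(c("father", "mother", "child1", "child2"), each = nf),
    sex = c(rep("male", nf), rep("female", nf), child_sex[, 1], child_sex[, 2]),
    trait = c(par_trait, tr$child_trait[[1]], tr$child_trait[[2]]),
    genetic_value = c(as.vector(Df %*% tr$beta), as.vector(Dm %*% tr$beta),
                      tr$child_genetic[[1]], tr$child_genetic[[2]]),
    srs_total = c(srs, rep(NA_real_, 2 * nf)),
    bapq_total = c(bapq, rep(NA_real_, 2 * nf)),
    age = c(round(rnorm(2 * nf, 38, 5)), rep(NA_real_, 2 * nf)),
    highest_education = c(sample(1:5, 2 * nf, replace = TRUE),
                          rep(NA_integer_, 2 * nf)),
    stringsAsFactors = FALSE)

  effects <- data.frame(id = freqs$id[tr$causal_idx],
                        beta = tr$beta[tr$causal_idx],
                        stringsAsFactors = FALSE)
  structure(list(geno = geno, pedigree = pedigree, traits = traits,
                 alpha = alpha_all, effects = effects, freqs = freqs,
                 threshold = tr$threshold, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d families (%d simplex-like), %d markers, fst = %g, rho_ancestry = %g, rho_trait = %g\n",
              nrow(x$pedigree), sum(x$pedigree$retained_simplex),
              n_variants(x$geno), x$config$fst, x$config$rho_ancestry,
              x$config$rho_trait))
  invisible(x)
}

#' Draw labelled reference panels
#'
#' Panels at the two ancestral poles (alpha = 1 and 0) plus three
#' intermediate labelled subpanels, for exercising the centroid-rule
#' ancestry assignment: the poles act as the continental contrast
#' panels (round 1), the intermediates as the retained-ancestry
#' subpanels (round 2).
#'
#' @param freqs frequency table from [draw_subpop_freqs()].
#' @param n_per samples per panel.
#' @param alphas named vector of panel admixture proportions.
#' @return list with `geno` ([genotype_matrix()]) and `labels` (named
#'   character vector, panel label per sample).
#' @export
draw_reference_panels <- function(freqs, n_per = 60,
                                  alphas = c(pole_a = 1, pole_b = 0,
                                             sub_a = 0.65, sub_b = 0.5,
                                             sub_c = 0.35)) {
  mats <- list()
  labels <- character(0)
  ids <- character(0)
  for (lab in names(alphas)) {
    fd <- draw_founders(freqs, n_per, alpha = alphas[[lab]])
    mats[[lab]] <- fd$dosages
    ids <- c(ids, sprintf("%s_%03d", lab, seq_len(n_per)))
    labels <- c(labels, rep(lab, n_per))
  }
  D <- do.call(rbind, mats)
  rownames(D) <- ids
  list(geno = genotype_matrix(D, freqs[, c("id", "chrom", "pos", "a1", "a2")]),
       labels = setNames(labels, ids))
}

#' Write a simulated dataset to disk
#'
#' Emits the cohort as a PLINK triplet plus `pedigree.tsv` and
#' `traits.tsv`, the reference panels as a second PLINK triplet with
#' `ref_labels.tsv`, and a `manifest.json` recording seed and
#' configuration.  Output is deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return the `sim_cohort`, invisibly.
#' @export
emit_dataset <- function(config, dir) {
  cohort <- simulate_cohort(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ped <- cohort$pedigree
  nf <- nrow(ped)
  fam <- data.frame(
    fid = rep(ped$family_id, 4),
    iid = c(ped$father_id, ped$mother_id, ped$proband_id, ped$sibling_id),
    pat = c(rep("0", 2 * nf), rep(ped$father_id, 2)),
    mat = c(rep("0", 2 * nf), rep(ped$mother_id, 2)),
    sex = c(rep(1L, nf), rep(2L, nf),
            ifelse(ped$proband_sex == "male", 1L, 2L),
            ifelse(ped$sibling_sex == "male", 1L, 2L)),
    pheno = c(rep(1, 2 * nf), ifelse(ped$proband_affected, 2, 1),
              ifelse(ped$sibling_affected, 2, 1)),
    stringsAsFactors = FALSE)
  g <- subset_genotypes(cohort$geno, sample_ids = fam$iid)
  write_plink(g, file.path(dir, "cohort"), fam = fam)
  write.table(ped, file.path(dir, "pedigree.tsv"), quote = FALSE,
              sep = "\t", row.names = FALSE)
  write.table(cohort$traits, file.path(dir, "traits.tsv"), quote = FALSE,
              sep = "\t", row.names = FALSE)
  ref <- draw_reference_panels(cohort$freqs)
  write_plink(ref$geno, file.path(dir, "ref_panels"))
  write.table(data.frame(sample_id = names(ref$labels), label = ref$labels,
                         row.names = NULL),
              file.path(dir, "ref_labels.tsv"), quote = FALSE,
              sep = "\t", row.names = FALSE)
  cfg <- unclass(cohort$config)
  jsonlite::write_json(list(seed = cfg$seed, config = cfg),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}
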