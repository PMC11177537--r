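# End-to-end driver: simulate -> QC -> ancestry (two rounds) ->
# spousal correlations -> PGS / pTDT / odd-even theta -> intra- and
# inter-locus structure.  Every stochastic stage draws from the single
# stream seeded by the run seed, so identical configurations reproduce
# identical outputs.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] for the generated cohort.
#' @param stages character vector of stages to run after simulation,
#'   any of `"qc"`, `"ancestry"`, `"amcorr"`, `"pgs"`, `"ldstruct"`.
#'   Later stages require the earlier ones.
#' @param qc_thresholds passed to [apply_qc_chain()].
#' @param k_pcs PCs for the ancestry model.
#' @param n_iter,top_k,min_gap_bp resampling-comparison parameters.
#' @param min_n_r,min_n_power,min_n_alpha the subgroup power rule: a
#'   stratum is analysed only when its family count reaches
#'   `min_n_for_power(min_n_r, min_n_alpha, min_n_power)`.
#' @param m_tests Bonferroni family size used to annotate results
#'   (the full enumeration of tests is a property of the study design,
#'   taken as configuration).
#' @param out_dir optional output directory for TSV/JSON results.
#' @param seed run seed (also overrides `sim$seed`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("qc", "ancestry", "amcorr",
                                       "pgs", "ldstruct"),
                            qc_thresholds = list(), k_pcs = 20,
                            n_iter = 100, top_k = 100, min_gap_bp = 5e5,
                            min_n_r = 0.3, min_n_power = 0.8,
                            min_n_alpha = 0.05, m_tests = 336,
                            out_dir = NULL, seed = 1) {
  sim$seed <- seed
  cfg <- list(sim = sim, stages = stages, qc_thresholds = qc_thresholds,
              k_pcs = k_pcs, n_iter = n_iter, top_k = top_k,
              min_gap_bp = min_gap_bp, min_n_r = min_n_r,
              min_n_power = min_n_power, min_n_alpha = min_n_alpha,
              m_tests = m_tests, out_dir = out_dir, seed = seed)
  stop_if_not(all(stages %in% c("qc", "ancestry", "amcorr", "pgs", "ldstruct")),
              "unknown stage name")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` holding the per-stage
#'   outputs (`cohort`, `qc`, `ancestry`, `spousal`, `comparisons`,
#'   `skipped_strata`, `pgs`, `ldstruct`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "pipeline_config"), "need a pipeline_config")
  stages <- config$stages
  counts <- list()
  res <- list(config = config)
  min_n <- min_n_for_power(config$min_n_r, config$min_n_alpha,
                           config$min_n_power)

  cohort <- simulate_cohort(config$sim)
  res$cohort <- cohort
  counts$families <- nrow(cohort$pedigree)
  counts$variants_simulated <- n_variants(cohort$geno)
  g <- cohort$geno
  ped <- cohort$pedigree

  if ("qc" %in% stages) {
    qc <- apply_qc_chain(g, ped, regions = NULL,
                         thresholds = config$qc_thresholds)
    g <- qc$geno
    res$qc <- qc$report
    counts$variants_post_qc <- n_variants(g)
  }

  founder_ids <- intersect(c(ped$father_id, ped$mother_id), samples(g))
  child_ids <- intersect(c(ped$proband_id, ped$sibling_id), samples(g))
  g_founders <- subset_genotypes(g, sample_ids = founder_ids)
  g_children <- subset_genotypes(g, sample_ids = child_ids)

  if ("ancestry" %in% stages) {
    ref <- draw_reference_panels(cohort$freqs)
    ref_g <- subset_genotypes(ref$geno, variant_keep = g$variants$id)
    # round 1: pole contrasts for inclusion
    r1_ids <- names(ref$labels)[ref$labels %in% c("sub_b", "pole_a", "pole_b")]
    pruned <- ld_prune(g_founders)
    gf_p <- subset_genotypes(g_founders, variant_keep = pruned$id)
    gr_p <- subset_genotypes(ref_g, sample_ids = r1_ids,
                             variant_keep = pruned$id)
    m1 <- fit_reference_pca(gf_p, gr_p, k = min(config$k_pcs, 10))
    all_scores1 <- rbind(
      m1$scores[founder_ids, , drop = FALSE],
      project_samples(m1, subset_genotypes(g_children,
                                           variant_keep = pruned$id)))
    ref_scores1 <- m1$scores[r1_ids, , drop = FALSE]
    call1 <- assign_ancestry(all_scores1, ref_scores1,
                             ref$labels[r1_ids], target = "sub_b")
    assigned <- setNames(call1$assigned, call1$sample_id)
    fam_ok <- assigned[ped$father_id] & assigned[ped$mother_id] &
      assigned[ped$proband_id] & assigned[ped$sibling_id]
    ped_r <- ped[fam_ok, , drop = FALSE]
    counts$families_assigned <- nrow(ped_r)

    # round 2: retained-ancestry subpanels; loadings used downstream
    founder_r <- intersect(c(ped_r$father_id, ped_r$mother_id), samples(g))
    r2_ids <- names(ref$labels)[ref$labels %in% c("sub_a", "sub_b", "sub_c")]
    gf2 <- subset_genotypes(g, sample_ids = founder_r,
                            variant_keep = pruned$id)
    gr2 <- subset_genotypes(ref_g, sample_ids = r2_ids,
                            variant_keep = pruned$id)
    m2 <- fit_reference_pca(gf2, gr2, k = config$k_pcs)
    child_r <- intersect(c(ped_r$proband_id, ped_r$sibling_id), samples(g))
    child_scores <- project_samples(
      m2, subset_genotypes(g, sample_ids = child_r, variant_keep = pruned$id))
    scores <- rbind(m2$scores[founder_r, , drop = FALSE], child_scores)
    res$ancestry <- list(round1 = m1, round2 = m2, calls = call1,
                         scores = scores, pruned = pruned)
    ped <- ped_r
  } else {
    scores <- NULL
  }

  if ("amcorr" %in% stages) {
    stop_if_not(!is.null(scores), "amcorr stage requires ancestry")
    spousal <- list()
    comparisons <- list()
    skipped <- list()
    tr <- cohort$traits
    vars <- list(
      PC1 = list(get = function(ids) scores[ids, 1], method = "pearson"),
      PC2 = list(get = function(ids) scores[ids, 2], method = "pearson"),
      srs_total = list(get = function(ids)
        tr$srs_total[match(ids, tr$sample_id)], method = "spearman"),
      bapq_total = list(get = function(ids)
        tr$bapq_total[match(ids, tr$sample_id)], method = "spearman"))
    strata <- list(all = rep(TRUE, nrow(ped)))
    for (gl in unique(ped$group_label))
      strata[[gl]] <- ped$group_label == gl
    for (v in names(vars)) {
      per_stratum <- list()
      for (s in names(strata)) {
        sel <- strata[[s]]
        if (s != "all" && sum(sel) < min_n) {
          skipped[[length(skipped) + 1]] <- data.frame(
            variable = v, stratum = s, n = sum(sel),
            reason = sprintf("below minimum n %d", min_n))
          next
        }
        sc <- spousal_correlation(vars[[v]]$get(ped$father_id[sel]),
                                  vars[[v]]$get(ped$mother_id[sel]),
                                  method = vars[[v]]$method,
                                  variable = v, stratum = s)
        per_stratum[[s]] <- sc
        spousal[[length(spousal) + 1]] <- data.frame(
          variable = v, stratum = s, method = sc$method, r = sc$r,
          n = sc$n, ci_lo = sc$conf_int[1], ci_hi = sc$conf_int[2],
          p = sc$p)
      }
      if (all(c("with_CI_ID", "without_CI_ID") %in% names(per_stratum))) {
        cmp <- compare_correlations(per_stratum$with_CI_ID,
                                    per_stratum$without_CI_ID)
        comparisons[[length(comparisons) + 1]] <- data.frame(
          variable = v, z = cmp$z, p = cmp$p,
          significant_bonferroni =
            cmp$p < bonferroni_threshold(0.05, config$m_tests))
      }
    }
    res$spousal <- do.call(rbind, spousal)
    res$comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
    res$skipped_strata <- if (length(skipped)) do.call(rbind, skipped)
  }

  if ("pgs" %in% stages) {
    founder_ids2 <- intersect(c(ped$father_id, ped$mother_id), samples(g))
    pg <- score_pgs(g, cohort$effects, founders = founder_ids2)
    sc_named <- setNames(pg$std, pg$sample_id)
    ped_simplex <- ped[ped$retained_simplex, , drop = FALSE]
    ptdt_pro <- if (nrow(ped_simplex) >= 2)
      ptdt(sc_named, ped_simplex, "proband")
    ptdt_sib <- if (nrow(ped_simplex) >= 2)
      ptdt(sc_named, ped_simplex, "sibling")
    theta <- odd_even_theta(subset_genotypes(g, sample_ids = founder_ids2),
                            cohort$effects, k = config$k_pcs)
    res$pgs <- list(scores = pg, ptdt_proband = ptdt_pro,
                    ptdt_sibling = ptdt_sib, theta = theta)
    counts$simplex_trios <- nrow(ped_simplex)
  }

  if ("ldstruct" %in% stages) {
    stop_if_not(!is.null(res$ancestry), "ldstruct stage requires ancestry")
    founder_ids2 <- intersect(c(ped$father_id, ped$mother_id), samples(g))
    g_pruned <- subset_genotypes(g, variant_keep = res$ancestry$pruned$id)
    res$ldstruct <- resampling_comparison(
      g_pruned, ped, res$ancestry$round2, n_iter = config$n_iter,
      top_k = config$top_k, min_gap_bp = config$min_gap_bp,
      seed = config$seed)
  }

  res$manifest <- list(seed = config$seed, stages = stages,
                       counts = counts,
                       config = unclass(config$sim))
  class(res) <- "pipeline_result"

  if (!is.null(config$out_dir)) {
    tables <- Filter(Negate(is.null),
                     list(qc_report = res$qc, spousal = res$spousal,
                          comparisons = res$comparisons,
                          skipped_strata = res$skipped_strata,
                          ldstruct_tests = if (!is.null(res$ldstruct))
                            res$ldstruct$tests))
    write_results(tables, config$out_dir, manifest = res$manifest)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat("  stages:", paste(x$manifest$stages, collapse = ", "), "\n")
  cnt <- x$manifest$counts
  for (nm in names(cnt)) cat(sprintf("  %s: %s\n", nm, cnt[[nm]]))
  invisible(x)
}
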