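# Text-format readers/writers: BED3 regions, GWAS summary statistics,
# quantitative trait tables, and the results bundle writer.

#' Read a BED file of genomic regions
#'
#' BED coordinates are 0-based, half-open.  A variant at 1-based position
#' `p` lies inside a region `(start, end)` iff `start < p <= end`.
#'
#' @param path BED3(+) file; at least chrom, start, end columns, no header.
#' @return data frame (`chrom`, `start`, `end`) of class `ld_regions`.
#' @export
read_bed_regions <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  stop_if_not(ncol(df) >= 3, "BED file needs at least 3 columns")
  df <- df[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- df$start >= df$end
  stop_if_not(!any(bad),
              sprintf("BED records with start >= end: %d (first at row %d)",
                      sum(bad), which(bad)[1]))
  class(df) <- c("ld_regions", "data.frame")
  df
}

#' Which variants fall inside a set of regions?
#'
#' @param variants variant data frame (`chrom`, `pos` 1-based).
#' @param regions an `ld_regions` data frame from [read_bed_regions()].
#' @return logical vector, `TRUE` where the variant is inside any region.
#' @export
variant_in_regions <- function(variants, regions) {
  inside <- logical(nrow(variants))
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    idx <- which(variants$chrom == ch)
    if (length(idx) == 0) next
    p <- variants$pos[idx]
    hit <- rep(FALSE, length(idx))
    for (k in seq_len(nrow(r)))
      hit <- hit | (r$start[k] < p & p <= r$end[k])
    inside[idx] <- hit
  }
  inside
}

#' Read GWAS summary statistics
#'
#' @param path TSV with header.
#' @param cols named list mapping the canonical names `id`,
#'   `effect_allele`, `other_allele`, `beta`, `se` and, as available,
#'   `n_case`, `n_control` (binary trait) or `n` (quantitative trait) to
#'   the file's column names.
#' @return data frame of class `summary_stats` with canonical columns.
#' @export
read_summary_stats <- function(path, cols = list()) {
  defaults <- list(id = "id", effect_allele = "effect_allele",
                   other_allele = "other_allele", beta = "beta", se = "se",
                   n_case = "n_case", n_control = "n_control", n = "n")
  cols <- utils::modifyList(defaults, cols)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "effect_allele", "other_allele", "beta", "se")
  for (f in need)
    stop_if_not(cols[[f]] %in% names(df),
                paste("summary statistics missing mandatory column:", cols[[f]]))
  out <- data.frame(id = as.character(df[[cols$id]]),
                    effect_allele = toupper(df[[cols$effect_allele]]),
                    other_allele = toupper(df[[cols$other_allele]]),
                    beta = as.numeric(df[[cols$beta]]),
                    se = as.numeric(df[[cols$se]]),
                    stringsAsFactors = FALSE)
  for (f in c("n_case", "n_control", "n"))
    if (cols[[f]] %in% names(df)) out[[f]] <- as.numeric(df[[cols[[f]]]])
  stop_if_not(all(nzchar(out$effect_allele)) && all(nzchar(out$other_allele)),
              "empty alleles in summary statistics")
  bad_se <- !is.na(out$se) & out$se <= 0
  stop_if_not(!any(bad_se),
              sprintf("summary statistics with se <= 0: %d record(s)", sum(bad_se)))
  for (f in c("n_case", "n_control", "n"))
    if (f %in% names(out))
      stop_if_not(all(is.na(out[[f]]) | out[[f]] > 0),
                  paste("non-positive", f, "in summary statistics"))
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Harmonize summary statistics to a variant panel
#'
#' Aligns effect sizes to the panel's `a1` allele: where the summary
#' effect allele equals `a2` and the other allele equals `a1`, the sign
#' of `beta` is flipped.  Palindromic variants (A/T, C/G) and variants
#' whose allele pair does not match the panel are dropped, with counts
#' in the `"dropped"` attribute.  Any polygenic score computed from the
#' harmonized weights is invariant to how the input labelled its alleles.
#'
#' @param stats a `summary_stats` data frame.
#' @param variants variant data frame (`id`, `a1`, `a2`).
#' @return `summary_stats` restricted to matched variants, `beta` aligned
#'   to `a1`, in panel order.
#' @export
harmonize_sumstats <- function(stats, variants) {
  i <- match(variants$id, stats$id)
  present <- !is.na(i)
  s <- stats[i[present], , drop = FALSE]
  v <- variants[present, , drop = FALSE]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palin <- s$effect_allele == unname(comp[s$other_allele]) &
    !is.na(comp[s$other_allele])
  same <- s$effect_allele == v$a1 & s$other_allele == v$a2
  flip <- s$effect_allele == v$a2 & s$other_allele == v$a1
  keep <- (same | flip) & !palin
  out <- s[keep, , drop = FALSE]
  out$beta <- ifelse(flip[keep], -out$beta, out$beta)
  out$effect_allele <- v$a1[keep]
  out$other_allele <- v$a2[keep]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(absent = sum(!present),
                            palindromic = sum(palin & (same | flip)),
                            allele_mismatch = sum(!(same | flip)))
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Read a quantitative trait table
#'
#' Expects one row per parent with a `sample_id` column; score and
#' covariate columns are kept as numeric (missing values preserved),
#' `sex` as character.
#'
#' @param path TSV with header.
#' @param required columns that must be present besides `sample_id`.
#' @return data frame of class `trait_table`.
#' @export
read_trait_table <- function(path, required = character()) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stop_if_not("sample_id" %in% names(df),
              "trait table missing mandatory column: sample_id")
  for (f in required)
    stop_if_not(f %in% names(df),
                paste("trait table missing mandatory column:", f))
  if ("sex" %in% names(df)) {
    df$sex <- as.character(df$sex)
    stop_if_not(all(df$sex %in% c("male", "female", NA)),
                "sex must be 'male' or 'female'")
  }
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Write an analysis results bundle
#'
#' One TSV per named table plus a JSON run manifest recording the seed,
#' configuration and package version.
#'
#' @param tables named list of data frames.
#' @param dir output directory (created if needed).
#' @param manifest named list folded into the manifest JSON.
#' @return `dir`, invisibly.
#' @export
write_results <- function(tables, dir, manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    write.table(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                quote = FALSE, sep = "\t", row.names = FALSE)
  }
  manifest$package_version <- as.character(utils::packageVersion("amstruct"))
  manifest$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
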