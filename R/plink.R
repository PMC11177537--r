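# PLINK 1.x binary (.bed/.bim/.fam) reader and writer.
#
# .bed layout: 3 magic bytes (0x6c 0x1b 0x01 = SNP-major), then
# ceiling(n_samples/4) bytes per variant.  Each byte packs four samples,
# first sample in the two lowest-order bits.  Two-bit codes:
#   00 homozygous a1 (dosage 2), 01 missing, 10 heterozygous (1),
#   11 homozygous a2 (dosage 0).

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

# decode map: value of 2-bit code -> a1 dosage
.code_to_dosage <- c(2L, NA_integer_, 1L, 0L)

# 256 x 4 lookup: byte value + 1 -> dosages of its four packed samples
.plink_decode_lut <- local({
  m <- matrix(NA_integer_, 256, 4)
  for (b in 0:255) {
    for (s in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * s), 3L)
      m[b + 1, s + 1] <- .code_to_dosage[code + 1]
    }
  }
  m
})

# encode map: dosage (NA,0,1,2) -> 2-bit code
.dosage_to_code <- function(d) {
  code <- integer(length(d))
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 0L] <- 3L
  code[!is.na(d) & d == 1L] <- 2L
  code[!is.na(d) & d == 2L] <- 0L
  code
}

#' Read a PLINK 1.x binary fileset
#'
#' Reads the `.bed`/`.bim`/`.fam` triplet at `prefix`.  Non-autosomal
#' variants and variants whose two alleles coincide (non-bi-allelic
#' placeholders) are dropped; for variants sharing a (chromosome,
#' position) pair only the first occurrence is kept.  Exclusion counts
#' are reported via `message()` and attached as the `"excluded"`
#' attribute of the result.
#'
#' @param prefix path prefix (without extension) of the fileset.
#' @return list with elements `geno` (a [genotype_matrix()]) and `fam`
#'   (data frame: `fid`, `iid`, `pat`, `mat`, `sex`, `pheno`).
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    stop_if_not(file.exists(f), paste("missing file:", f))

  fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                       col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                       colClasses = c("character", "character", "character",
                                      "character", "integer", "numeric"))
  stop_if_not(!anyDuplicated(fam_df$iid),
              "duplicate sample ids in .fam; ids must be unique")
  bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                       col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                       colClasses = c("character", "character", "numeric",
                                      "integer", "character", "character"))
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  bpv <- (n + 3L) %/% 4L

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  stop_if_not(length(raw) >= 3 && identical(raw[1:3], PLINK_MAGIC),
              "not a SNP-major PLINK .bed file (bad magic bytes)")
  body <- raw[-(1:3)]
  stop_if_not(length(body) == bpv * m,
              sprintf(".bed size inconsistent with %d samples x %d variants", n, m))

  # decode all variants at once: 4*bpv rows per variant, samples first
  dec <- .plink_decode_lut[as.integer(body) + 1L, , drop = FALSE]
  arr <- array(t(dec), dim = c(4L * bpv, m))
  dosages <- arr[seq_len(n), , drop = FALSE]
  rownames(dosages) <- fam_df$iid

  keep_auto <- is_autosome(bim_df$chrom)
  keep_bi <- bim_df$a1 != bim_df$a2
  dup <- duplicated(bim_df[, c("chrom", "pos")])
  keep <- keep_auto & keep_bi & !dup
  excluded <- c(non_autosomal = sum(!keep_auto),
                non_biallelic = sum(keep_auto & !keep_bi),
                duplicate_position = sum(keep_auto & keep_bi & dup))
  if (any(excluded > 0))
    message(sprintf("read_plink: excluded %d non-autosomal, %d non-bi-allelic, %d duplicate-position variants",
                    excluded[1], excluded[2], excluded[3]))

  g <- genotype_matrix(dosages[, keep, drop = FALSE],
                       bim_df[keep, c("id", "chrom", "pos", "a1", "a2")])
  attr(g, "excluded") <- excluded
  list(geno = g, fam = fam_df)
}

#' Write a PLINK 1.x binary fileset
#'
#' Inverse of [read_plink()]: `read_plink(write_plink(g, p))` round-trips
#' dosages, ids and positions exactly.
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix.
#' @param fam optional data frame as returned by [read_plink()]; defaults
#'   to a skeleton with fid = iid, unknown parents, sex 0, phenotype -9.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix, fam = NULL) {
  d <- g$dosages
  v <- g$variants
  n <- nrow(d)
  m <- ncol(d)
  if (is.null(fam)) {
    fam <- data.frame(fid = rownames(d), iid = rownames(d),
                      pat = "0", mat = "0", sex = 0L, pheno = -9,
                      stringsAsFactors = FALSE)
  }
  stop_if_not(nrow(fam) == n && identical(fam$iid, rownames(d)),
              "fam rows must match genotype samples in order")

  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = v$chrom, id = v$id, cm = 0,
                    pos = sprintf("%d", as.integer(v$pos)),
                    a1 = v$a1, a2 = v$a2)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)

  bpv <- (n + 3L) %/% 4L
  pad <- 4L * bpv - n
  codes <- .dosage_to_code(as.vector(d))           # column-major: variant blocks
  codes <- matrix(codes, nrow = n, ncol = m)
  if (pad > 0) codes <- rbind(codes, matrix(3L, pad, m))  # pad codes ignored on read
  # pack 4 codes per byte, first sample lowest bits
  i4 <- array(codes, dim = c(4L, bpv, m))
  bytes <- i4[1, , ] + bitwShiftL(i4[2, , ], 2L) +
    bitwShiftL(i4[3, , ], 4L) + bitwShiftL(i4[4, , ], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(PLINK_MAGIC, con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}
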