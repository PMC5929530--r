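# PLINK 1 binary fileset codec (.bed/.bim/.fam, SNP-major).
#
# The .bed payload stores genotypes two bits per sample, variant by variant,
# four samples per byte, least-significant crumb first:
#   00 -> two copies of allele 1 (dosage 2)
#   01 -> missing
#   10 -> heterozygous (dosage 1)
#   11 -> zero copies of allele 1 (dosage 0)
# Dosage therefore counts allele 1 of the .bim record; minor-allele frequency
# is always recomputed downstream, never assumed from file order.

BED_MAGIC <- as.raw(c(0x6c, 0x1b))
BED_SNP_MAJOR <- as.raw(0x01)
.code_to_dosage <- c(2L, NA_integer_, 1L, 0L)  # indexed by 2-bit code + 1

#' Read a PLINK binary fileset
#'
#' Reads `prefix.bed`, `prefix.bim` and `prefix.fam` into a
#' [cohort_bundle()]. Only the SNP-major layout (third magic byte `0x01`) is
#' supported; the obsolete individual-major layout is rejected with an
#' explicit message.
#'
#' @param prefix Path prefix of the fileset (without extension).
#' @return A `cohort_bundle`. Samples carry the .fam columns
#'   (`family_id`, `sample_id`, `father`, `mother`, `sex`, `phenotype`);
#'   variants carry the .bim columns (`chrom`, `variant_id`, `cm`, `pos`,
#'   `allele1`, `allele2`). The dosage convention is recorded in the
#'   `dosage_allele` attribute.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing fileset member(s): ", paste(missing, collapse = ", "))

  bim <- utils::read.table(paths[2], header = FALSE, sep = "\t",
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "variant_id", "cm", "pos", "allele1", "allele2")
  fam <- utils::read.table(paths[3], header = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"))
  names(fam) <- c("family_id", "sample_id", "father", "mother", "sex",
                  "phenotype")

  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || !identical(raw[1:2], BED_MAGIC))
    stop("not a PLINK .bed file: bad magic bytes")
  if (raw[3] != BED_SNP_MAJOR) {
    if (raw[3] == as.raw(0x00))
      stop("individual-major .bed layout is not supported; ",
           "re-export in SNP-major mode")
    stop("unrecognised .bed mode byte: ", as.integer(raw[3]))
  }
  bpv <- ceiling(n / 4)  # bytes per variant
  if (length(raw) - 3L != bpv * m)
    stop(sprintf(
      ".bed payload (%d bytes) inconsistent with %d samples x %d variants",
      length(raw) - 3L, n, m))

  bytes <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  for (k in 0:3) {
    s <- seq.int(k + 1L, by = 4L, length.out = bpv)
    keep <- s <= n
    if (!any(keep)) next
    crumbs <- bitwAnd(bitwShiftR(bytes[keep, , drop = FALSE], 2L * k), 3L)
    geno[s[keep], ] <- .code_to_dosage[crumbs + 1L]
  }

  bundle <- cohort_bundle(geno, fam, bim)
  attr(bundle, "dosage_allele") <- "allele1"
  bundle
}

#' Write a PLINK binary fileset
#'
#' Inverse of [read_plink()]: emits a bit-exact SNP-major `.bed` (padding
#' crumbs zeroed), a `.bim` with 1-based positions and a `.fam` whose
#' phenotype column uses the PLINK missing code -9 where unknown.
#'
#' @param bundle A `cohort_bundle`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(bundle, prefix) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  geno <- bundle$genotypes
  n <- nrow(geno); m <- ncol(geno)

  codes <- matrix(1L, n, m)  # 01 = missing
  codes[!is.na(geno) & geno == 2L] <- 0L
  codes[!is.na(geno) & geno == 1L] <- 2L
  codes[!is.na(geno) & geno == 0L] <- 3L
  pad <- (4L - n %% 4L) %% 4L
  if (pad) codes <- rbind(codes, matrix(0L, pad, m))
  i <- seq.int(1L, n + pad, by = 4L)
  bytes <- codes[i, , drop = FALSE] +
    4L  * codes[i + 1L, , drop = FALSE] +
    16L * codes[i + 2L, , drop = FALSE] +
    64L * codes[i + 3L, , drop = FALSE]

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(BED_MAGIC, BED_SNP_MAJOR, as.raw(bytes)), con)

  v <- bundle$variants
  bim <- data.frame(
    chrom = v$chrom %||% rep("0", m),
    id = v$variant_id,
    cm = v$cm %||% rep(0, m),
    pos = as.integer(v$pos %||% seq_len(m)),
    a1 = v$allele1 %||% rep("A", m),
    a2 = v$allele2 %||% rep("B", m)
  )
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  s <- bundle$samples
  phe <- s$phenotype %||% rep(NA_real_, n)
  phe[is.na(phe)] <- -9
  fam <- data.frame(
    fid = s$family_id %||% s$sample_id,
    iid = s$sample_id,
    pat = s$father %||% rep("0", n),
    mat = s$mother %||% rep("0", n),
    sex = s$sex %||% rep(0L, n),
    phe = phe
  )
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

GRADE_SYMPTOMS <- c("diarrhoea", "mucositis", "neutropenia", "hfs")
TREATMENT_LEVELS <- c("5FU", "Capecitabine")

#' Read a per-sample toxicity grade table
#'
#' Expects a tab- (or other-) delimited file with a header naming at minimum
#' `sample_id`, the four NCI-CTC symptom grade columns (`diarrhoea`,
#' `mucositis`, `neutropenia`, `hfs`; integers 0-4, empty = not recorded) and
#' a `treatment` column (`5FU` or `Capecitabine`). A `batch` column and the
#' demographic columns `sex`/`age` are carried through when present.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return A validated `grade_table` data frame.
#' @export
read_grades <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  grade_table(df)
}

#' Validate a toxicity grade table
#'
#' @param df Data frame with `sample_id`, symptom grade columns and
#'   `treatment`.
#' @return `df` with class `grade_table` prepended.
#' @export
grade_table <- function(df) {
  need <- c("sample_id", GRADE_SYMPTOMS, "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("grade table is missing column(s): ", paste(miss, collapse = ", "))
  for (col in GRADE_SYMPTOMS) {
    g <- df[[col]]
    bad <- which(!is.na(g) & (g != as.integer(g) | g < 0 | g > 4))
    if (length(bad))
      stop(sprintf("invalid %s grade %s for sample %s (grades must be 0-4)",
                   col, g[bad[1]], df$sample_id[bad[1]]))
    df[[col]] <- as.integer(g)
  }
  if (anyNA(df$treatment))
    stop("treatment label required for every sample; missing for sample ",
         df$sample_id[which(is.na(df$treatment))[1]])
  unk <- setdiff(unique(df$treatment), TREATMENT_LEVELS)
  if (length(unk))
    stop("unknown treatment label(s): ", paste(unk, collapse = ", "),
         " (expected ", paste(TREATMENT_LEVELS, collapse = " or "), ")")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in grade table")
  class(df) <- unique(c("grade_table", class(df)))
  df
}

#' Write a grade table as TSV
#' @param grades A `grade_table`.
#' @param path Output path.
#' @export
write_grades <- function(grades, path) {
  utils::write.table(grades, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
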