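#' Cohort bundle: genotypes plus sample and variant tables
#'
#' The central container of the pipeline, mirroring a PLINK fileset held in
#' memory. Genotypes are stored as a samples x variants integer matrix of
#' additive dosages of allele 1 of each variant record (0, 1, 2), with
#' `NA` as the missing-genotype sentinel; -9 and NaN never appear inside the
#' matrix. Row names are sample identifiers, column names variant identifiers.
#'
#' @param genotypes samples x variants integer dosage matrix.
#' @param samples `data.frame` with at least a unique `sample_id` column;
#'   typically also `sex`, `age`, `batch`, `treatment`, `population`.
#' @param variants `data.frame` with at least unique `variant_id`, plus
#'   `chrom`, `pos` (1-based), `allele1`, `allele2`; optionally `gene`,
#'   `protein_altering`, `in_region`.
#' @return An object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(genotypes, samples, variants) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(is.data.frame(samples), is.data.frame(variants))
  if (nrow(samples) != nrow(genotypes))
    stop("sample count does not match genotype row count")
  if (nrow(variants) != ncol(genotypes))
    stop("variant count does not match genotype column count")
  if (anyDuplicated(samples$sample_id))
    stop("sample identifiers must be unique")
  if (anyDuplicated(variants$variant_id))
    stop("variant identifiers must be unique")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype dosages must be 0, 1, 2 or NA")
  rownames(genotypes) <- samples$sample_id
  colnames(genotypes) <- variants$variant_id
  structure(
    list(genotypes = genotypes, samples = samples, variants = variants),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("cohort_bundle: %d samples x %d variants\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  missing genotype rate: %.4f\n", mean(is.na(x$genotypes))))
  if (!is.null(x$variants$in_region))
    cat(sprintf("  region variants: %d\n", sum(x$variants$in_region)))
  invisible(x)
}

#' @export
dim.cohort_bundle <- function(x) dim(x$genotypes)

#' Subset a cohort bundle by samples and/or variants
#'
#' @param bundle A `cohort_bundle`.
#' @param samples,variants Logical/integer/character index into the sample or
#'   variant dimension (default: keep all).
#' @return The subsetted `cohort_bundle`.
#' @export
subset_bundle <- function(bundle, samples = NULL, variants = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  si <- samples %||% seq_len(nrow(bundle$genotypes))
  vi <- variants %||% seq_len(ncol(bundle$genotypes))
  if (is.character(si)) si <- match(si, bundle$samples$sample_id)
  if (is.character(vi)) vi <- match(vi, bundle$variants$variant_id)
  cohort_bundle(
    bundle$genotypes[si, vi, drop = FALSE],
    bundle$samples[si, , drop = FALSE],
    bundle$variants[vi, , drop = FALSE]
  )
}
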