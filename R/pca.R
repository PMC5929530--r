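# Ancestry principal components on LD-pruned common variants, with
# iterative outlier removal (smartpca-style: samples further than a fixed
# number of SDs from the per-component median are dropped and the
# decomposition repeated).

#' Greedy LD pruning
#'
#' Sliding-window pruning of autosomal variants: within each window of
#' `window` variants (advanced by `step`), one member of every pair with
#' genotype r-squared above `r2_max` is greedily dropped (the later variant
#' of the pair). Variants with MAF at or below `maf_min` are excluded
#' before pruning.
#'
#' @param bundle A `cohort_bundle`.
#' @param maf_min MAF that retained variants must exceed (default 0.01).
#' @param window Window size in variants.
#' @param step Window advance in variants.
#' @param r2_max Maximum tolerated pairwise r-squared.
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(bundle, maf_min = 0.01, window = 50L, step = 5L,
                     r2_max = 0.5) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  g <- bundle$genotypes
  maf <- variant_maf(g)
  cand <- which(!is.na(maf) & maf > maf_min)
  if (!length(cand)) return(character(0))
  gi <- impute_mean(g[, cand, drop = FALSE])
  keep <- rep(TRUE, length(cand))
  start <- 1L
  repeat {
    end <- min(start + window - 1L, length(cand))
    win <- start:end
    active <- win[keep[win]]
    if (length(active) > 1L) {
      cc <- suppressWarnings(stats::cor(gi[, active, drop = FALSE]))
      cc[is.na(cc)] <- 0
      for (ii in seq_along(active)[-1]) {
        if (!keep[active[ii]]) next
        prev <- active[seq_len(ii - 1L)]
        prev <- prev[keep[prev]]
        if (length(prev) &&
            any(cc[match(prev, active), ii]^2 > r2_max))
          keep[active[ii]] <- FALSE
      }
    }
    if (end == length(cand)) break
    start <- start + step
  }
  bundle$variants$variant_id[cand[keep]]
}

#' Principal components of ancestry
#'
#' EIGENSTRAT-style decomposition: each variant is mean-centred and scaled
#' by the binomial standard deviation `sqrt(p(1-p))` with `p` its sample
#' allele frequency; missing genotypes are imputed to the variant mean
#' before scaling. Scores are the unit-norm left singular vectors (sample
#' eigenvectors), with a deterministic sign convention (largest-magnitude
#' loading positive) so repeated runs are identical.
#'
#' @param bundle A `cohort_bundle`.
#' @param variant_ids Variants to use (typically from [ld_prune()]).
#' @param K Number of components.
#' @return An object of class `pca_result`: `scores` (samples x K,
#'   rownames = sample ids), `eigenvalues` (non-increasing), `variant_ids`
#'   used, and bookkeeping fields for the outlier loop.
#' @export
compute_pcs <- function(bundle, variant_ids = NULL, K = 10L) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  ids <- variant_ids %||% bundle$variants$variant_id
  g <- bundle$genotypes[, ids, drop = FALSE]
  n <- nrow(g)
  stopifnot(n >= K + 1, ncol(g) >= 1)
  p <- allele1_freq(g)
  usable <- which(!is.na(p) & p > 0 & p < 1)
  if (length(usable) < ncol(g))
    warning(sprintf("%d zero-variance variant(s) dropped from PCA",
                    ncol(g) - length(usable)))
  g <- impute_mean(g[, usable, drop = FALSE])
  p <- p[usable]
  x <- scale(g, center = 2 * p, scale = sqrt(p * (1 - p)))
  K <- min(K, n - 1L, ncol(x))
  sv <- svd(x, nu = K, nv = 0)
  scores <- sv$u
  # deterministic sign: make the entry with the largest magnitude positive
  for (j in seq_len(K)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- bundle$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(K))
  structure(list(scores = scores,
                 eigenvalues = sv$d[seq_len(K)]^2 / (n - 1),
                 variant_ids = ids[usable],
                 iterations = 1L,
                 removed = list()),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components, %d variants\n",
              nrow(x$scores), ncol(x$scores), length(x$variant_ids)))
  cat(sprintf("  iterations: %d; removed: %d sample(s)\n",
              x$iterations, length(unlist(x$removed))))
  invisible(x)
}

#' Iterative ancestry-outlier removal
#'
#' Repeats [compute_pcs()] and removes every sample whose score on any of
#' the first `n_outlier_pcs` components lies more than `sd_limit` standard
#' deviations from that component's median (both computed on the current
#' iteration's scores), until no sample is flagged or `max_iter` is
#' reached.
#'
#' @param bundle A `cohort_bundle`.
#' @param variant_ids Variants to use for the decomposition.
#' @param K Components to return.
#' @param n_outlier_pcs Components screened for outliers (default 5).
#' @param sd_limit Distance from the median, in SDs, above which a sample
#'   is an outlier (default 6).
#' @param max_iter Iteration cap.
#' @return A `pca_result` for the retained samples, with `removed` listing
#'   the sample ids dropped at each iteration and `retained_ids` the final
#'   sample set (original order preserved).
#' @export
iterative_outlier_removal <- function(bundle, variant_ids = NULL, K = 10L,
                                      n_outlier_pcs = 5L, sd_limit = 6,
                                      max_iter = 10L) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  current <- bundle
  removed <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    pcs <- compute_pcs(current, variant_ids, K)
    sc <- pcs$scores[, seq_len(min(n_outlier_pcs, ncol(pcs$scores))),
                     drop = FALSE]
    out <- rep(FALSE, nrow(sc))
    for (j in seq_len(ncol(sc))) {
      md <- stats::median(sc[, j])
      sdev <- stats::sd(sc[, j])
      if (sdev > 0) out <- out | abs(sc[, j] - md) > sd_limit * sdev
    }
    if (!any(out) || iter >= max_iter) {
      pcs$iterations <- iter
      pcs$removed <- removed
      pcs$retained_ids <- current$samples$sample_id
      return(pcs)
    }
    ids <- current$samples$sample_id[out]
    removed[[iter]] <- ids
    keep <- !(current$samples$sample_id %in% ids)
    if (!any(keep)) stop("all samples removed as outliers; degenerate input")
    current <- subset_bundle(current, samples = keep)
  }
}
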