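# Region-wide enrichment test: the sum of per-SNP chi-squared association
# statistics over a region, referred to a null distribution generated by
# permuting case/control labels (10,000 permutations by default). The
# empirical p-value is the fraction of permutations whose sum equals or
# exceeds the observed sum.

#' Region specification
#'
#' 1-based, closed genomic interval. The default span is the conventional
#' extended MHC interval chr6:29,600,000-33,100,000.
#'
#' @param chrom Chromosome label.
#' @param start,end Closed interval bounds (1-based).
#' @return A `region_spec` list.
#' @export
region_spec <- function(chrom = "6", start = 29600000L, end = 33100000L) {
  stopifnot(start <= end)
  structure(list(chrom = as.character(chrom), start = as.integer(start),
                 end = as.integer(end)),
            class = "region_spec")
}

# variant ids of a bundle falling inside a region (closed interval)
resolve_region <- function(bundle, region) {
  v <- bundle$variants
  ids <- v$variant_id[v$chrom == region$chrom &
                        v$pos >= region$start & v$pos <= region$end]
  if (!length(ids)) stop("region resolves to no variants")
  ids
}

#' Sum of per-variant chi-squared statistics over a region
#'
#' @param statistics Named numeric vector of 1-df chi-squared statistics
#'   (names = variant ids). Untestable variants must already be excluded —
#'   identically in the observed and permuted passes.
#' @param variant_ids Region member variants.
#' @return The arithmetic sum.
#' @export
region_sum <- function(statistics, variant_ids) {
  if (!length(variant_ids)) stop("empty region")
  miss <- setdiff(variant_ids, names(statistics))
  if (length(miss))
    stop("no statistic for region variant(s): ", paste(miss, collapse = ", "))
  sum(statistics[variant_ids])
}

# Allelic chi-squared statistics for many label vectors at once.
# G: analysed-samples x region-variants dosages (NA = missing);
# Y: analysed-samples x n_label 0/1 case-indicator matrix.
# Returns an n_label x n_variant matrix of 1-df Pearson statistics
# (0 where a margin degenerates for that labelling).
.allelic_chi2_matrix <- function(G, Y) {
  G0 <- G; G0[is.na(G0)] <- 0
  Mis <- is.na(G) + 0
  n <- nrow(G)
  n_case <- colSums(Y)
  a <- t(crossprod(G0, Y))          # case allele-1 counts  (labels x variants)
  miss_case <- t(crossprod(Mis, Y))
  tot1 <- colSums(G0)               # allele-1 counts over all analysed
  nobs <- n - colSums(Mis)
  obs_case <- outer(n_case, rep(1, ncol(G))) - miss_case
  obs_ctrl <- outer(rep(1, nrow(a)), nobs) - obs_case
  r1 <- 2 * obs_case
  r2 <- 2 * obs_ctrl
  b <- r1 - a
  cc <- outer(rep(1, nrow(a)), tot1) - a
  d <- r2 - cc
  N <- r1 + r2
  c2tot <- N - outer(rep(1, nrow(a)), tot1)
  den <- r1 * r2 * outer(rep(1, nrow(a)), tot1) * c2tot
  num <- N * (a * d - b * cc)^2
  chi <- ifelse(den > 0, num / den, 0)
  chi
}

# score-test statistics (covariate-adjusted) for one label vector
.score_chi2_vector <- function(G, y, covariates) {
  X <- cbind(rep(1, length(y)), covariates)
  fit0 <- stats::glm.fit(X, y, family = stats::binomial())
  mu <- fit0$fitted.values
  v <- mu * (1 - mu)
  r <- y - mu
  U <- as.vector(crossprod(G, r))
  GV <- G * v
  GtVG <- colSums(G * GV)
  XtVX <- crossprod(X, X * v)
  GtVX <- crossprod(GV, X)
  Vj <- GtVG - rowSums((GtVX %*% solve(XtVX)) * GtVX)
  ifelse(Vj > 1e-12, U^2 / Vj, 0)
}

#' Permutation null distribution of the region sum
#'
#' Generates `n_perm` permutations of the case/control labels over the
#' analysed samples (case count preserved; genotype-covariate structure
#' untouched), recomputes every region variant's statistic under each
#' relabelling with exactly the observed pass's statistic type and variant
#' inclusion list, and sums. Fully reproducible from `seed`.
#'
#' @param bundle A `cohort_bundle`.
#' @param status Outcome ([dichotomize()] vector or 0/1).
#' @param region A [region_spec()] or character vector of variant ids.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param statistic `"allelic"` (default; unadjusted 2x2 allele-count
#'   chi-squared) or `"score"` (covariate-adjusted logistic score test).
#' @param covariates Covariate matrix for `statistic = "score"`.
#' @return `list(observed, permuted, variant_ids, n_perm, seed, statistic)`.
#' @export
permutation_null <- function(bundle, status, region, n_perm = 10000L,
                             seed = 1L, statistic = c("allelic", "score"),
                             covariates = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (n_perm < 1L) stop("n_perm must be at least 1")
  statistic <- match.arg(statistic)
  ids <- if (inherits(region, "region_spec")) resolve_region(bundle, region)
         else region
  y_all <- as_case_indicator(status)
  keep <- which(!is.na(y_all))
  y <- y_all[keep]
  if (sum(y) < 1 || sum(1 - y) < 1)
    stop("outcome must have at least one case and one control")
  G <- bundle$genotypes[keep, ids, drop = FALSE]
  # inclusion list fixed once: polymorphic among analysed samples
  f <- allele1_freq(G)
  inc <- which(!is.na(f) & f > 0 & f < 1)
  if (!length(inc)) stop("no testable variants in region")
  G <- G[, inc, drop = FALSE]
  ids <- ids[inc]
  n <- length(y)
  n_case <- sum(y)

  set.seed(split_seed(seed, 5L))
  if (statistic == "allelic") {
    Y <- matrix(0L, n, n_perm + 1L)
    Y[, 1L] <- y
    for (k in seq_len(n_perm)) Y[sample.int(n, n_case), k + 1L] <- 1L
    chi <- .allelic_chi2_matrix(G, Y)
    sums <- rowSums(chi)
    observed <- sums[1L]
    permuted <- sums[-1L]
  } else {
    Gi <- impute_mean(G)
    cv <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]
    observed <- sum(.score_chi2_vector(Gi, y, cv))
    permuted <- vapply(seq_len(n_perm), function(k) {
      yp <- y[sample.int(n)]
      sum(.score_chi2_vector(Gi, yp, cv))
    }, 0)
  }
  list(observed = observed, permuted = permuted, variant_ids = ids,
       n_perm = as.integer(n_perm), seed = as.integer(seed),
       statistic = statistic)
}

#' Empirical permutation p-value
#'
#' Count of permuted sums that equal or exceed the observed sum, divided
#' by the number of permutations (ties count as exceedance). The add-one
#' estimator `(k + 1)/(n + 1)` is available but off by default.
#'
#' @param observed Observed sum.
#' @param permuted Vector of permuted sums.
#' @param add_one Use the add-one estimator.
#' @return Empirical p-value in [0, 1].
#' @export
empirical_p <- function(observed, permuted, add_one = FALSE) {
  if (!length(permuted)) stop("permuted sums must be non-empty")
  k <- sum(permuted >= observed)
  if (add_one) (k + 1) / (length(permuted) + 1) else k / length(permuted)
}

#' Region-wide enrichment test
#'
#' Orchestrates [permutation_null()] and [empirical_p()] into a single
#' result object with full provenance (seed, statistic type, permutation
#' count, variant inclusion list).
#'
#' @inheritParams permutation_null
#' @param add_one Use the add-one empirical-p estimator.
#' @return An object of class `region_result`.
#' @export
run_region_test <- function(bundle, status, region = region_spec(),
                            n_perm = 10000L, seed = 1L,
                            statistic = c("allelic", "score"),
                            covariates = NULL, add_one = FALSE) {
  null <- permutation_null(bundle, status, region, n_perm = n_perm,
                           seed = seed, statistic = statistic,
                           covariates = covariates)
  p <- empirical_p(null$observed, null$permuted, add_one = add_one)
  structure(list(observed = null$observed, permuted = null$permuted,
                 p = p, n_perm = null$n_perm, seed = null$seed,
                 statistic = null$statistic,
                 n_variants = length(null$variant_ids),
                 variant_ids = null$variant_ids, add_one = add_one),
            class = "region_result")
}

#' @export
print.region_result <- function(x, ...) {
  cat(sprintf(
    "region_result: observed sum %.2f over %d variants\n",
    x$observed, x$n_variants))
  cat(sprintf("  empirical p = %.4g (%d permutations, %s statistic, seed %d)\n",
              x$p, x$n_perm, x$statistic, x$seed))
  invisible(x)
}

#' Serialize a region result to JSON
#' @param result A `region_result`.
#' @param path Output path.
#' @param keep_permuted Include the full permuted-sum vector.
#' @export
write_region_result <- function(result, path, keep_permuted = TRUE) {
  out <- unclass(result)
  if (!keep_permuted) out$permuted <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
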