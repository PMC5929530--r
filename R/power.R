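# Multiple-testing thresholds and case-control power / sample-size design
# for the 1-df allelic association test.

#' Bonferroni significance threshold
#'
#' `family_alpha / n_tests`, exact up to display rounding; the 2
#' significant-figure display form matches how such thresholds are quoted
#' (0.05/59,277 -> 8.4e-7; 0.05/6,696 -> 7.5e-6; 0.05/10,000 -> 5e-6).
#'
#' @param n_tests Number of tests (>= 1).
#' @param family_alpha Family-wise error rate.
#' @return `list(threshold, display)`.
#' @export
bonferroni_threshold <- function(n_tests, family_alpha = 0.05) {
  if (length(n_tests) != 1 || n_tests < 1) stop("n_tests must be >= 1")
  thr <- family_alpha / n_tests
  list(threshold = thr, display = signif(thr, 2))
}

#' Power query for the allelic case-control test
#'
#' @param maf Population risk-allele frequency, in (0, 1).
#' @param or Per-allele odds ratio (> 0).
#' @param alpha Two-sided significance level.
#' @param case_fraction Affected / (affected + unaffected), in (0, 1).
#' @param target_power Desired power (for [sample_size_for_power()]).
#' @return A validated `power_query` list.
#' @export
power_query <- function(maf, or, alpha, case_fraction,
                        target_power = 0.80) {
  stopifnot(maf > 0, maf < 1, or > 0, alpha > 0, alpha < 1,
            case_fraction > 0, case_fraction < 1,
            target_power > 0, target_power < 1)
  structure(list(maf = maf, or = or, alpha = alpha,
                 case_fraction = case_fraction,
                 target_power = target_power),
            class = "power_query")
}

# case allele frequency induced by a per-allele odds ratio applied to the
# control (population) frequency
.case_freq <- function(p0, or) (or * p0) / (1 + p0 * (or - 1))

#' Power of the allelic test at a total sample size
#'
#' Power of the two-sided 1-df allelic (2N-chromosome) Pearson chi-squared
#' test comparing risk-allele frequency between cases and controls, with
#' the case allele frequency induced by the per-allele odds ratio on the
#' control (population) frequency. The default `"exact"` method enumerates
#' the binomial allele-count distribution of the test (support truncated
#' at negligible tail mass), so it agrees with simulation by construction;
#' `"approx"` is the pooled-variance (score-type) two-proportion normal
#' approximation evaluated on the noncentral chi-squared distribution,
#' which is smooth in `n_total` and cheap at any size. `or = 1` returns
#' `alpha` (degenerate null identity) under both methods.
#'
#' @param query A [power_query()].
#' @param n_total Total individuals (cases + controls).
#' @param method `"exact"` (enumeration) or `"approx"` (normal
#'   approximation).
#' @return Power in (0, 1).
#' @export
power_at_n <- function(query, n_total, method = c("exact", "approx")) {
  stopifnot(inherits(query, "power_query"), n_total >= 4)
  method <- match.arg(method)
  if (query$or == 1) return(query$alpha)
  p0 <- query$maf
  p1 <- .case_freq(p0, query$or)
  n_case <- round(query$case_fraction * n_total)
  n_ctrl <- n_total - n_case
  a1 <- 2 * n_case; a2 <- 2 * n_ctrl  # allele counts
  crit <- stats::qchisq(1 - query$alpha, df = 1)
  if (method == "approx" || a1 < 1 || a2 < 1 ||
      as.numeric(a1) * a2 > 4e7) {
    pbar <- (p1 * a1 + p0 * a2) / (a1 + a2)
    v0 <- pbar * (1 - pbar) * (1 / a1 + 1 / a2)
    ncp <- (p1 - p0)^2 / v0
    return(stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE))
  }
  x1 <- stats::qbinom(1e-14, a1, p1):stats::qbinom(1 - 1e-14, a1, p1)
  x2 <- stats::qbinom(1e-14, a2, p0):stats::qbinom(1 - 1e-14, a2, p0)
  X1 <- outer(x1, rep(1, length(x2)))
  X2 <- outer(rep(1, length(x1)), x2)
  c1 <- X1 + X2; c2 <- a1 + a2 - c1
  N <- a1 + a2
  num <- N * (X1 * (a2 - X2) - (a1 - X1) * X2)^2
  den <- as.numeric(a1) * a2 * c1 * c2
  chi <- ifelse(den > 0, num / den, 0)
  w <- outer(stats::dbinom(x1, a1, p1), stats::dbinom(x2, a2, p0))
  sum(w[chi > crit])
}

#' Smallest total sample size reaching a target power
#'
#' Integer bisection (then linear refinement) over the total sample size,
#' holding the case fraction fixed. The returned N satisfies
#' `power_at_n(N) >= target > power_at_n(N - 2)` (a 2-step contract, since
#' rounding the case split can make power non-monotone over single steps).
#'
#' @param query A [power_query()] with `or != 1`.
#' @param method Power evaluation method, as in [power_at_n()].
#' @param n_max Search cap.
#' @return The smallest total N (integer).
#' @export
sample_size_for_power <- function(query, method = c("exact", "approx"),
                                  n_max = 1e7) {
  stopifnot(inherits(query, "power_query"))
  method <- match.arg(method)
  if (query$or == 1)
    stop("power never exceeds alpha when or = 1; target unreachable")
  target <- query$target_power
  lo <- 4; hi <- 8
  while (power_at_n(query, hi, method) < target) {
    lo <- hi; hi <- hi * 2
    if (hi > n_max) stop("target power unreachable below n_max")
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (power_at_n(query, mid, method) >= target) hi <- mid else lo <- mid
  }
  # linear refinement against case-split / discreteness wobble
  while (hi > 4 && power_at_n(query, hi - 1, method) >= target) hi <- hi - 1
  as.integer(hi)
}

#' Monte-Carlo power of the allelic test
#'
#' Simulates replicate case-control studies (binomial allele counts at the
#' induced case/control frequencies), applies the Pearson allelic
#' chi-squared test, and reports the rejection frequency — an independent
#' cross-check of [power_at_n()].
#'
#' @param query A [power_query()].
#' @param n_total Total individuals.
#' @param n_replicates Number of simulated studies.
#' @param seed Integer seed.
#' @return `list(power, se, n_replicates)`.
#' @export
simulate_power <- function(query, n_total, n_replicates = 2000L, seed = 1L) {
  stopifnot(inherits(query, "power_query"))
  set.seed(split_seed(seed, 7L))
  p0 <- query$maf
  p1 <- .case_freq(p0, query$or)
  n_case <- round(query$case_fraction * n_total)
  a1 <- 2 * n_case; a2 <- 2 * (n_total - n_case)
  x1 <- stats::rbinom(n_replicates, a1, p1)
  x2 <- stats::rbinom(n_replicates, a2, p0)
  # vectorized Pearson chi-squared on the 2x2 allele-count tables
  c1 <- x1 + x2; c2 <- a1 + a2 - c1
  N <- a1 + a2
  num <- N * (x1 * (a2 - x2) - (a1 - x1) * x2)^2
  den <- as.numeric(a1) * a2 * c1 * c2
  chi <- ifelse(den > 0, num / den, 0)
  crit <- stats::qchisq(1 - query$alpha, df = 1)
  rej <- chi > crit
  p <- mean(rej)
  list(power = p, se = sqrt(p * (1 - p) / n_replicates),
       n_replicates = n_replicates)
}
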