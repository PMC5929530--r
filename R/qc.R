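# Variant- and sample-level quality control.
#
# Filter order (recorded in the report): variant filters (call rate, exact
# HWE) -> sample call-rate filter -> cryptic-relatedness removal ->
# known-risk-carrier (DPYD-type) exclusion.

# --------------------------------------------------------------------------
# Exact Hardy-Weinberg test

# Exact-test p-values for every admissible heterozygote count given n
# diploid samples and minor-allele count m. The sampling distribution is
# evaluated by log-space recurrence ratios between adjacent heterozygote
# counts (parity-preserving); the p-value for each configuration is the sum
# of probabilities <= that configuration's probability (mid-less exact
# test). Returns a list(h = het counts, p = p-values).
.hwe_het_pvalues <- function(n, m) {
  h <- seq.int(m %% 2L, m, by = 2L)
  if (length(h) == 1L) return(list(h = h, p = 1))
  hh <- h[-length(h)]
  logr <- log(4) + log((m - hh) / 2) + log(n - (m + hh) / 2) -
    log(hh + 1) - log(hh + 2)
  lu <- cumsum(c(0, logr))
  pr <- exp(lu - max(lu))
  pr <- pr / sum(pr)
  ord <- order(pr)
  cs <- cumsum(pr[ord])
  # ties count: detect with a small relative tolerance
  p <- cs[findInterval(pr * (1 + 1e-10), pr[ord])]
  list(h = h, p = pmin(p, 1))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test from genotype counts: the p-value is the sum of the
#' probabilities of all heterozygote counts (same allele totals and parity)
#' whose probability under the exact sampling distribution does not exceed
#' that of the observed count. No mid-p correction is applied. Monomorphic
#' input returns 1 by convention.
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts
#'   (homozygous for one allele, heterozygous, homozygous for the other).
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  cnt <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("counts must be non-negative integers")
  n <- sum(cnt)
  if (n == 0) stop("at least one observation required")
  m <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)  # minor allele count
  if (m == 0) return(1)
  d <- .hwe_het_pvalues(n, m)
  d$p[match(n_het, d$h)]
}

# vectorized over variants: genotype count triples -> p-values
.hwe_pvalues <- function(n2, n1, n0) {
  mapply(function(a, b, c) {
    if (a + b + c == 0) return(NA_real_)
    hwe_exact_test(a, b, c)
  }, n2, n1, n0)
}

# --------------------------------------------------------------------------
# QC report plumbing

.qc_step <- function(name, threshold, tested, removed_ids) {
  list(name = name, threshold = threshold, tested = tested,
       removed = length(removed_ids), removed_ids = removed_ids)
}

.qc_report <- function(steps, dim_in, dim_out) {
  structure(list(steps = steps, dim_in = dim_in, dim_out = dim_out),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d x %d -> %d x %d (samples x variants)\n",
              x$dim_in[1], x$dim_in[2], x$dim_out[1], x$dim_out[2]))
  for (s in x$steps)
    cat(sprintf("  %-28s threshold=%-10s tested=%-7d removed=%d\n",
                s$name, format(s$threshold), s$tested, s$removed))
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# merge consecutive reports into one chained report
.merge_reports <- function(reports) {
  .qc_report(do.call(c, lapply(reports, `[[`, "steps")),
             reports[[1]]$dim_in, reports[[length(reports)]]$dim_out)
}

# --------------------------------------------------------------------------
# Filters

#' Variant-level QC filters
#'
#' Removes variants with call rate below `call_rate_min` (default 0.99,
#' i.e. retained variants have call rate >= 0.99), then variants whose
#' exact HWE p-value is <= `hwe_p_min` (retained variants have p > 1e-6).
#'
#' @param bundle A `cohort_bundle`.
#' @param call_rate_min Minimum variant call rate retained.
#' @param hwe_p_min HWE p-value at or below which a variant is removed.
#' @return `list(bundle, report)`.
#' @export
filter_variants <- function(bundle, call_rate_min = 0.99, hwe_p_min = 1e-6) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dim_in <- dim(bundle$genotypes)
  cr <- variant_call_rate(bundle$genotypes)
  rm_cr <- bundle$variants$variant_id[cr < call_rate_min]
  b2 <- subset_bundle(bundle, variants = !(bundle$variants$variant_id %in% rm_cr))
  g <- b2$genotypes
  p <- .hwe_pvalues(colSums(g == 2L, na.rm = TRUE),
                    colSums(g == 1L, na.rm = TRUE),
                    colSums(g == 0L, na.rm = TRUE))
  rm_hwe <- b2$variants$variant_id[!is.na(p) & p <= hwe_p_min]
  out <- subset_bundle(b2, variants = !(b2$variants$variant_id %in% rm_hwe))
  report <- .qc_report(list(
    .qc_step("variant_call_rate", call_rate_min, dim_in[2], rm_cr),
    .qc_step("variant_hwe", hwe_p_min, ncol(b2$genotypes), rm_hwe)
  ), dim_in, dim(out$genotypes))
  list(bundle = out, report = report)
}

#' Sample-level call-rate filter
#'
#' Samples are retained only when their call rate is strictly greater than
#' `call_rate_min` (default 0.97): a sample at exactly the threshold is
#' removed. Variant call rates are not recomputed afterwards (single-pass
#' semantics); re-run [filter_variants()] explicitly if desired.
#'
#' @inheritParams filter_variants
#' @param call_rate_min Call rate that a retained sample must exceed.
#' @return `list(bundle, report)`.
#' @export
filter_samples <- function(bundle, call_rate_min = 0.97) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dim_in <- dim(bundle$genotypes)
  cr <- sample_call_rate(bundle$genotypes)
  rm_id <- bundle$samples$sample_id[cr <= call_rate_min]
  out <- subset_bundle(bundle, samples = !(bundle$samples$sample_id %in% rm_id))
  report <- .qc_report(list(
    .qc_step("sample_call_rate", call_rate_min, dim_in[1], rm_id)
  ), dim_in, dim(out$genotypes))
  list(bundle = out, report = report)
}

#' Method-of-moments relatedness scan (PI_HAT)
#'
#' Estimates the genome-wide proportion of alleles shared identical by
#' descent for every sample pair from identity-by-state counts on common
#' variants, using the method-of-moments decomposition
#' `PI_HAT = P(IBD=1)/2 + P(IBD=2)` (small-sample correction terms
#' omitted). For each pair at or above `pi_hat_min` — the conventional
#' first-degree boundary — the member with the lower call rate is flagged
#' for removal.
#'
#' @param bundle A `cohort_bundle`.
#' @param pi_hat_min PI_HAT at or above which a pair is flagged.
#' @param maf_min Minimum MAF for informative variants.
#' @param min_variants Minimum number of informative variants; below this
#'   the scan is skipped with a warning.
#' @return `list(pairs, remove, skipped)` where `pairs` is a data frame of
#'   all pairs with IBS counts and PI_HAT.
#' @export
relatedness_scan <- function(bundle, pi_hat_min = 0.4, maf_min = 0.05,
                             min_variants = 50L) {
  stopifnot(inherits(bundle, "cohort_bundle"), nrow(bundle$genotypes) >= 2)
  g <- bundle$genotypes
  f <- allele1_freq(g)
  keep <- which(!is.na(f) & pmin(f, 1 - f) >= maf_min)
  if (length(keep) < min_variants) {
    warning(sprintf("only %d informative variants (< %d); relatedness scan skipped",
                    length(keep), min_variants))
    return(list(pairs = data.frame(), remove = character(0), skipped = TRUE))
  }
  g <- g[, keep, drop = FALSE]
  p <- f[keep]; q <- 1 - p
  # per-variant expected IBS probabilities conditional on IBD state
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  n <- nrow(g)
  ids <- bundle$samples$sample_id
  cr <- sample_call_rate(bundle$genotypes)
  pair_i <- integer(0); pair_j <- integer(0)
  res <- list()
  kk <- 0L
  for (i in seq_len(n - 1L)) {
    gi <- g[i, ]
    for (j in (i + 1L):n) {
      gj <- g[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      d <- abs(gi[ok] - gj[ok])
      s0 <- sum(d == 2L); s1 <- sum(d == 1L); s2 <- sum(d == 0L)
      P0 <- s0 / sum(e0_ibd0[ok])
      P1 <- (s1 - P0 * sum(e1_ibd0[ok])) / sum(e1_ibd1[ok])
      P0 <- min(max(P0, 0), 1); P1 <- min(max(P1, 0), 1 - P0)
      P2 <- 1 - P0 - P1
      kk <- kk + 1L
      res[[kk]] <- c(i, j, s0, s1, s2, P1 / 2 + P2)
    }
  }
  tab <- as.data.frame(do.call(rbind, res))
  names(tab) <- c("i", "j", "ibs0", "ibs1", "ibs2", "pi_hat")
  tab$id1 <- ids[tab$i]; tab$id2 <- ids[tab$j]
  tab$flagged <- tab$pi_hat >= pi_hat_min
  remove <- character(0)
  for (r in which(tab$flagged)) {
    pick <- if (cr[tab$i[r]] <= cr[tab$j[r]]) tab$id1[r] else tab$id2[r]
    remove <- union(remove, pick)
  }
  list(pairs = tab, remove = remove, skipped = FALSE)
}

#' Exclude carriers of listed risk variants
#'
#' Removes every sample carrying at least one minor allele at any of the
#' listed variants (e.g. the four established DPYD toxicity variants).
#' Missing genotypes count as non-carrier (exclusion requires an observed
#' copy); listed variants absent from the bundle are warned about, not an
#' error.
#'
#' @param bundle A `cohort_bundle`.
#' @param variant_ids Identifiers of the risk variants.
#' @return `list(bundle, report)`.
#' @export
exclude_known_risk_carriers <- function(bundle, variant_ids) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dim_in <- dim(bundle$genotypes)
  found <- intersect(variant_ids, bundle$variants$variant_id)
  absent <- setdiff(variant_ids, found)
  if (length(absent))
    warning("risk variant(s) not in bundle: ", paste(absent, collapse = ", "))
  carriers <- character(0)
  if (length(found)) {
    gm <- minor_dosage(bundle$genotypes[, found, drop = FALSE])
    gm[is.na(gm)] <- 0L
    carriers <- bundle$samples$sample_id[rowSums(gm >= 1L) > 0]
  }
  out <- subset_bundle(bundle,
                       samples = !(bundle$samples$sample_id %in% carriers))
  report <- .qc_report(list(
    .qc_step("risk_carrier_exclusion", paste(found, collapse = ","),
             dim_in[1], carriers)
  ), dim_in, dim(out$genotypes))
  list(bundle = out, report = report)
}

#' Batch concordance checks
#'
#' Two diagnostics for genotype batch effects: (1) a per-variant Pearson
#' chi-squared comparison of allele counts between batches, with a
#' genomic-control-style inflation summary of those statistics; (2) the
#' association of the leading principal components with batch label
#' (point-biserial correlation for two batches, ANOVA otherwise).
#'
#' @param bundle A `cohort_bundle`.
#' @param batch Batch labels (default: the sample table's `batch` column).
#' @param pcs Optional samples x components score matrix from
#'   [compute_pcs()].
#' @param n_pcs Number of leading PCs to test against batch.
#' @return `list(variant_tests, inflation, pc_batch, skipped)`.
#' @export
batch_concordance <- function(bundle, batch = NULL, pcs = NULL, n_pcs = 5L) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  batch <- batch %||% bundle$samples$batch
  if (is.null(batch)) stop("no batch labels available")
  batch <- factor(batch)
  k <- nlevels(batch)
  if (k < 2L)
    return(list(variant_tests = data.frame(), inflation = NA_real_,
                pc_batch = data.frame(), skipped = TRUE))
  g <- bundle$genotypes
  m <- ncol(g)
  # allele-1 counts and observed allele totals per batch
  a <- matrix(0, k, m); tot <- matrix(0, k, m)
  for (j in seq_len(k)) {
    rows <- which(batch == levels(batch)[j])
    gj <- g[rows, , drop = FALSE]
    a[j, ] <- colSums(gj, na.rm = TRUE)
    tot[j, ] <- 2 * colSums(!is.na(gj))
  }
  c1 <- colSums(a); N <- colSums(tot); c2 <- N - c1
  chi2 <- rep(0, m)
  for (j in seq_len(k)) {
    e1 <- tot[j, ] * c1 / N
    e2 <- tot[j, ] * c2 / N
    chi2 <- chi2 + ifelse(e1 > 0, (a[j, ] - e1)^2 / e1, 0) +
      ifelse(e2 > 0, (tot[j, ] - a[j, ] - e2)^2 / e2, 0)
  }
  poly <- c1 > 0 & c2 > 0
  chi2[!poly] <- NA_real_
  pval <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  inflation <- stats::median(chi2, na.rm = TRUE) /
    stats::qchisq(0.5, df = k - 1)
  vt <- data.frame(variant_id = bundle$variants$variant_id,
                   chisq = chi2, p = pval)
  pc_batch <- data.frame()
  if (!is.null(pcs)) {
    n_pcs <- min(n_pcs, ncol(pcs))
    pc_batch <- do.call(rbind, lapply(seq_len(n_pcs), function(i) {
      if (k == 2L) {
        ct <- stats::cor.test(pcs[, i], as.numeric(batch == levels(batch)[2]))
        data.frame(pc = i, statistic = unname(ct$estimate), p = ct$p.value)
      } else {
        fit <- stats::aov(pcs[, i] ~ batch)
        s <- summary(fit)[[1]]
        data.frame(pc = i,
                   statistic = sqrt(s[["Sum Sq"]][1] / sum(s[["Sum Sq"]])),
                   p = s[["Pr(>F)"]][1])
      }
    }))
  }
  list(variant_tests = vt, inflation = inflation, pc_batch = pc_batch,
       skipped = FALSE)
}

#' Run the full QC pipeline
#'
#' Applies, in order: variant call-rate and HWE filters, the sample
#' call-rate filter, relatedness-based removal, and known-risk-carrier
#' exclusion. The returned report chains the dimensions of each step.
#'
#' @param bundle A `cohort_bundle`.
#' @param risk_variants Variant ids whose carriers are excluded.
#' @param variant_call_rate_min,hwe_p_min,sample_call_rate_min,pi_hat_min
#'   Thresholds forwarded to the individual filters.
#' @return `list(bundle, report)`.
#' @export
run_qc <- function(bundle, risk_variants = character(0),
                   variant_call_rate_min = 0.99, hwe_p_min = 1e-6,
                   sample_call_rate_min = 0.97, pi_hat_min = 0.4) {
  r1 <- filter_variants(bundle, variant_call_rate_min, hwe_p_min)
  r2 <- filter_samples(r1$bundle, sample_call_rate_min)
  rel <- relatedness_scan(r2$bundle, pi_hat_min = pi_hat_min)
  b3 <- subset_bundle(r2$bundle,
                      samples = !(r2$bundle$samples$sample_id %in% rel$remove))
  rel_report <- .qc_report(list(
    .qc_step("relatedness", pi_hat_min, nrow(r2$bundle$genotypes), rel$remove)
  ), dim(r2$bundle$genotypes), dim(b3$genotypes))
  r4 <- exclude_known_risk_carriers(b3, risk_variants)
  list(bundle = r4$bundle,
       report = .merge_reports(list(r1$report, r2$report, rel_report,
                                    r4$report)))
}
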