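# Per-variant case-control association with ancestry covariates, genomic
# control diagnostics, and QQ/Manhattan export. The same logistic machinery
# serves the scan over imputed HLA markers.

CHI2_MEDIAN_1DF <- stats::qchisq(0.5, df = 1)  # 0.45493642...

# single logistic fit of y on dosage + covariates; returns the per-dosage
# coefficient's Wald statistics, flagging non-convergence and separation
.logistic_one <- function(g, y, covs = NULL) {
  obs <- which(!is.na(g) & !is.na(y))
  g <- g[obs]; y <- y[obs]
  X <- if (is.null(covs)) NULL else covs[obs, , drop = FALSE]
  out <- list(beta = NA_real_, se = NA_real_, chisq = NA_real_, p = NA_real_,
              n = length(obs), flag = "ok")
  if (length(unique(g)) < 2L || length(unique(y)) < 2L) {
    out$flag <- "monomorphic"
    return(out)
  }
  dat <- if (is.null(X)) data.frame(y = y, g = g)
         else data.frame(y = y, g = g, X)
  fit <- suppressWarnings(stats::glm(y ~ ., data = dat,
                                     family = stats::binomial()))
  cf <- summary(fit)$coefficients
  if (!("g" %in% rownames(cf)) || !fit$converged) {
    out$flag <- "nonconverged"
    return(out)
  }
  b <- cf["g", "Estimate"]; se <- cf["g", "Std. Error"]
  if (!is.finite(b) || !is.finite(se) || se > 20 || abs(b) > 15) {
    out$flag <- "separation"  # quasi-complete separation: no finite OR
    return(out)
  }
  out$beta <- b; out$se <- se
  out$chisq <- (b / se)^2
  out$p <- stats::pchisq(out$chisq, 1, lower.tail = FALSE)
  out
}

#' Single-variant logistic association
#'
#' Fits, per variant, an additive-dosage logistic model of the binary
#' outcome with the supplied covariates (typically the first two ancestry
#' principal components) and reports the Wald chi-squared test of the
#' dosage term. Samples with a missing genotype are dropped per variant
#' (complete-case). Non-converged or separated fits are flagged — and
#' excluded from [genomic_inflation()] — rather than silently dropped.
#'
#' @param bundle A `cohort_bundle`.
#' @param status Outcome: a [dichotomize()] status vector (aligned with the
#'   bundle's samples) or a 0/1 vector.
#' @param covariates Optional samples x covariates numeric matrix.
#' @return A data frame of class `assoc_result`: one row per variant with
#'   coded-allele (allele-1) frequency, log-odds `beta`, `se`, `or`,
#'   1-df `chisq`, `p`, analysed `n`, and `flag`.
#' @export
logistic_assoc <- function(bundle, status, covariates = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  y <- as_case_indicator(status)
  stopifnot(length(y) == nrow(bundle$genotypes))
  if (sum(y == 1L, na.rm = TRUE) < 1 || sum(y == 0L, na.rm = TRUE) < 1)
    stop("outcome must have at least one case and one control")
  g <- bundle$genotypes
  rows <- lapply(seq_len(ncol(g)), function(j)
    .logistic_one(g[, j], y, covariates))
  res <- data.frame(
    variant_id = bundle$variants$variant_id,
    chrom = bundle$variants$chrom %||% NA,
    pos = bundle$variants$pos %||% NA,
    freq = allele1_freq(g),
    beta = vapply(rows, `[[`, 0, "beta"),
    se = vapply(rows, `[[`, 0, "se"),
    chisq = vapply(rows, `[[`, 0, "chisq"),
    p = vapply(rows, `[[`, 0, "p"),
    n = vapply(rows, `[[`, 0L, "n"),
    flag = vapply(rows, `[[`, "", "flag"),
    stringsAsFactors = FALSE
  )
  res$or <- exp(res$beta)
  res$test <- "logistic-wald"
  class(res) <- c("assoc_result", class(res))
  res
}

#' Allelic 2x2 chi-squared test
#'
#' Pearson chi-squared (1 df, no continuity correction) on the 2x2 table of
#' allele counts in cases and controls. Tables with a zero allele margin
#' (monomorphic) are flagged and get `NA` statistics.
#'
#' @param case_counts,control_counts Length-2 vectors of (allele1, allele2)
#'   counts.
#' @return `list(chisq, p, flag)`.
#' @export
allelic_chi2 <- function(case_counts, control_counts) {
  tab <- rbind(case_counts, control_counts)
  if (any(tab < 0)) stop("allele counts must be non-negative")
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    return(list(chisq = NA_real_, p = NA_real_, flag = "zero-margin"))
  N <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / N
  chisq <- sum((tab - e)^2 / e)
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE),
       flag = "ok")
}

#' Genomic inflation factor
#'
#' `lambda` = median of the valid 1-df association statistics divided by
#' the median of the chi-squared(1) distribution (0.4549...). Flagged
#' (non-converged/separated) results are excluded. With fewer than
#' `min_stats` valid statistics a warning is raised and `NA` returned.
#'
#' @param results An `assoc_result` data frame, or a numeric vector of 1-df
#'   chi-squared statistics.
#' @param min_stats Minimum usable statistics.
#' @return `lambda` (numeric scalar).
#' @export
genomic_inflation <- function(results, min_stats = 100L) {
  stat <- if (is.numeric(results)) results
          else results$chisq[results$flag == "ok"]
  stat <- stat[is.finite(stat)]
  if (length(stat) < min_stats) {
    warning(sprintf("only %d valid statistics (< %d); lambda omitted",
                    length(stat), min_stats))
    return(NA_real_)
  }
  stats::median(stat) / CHI2_MEDIAN_1DF
}

#' Association scan over imputed-marker dosages
#'
#' Runs the single-variant logistic machinery over a matrix of binary or
#' fractional dosages in [0, 2] standing in for imputed HLA alleles, amino
#' acids and SNPs, and applies a Bonferroni significance threshold for the
#' number of markers actually tested. Constant markers are skipped with a
#' log entry in the returned `skipped` attribute.
#'
#' @param markers samples x markers dosage matrix (colnames = marker ids).
#' @param status Outcome as in [logistic_assoc()].
#' @param covariates Optional covariate matrix.
#' @param family_alpha Family-wise error rate for the Bonferroni threshold.
#' @return An `assoc_result` data frame with a `significant` column;
#'   attributes `threshold` and `skipped`.
#' @export
marker_scan <- function(markers, status, covariates = NULL,
                        family_alpha = 0.05) {
  markers <- as.matrix(markers)
  if (any(markers < 0 | markers > 2, na.rm = TRUE))
    stop("marker dosages must lie in [0, 2]")
  y <- as_case_indicator(status)
  const <- vapply(seq_len(ncol(markers)), function(j) {
    v <- markers[!is.na(markers[, j]), j]
    length(unique(v)) < 2L
  }, TRUE)
  ids <- colnames(markers) %||% sprintf("marker%05d", seq_len(ncol(markers)))
  tested <- which(!const)
  rows <- lapply(tested, function(j) .logistic_one(markers[, j], y, covariates))
  res <- data.frame(
    variant_id = ids[tested],
    freq = colMeans(markers[, tested, drop = FALSE], na.rm = TRUE) / 2,
    beta = vapply(rows, `[[`, 0, "beta"),
    se = vapply(rows, `[[`, 0, "se"),
    chisq = vapply(rows, `[[`, 0, "chisq"),
    p = vapply(rows, `[[`, 0, "p"),
    n = vapply(rows, `[[`, 0L, "n"),
    flag = vapply(rows, `[[`, "", "flag"),
    stringsAsFactors = FALSE
  )
  res$or <- exp(res$beta)
  res$test <- "logistic-wald"
  threshold <- family_alpha / length(tested)
  res$significant <- !is.na(res$p) & res$p < threshold
  class(res) <- c("assoc_result", class(res))
  attr(res, "threshold") <- threshold
  attr(res, "skipped") <- ids[const]
  res
}

#' QQ- and Manhattan-plot data
#'
#' @param results An `assoc_result` data frame with `p` (and, for the
#'   Manhattan table, `chrom`/`pos`).
#' @return `list(qq, manhattan)`: `qq` pairs expected quantiles
#'   `-log10((i - 0.5)/n)` with the sorted observed `-log10(p)`;
#'   `manhattan` adds a genome-wide cumulative coordinate per chromosome.
#' @export
export_plot_data <- function(results) {
  p <- results$p[!is.na(results$p)]
  n <- length(p)
  qq <- if (n) {
    data.frame(expected = -log10((seq_len(n) - 0.5) / n),
               observed = -log10(sort(p)))
  } else data.frame(expected = numeric(0), observed = numeric(0))
  man <- data.frame()
  if (n && !is.null(results$chrom) && !all(is.na(results$chrom))) {
    ok <- !is.na(results$p)
    man <- results[ok, c("variant_id", "chrom", "pos", "p")]
    chr_order <- unique(man$chrom[order(suppressWarnings(
      as.numeric(man$chrom)), man$chrom)])
    offset <- 0
    man$cum_pos <- NA_real_
    for (ch in chr_order) {
      i <- man$chrom == ch
      man$cum_pos[i] <- man$pos[i] + offset
      offset <- offset + max(man$pos[i])
    }
    man$neglog10p <- -log10(man$p)
    man <- man[order(man$cum_pos), ]
  }
  list(qq = qq, manhattan = man)
}
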