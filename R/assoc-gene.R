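# Gene-level rare-variant association: CMC carrier-collapsing and SKAT.
#
# With the MAF < 0.05 membership filter the multivariate (common-variant)
# component of CMC is empty, so CMC reduces to a logistic test of a
# per-sample carrier indicator. SKAT is the variance-component score test
# with a weighted linear kernel; its null distribution is a mixture of
# 1-df chi-squared variables whose tail is evaluated by Imhof
# characteristic-function inversion with a Liu moment-matching fallback.

#' SKAT default variant weights
#'
#' The Beta(a, b) density evaluated at the minor-allele frequency; the
#' canonical default is Beta(1, 25), i.e. `w = 25 (1 - MAF)^24`, which
#' up-weights the rarest variants.
#'
#' @param maf Minor-allele frequencies.
#' @param a,b Beta shape parameters.
#' @return Weights, same length as `maf`.
#' @export
beta_maf_weights <- function(maf, a = 1, b = 25) {
  stats::dbeta(maf, a, b)
}

#' Upper-tail probability of a weighted sum of chi-squared(1) variables
#'
#' `P(sum_i lambda_i X_i > q)` with `X_i ~ chi-squared(1)` independent.
#' Primary route: Imhof's characteristic-function inversion, integrated
#' numerically. Fallback (integration failure or out-of-range result): the
#' Liu et al. moment-matching noncentral chi-squared approximation.
#'
#' @param q Observed statistic.
#' @param lambda Positive mixture weights (eigenvalues).
#' @return `list(p, method)` with `method` one of `"imhof"`, `"liu"`.
#' @export
pchisq_mixture <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-10 * max(lambda)]
  if (!length(lambda)) stop("no positive mixture weights")
  if (length(lambda) == 1L)
    return(list(p = stats::pchisq(q / lambda, 1, lower.tail = FALSE),
                method = "exact"))
  # the tail probability is scale-invariant; normalise so the integrand's
  # oscillation scale is O(1) regardless of the eigenvalue magnitudes
  sc <- max(lambda)
  lambda <- lambda / sc
  q <- q / sc
  integrand <- function(u) {
    vapply(u, function(ui) {
      theta <- 0.5 * sum(atan(lambda * ui)) - 0.5 * q * ui
      rho <- exp(0.25 * sum(log1p((lambda * ui)^2)))
      sin(theta) / (ui * rho)
    }, 0)
  }
  val <- tryCatch(
    stats::integrate(integrand, 0, Inf, subdivisions = 2000L,
                     rel.tol = 1e-9, abs.tol = 1e-12),
    error = function(e) NULL)
  if (!is.null(val) && val$message == "OK") {
    p <- 0.5 + val$value / pi
    if (p > -1e-6 && p < 1 + 1e-6)
      return(list(p = min(max(p, 1e-300), 1), method = "imhof"))
  }
  list(p = .liu_pvalue(q, lambda), method = "liu")
}

# Liu-Tang-Zhang moment-matching approximation
.liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + delta; sigma_x <- sqrt(2 * (l + 2 * delta))
  tstar <- (q - mu_q) / sigma_q
  stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = delta,
                lower.tail = FALSE)
}

#' Build gene sets of rare protein-altering variants
#'
#' Groups variants into per-gene sets using the bundle's annotation (or an
#' explicit `variant_id`/`gene` table). Membership requires MAF strictly
#' below `maf_max` and, by default, a protein-altering annotation. A
#' variant annotated to several genes appears in each. Genes left with no
#' qualifying variants are kept as empty sets (skipped by the tests).
#'
#' @param bundle A `cohort_bundle`.
#' @param annotation Optional `data.frame(variant_id, gene)`; default uses
#'   the bundle's variant table (`gene`, `protein_altering` columns).
#' @param maf_max Exclusive MAF upper bound for membership.
#' @param protein_altering_only Restrict to protein-altering variants.
#' @return Named list of character vectors (gene -> member variant ids).
#' @export
build_gene_sets <- function(bundle, annotation = NULL, maf_max = 0.05,
                            protein_altering_only = TRUE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  v <- bundle$variants
  if (is.null(annotation)) {
    if (is.null(v$gene)) stop("no gene annotation available")
    annotation <- data.frame(variant_id = v$variant_id, gene = v$gene,
                             stringsAsFactors = FALSE)
    annotation <- annotation[!is.na(annotation$gene), ]
  }
  maf <- variant_maf(bundle$genotypes)
  names(maf) <- v$variant_id
  pa <- v$protein_altering %||% rep(TRUE, nrow(v))
  names(pa) <- v$variant_id
  qual <- annotation$variant_id %in% v$variant_id &
    !is.na(maf[annotation$variant_id]) &
    maf[annotation$variant_id] < maf_max &
    maf[annotation$variant_id] > 0
  if (protein_altering_only) qual <- qual & pa[annotation$variant_id]
  genes <- unique(annotation$gene)
  sets <- lapply(genes, function(g)
    annotation$variant_id[qual & annotation$gene == g])
  names(sets) <- genes
  sets
}

#' CMC collapsing test
#'
#' Collapses the gene's rare variants into a per-sample carrier indicator
#' (1 if the sample carries at least one minor allele across the set) and
#' tests it against the outcome in a logistic model with covariates
#' (1-df Wald test). With all member variants below the rare-MAF bound the
#' collapsed indicator is the entire CMC statistic.
#'
#' @param bundle A `cohort_bundle`.
#' @param variant_ids Member variants of the gene set.
#' @param status Outcome as in [logistic_assoc()].
#' @param covariates Optional covariate matrix (e.g. first two ancestry
#'   PCs).
#' @return `list(p, beta, or, n_carriers, n, flag)`.
#' @export
cmc_test <- function(bundle, variant_ids, status, covariates = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!length(variant_ids))
    return(list(p = NA_real_, beta = NA_real_, or = NA_real_,
                n_carriers = 0L, n = 0L, flag = "empty-set"))
  y <- as_case_indicator(status)
  gm <- minor_dosage(bundle$genotypes[, variant_ids, drop = FALSE])
  gm[is.na(gm)] <- 0L  # missing genotype contributes no observed copy
  carrier <- as.integer(rowSums(gm >= 1L) > 0)
  keep <- !is.na(y)
  nc <- sum(carrier[keep])
  if (nc == 0L || nc == sum(keep))
    return(list(p = NA_real_, beta = NA_real_, or = NA_real_,
                n_carriers = nc, n = sum(keep), flag = "untestable"))
  fit <- .logistic_one(carrier, y, covariates)
  list(p = fit$p, beta = fit$beta, or = exp(fit$beta),
       n_carriers = nc, n = fit$n, flag = fit$flag)
}

#' Sequence kernel association test (SKAT)
#'
#' Variance-component score test for the joint effect of a gene's rare
#' variants. A null logistic model of the outcome on the covariates alone
#' gives fitted probabilities `mu`; the statistic is
#' `Q = sum_j w_j^2 (g_j' (y - mu))^2` with `w_j` the Beta(1,25) density
#' at variant j's MAF (computed on the analysed samples; missing dosages
#' mean-imputed). Under the null, Q is distributed as
#' `sum_i lambda_i chi2_1` with `lambda_i` the eigenvalues of
#' `W G' P0 G W`, where `P0` is the null-model projected variance operator;
#' the tail probability comes from [pchisq_mixture()].
#'
#' @inheritParams cmc_test
#' @param weight_beta Beta shape parameters for the MAF weights.
#' @return `list(Q, p, n_variants, n, method, flag)` where `method` records
#'   the p-value algorithm used (imhof/liu/exact).
#' @export
skat_test <- function(bundle, variant_ids, status, covariates = NULL,
                      weight_beta = c(1, 25)) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!length(variant_ids))
    return(list(Q = NA_real_, p = NA_real_, n_variants = 0L, n = 0L,
                method = NA_character_, flag = "empty-set"))
  y <- as_case_indicator(status)
  keep <- which(!is.na(y))
  y <- y[keep]
  G <- bundle$genotypes[keep, variant_ids, drop = FALSE]
  X <- cbind(rep(1, length(y)),
             if (!is.null(covariates)) covariates[keep, , drop = FALSE])
  maf <- variant_maf(G)
  poly <- which(!is.na(maf) & maf > 0)
  if (!length(poly))
    return(list(Q = NA_real_, p = NA_real_, n_variants = 0L, n = length(y),
                method = NA_character_, flag = "untestable"))
  G <- impute_mean(G[, poly, drop = FALSE])
  w <- beta_maf_weights(maf[poly], weight_beta[1], weight_beta[2])

  fit0 <- stats::glm.fit(X, y, family = stats::binomial())
  mu <- fit0$fitted.values
  r <- y - mu
  v <- mu * (1 - mu)

  Q <- sum((w * as.vector(crossprod(G, r)))^2)

  GV <- G * v
  GtVG <- crossprod(G, GV)
  XtVX <- crossprod(X, X * v)
  GtVX <- crossprod(GV, X)
  A <- GtVG - GtVX %*% solve(XtVX, t(GtVX))
  A <- (w %o% w) * A
  lam <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-10 * max(abs(lam))]
  if (!length(lam))
    return(list(Q = Q, p = NA_real_, n_variants = length(poly), n = length(y),
                method = NA_character_, flag = "degenerate-kernel"))
  pv <- tryCatch(pchisq_mixture(Q, lam),
                 error = function(e) list(p = .liu_pvalue(Q, lam),
                                          method = "liu-fallback"))
  list(Q = Q, p = pv$p, n_variants = length(poly), n = length(y),
       method = pv$method, flag = "ok")
}

#' Gene-level association scan
#'
#' Runs [cmc_test()] and [skat_test()] for every gene set and applies a
#' Bonferroni threshold of `family_alpha` over the number of testable
#' genes (e.g. 0.05 / 10,000 = 5e-6 at the exome-wide gene count).
#'
#' @param bundle A `cohort_bundle`.
#' @param status Outcome.
#' @param gene_sets Output of [build_gene_sets()].
#' @param covariates Optional covariate matrix.
#' @param family_alpha Family-wise error rate.
#' @param n_genes Number of genes for the Bonferroni correction (default:
#'   the number of testable sets).
#' @return A data frame (class `gene_test_result`) with one row per gene;
#'   attribute `threshold` carries the Bonferroni cutoff.
#' @export
gene_scan <- function(bundle, status, gene_sets, covariates = NULL,
                      family_alpha = 0.05, n_genes = NULL) {
  rows <- lapply(names(gene_sets), function(gname) {
    set <- gene_sets[[gname]]
    cmc <- cmc_test(bundle, set, status, covariates)
    sk <- skat_test(bundle, set, status, covariates)
    data.frame(gene = gname, n_variants = length(set),
               cmc_p = cmc$p, cmc_or = cmc$or, cmc_flag = cmc$flag,
               skat_Q = sk$Q, skat_p = sk$p,
               skat_method = sk$method %||% NA_character_,
               skat_flag = sk$flag, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  testable <- sum(!is.na(res$skat_p) | !is.na(res$cmc_p))
  n_genes <- n_genes %||% max(testable, 1L)
  threshold <- family_alpha / n_genes
  res$significant <- (!is.na(res$cmc_p) & res$cmc_p < threshold) |
    (!is.na(res$skat_p) & res$skat_p < threshold)
  class(res) <- c("gene_test_result", class(res))
  attr(res, "threshold") <- threshold
  res
}
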