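# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis assumes: a ~500-sample
# European-ancestry exome-array cohort with mostly-rare protein-altering
# variants, one dense-LD region standing in for the MHC, mild two-population
# stratification, two genotyping batches, and ordinal toxicity grades from a
# liability-threshold model.

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the study conditions: 504 samples (254 on
#' Capecitabine), ~60k mostly-rare variants of which 2,283 sit in a dense-LD
#' chr6 region, two batches in the 1798:650 ratio of the calling batches,
#' mild two-population structure (Fst 0.005) and sparse missingness
#' compatible with post-QC call rates.
#'
#' @param n_samples Number of samples.
#' @param n_variants Total number of variants (region variants included).
#' @param maf_dist Ancestral minor-allele-frequency distribution for
#'   off-region variants: `list(type = "beta", shape1, shape2, min, max)` or
#'   `list(type = "fixed", value)`.
#' @param region Dense-LD region settings: `list(n_variants, block_length,
#'   pool_size, maf_dist, chrom, start, end)`. Haplotypes for each block are
#'   drawn from a finite pool of size `pool_size`, which induces positive
#'   adjacent-SNP r-squared. Set `n_variants = 0` for no region.
#' @param ancestry `list(k, fst, proportions)`: number of subpopulations,
#'   Balding-Nichols allele-frequency divergence, and mixing proportions.
#' @param batches Named numeric vector of batch proportions.
#' @param missing_rate Independent per-genotype missingness probability.
#' @param capecitabine_fraction Fraction of samples on Capecitabine (the
#'   rest are 5FU monotherapy/combination).
#' @param seed Master seed; identical spec + seed gives a bit-identical
#'   cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 504L,
                        n_variants = 60000L,
                        maf_dist = list(type = "beta", shape1 = 0.2,
                                        shape2 = 2, min = 1e-4, max = 0.5),
                        region = list(n_variants = 2283L, block_length = 10L,
                                      pool_size = 8L,
                                      maf_dist = list(type = "beta",
                                                      shape1 = 2, shape2 = 2,
                                                      min = 0.05, max = 0.5),
                                      chrom = "6", start = 29600000L,
                                      end = 33100000L),
                        ancestry = list(k = 2L, fst = 0.005,
                                        proportions = c(0.5, 0.5)),
                        batches = c(batch1 = 1798, batch2 = 650) / 2448,
                        missing_rate = 0.002,
                        capecitabine_fraction = 254 / 504,
                        seed = 1L) {
  stopifnot(n_samples >= 1, n_variants >= 1,
            missing_rate >= 0, missing_rate <= 1,
            capecitabine_fraction >= 0, capecitabine_fraction <= 1,
            all(ancestry$proportions >= 0),
            abs(sum(ancestry$proportions) - 1) < 1e-8,
            region$n_variants <= n_variants)
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 maf_dist = maf_dist, region = region, ancestry = ancestry,
                 batches = batches, missing_rate = missing_rate,
                 capecitabine_fraction = capecitabine_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.draw_maf <- function(n, dist) {
  if (identical(dist$type, "fixed")) return(rep(dist$value, n))
  pmin(pmax(stats::rbeta(n, dist$shape1, dist$shape2),
            dist$min %||% 0), dist$max %||% 0.5)
}

# Balding-Nichols subpopulation frequencies around ancestral p
.subpop_freqs <- function(p, k, fst) {
  if (k <= 1L || fst <= 0) return(matrix(p, nrow = length(p), ncol = max(k, 1L)))
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  out <- matrix(0, length(p), k)
  for (j in seq_len(k)) out[, j] <- stats::rbeta(length(p), a, b)
  pmin(pmax(out, 1e-6), 1 - 1e-6)
}

#' Simulate genotypes for a synthetic cohort
#'
#' Off-region genotypes are independent binomial draws from subpopulation
#' allele frequencies (Hardy-Weinberg within subpopulation); region
#' genotypes are unions of two haplotypes drawn from a per-subpopulation
#' finite pool per LD block, which yields realistic within-block r-squared
#' decay while keeping Hardy-Weinberg proportions. Missingness is applied
#' independently at `missing_rate`.
#'
#' @param spec A [cohort_spec()].
#' @return A [cohort_bundle()] whose variant table carries `gene`,
#'   `protein_altering` and `in_region` annotation and whose sample table
#'   carries `population`, `batch`, `treatment`, `sex` and `age`.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  m <- spec$n_variants
  mr <- spec$region$n_variants %||% 0L
  if (mr > 0L && (spec$region$pool_size %||% 0L) < 2L)
    stop("haplotype pool size must be at least 2")
  set.seed(split_seed(spec$seed, 1L))

  k <- spec$ancestry$k %||% 1L
  pop <- sample.int(k, n, replace = TRUE, prob = spec$ancestry$proportions)

  geno <- matrix(0L, n, m)
  # --- off-region variants: independent sites
  mo <- m - mr
  if (mo > 0L) {
    p0 <- .draw_maf(mo, spec$maf_dist)
    pk <- .subpop_freqs(p0, k, spec$ancestry$fst)
    for (j in seq_len(k)) {
      rows <- which(pop == j)
      if (!length(rows)) next
      geno[rows, seq_len(mo)] <- matrix(
        stats::rbinom(length(rows) * mo, 2L, rep(pk[, j], each = length(rows))),
        nrow = length(rows))
    }
  }
  # --- region variants: finite haplotype pools per LD block
  if (mr > 0L) {
    bl <- spec$region$block_length
    H <- spec$region$pool_size
    p0r <- .draw_maf(mr, spec$region$maf_dist)
    pkr <- .subpop_freqs(p0r, k, spec$ancestry$fst)
    starts <- seq.int(1L, mr, by = bl)
    for (s in starts) {
      idx <- s:min(s + bl - 1L, mr)
      cols <- mo + idx
      for (j in seq_len(k)) {
        rows <- which(pop == j)
        if (!length(rows)) next
        pool <- matrix(stats::rbinom(H * length(idx), 1L,
                                     rep(pkr[idx, j], each = H)),
                       nrow = H)
        h1 <- sample.int(H, length(rows), replace = TRUE)
        h2 <- sample.int(H, length(rows), replace = TRUE)
        geno[rows, cols] <- pool[h1, , drop = FALSE] +
          pool[h2, , drop = FALSE]
      }
    }
  }
  # --- missingness
  if (spec$missing_rate > 0) {
    drop <- stats::runif(length(geno)) < spec$missing_rate
    geno[drop] <- NA_integer_
  }

  variants <- .synth_variant_table(mo, mr, spec)
  samples <- .synth_sample_table(n, pop, spec)
  bundle <- cohort_bundle(geno, samples, variants)
  attr(bundle, "dosage_allele") <- "allele1"
  bundle
}

# variant annotation: off-region variants spread over chr1-22 (skipping the
# region span), grouped into pseudo-genes; region variants on the region chrom
.synth_variant_table <- function(mo, mr, spec) {
  m <- mo + mr
  ids <- sprintf("var%06d", seq_len(m))
  chrom <- character(m); pos <- integer(m)
  gene <- rep(NA_character_, m)
  if (mo > 0L) {
    chr_set <- setdiff(as.character(1:22), spec$region$chrom %||% "none")
    per_chr <- as.integer(ceiling(mo / length(chr_set)))
    chrom[seq_len(mo)] <- rep(chr_set, each = per_chr)[seq_len(mo)]
    within <- (seq_len(mo) - 1L) %% per_chr
    pos[seq_len(mo)] <- 1000000L + 1500L * within
    # consecutive variants on a chromosome share a gene in blocks of 1..8
    sizes <- sample(1:8, ceiling(mo / 2), replace = TRUE)
    gidx <- rep.int(seq_along(sizes), sizes)[seq_len(mo)]
    gene[seq_len(mo)] <- sprintf("GENE%05d", gidx)
  }
  if (mr > 0L) {
    ridx <- mo + seq_len(mr)
    chrom[ridx] <- spec$region$chrom
    pos[ridx] <- as.integer(round(seq(spec$region$start, spec$region$end,
                                      length.out = mr)))
    gene[ridx] <- "MHC_TAG"
  }
  data.frame(variant_id = ids, chrom = chrom, pos = pos,
             allele1 = "A", allele2 = "G", gene = gene,
             protein_altering = c(rep(TRUE, mo), rep(FALSE, mr)),
             in_region = c(rep(FALSE, mo), rep(TRUE, mr)),
             stringsAsFactors = FALSE)
}

.synth_sample_table <- function(n, pop, spec) {
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    family_id = sprintf("F%04d", seq_len(n)),
    population = pop,
    batch = names(spec$batches)[
      sample.int(length(spec$batches), n, replace = TRUE,
                 prob = spec$batches)],
    treatment = ifelse(stats::runif(n) < spec$capecitabine_fraction,
                       "Capecitabine", "5FU"),
    sex = ifelse(stats::runif(n) < 0.60, 1L, 2L),  # 1 = male, ~60% as observed
    age = round(stats::rnorm(n, 63.5, 11.5), 1),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# Liability-threshold grade model

# P(at least one of the symptom liabilities exceeds its threshold) for
# equicorrelated standard-normal liabilities (shared-frailty representation)
.p_any_exceed <- function(thresholds, rho) {
  f <- function(u) {
    sapply(u, function(ui) {
      stats::dnorm(ui) *
        prod(stats::pnorm((thresholds - sqrt(rho) * ui) / sqrt(1 - rho)))
    })
  }
  1 - stats::integrate(f, -9, 9, rel.tol = 1e-10)$value
}

#' Calibrate liability cut-points to target outcome prevalences
#'
#' Solves the severe-grade thresholds of the liability model so that, with
#' zero genetic effects, the four dichotomized outcomes match target
#' affected fractions (defaults: the study margins 133/502 DMN, 50/249 DM,
#' 36/254 HFS, 13/254 severe HFS). Symptom liabilities are standard normal
#' with pairwise correlation `rho` via a shared patient frailty.
#'
#' @param targets Named vector of affected fractions for `dmn`, `dm`,
#'   `hfs`, `shfs`.
#' @param rho Between-symptom liability correlation.
#' @return Named list of length-4 cut-point vectors (thresholds for grades
#'   >= 1..4) per symptom; HFS has no grade 4 (threshold `Inf`).
#' @export
calibrate_cutpoints <- function(targets = c(dmn = 133 / 502, dm = 50 / 249,
                                            hfs = 36 / 254, shfs = 13 / 254),
                                rho = 0.3) {
  stopifnot(all(targets > 0 & targets < 1), rho >= 0, rho < 1)
  # HFS outcomes are single-symptom: thresholds are plain normal quantiles
  t2_hfs <- stats::qnorm(1 - targets[["hfs"]])
  t3_hfs <- stats::qnorm(1 - targets[["shfs"]])
  # DM: diarrhoea and mucositis share a severe threshold t with
  # P(max liability >= t) = target
  t_dm <- stats::uniroot(
    function(t) .p_any_exceed(c(t, t), rho) - targets[["dm"]],
    c(0.5, 4), tol = 1e-9)$root
  # DMN: neutropenia threshold solved given the DM thresholds
  t_n <- stats::uniroot(
    function(t) .p_any_exceed(c(t_dm, t_dm, t), rho) - targets[["dmn"]],
    c(0.5, 6), tol = 1e-9)$root
  mild <- c(stats::qnorm(0.40), stats::qnorm(0.65))  # grade 1/2 cuts
  list(
    diarrhoea   = c(mild, t_dm, t_dm + 0.6),
    mucositis   = c(mild, t_dm, t_dm + 0.6),
    neutropenia = c(mild, t_n, t_n + 0.6),
    hfs         = c(0, t2_hfs, t3_hfs, Inf)
  )
}

#' Specification of genetic and covariate effects on toxicity liability
#'
#' @param cutpoints Per-symptom grade cut-points as returned by
#'   [calibrate_cutpoints()] (the default). Each must be strictly
#'   increasing.
#' @param variant_effects `data.frame(variant_id, symptom, beta)`: additive
#'   liability shift per minor allele.
#' @param region_effect `list(symptom, n_causal, beta)`: plants `n_causal`
#'   causal variants (chosen reproducibly) inside the LD region, each adding
#'   `beta` per minor allele to the named symptom's liability.
#' @param ancestry_effect Liability shift added for samples outside
#'   subpopulation 1 (scalar, applied to all symptoms) — nonzero values
#'   induce confounding by population structure.
#' @param rho Between-symptom liability correlation (shared frailty).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(cutpoints = calibrate_cutpoints(),
                        variant_effects = NULL,
                        region_effect = NULL,
                        ancestry_effect = 0,
                        rho = 0.3) {
  for (s in names(cutpoints)) {
    cp <- cutpoints[[s]]
    if (any(diff(cp) <= 0)) stop("cut-points must be strictly increasing: ", s)
  }
  if (!is.null(variant_effects))
    stopifnot(all(c("variant_id", "symptom", "beta") %in%
                    names(variant_effects)))
  structure(list(cutpoints = cutpoints, variant_effects = variant_effects,
                 region_effect = region_effect,
                 ancestry_effect = ancestry_effect, rho = rho),
            class = "effect_spec")
}

#' Simulate toxicity grades from genotypes under a liability model
#'
#' For each symptom s, liability is
#' `L_s = G beta_s + ancestry + sqrt(rho) eta + sqrt(1-rho) eps_s` with
#' `eta` (patient frailty) and `eps_s` standard normal, and the grade is the
#' number of cut-points below `L_s`. Missing genotypes contribute zero
#' liability.
#'
#' @param bundle A [cohort_bundle()] (its sample table supplies treatment,
#'   batch, sex, age and population).
#' @param effects An [effect_spec()].
#' @param seed Integer seed.
#' @return A `grade_table` with one row per sample. The planted causal
#'   variant ids (if any) are attached as attribute `causal_variants`.
#' @export
simulate_grades <- function(bundle, effects = effect_spec(), seed = 1L) {
  stopifnot(inherits(bundle, "cohort_bundle"), inherits(effects, "effect_spec"))
  n <- nrow(bundle$genotypes)
  set.seed(split_seed(seed, 2L))
  rho <- effects$rho

  # per-symptom genetic liability
  gshift <- matrix(0, n, length(GRADE_SYMPTOMS),
                   dimnames = list(NULL, GRADE_SYMPTOMS))
  causal <- character(0)
  ve <- effects$variant_effects
  if (!is.null(effects$region_effect)) {
    re <- effects$region_effect
    rvars <- bundle$variants$variant_id[bundle$variants$in_region %||%
                                          rep(FALSE, ncol(bundle$genotypes))]
    if (length(rvars) < re$n_causal)
      stop("region has fewer variants than n_causal")
    pick <- rvars[round(seq(1, length(rvars), length.out = re$n_causal))]
    causal <- pick
    ve <- rbind(ve, expand.grid(variant_id = pick, symptom = re$symptom,
                                stringsAsFactors = FALSE,
                                KEEP.OUT.ATTRS = FALSE) |>
                  transform(beta = re$beta))
  }
  if (!is.null(ve)) {
    miss <- setdiff(ve$variant_id, bundle$variants$variant_id)
    if (length(miss))
      stop("effect variant(s) not in bundle: ", paste(miss, collapse = ", "))
    gm <- minor_dosage(bundle$genotypes[, unique(ve$variant_id), drop = FALSE])
    gm[is.na(gm)] <- 0L
    # centre causal dosages so planted effects shift liability variance and
    # association, not the cohort-wide baseline prevalence
    gm <- scale(gm, center = TRUE, scale = FALSE)
    for (s in unique(ve$symptom)) {
      rows <- ve[ve$symptom == s, ]
      b <- tapply(rows$beta, rows$variant_id, sum)
      gshift[, s] <- gshift[, s] +
        as.vector(gm[, names(b), drop = FALSE] %*% as.numeric(b))
    }
  }
  anc <- effects$ancestry_effect *
    as.numeric((bundle$samples$population %||% rep(1L, n)) != 1L)

  eta <- stats::rnorm(n)
  grades <- lapply(GRADE_SYMPTOMS, function(s) {
    L <- gshift[, s] + anc + sqrt(rho) * eta + sqrt(1 - rho) * stats::rnorm(n)
    findInterval(L, effects$cutpoints[[s]])
  })
  names(grades) <- GRADE_SYMPTOMS

  out <- data.frame(sample_id = bundle$samples$sample_id,
                    grades, stringsAsFactors = FALSE)
  out$treatment <- bundle$samples$treatment %||% rep("5FU", n)
  if (!is.null(bundle$samples$batch)) out$batch <- bundle$samples$batch
  if (!is.null(bundle$samples$sex)) out$sex <- bundle$samples$sex
  if (!is.null(bundle$samples$age)) out$age <- bundle$samples$age
  out <- grade_table(out)
  attr(out, "causal_variants") <- causal
  out
}

#' Simulate a full cohort: genotypes, grades and ground truth
#'
#' @param spec A [cohort_spec()].
#' @param effects An [effect_spec()].
#' @return `list(bundle, grades, truth)` where `truth` records the planted
#'   causal variants and the seeds used.
#' @export
simulate_cohort <- function(spec = cohort_spec(), effects = effect_spec()) {
  bundle <- simulate_genotypes(spec)
  grades <- simulate_grades(bundle, effects, seed = spec$seed)
  list(bundle = bundle, grades = grades,
       truth = list(causal_variants = attr(grades, "causal_variants"),
                    seed = spec$seed))
}
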