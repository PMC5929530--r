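---
title: "Methods: exome-array association analysis of fluoropyrimidine toxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exome-array association analysis of fluoropyrimidine toxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxassoc)
```

## The problem

Fluoropyrimidines (5-fluorouracil and its pro-drug Capecitabine) are
first-line chemotherapy for gastrointestinal cancers, and adverse drug
reactions — diarrhoea, mucositis, neutropenia, and the Capecitabine-typical
hand-and-foot syndrome (HFS) — frequently force dose reduction or
discontinuation. Toxicity is graded 0–4 on the NCI-CTC scale per symptom.
Beyond the established rare *DPYD* loss-of-function alleles, the genetic
contribution is poorly characterised. `toxassoc` implements a complete
exome-array case-control pipeline for this setting: cohort quality control,
ancestry adjustment, single-variant and gene-level association, a
region-wide enrichment test aimed at the HLA, and the design calculations
(multiple-testing thresholds, power) that frame such a study. A
synthetic-cohort generator with the same statistical structure makes every
stage testable without access to patient data.

## Outcome definitions

Four binary outcomes are derived from the per-symptom grades:

| outcome | symptoms | affected | subgroup |
|---|---|---|---|
| DMN | diarrhoea, mucositis, neutropenia | grade 3–4 | all patients |
| DM | diarrhoea, mucositis | grade 3–4 | Capecitabine only |
| HFS | hand-and-foot syndrome | grade 2–3 | Capecitabine only |
| sHFS | hand-and-foot syndrome | grade 3 | Capecitabine only |

Two rules were genuinely open and are fixed here as package conventions:
multi-symptom outcomes use the **maximum grade over their constituent
symptoms** ("any severe constituent", the standard toxicity convention);
and a hypothetical grade-4 HFS — never observed clinically, since the HFS
scale effectively tops out at 3 — would count as affected for both HFS
outcomes. Samples outside an outcome's treatment subgroup are *excluded*
(not "unaffected"), and a sample missing any constituent grade has a
*missing* outcome rather than being optimistically classified.

## Quality control

Filters run in a recorded order: variant call rate (retain ≥ 0.99), exact
Hardy–Weinberg test (retain p > 1e-6), sample call rate (retain strictly
> 0.97 — a sample at exactly 0.97 is removed, following the strict
inequality in the convention this pipeline follows), cryptic-relatedness
removal, and exclusion of carriers of listed risk variants (the four
established *DPYD* toxicity alleles, supplied as variant ids).

The HWE test is the standard mid-less exact test: the p-value sums the
probabilities of all heterozygote counts (same allele totals, same parity)
whose exact sampling probability does not exceed the observed one. The
distribution is built by log-space recurrence ratios between adjacent
heterozygote counts, which is numerically safe to n in the thousands; ties
are detected with a relative tolerance of 1e-10. Monomorphic input returns
p = 1 by convention.

Relatedness uses the method-of-moments IBD decomposition
(`PI_HAT = P(IBD=1)/2 + P(IBD=2)`) from identity-by-state counts on common
variants. The small-sample correction factors of the original
method-of-moments estimator are omitted; at the pair-screening accuracy
needed here (duplicates ≈ 1, first-degree ≈ 0.5, unrelated ≈ 0) they are
immaterial. The flagging threshold defaults to `PI_HAT >= 0.4`, the
conventional first-degree boundary; for each flagged pair the member with
the lower call rate is removed. A missing genotype at a risk variant counts
as non-carrier: exclusion requires an observed copy.

Batch concordance is checked two ways: per-variant allele-count chi-squared
between batches (with a genomic-control-style inflation summary), and
correlation of the leading principal components with batch label.

## Ancestry principal components

PCA follows the EIGENSTRAT construction: LD-pruned (greedy sliding window;
defaults window 50 variants, step 5, r² ≤ 0.5 — the ubiquitous defaults,
exposed as arguments since the convention leaves them open) common variants
(MAF > 0.01), each mean-centred and scaled by `sqrt(p(1-p))`, missing
values imputed to the variant mean before scaling. Scores are unit-norm
sample eigenvectors with a deterministic sign convention (largest-magnitude
entry positive), so repeated runs are bit-identical. The outlier loop
recomputes the decomposition and removes any sample more than 6 SD from the
per-component **median** on the first 5 components, iterating to
convergence; the SD is computed on the current iteration's scores. Both
choices (median centring, current-iteration SD) are the literal reading of
the smartpca-style procedure this reproduces. Projection onto external
reference panels is out of scope: the synthetic generator provides its own
labelled subpopulations, which exercises the same mechanism.

## Single-variant association

Per variant, an additive-dosage logistic model with covariates (typically
the first two PCs) is fitted and the Wald 1-df chi-squared reported.
Missing genotypes are handled complete-case per variant. Non-convergence
and quasi-complete separation (detected as |log-odds| > 15 or SE > 20) are
*flagged*, reported without a finite OR, and excluded from the genomic
inflation factor `lambda = median(chi2) / 0.45494` — flagged sentinel
values would otherwise distort the median. The same machinery drives the
scan over imputed-HLA marker dosages, with a Bonferroni threshold for the
number of markers actually tested (0.05/6,696 ≈ 7.5e-6 at the full imputed
panel size).

## Gene-level tests

Gene sets contain protein-altering variants with MAF strictly below 0.05
(the boundary is strict, read literally). With that filter the multivariate
common-variant component of the CMC test is empty, so CMC reduces to its
collapsing part: a per-sample carrier indicator (any minor allele across
the set) tested in a covariate-adjusted logistic model.

SKAT is the variance-component score test
`Q = sum_j w_j^2 (g_j'(y - mu))^2` with `mu` from the covariate-only null
model and `w_j` the Beta(1,25) density at variant j's MAF — the canonical
default weights, computed on the analysed case+control sample. Under the
null, Q follows a mixture `sum_i lambda_i chi2_1` with eigenvalues from
the null-projected kernel `W G' P0 G W`. The tail probability is computed
by Imhof characteristic-function inversion (eigenvalues scale-normalised
first, which keeps the oscillatory integrand well conditioned), with the
Liu moment-matching approximation as fallback; the algorithm actually used
is recorded in each result. A single-variant set reduces analytically to
the weighted 1-df score test, which the test suite checks.

Asymptotic small-sample behaviour is a known limitation: at cohort sizes
of a few dozen, the mixture p-value and the Wald CMC p-value can deviate
from the exact permutation distribution of the same statistics by a few
hundredths (more in far tails), because the score vector is a sum of few
discrete terms. The test suite quantifies this against 20,000-draw
permutation oracles; the package intentionally keeps the standard
analytic algorithms rather than switching to permutation p-values.

## Region-wide enrichment test

The package's central statistic: the sum of per-variant 1-df chi-squared
association statistics over a genomic region (default: the conventional
extended MHC span chr6:29,600,000–33,100,000, 1-based closed interval),
referred to a null distribution obtained by permuting case/control labels
(10,000 permutations by default) and recomputing the identical sum. The
empirical p-value counts permutations whose sum **equals or exceeds** the
observed sum, divided by the permutation count; ties count as exceedance,
and the add-one estimator is available but off by default, following the
literal counting rule.

Two per-variant statistics are supported. The default is the unadjusted
2×2 allelic chi-squared — the most literal "chi-squared association
statistic", and fast enough to vectorise all permutations as two matrix
products. A covariate-adjusted logistic score statistic is selectable for
sensitivity analyses; whether the original procedure adjusted the permuted
statistics for PCs is not determinable, so the simpler reading is the
default. Labels are permuted jointly against both genotypes and
covariates, preserving the genotype–covariate structure. The variant
inclusion list (polymorphic among analysed samples) is computed once and
applied identically to the observed and every permuted pass, so no
selection asymmetry can bias the sum.

## The synthetic-cohort generator

Defaults emulate the study conditions: 504 samples (254 Capecitabine),
~60k mostly-rare variants (ancestral MAF ~ Beta(0.2, 2); many are
monomorphic at this sample size, as on a real exome array), a 2,283-variant
dense-LD region on chr6 standing in for the HLA, two genotyping batches in
the 1798:650 ratio, mild two-population structure (Balding–Nichols,
Fst 0.005), and 0.2% missingness.

LD is produced by finite haplotype pools: each region block (default 10
variants) draws its haplotypes from a pool of 8 per subpopulation, and each
sample is the union of two random pool members. This guarantees valid
genotypes, Hardy–Weinberg proportions within subpopulation, and realistic
block-wise r² (≈ 1/pool-size on average) without constructing correlation
matrices. A side effect worth knowing: lower-frequency region variants can
be monomorphic in the pool, which mimics real tag-SNP redundancy.

Grades come from a liability-threshold model: for each symptom,
`L = G beta + ancestry + sqrt(rho) eta + sqrt(1-rho) eps`, with a shared
patient frailty `eta` giving between-symptom correlation `rho = 0.3`
(chosen once as a realistic within-patient toxicity correlation), and the
grade is the number of cut-points below `L`. The severe cut-points are
calibrated numerically (`calibrate_cutpoints()`, one-dimensional root
finding over the shared-frailty integral) so that, with zero genetic
effects, the four outcome prevalences hit the cohort margins 133/502 (DMN),
50/249 (DM), 36/254 (HFS) and 13/254 (severe HFS); HFS has no grade 4.
Grade-1/2 cut-points, which the dichotomizations never see, are fixed at
plausible marginal frequencies (60% / 35% for the DMN symptoms).

Planted genetic effects are parametrized on **centred** minor-allele
dosage, so an effect changes genotype–phenotype association without moving
the baseline prevalence (an uncentred common-allele effect would shift the
whole cohort across the threshold). The planted-region default used by the
test suite — 10 causal variants at +0.5 liability per minor allele on each
DMN constituent symptom — was calibrated once, analytically and by a small
pilot simulation, to give ≥80% rejection for the region test at 200
samples and 500 permutations while the zero-effect generator rejects at
the nominal 5%.

What the generator does *not* emulate: real human haplotype structure
beyond block-wise r², imputation error in HLA markers, genotype-calling
artefacts, age/sex effects on toxicity, and per-cycle longitudinal dosing.
Passing tests therefore demonstrate the statistical machinery is correct
and calibrated under the stated generative model — not that the pipeline
is robust to every artefact of real intensity-derived genotypes.

## Design calculations

`bonferroni_threshold()` is exact rational arithmetic with a
2-significant-figure display form (0.05/59,277 → 8.4e-7 for the
exome-wide protein-altering scan; 0.05/6,696 → 7.5e-6 for the imputed HLA
panel; 0.05/10,000 → 5e-6 for gene tests).

Power for the allelic (2N-chromosome) case-control test uses the case
allele frequency induced by a per-allele odds ratio on the control
frequency. The default evaluation is **exact**: the binomial allele-count
distribution of the Pearson statistic is enumerated (support truncated at
1e-14 tail mass), so the analytic value agrees with simulation by
construction. The pooled-variance normal approximation is available as
`method = "approx"`; it is smooth and cheap but overstates power by a few
percent in strong-effect, unbalanced designs, which is exactly the regime
of the headline query (MAF 0.05, OR 3, alpha 8.4e-7, case fraction
133/502, 80% power). `or = 1` returns alpha exactly, as the degenerate
null identity. `sample_size_for_power()` bisects and then linearly refines;
because the case split is rounded, minimality is guaranteed at step 2
(allele-count parity), which the suite asserts as
`power(N) >= target > power(N-2)`.

## Numerical conventions, in one place

- Missing genotypes: `NA` inside the dosage matrix, never −9 or NaN;
  −9 appears only in the `.fam` phenotype column on disk.
- Dosage counts allele 1 of the variant record; minor-allele orientation
  is recomputed wherever "minor" matters (weights, carrier status).
- Positions are 1-based; regions are closed intervals.
- One master seed is split deterministically per stage
  (`split_seed()`), so any stage reproduces in isolation; all derived
  seeds stay below 2^31.
- Problem sizes used by the test suite (500 null cohorts of 200×300 for
  permutation calibration, 40 planted replicates for power, exhaustive
  HWE to n = 200, 20,000-draw oracles) are the package's chosen
  verification scales; the same machinery runs unchanged at full study
  scale.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_samples = 504, n_variants = 5000,
                    region = list(n_variants = 300, block_length = 10,
                                  pool_size = 8,
                                  maf_dist = list(type = "beta", shape1 = 2,
                                                  shape2 = 2, min = 0.05,
                                                  max = 0.5),
                                  chrom = "6", start = 29600000,
                                  end = 33100000),
                    seed = 1)
sim <- simulate_cohort(spec)
qc <- run_qc(sim$bundle)
pcs <- compute_pcs(qc$bundle, ld_prune(qc$bundle), K = 10)
status <- dichotomize(sim$grades, "HFS")
status <- status[match(qc$bundle$samples$sample_id, names(status))]
single <- logistic_assoc(qc$bundle, status, pcs$scores[, 1:2])
genomic_inflation(single)
run_region_test(qc$bundle, status, region_spec(), n_perm = 10000, seed = 17)
```
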