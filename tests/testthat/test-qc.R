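# independent closed-form oracle for the exact HWE test: probabilities from
# the lfactorial expression, p-values by direct pairwise tie summation
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  m <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (m == 0) return(1)
  h <- seq.int(m %% 2L, m, by = 2L)
  hommin <- (m - h) / 2
  hommaj <- n - (m + h) / 2
  lp <- lfactorial(n) - lfactorial(hommin) - lfactorial(h) -
    lfactorial(hommaj) + h * log(2) +
    lfactorial(m) + lfactorial(2 * n - m) - lfactorial(2 * n)
  pr <- exp(lp)
  i <- match(n_het, h)
  sum(pr[pr <= pr[i] * (1 + 1e-10)])
}

test_that("HWE exact test matches the enumeration oracle on stated examples", {
  expect_identical(hwe_exact_test(10, 0, 0), 1)            # monomorphic
  expect_equal(hwe_exact_test(10, 10, 10), hwe_oracle(10, 10, 10))
  # exact HWE proportions: the observed configuration is modal, p ~= 1
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25))
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-9)
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("HWE exact test equals the oracle over a randomised configuration sweep", {
  set.seed(12)
  for (rep in 1:400) {
    n <- sample(1:200, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1); c <- n - a - b
    expect_equal(hwe_exact_test(a, b, c), hwe_oracle(a, b, c),
                 tolerance = 1e-12)
  }
})

test_that("variant filters apply the call-rate and HWE thresholds literally", {
  set.seed(101)
  g <- matrix(rbinom(100 * 4, 2, 0.3), 100, 4)
  g[1:2, 1] <- NA                 # call rate 0.98 -> removed
  g[, 2] <- rep(c(0L, 2L), 50)    # no hets at 50/50 alleles: HWE p tiny
  b <- tiny_bundle(g)
  res <- filter_variants(b)
  expect_false("v001" %in% res$bundle$variants$variant_id)
  expect_false("v002" %in% res$bundle$variants$variant_id)
  expect_true(all(c("v003", "v004") %in% res$bundle$variants$variant_id))
  # dimension chain
  expect_identical(res$report$dim_in, c(100L, 4L))
  expect_identical(res$report$dim_out, dim(res$bundle$genotypes))
  # hwe boundary: p <= 1e-6 removed, p > 1e-6 retained
  expect_identical(hwe_exact_test(98, 0, 2) > 1e-6, TRUE)
})

test_that("sample filter removes call rate <= 0.97 (strict retention)", {
  g <- matrix(0L, 3, 100)
  g[1, 1:3] <- NA   # call rate 0.97 exactly -> removed
  g[2, 1:4] <- NA   # 0.96 -> removed
  b <- tiny_bundle(g)
  res <- filter_samples(b)
  expect_identical(res$bundle$samples$sample_id, "s003")
  # idempotence: re-running removes nothing
  res2 <- filter_samples(res$bundle)
  expect_identical(res2$report$steps[[1]]$removed, 0L)
})

test_that("filters are idempotent on their own output", {
  sp <- plain_spec(80, 120, seed = 67, missing_rate = 0.01)
  b <- simulate_genotypes(sp)
  r1 <- filter_variants(b)
  r2 <- filter_variants(r1$bundle)
  expect_identical(sum(sapply(r2$report$steps, `[[`, "removed")), 0L)
})

test_that("relatedness scan identifies duplicates and parent-child pairs", {
  set.seed(55)
  sp <- plain_spec(30, 300, seed = 71, missing_rate = 0,
                   maf_dist = list(type = "beta", shape1 = 2, shape2 = 2,
                                   min = 0.15, max = 0.5))
  b <- simulate_genotypes(sp)
  g <- b$genotypes
  g[2, ] <- g[1, ]  # duplicate pair
  f <- colMeans(g[-(1:4), ]) / 2
  g[4, ] <- rbinom(ncol(g), 1, g[3, ] / 2) + rbinom(ncol(g), 1, f)  # child of 3
  b$genotypes <- g
  rs <- relatedness_scan(b)
  pr <- rs$pairs
  expect_gt(pr$pi_hat[pr$i == 1 & pr$j == 2], 0.9)
  expect_gt(pr$pi_hat[pr$i == 3 & pr$j == 4], 0.35)
  unrelated <- pr$pi_hat[pr$i > 4]
  expect_lt(mean(unrelated), 0.1)
  expect_true(all(rs$remove %in% c("S0001", "S0002", "S0003", "S0004")))
  # too few informative variants: warning and skip
  expect_warning(rs2 <- relatedness_scan(tiny_bundle(matrix(1L, 5, 10))),
                 "skipped")
  expect_true(rs2$skipped)
})

test_that("carrier exclusion removes heterozygotes, keeps missing as non-carrier", {
  g <- matrix(0L, 6, 3)
  g[, 3] <- rep(2L, 6)   # allele1 is the major allele here -> dosage 2 = non-carrier
  g[1, 1] <- 1L          # het at listed variant -> carrier
  g[2, 1] <- NA          # missing -> retained
  b <- tiny_bundle(g)
  expect_warning(exclude_known_risk_carriers(b, "v999"), "not in bundle")
  suppressWarnings(res <- exclude_known_risk_carriers(b, c("v001", "v999")))
  expect_false("s001" %in% res$bundle$samples$sample_id)
  expect_true("s002" %in% res$bundle$samples$sample_id)
  # no carriers: unchanged
  res2 <- exclude_known_risk_carriers(b, "v002")
  expect_identical(dim(res2$bundle$genotypes), dim(b$genotypes))
})

test_that("batch concordance is null-calibrated for random splits and flags planted shifts", {
  set.seed(91)
  sp <- plain_spec(300, 800, seed = 81, missing_rate = 0)
  b <- simulate_genotypes(sp)
  batch <- sample(rep(c("A", "B"), length.out = 300))
  rep1 <- batch_concordance(b, batch)
  frac <- mean(rep1$variant_tests$p < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 800))
  expect_lt(abs(rep1$inflation - 1), 0.25)
  # planted 0.25 frequency shift at one variant in batch A
  g <- b$genotypes
  ia <- which(batch == "A")
  g[ia, 1] <- rbinom(length(ia), 2, pmin(mean(g[, 1]) / 2 + 0.25, 0.95))
  b2 <- b; b2$genotypes <- g
  rep2 <- batch_concordance(b2, batch)
  expect_lt(rep2$variant_tests$p[1], 0.05 / 800)
  # identical batches (copy of every sample in both labels) -> statistics 0
  bdup <- cohort_bundle(rbind(b$genotypes, b$genotypes),
                        data.frame(sample_id = sprintf("d%03d", 1:600)),
                        b$variants)
  rep3 <- batch_concordance(bdup, rep(c("A", "B"), each = 300))
  expect_lt(max(rep3$variant_tests$chisq, na.rm = TRUE), 1e-9)
  # single batch: no-op
  expect_true(batch_concordance(b, rep("A", 300))$skipped)
})

test_that("run_qc chains dimensions through every step", {
  sp <- plain_spec(60, 150, seed = 99, missing_rate = 0.01)
  b <- simulate_genotypes(sp)
  res <- run_qc(b)
  expect_identical(res$report$dim_in, c(60L, 150L))
  expect_identical(res$report$dim_out, dim(res$bundle$genotypes))
  # serialization round
  path <- file.path(withr::local_tempdir(), "qc.json")
  write_qc_report(res$report, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
})
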