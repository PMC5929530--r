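test_that("region sums, empirical p and tie handling follow their definitions", {
  stats <- c(a = 1.2, b = 3.4, c = 0.4)
  expect_equal(region_sum(stats, c("a", "b", "c")), 5.0)
  expect_equal(region_sum(stats, "b"), 3.4)
  # excluding a variant changes the sum by exactly its statistic
  expect_equal(region_sum(stats, c("a", "b")), 5.0 - 0.4)
  expect_error(region_sum(stats, character(0)), "empty")
  expect_error(region_sum(stats, c("a", "zz")), "zz")

  expect_equal(empirical_p(5.0, c(6, 4, 5, 3)), 0.5)  # tie counts
  expect_equal(empirical_p(10, c(1, 2, 3)), 0)        # literal rule
  expect_equal(empirical_p(10, c(1, 2, 3), add_one = TRUE), 1 / 4)
  expect_equal(empirical_p(1, c(1, 2, 3)), 1)         # observed at the minimum
  expect_error(empirical_p(1, numeric(0)), "non-empty")
})

test_that("permutation null is reproducible from the seed and records provenance", {
  sp <- region_fixture_spec(301)
  b <- simulate_genotypes(sp)
  g <- simulate_grades(b, effect_spec(), seed = 301)
  st <- dichotomize(g, "DMN")
  r1 <- run_region_test(b, st, n_perm = 200, seed = 17)
  r2 <- run_region_test(b, st, n_perm = 200, seed = 17)
  expect_identical(r1$permuted, r2$permuted)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$n_perm, 200L)
  expect_identical(r1$seed, 17L)
  r3 <- run_region_test(b, st, n_perm = 200, seed = 18)
  expect_false(identical(r1$permuted, r3$permuted))
  expect_error(permutation_null(b, st, region_spec(), n_perm = 0),
               "at least 1")
})

test_that("the vectorized allelic pass equals per-variant allelic_chi2", {
  sp <- region_fixture_spec(303)
  b <- simulate_genotypes(sp)
  g <- simulate_grades(b, effect_spec(), seed = 303)
  st <- dichotomize(g, "DMN")
  r <- permutation_null(b, st, region_spec(), n_perm = 1, seed = 1)
  y <- ifelse(st == "affected", 1L, 0L)
  direct <- sum(vapply(r$variant_ids, function(v) {
    gv <- b$genotypes[, v]
    ok <- !is.na(gv)
    a1c <- sum(gv[ok & y == 1]); n1 <- 2 * sum(ok & y == 1)
    a1u <- sum(gv[ok & y == 0]); n0 <- 2 * sum(ok & y == 0)
    allelic_chi2(c(a1c, n1 - a1c), c(a1u, n0 - a1u))$chisq
  }, 0))
  expect_equal(r$observed, direct, tolerance = 1e-10)
})

test_that("observed and permuted passes share one variant inclusion list", {
  sp <- region_fixture_spec(305)
  b <- simulate_genotypes(sp)
  # force two monomorphic region variants
  b$genotypes[, 10] <- 0L
  b$genotypes[, 20] <- 2L
  g <- simulate_grades(b, effect_spec(), seed = 305)
  st <- dichotomize(g, "DMN")
  r <- permutation_null(b, st, region_spec(), n_perm = 5, seed = 2)
  expect_false(b$variants$variant_id[10] %in% r$variant_ids)
  expect_false(b$variants$variant_id[20] %in% r$variant_ids)
  # inclusion equals the polymorphic set, computed independently
  f <- colMeans(b$genotypes, na.rm = TRUE) / 2
  poly <- b$variants$variant_id[!is.na(f) & f > 0 & f < 1]
  expect_identical(r$variant_ids, poly)
})

test_that("empirical p is invariant to permutation-order relabelling", {
  perms <- c(3.1, 8.2, 5.5, 2.0, 9.9)
  expect_equal(empirical_p(5.0, perms), empirical_p(5.0, rev(perms)))
  expect_equal(empirical_p(5.0, perms), empirical_p(5.0, sample(perms)))
})

test_that("planted region effects raise the observed sum above the permuted mean", {
  rej_null <- rej_alt <- logical(6)
  for (i in 1:6) {
    sp <- region_fixture_spec(400 + i)
    b <- simulate_genotypes(sp)
    g0 <- simulate_grades(b, effect_spec(), seed = 400 + i)
    ga <- simulate_grades(b, planted_region_effects(), seed = 400 + i)
    r0 <- run_region_test(b, dichotomize(g0, "DMN"), n_perm = 300, seed = i)
    ra <- run_region_test(b, dichotomize(ga, "DMN"), n_perm = 300, seed = i)
    rej_null[i] <- r0$p < 0.05
    rej_alt[i] <- ra$p < 0.05
  }
  # power strictly exceeds the null rejection rate on the same fixtures
  expect_gt(sum(rej_alt), sum(rej_null))
  expect_gte(sum(rej_alt), 5)
})

test_that("the covariate-adjusted score statistic variant runs and is deterministic", {
  sp <- region_fixture_spec(501)
  b <- simulate_genotypes(sp)
  g <- simulate_grades(b, effect_spec(), seed = 501)
  st <- dichotomize(g, "DMN")
  cv <- matrix(rnorm(2 * nrow(b$genotypes)), ncol = 2)
  r1 <- run_region_test(b, st, n_perm = 50, seed = 3, statistic = "score",
                        covariates = cv)
  r2 <- run_region_test(b, st, n_perm = 50, seed = 3, statistic = "score",
                        covariates = cv)
  expect_identical(r1$permuted, r2$permuted)
  expect_identical(r1$statistic, "score")
  expect_gte(r1$p, 0)
})

test_that("region result JSON serialization carries provenance", {
  sp <- region_fixture_spec(601)
  b <- simulate_genotypes(sp)
  g <- simulate_grades(b, effect_spec(), seed = 601)
  r <- run_region_test(b, dichotomize(g, "DMN"), n_perm = 20, seed = 4)
  path <- file.path(withr::local_tempdir(), "region.json")
  write_region_result(r, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$n_perm, 20)
  expect_equal(back$seed, 4)
  expect_equal(length(back$permuted), 20)
})
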