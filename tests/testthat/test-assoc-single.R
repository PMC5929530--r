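test_that("logistic fit matches a brute-force likelihood grid on a toy dataset", {
  g <- c(0, 0, 1, 2, 0, 1, 1, 0)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1)
  b <- tiny_bundle(matrix(as.integer(g), ncol = 1))
  res <- logistic_assoc(b, y)
  # grid-search oracle: maximize the Bernoulli log-likelihood directly
  ll <- function(b0, b1) sum(y * (b0 + b1 * g) - log(1 + exp(b0 + b1 * g)))
  grid <- expand.grid(b0 = seq(-6, 6, by = 0.05), b1 = seq(-6, 6, by = 0.05))
  best <- grid[which.max(mapply(ll, grid$b0, grid$b1)), ]
  refine <- expand.grid(b0 = seq(best$b0 - 0.06, best$b0 + 0.06, by = 0.001),
                        b1 = seq(best$b1 - 0.06, best$b1 + 0.06, by = 0.001))
  best <- refine[which.max(mapply(ll, refine$b0, refine$b1)), ]
  expect_equal(res$beta[1], best$b1, tolerance = 2e-3)
  expect_equal(res$or[1], exp(res$beta[1]))
})

test_that("a variant carried only by cases is flagged as separated", {
  g <- c(rep(0L, 10), rep(1L, 5))
  y <- c(rep(0L, 10), rep(1L, 5))
  res <- logistic_assoc(tiny_bundle(matrix(g, ncol = 1)), y)
  expect_identical(res$flag[1], "separation")
  expect_true(is.na(res$or[1]))
})

test_that("allelic chi-squared equals the hand-computed Pearson formula", {
  # equal frequencies: statistic 0, p 1
  r0 <- allelic_chi2(c(20, 80), c(40, 160))
  expect_equal(r0$chisq, 0)
  expect_equal(r0$p, 1)
  # ((30,170),(10,190)) against sum((O-E)^2/E) computed cell by cell
  tab <- rbind(c(30, 170), c(10, 190))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(allelic_chi2(tab[1, ], tab[2, ])$chisq,
               sum((tab - e)^2 / e))
  # doubling every cell doubles the statistic
  expect_equal(allelic_chi2(2 * tab[1, ], 2 * tab[2, ])$chisq,
               2 * allelic_chi2(tab[1, ], tab[2, ])$chisq)
  # zero margin flagged
  expect_identical(allelic_chi2(c(0, 50), c(0, 50))$flag, "zero-margin")
})

test_that("genomic inflation follows its definition and scaling", {
  stats1 <- rep(qchisq(0.5, 1), 150)
  expect_equal(genomic_inflation(stats1), 1)
  expect_equal(genomic_inflation(2 * stats1), 2)
  expect_warning(lam <- genomic_inflation(stats1[1:50]), "omitted")
  expect_true(is.na(lam))
})

test_that("null simulation keeps lambda near 1 and p-values uniform", {
  sp <- plain_spec(250, 600, seed = 47)
  b <- simulate_genotypes(sp)
  g <- simulate_grades(b, effect_spec(), seed = 47)
  res <- logistic_assoc(b, dichotomize(g, "DMN"))
  lam <- genomic_inflation(res)
  expect_gt(lam, 0.9)
  expect_lt(lam, 1.1)
  qq <- export_plot_data(res)$qq
  expect_lt(max(abs(qq$expected - qq$observed)[qq$expected < 1]), 0.5)
})

test_that("score-free logistic agrees with allelic chi-squared on complete common data", {
  set.seed(59)
  n <- 500
  G <- sapply(runif(40, 0.05, 0.5), function(p) rbinom(n, 2, p))
  y <- rbinom(n, 1, 0.4)
  b <- tiny_bundle(G)
  res <- logistic_assoc(b, y)
  al <- sapply(seq_len(40), function(j) {
    a1c <- sum(G[y == 1, j]); a1u <- sum(G[y == 0, j])
    allelic_chi2(c(a1c, 2 * sum(y) - a1c),
                 c(a1u, 2 * sum(1 - y) - a1u))$chisq
  })
  ok <- res$flag == "ok"
  expect_gt(cor(res$chisq[ok], al[ok]), 0.99)
})

test_that("results are invariant to sample order and to allele-coding swap", {
  set.seed(61)
  n <- 120
  G <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  y <- rbinom(n, 1, 0.5)
  b <- tiny_bundle(G)
  r1 <- logistic_assoc(b, y)
  perm <- sample(n)
  r2 <- logistic_assoc(tiny_bundle(G[perm, ]), y[perm])
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
  rswap <- logistic_assoc(tiny_bundle(2L - G), y)
  expect_equal(rswap$beta, -r1$beta, tolerance = 1e-8)
  expect_equal(rswap$p, r1$p, tolerance = 1e-8)
})

test_that("marker scan matches single-variant results and applies Bonferroni", {
  set.seed(63)
  n <- 150
  G <- matrix(rbinom(n * 6, 2, 0.3), n, 6)
  colnames(G) <- paste0("mk", 1:6)
  y <- rbinom(n, 1, 0.4)
  res_assoc <- logistic_assoc(tiny_bundle(G), y)
  M <- cbind(G, allzero = 0L)
  scan <- marker_scan(M, y)
  expect_equal(scan$p, res_assoc$p, tolerance = 1e-10)
  expect_identical(attr(scan, "skipped"), "allzero")
  expect_equal(attr(scan, "threshold"), 0.05 / 6)
  expect_error(marker_scan(matrix(3, 2, 2), c(0, 1)), "\\[0, 2\\]")
})

test_that("plot exports have the documented shapes and handle empty input", {
  res <- data.frame(variant_id = c("a", "b"), chrom = c("1", "2"),
                    pos = c(100L, 200L), p = c(0.5, 0.01))
  out <- export_plot_data(res)
  expect_identical(nrow(out$qq), 2L)
  expect_equal(out$qq$expected, -log10((1:2 - 0.5) / 2))
  expect_identical(nrow(out$manhattan), 2L)
  empty <- export_plot_data(data.frame(p = numeric(0)))
  expect_identical(nrow(empty$qq), 0L)
})
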