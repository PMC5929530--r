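test_that("gene sets respect the MAF bound, annotation and overlap rule", {
  set.seed(71)
  n <- 400
  G <- cbind(rbinom(n, 2, 0.02), rbinom(n, 2, 0.03), rbinom(n, 2, 0.2),
             rbinom(n, 2, 0.01), 0L)
  b <- tiny_bundle(G)
  ann <- data.frame(variant_id = c("v001", "v002", "v002", "v003", "v004",
                                   "v005"),
                    gene = c("A", "A", "B", "B", "B", "C"))
  sets <- build_gene_sets(b, ann)
  expect_setequal(sets$A, c("v001", "v002"))
  expect_true("v002" %in% sets$B)          # overlapping-gene variant in both
  expect_false("v003" %in% sets$B)         # MAF 0.2 >= 0.05 excluded
  expect_identical(sets$C, character(0))   # monomorphic -> empty set kept
})

test_that("CMC on a single-variant gene equals dominant-coded logistic association", {
  set.seed(73)
  n <- 300
  g <- rbinom(n, 2, 0.04)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * (g > 0)))
  b <- tiny_bundle(matrix(g, ncol = 1))
  cv <- matrix(rnorm(2 * n), n, 2)
  cm <- cmc_test(b, "v001", y, cv)
  dom <- logistic_assoc(tiny_bundle(matrix(as.integer(g > 0), ncol = 1)),
                        y, cv)
  expect_equal(cm$p, dom$p[1], tolerance = 1e-10)
  # degenerate sets are flagged, not fitted
  expect_identical(cmc_test(b, character(0), y)$flag, "empty-set")
  expect_identical(cmc_test(tiny_bundle(matrix(0L, 10, 1)), "v001",
                            rep(c(0L, 1L), 5))$flag, "untestable")
})

test_that("SKAT weights follow the Beta(1,25) closed form", {
  expect_equal(beta_maf_weights(0.05), 25 * 0.95^24)
  expect_equal(beta_maf_weights(0.5), 25 * 0.5^24)
})

test_that("mixture tail probability matches direct Monte-Carlo of the mixture", {
  set.seed(75)
  lam <- c(3.2, 1.5, 0.8, 0.3, 0.1)
  draws <- colSums(lam * matrix(rchisq(5 * 2e5, 1), 5))
  for (q in c(2, 8, 20)) {
    mc <- mean(draws > q)
    pv <- pchisq_mixture(q, lam)
    expect_lt(abs(pv$p - mc), 4 * sqrt(mc * (1 - mc) / 2e5) + 2e-3)
  }
  # single-weight case is an exact chi-squared
  expect_equal(pchisq_mixture(5, 2)$p, pchisq(2.5, 1, lower.tail = FALSE))
})

test_that("single-variant SKAT reduces to the weighted 1-df score test", {
  set.seed(77)
  n <- 200
  g <- rbinom(n, 2, 0.1)
  y <- rbinom(n, 1, 0.4)
  cv <- matrix(rnorm(2 * n), n, 2)
  b <- tiny_bundle(matrix(g, ncol = 1))
  sk <- skat_test(b, "v001", y, cv)
  # closed-form score test with the null-model projected variance
  X <- cbind(1, cv)
  f0 <- glm.fit(X, y, family = binomial())
  mu <- f0$fitted.values; v <- mu * (1 - mu); r <- y - mu
  U <- sum(g * r)
  XtGV <- crossprod(X, g * v)
  Vj <- sum(g^2 * v) - as.numeric(t(XtGV) %*% solve(crossprod(X, X * v), XtGV))
  expect_equal(sk$p, pchisq(U^2 / Vj, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_identical(sk$method, "exact")
})

test_that("SKAT Q is invariant to variant order within a gene", {
  set.seed(79)
  n <- 150
  G <- sapply(c(0.03, 0.08, 0.15, 0.05), function(p) rbinom(n, 2, p))
  y <- rbinom(n, 1, 0.3)
  b <- tiny_bundle(G)
  s1 <- skat_test(b, paste0("v00", 1:4), y)
  s2 <- skat_test(b, paste0("v00", c(3, 1, 4, 2)), y)
  expect_equal(s1$Q, s2$Q)
  expect_equal(s1$p, s2$p)
})

test_that("CMC and SKAT are calibrated under the null across many genes", {
  set.seed(81)
  sp <- plain_spec(150, 1200, seed = 83, missing_rate = 0,
                   maf_dist = list(type = "beta", shape1 = 0.4, shape2 = 6,
                                   min = 0.005, max = 0.2))
  b <- simulate_genotypes(sp)
  y <- rbinom(150, 1, 0.35)  # outcome independent of every genotype
  sets <- split(b$variants$variant_id,
                rep(seq_len(300), each = 4))  # 300 four-variant genes
  names(sets) <- paste0("G", seq_along(sets))
  res <- gene_scan(b, y, sets)
  skp <- res$skat_p[!is.na(res$skat_p)]
  cmp <- res$cmc_p[!is.na(res$cmc_p)]
  expect_lt(abs(mean(skp < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / length(skp)) + 0.02)
  expect_lt(abs(mean(cmp < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / length(cmp)) + 0.02)
  expect_identical(nrow(res), 300L)
})

test_that("gene scan applies the Bonferroni threshold for the gene count", {
  expect_equal(bonferroni_threshold(10000)$threshold, 5e-6)
  set.seed(85)
  G <- sapply(c(0.03, 0.04), function(p) rbinom(80, 2, p))
  b <- tiny_bundle(G)
  y <- rbinom(80, 1, 0.5)
  sets <- list(g1 = c("v001", "v002"))
  res <- gene_scan(b, y, sets, n_genes = 10000)
  expect_equal(attr(res, "threshold"), 5e-6)
})
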