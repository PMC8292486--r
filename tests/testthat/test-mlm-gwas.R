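# simulate y = polygenic + residual for a given variance ratio
sim_mlm_y <- function(G, h2_ratio, seed) {
  set.seed(seed)
  n <- nrow(G)
  ee <- eigen(G, symmetric = TRUE)
  a <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) * rnorm(n))
  drop(sqrt(h2_ratio) * a + rnorm(n))
}

test_that("spectral restricted likelihood equals dense evaluation", {
  s <- small_sim(seed = 161, n = 60, p = 100, blocks = 10, litters = 10)
  G <- grm_centered(s$geno)
  y <- sim_mlm_y(G, 1, 2)
  null <- fit_mlm_null(y, G)
  X <- matrix(1, 60, 1)
  n <- 60; k <- 1
  dense_ll <- function(log_delta) {
    V <- G + exp(log_delta) * diag(n)
    Vi <- solve(V)
    XtVX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XtVX, t(X) %*% Vi)
    rss <- sum(y * (P %*% y))
    s2 <- rss / (n - k)
    -0.5 * ((n - k) * (log(2 * pi * s2) + 1) +
              determinant(V, logarithm = TRUE)$modulus +
              determinant(XtVX, logarithm = TRUE)$modulus)
  }
  for (ld in c(-2, -1, 0, 1, 2)) {
    expect_equal(null$restricted_ll(ld), dense_ll(ld), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("the variance ratio is recovered and vanishes under the null", {
  hits_null <- 0; hits_one <- 0
  for (r in 1:20) {
    s <- small_sim(seed = 170 + r, n = 150, p = 200, blocks = 20,
                   litters = 25)
    G <- grm_centered(s$geno)
    G <- G / mean(diag(G))
    y0 <- sim_mlm_y(G, 0, 300 + r)
    n0 <- fit_mlm_null(y0, G)
    if (n0$sigma2_a / (n0$sigma2_a + n0$sigma2_e) < 0.1) {
      hits_null <- hits_null + 1
    }
    y1 <- sim_mlm_y(G, 1, 400 + r)
    n1 <- fit_mlm_null(y1, G)
    ratio <- n1$sigma2_a / n1$sigma2_e
    if (ratio > 0.5 && ratio < 2.0) hits_one <- hits_one + 1
  }
  expect_gte(hits_null, 18)
  expect_gte(hits_one, 14)
})

test_that("with zero polygenic variance the Wald p equals the OLS t-test p", {
  s <- small_sim(seed = 201, n = 80, p = 60, blocks = 6, litters = 10)
  set.seed(3)
  y <- rnorm(80)
  null0 <- fit_mlm_null(y, matrix(0, 80, 80))
  a <- wald_scan(s$geno, null0)
  for (j in which(!is.na(a$p))[1:20]) {
    ols <- summary(lm(y ~ s$geno$dosage[, j]))$coefficients
    expect_equal(a$p[j], ols[2, 4], tolerance = 1e-10)
    expect_equal(a$beta[j], ols[2, 1], tolerance = 1e-10)
  }
})

test_that("degenerate markers are flagged, not tested", {
  s <- small_sim(seed = 211, n = 50, p = 40, blocks = 4, litters = 8)
  G <- grm_centered(s$geno)
  y <- sim_mlm_y(G, 0.5, 4)
  null <- fit_mlm_null(y, G)
  mk <- cbind(mono = rep(2, 50), inter = rep(1, 50),
              ok = s$geno$dosage[, which(geno_maf(s$geno) > 0.1)[1]])
  a <- wald_scan(mk, null)
  expect_equal(a$reason[1], "monomorphic")
  expect_equal(a$reason[2], "monomorphic")   # constant column
  expect_true(is.na(a$p[1]) && is.na(a$p[2]))
  expect_false(is.na(a$p[3]))
  # a marker duplicating the intercept after centering: collinear
  null_i <- fit_mlm_null(y, G, X = cbind(1, s$geno$dosage[, 1]))
  a2 <- wald_scan(s$geno$dosage[, 1, drop = FALSE], null_i)
  expect_equal(a2$reason[1], "collinear")
})

test_that("p3d and per-marker REML p-values agree under the null", {
  s <- small_sim(seed = 221, n = 100, p = 150, blocks = 15, litters = 15)
  G <- grm_centered(s$geno)
  y <- sim_mlm_y(G, 0.7, 5)
  null <- fit_mlm_null(y, G)
  poly <- which(geno_maf(s$geno) > 0.05)[1:60]
  a1 <- wald_scan(s$geno$dosage[, poly], null, mode = "p3d")
  a2 <- wald_scan(s$geno$dosage[, poly], null, mode = "per-marker-reml")
  expect_gt(cor(a1$p, a2$p, method = "spearman", use = "complete.obs"),
            0.99)
})

test_that("p-values are equivariant under joint sample permutation", {
  s <- small_sim(seed = 231, n = 60, p = 80, blocks = 8, litters = 10)
  G <- grm_centered(s$geno)
  y <- sim_mlm_y(G, 1, 6)
  a1 <- wald_scan(s$geno$dosage, fit_mlm_null(y, G))
  set.seed(7)
  pm <- sample(60)
  a2 <- wald_scan(s$geno$dosage[pm, ],
                  fit_mlm_null(y[pm], G[pm, pm]))
  expect_equal(a1$p, a2$p, tolerance = 1e-6)
})

test_that("Bonferroni thresholds reproduce the three published regimes", {
  chip <- bonferroni_thresholds(36969)
  expect_equal(signif(chip$genome_wide, 3), 1.35e-6)
  expect_equal(signif(chip$suggestive, 3), 2.70e-5)
  imputed <- bonferroni_thresholds(3072572)
  expect_equal(signif(imputed$genome_wide, 3), 1.63e-8)
  expect_equal(signif(imputed$suggestive, 3), 3.25e-7)
  hap <- bonferroni_thresholds(274741)
  expect_equal(signif(hap$genome_wide, 3), 1.82e-7)
  expect_equal(signif(hap$suggestive, 3), 3.64e-6)
  expect_error(bonferroni_thresholds(0), "n_tests")
})

test_that("genomic lambda behaves on constructed and null inputs", {
  m <- 5000
  grid_p <- (seq_len(m) - 0.5) / m
  expect_equal(genomic_lambda(grid_p), 1.00, tolerance = 0.01)
  # doubling every chi-square statistic doubles lambda
  chi <- qchisq(grid_p, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p2), 2.00, tolerance = 0.02)
  set.seed(8)
  expect_lt(abs(genomic_lambda(runif(5000)) - 1), 0.1)
  expect_warning(genomic_lambda(runif(50)), "unstable")
  # regression method also centers at 1 under the null
  expect_lt(abs(genomic_lambda(grid_p, method = "regression") - 1), 0.05)
})
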