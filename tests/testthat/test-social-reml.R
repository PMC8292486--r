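test_that("social incidence encodes pen mates", {
  cohort <- data.frame(
    id = c("a", "b", "c", "d"), sex = c("male", "female", "male", "male"),
    litter = c(1, 1, 2, 2), pen = c(1, 1, 1, 2),
    test_ym = "t1", birth_ym = c("b1", "b1", "b2", "b2"),
    stringsAsFactors = FALSE
  )
  traits <- data.frame(id = cohort$id, y = c(1, 2, 3, 4))
  des <- build_design(cohort, traits)
  expect_equal(des$Z_S[1:3, 1:3],
               matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3),
               ignore_attr = TRUE)
  expect_equal(unname(des$Z_S[4, ]), c(0, 0, 0, 0))  # alone in its pen
  expect_equal(unname(rowSums(des$W)), rep(1, 4))
  expect_equal(unname(rowSums(des$V)), rep(1, 4))
})

test_that("Z_S row sums equal pen size minus one on simulated cohorts", {
  s <- small_sim(seed = 111, n = 45, group_size = 7, litters = 9)
  des <- build_design(s$cohort, s$traits)
  pen_size <- table(s$cohort$pen)[des$pen]
  expect_equal(unname(rowSums(des$Z_S)), as.numeric(pen_size) - 1)
  expect_true(all(diag(des$Z_S) == 0))
})

test_that("records with missing structure are excluded with a warning", {
  s <- small_sim(seed = 112, n = 30, group_size = 6, litters = 6)
  s$cohort$pen[3] <- NA
  expect_warning(des <- build_design(s$cohort, s$traits), "excluding")
  expect_equal(length(des$y), 29)
})

test_that("single-random-effect REML matches a derivative-free oracle", {
  set.seed(123)
  s <- small_sim(seed = 123, n = 100, p = 150, blocks = 15, litters = 20)
  K <- grm_centered(s$geno, method = "scaled")
  des <- build_design(s$cohort, s$traits)
  fit <- reml_fit_social(des, K, include_social = FALSE,
                         include_litter = FALSE, include_group = FALSE,
                         compute_ebv = FALSE)
  # independent oracle: Nelder-Mead over log-variances on the dense
  # restricted likelihood
  y <- des$y; X <- des$X; n <- length(y)
  dense_rll <- function(lv) {
    V <- exp(lv[1]) * K + exp(lv[2]) * diag(n)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(1e10)
    Vi <- chol2inv(cV)
    XtVX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XtVX, t(X) %*% Vi)
    0.5 * (2 * sum(log(diag(cV))) +
             determinant(XtVX, logarithm = TRUE)$modulus +
             sum(y * (P %*% y)))
  }
  opt <- optim(log(c(0.3, 0.7) * var(y)), dense_rll,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("REML log-likelihood is non-decreasing across iterations", {
  s <- small_sim(seed = 131, n = 150, p = 200, blocks = 20,
                 group_size = 6, litters = 25)
  K <- grm_centered(s$geno, method = "scaled")
  des <- build_design(s$cohort, s$traits)
  fit <- reml_fit_social(des, K, compute_ebv = FALSE)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
})

test_that("EBVs beat a permuted baseline and DGE accuracy tops SGE accuracy", {
  s <- small_sim(seed = 141, n = 200, p = 300, blocks = 30,
                 group_size = 8, litters = 25)
  K <- grm_centered(s$geno, method = "scaled")
  des <- build_design(s$cohort, s$traits)
  fit <- reml_fit_social(des, K)
  r_true <- cor(fit$ebv_D, s$truth$true_a_D)
  set.seed(1)
  r_perm <- cor(sample(fit$ebv_D), s$truth$true_a_D)
  expect_gt(r_true, r_perm)
  expect_gt(r_true, 0.3)
  if (fit$varcomps["sigma2_S"] > 0) {
    accD <- accuracy_from_pev(fit$pev_D, fit$varcomps["sigma2_D"])
    accS <- accuracy_from_pev(fit$pev_S, fit$varcomps["sigma2_S"])
    expect_gte(mean(accD), mean(accS))
  }
})

test_that("accuracy from PEV follows the definition and clamps", {
  expect_equal(as.numeric(accuracy_from_pev(0.36, 1.0)), 0.8)
  expect_equal(as.numeric(accuracy_from_pev(0, 2.5)), 1.0)
  r <- accuracy_from_pev(1.2, 1.0)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "clamped"))
  expect_error(accuracy_from_pev(0.1, 0), "variance")
})

test_that("deregression divides by squared accuracy with a usability floor", {
  expect_equal(deregress(0.7, 1)$debv, 0.7)
  expect_equal(deregress(0.5, 0.5)$debv, 2.0)
  low <- deregress(0.5, 0.05)
  expect_false(low$usable)
  expect_true(is.na(low$debv))
  expect_error(deregress(1, 1.5), "0, 1")
})

test_that("the deregressed table carries both effects for a social fit", {
  s <- small_sim(seed = 151, n = 120, group_size = 6, litters = 20)
  K <- grm_centered(s$geno, method = "scaled")
  des <- build_design(s$cohort, s$traits)
  fit <- reml_fit_social(des, K)
  tab <- deregressed_ebv_table(fit, trait = "adfi")
  expect_true(all(c("DGE") %in% tab$effect))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_true(all(is.na(tab$debv) | tab$usable))
  usable <- tab[tab$usable & tab$effect == "DGE", ]
  expect_equal(usable$debv, usable$ebv / usable$accuracy^2)
})
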