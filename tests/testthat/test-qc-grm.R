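# full-enumeration HWE oracle, independent of the package's recurrence
hwe_enum <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_A, 2 * n - n_A)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    exp(lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
          h * log(2) + lfactorial(n_A) + lfactorial(2 * n - n_A) -
          lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

test_that("exact HWE test matches full enumeration", {
  expect_equal(hwe_exact(100, 0, 0), 1.0)        # monomorphic
  expect_equal(hwe_exact(25, 50, 25), hwe_enum(25, 50, 25))
  expect_equal(hwe_exact(25, 50, 25), 1.0, tolerance = 1e-12)
  expect_lt(hwe_exact(0, 100, 0), 1e-10)
  for (cnt in list(c(10, 20, 70), c(40, 20, 40), c(5, 5, 90),
                   c(1, 1, 1), c(0, 3, 97))) {
    expect_equal(hwe_exact(cnt[1], cnt[2], cnt[3]),
                 hwe_enum(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

# 100-sample, 10-marker panel with hand-constructed failure modes
qc_fixture <- function() {
  n <- 100
  hwe_ok <- c(rep(0, 49), rep(1, 42), rep(2, 9))    # p = 0.3, near-HWE
  mk <- list(
    m01 = hwe_ok,                                   # no position (below)
    m02 = c(rep(1, 4), rep(0, 96)),                 # MAF 0.02 -> fail
    m03 = c(rep(2, 2), rep(1, 0), rep(0, 98)),      # MAF 0.02 -> fail
    m04 = c(rep(NA, 15), rep(1, 35), rep(0, 50)),   # call rate 0.85
    m05 = rep(1, 100),                              # all het -> HWE fail
    m06 = c(rep(1, 10), rep(0, 90)),                # MAF exactly 0.05
    m07 = hwe_ok, m08 = hwe_ok, m09 = hwe_ok, m10 = hwe_ok
  )
  dosage <- do.call(cbind, mk)
  map <- data.frame(id = names(mk), chr = 1L,
                    pos = seq(1000L, by = 1000L, length.out = 10L),
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  map$pos[1] <- NA                                   # marker without position
  geno_matrix(dosage, map)
}

test_that("marker QC removes by the fixed filter order with correct tallies", {
  res <- qc_markers(qc_fixture())
  rep <- res$report
  expect_equal(rep$n_input, 10L)
  expect_equal(rep$n_removed_no_position_or_sex_chr, 1L)
  expect_equal(rep$n_removed_callrate, 1L)
  expect_equal(rep$n_removed_maf, 2L)
  expect_equal(rep$n_removed_hwe, 1L)
  expect_equal(rep$n_retained, 5L)
  # marker at MAF exactly 0.05 retained (strict < removal)
  expect_true("m06" %in% res$geno$map$id)
  # idempotence: a second pass removes nothing
  res2 <- qc_markers(res$geno)
  expect_equal(res2$report$n_retained, res2$report$n_input)
})

test_that("sex-chromosome markers and quality scores are filtered", {
  g <- qc_fixture()
  g$map$pos[1] <- 1000L
  g$map$chr[2] <- "X"
  g$map$quality <- c(rep(0.95, 9), 0.5)
  res <- qc_markers(g, quality_min = 0.8)
  expect_equal(res$report$n_removed_no_position_or_sex_chr, 1L)
  expect_equal(res$report$n_removed_quality, 1L)
  expect_false("m10" %in% res$geno$map$id)
})

test_that("chip bookkeeping replay reproduces the retained count", {
  expect_equal(qc_bookkeeping(50697, 11874, 1854), 36969L)
  expect_error(qc_bookkeeping(10, 8, 5), "removed")
})

test_that("the centered GRM matches the column-by-column outer-product loop", {
  set.seed(13)
  X <- matrix(rbinom(200, 2, 0.4), 10, 20)
  G <- grm_centered(X)
  # brute-force oracle: explicit per-marker outer products
  Gb <- matrix(0, 10, 10)
  for (i in 1:20) {
    ci <- X[, i] - mean(X[, i])
    Gb <- Gb + ci %o% ci
  }
  Gb <- Gb / 20
  expect_lt(max(abs(G - Gb)), 1e-12)
})

test_that("GRM forced values, symmetry and centering invariants hold", {
  expect_equal(grm_centered(matrix(c(0, 1, 2), 3, 1)),
               matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3))
  # a monomorphic marker contributes the zero matrix
  X <- cbind(c(0, 1, 2), 2)
  expect_equal(grm_centered(X), grm_centered(matrix(c(0, 1, 2))) / 2)
  set.seed(29)
  Xr <- matrix(rbinom(600, 2, 0.3), 30, 20)
  G <- grm_centered(Xr)
  expect_equal(G, t(G))
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(G)) / 30)
  Xc <- sweep(Xr, 2, colMeans(Xr))
  expect_lt(max(abs(colMeans(Xc))), 1e-12)
  # missing dosages are mean-imputed before centering
  Xm <- Xr; Xm[1, 1] <- NA
  expect_silent(grm_centered(Xm))
})
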