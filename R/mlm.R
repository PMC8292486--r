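#' Fit the null polygenic model for association scans
#'
#' The unified mixed linear model `y = Xm + Wa + e` with
#' `a ~ MVN(0, G sigma2_a)` and `e ~ MVN(0, I sigma2_e)` is profiled on
#' the variance ratio `delta = sigma2_e / sigma2_a` after rotating every
#' quantity into the eigenbasis of `G`, where the covariance is diagonal
#' (the standard spectral trick). `delta` is found by a bounded 1-D
#' search of the restricted likelihood over `log(delta)` on `[-10, 10]`;
#' negative eigenvalues of `G` (possible for rank-deficient centered
#' GRMs) are clipped at zero and counted.
#'
#' @param y response vector (a deregressed-EBV pseudo-phenotype in the
#'   pipeline; any numeric response works).
#' @param G genomic relationship matrix over the same samples.
#' @param X covariate matrix; defaults to an intercept.
#' @return an object of class `mlm_null` caching the rotation, the
#'   optimal `delta`, rotated response/covariates and the variance
#'   component estimates.
#' @export
fit_mlm_null <- function(y, G, X = NULL) {
  n <- length(y)
  if (any(!is.finite(y))) stopf("response contains non-finite values")
  if (stats::var(y) <= 0) stopf("response has zero variance")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, all(dim(G) == c(n, n)))

  ee <- eigen((G + t(G)) / 2, symmetric = TRUE)
  n_clipped <- sum(ee$values < 0)
  lambda <- pmax(ee$values, 0)
  U <- ee$vectors
  uy <- drop(crossprod(U, y))
  ux <- crossprod(U, X)
  k <- ncol(X)

  restricted_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- lambda + delta
    xtwx <- crossprod(ux, ux / w)
    beta <- solve(xtwx, crossprod(ux, uy / w))
    r <- uy - drop(ux %*% beta)
    rss <- sum(r^2 / w)
    s2a <- rss / (n - k)
    -0.5 * ((n - k) * (log(2 * pi * s2a) + 1) + sum(log(w)) +
              determinant(xtwx, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(restricted_ll, interval = c(-10, 10),
                         maximum = TRUE, tol = 1e-10)
  delta <- exp(opt$maximum)
  w <- lambda + delta
  xtwx <- crossprod(ux, ux / w)
  beta <- solve(xtwx, crossprod(ux, uy / w))
  rss <- sum((uy - drop(ux %*% beta))^2 / w)
  s2a <- rss / (n - k)

  structure(list(
    lambda = lambda, U = U, delta = delta,
    uy = uy, ux = ux, n = n, k = k,
    sigma2_a = s2a, sigma2_e = s2a * delta,
    loglik = opt$objective, n_eigen_clipped = n_clipped,
    restricted_ll = restricted_ll
  ), class = "mlm_null")
}

#' @export
print.mlm_null <- function(x, ...) {
  cat(sprintf(paste0(
    "mlm_null: n = %d, delta = %.4g, sigma2_a = %.4g, sigma2_e = %.4g",
    " (%d eigenvalues clipped)\n"),
    x$n, x$delta, x$sigma2_a, x$sigma2_e, x$n_eigen_clipped))
  invisible(x)
}

#' Per-marker Wald association scan under the mixed model
#'
#' Each column of `markers` is tested as a fixed effect in the rotated
#' generalized-least-squares system of the null model. The Wald statistic
#' `m_hat^2 / SE^2` is referred to `F(1, n - k - 1)` with the residual
#' variance re-estimated per marker, which reduces exactly to the
#' ordinary regression t-test when the polygenic component vanishes.
#' `mode = "p3d"` reuses the null model's variance ratio for every marker
#' (population parameters previously determined); `mode =
#' "per-marker-reml"` re-optimizes the ratio with the marker in the model.
#' Monomorphic markers and markers collinear with the covariates get a
#' missing p-value with a reason code.
#'
#' @param markers n x p dosage matrix (or a [geno_matrix]), sample order
#'   matching the null fit.
#' @param null an [mlm_null].
#' @param mode `"p3d"` (default) or `"per-marker-reml"`.
#' @param map optional marker map (`id`, `chr`, `pos`) for the output; the
#'   map of a `geno_matrix` input is used automatically.
#' @return data.frame (`assoc_table`): `id`, `chr`, `pos`, `beta`, `se`,
#'   `p`, `reason` (NA for tested markers).
#' @export
wald_scan <- function(markers, null, mode = c("p3d", "per-marker-reml"),
                      map = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(null, "mlm_null"))
  if (inherits(markers, "geno_matrix")) {
    map <- map %||% markers$map
    markers <- markers$dosage
  }
  markers <- as.matrix(markers)
  n <- null$n
  stopifnot(nrow(markers) == n)
  p <- ncol(markers)
  if (anyNA(markers)) {
    mu <- colMeans(markers, na.rm = TRUE)
    idx <- which(is.na(markers), arr.ind = TRUE)
    markers[idx] <- mu[idx[, 2L]]
  }

  beta <- se <- pval <- rep(NA_real_, p)
  reason <- rep(NA_character_, p)
  mono <- apply(markers, 2L, function(x) max(x) - min(x) == 0)
  reason[mono] <- "monomorphic"

  k <- null$k
  df <- n - k - 1L
  ux_all <- crossprod(null$U, markers)   # rotated markers

  if (mode == "p3d") {
    w <- null$lambda + null$delta
    uy <- null$uy; ux <- null$ux
    xtwx <- crossprod(ux, ux / w)
    xtwx_inv <- solve(xtwx)
    xty <- crossprod(ux, uy / w)
    yty <- sum(uy^2 / w)
    # partitioned GLS: project marker and response off the covariates
    gtwg <- colSums(ux_all^2 / w)                       # g' W g
    xtwg <- crossprod(ux, ux_all / w)                   # X' W g (k x p)
    gty <- drop(crossprod(ux_all, uy / w))              # g' W y
    adj <- colSums(xtwg * (xtwx_inv %*% xtwg))
    gMg <- gtwg - adj
    gMy <- gty - colSums(xtwg * drop(xtwx_inv %*% xty))
    yMy <- yty - sum(xty * drop(xtwx_inv %*% xty))
    collinear <- !mono & gMg <= 1e-10 * pmax(gtwg, 1e-300)
    reason[collinear] <- "collinear"
    test <- which(is.na(reason))
    b <- gMy[test] / gMg[test]
    rss <- pmax(yMy - b^2 * gMg[test], 0)
    s2 <- rss / df
    se_t <- sqrt(s2 / gMg[test])
    fstat <- b^2 / se_t^2
    beta[test] <- b
    se[test] <- se_t
    pval[test] <- stats::pf(fstat, 1, df, lower.tail = FALSE)
  } else {
    for (j in which(is.na(reason))) {
      xj <- cbind(null$ux, crossprod(null$U, markers[, j]))
      fitj <- tryCatch(
        .reml_delta_fit(null$uy, xj, null$lambda),
        error = function(e) NULL
      )
      if (is.null(fitj)) { reason[j] <- "collinear"; next }
      beta[j] <- fitj$beta
      se[j] <- fitj$se
      pval[j] <- stats::pf((fitj$beta / fitj$se)^2, 1, n - k - 1L,
                           lower.tail = FALSE)
    }
  }

  out <- data.frame(
    id = if (!is.null(map)) map$id else sprintf("m%d", seq_len(p)),
    chr = if (!is.null(map)) map$chr else NA,
    pos = if (!is.null(map)) map$pos else NA,
    beta = beta, se = se, p = pval, reason = reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("assoc_table", "data.frame")
  out
}

# re-optimize delta with the marker in the fixed effects; rotated inputs
.reml_delta_fit <- function(uy, ux, lambda) {
  n <- length(uy); k <- ncol(ux)
  rll <- function(log_delta) {
    w <- lambda + exp(log_delta)
    xtwx <- crossprod(ux, ux / w)
    beta <- solve(xtwx, crossprod(ux, uy / w))
    rss <- sum((uy - drop(ux %*% beta))^2 / w)
    s2 <- rss / (n - k)
    -0.5 * ((n - k) * (log(2 * pi * s2) + 1) + sum(log(w)) +
              determinant(xtwx, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(rll, interval = c(-10, 10), maximum = TRUE,
                         tol = 1e-8)
  w <- lambda + exp(opt$maximum)
  xtwx <- crossprod(ux, ux / w)
  ci <- solve(xtwx)
  beta <- drop(ci %*% crossprod(ux, uy / w))
  rss <- sum((uy - drop(ux %*% beta))^2 / w)
  s2 <- rss / (n - k)
  list(beta = beta[k], se = sqrt(s2 * ci[k, k]))
}

#' Bonferroni significance thresholds
#'
#' Genome-wide threshold 0.05 / N and suggestive threshold 1 / N for N
#' tests. Values are returned at full precision; display uses 3
#' significant digits.
#'
#' @param n_tests number of tests (markers or haplotype alleles).
#' @return list with `genome_wide`, `suggestive`, `n_tests`.
#' @export
bonferroni_thresholds <- function(n_tests) {
  if (n_tests < 1) stopf("n_tests must be >= 1")
  structure(list(genome_wide = 0.05 / n_tests, suggestive = 1 / n_tests,
                 n_tests = as.integer(n_tests)),
            class = "bonf_thresholds")
}

#' @export
print.bonf_thresholds <- function(x, ...) {
  cat(sprintf("Bonferroni thresholds for %d tests: genome-wide %.3g, suggestive %.3g\n",
              x$n_tests, x$genome_wide, x$suggestive))
  invisible(x)
}

#' Genomic inflation factor
#'
#' Median method (default): lambda is the median of the 1-df chi-square
#' statistics implied by the p-values divided by the null median
#' (qchisq(0.5, 1) = 0.4549364). The regression method regresses sorted
#' observed statistics on their expected null quantiles through the
#' origin.
#'
#' @param pvalues vector of p-values (NAs dropped).
#' @param method `"median"` or `"regression"`.
#' @return lambda (scalar).
#' @export
genomic_lambda <- function(pvalues, method = c("median", "regression")) {
  method <- match.arg(method)
  p <- pvalues[!is.na(pvalues)]
  if (length(p) < 100L) {
    warnf("only %d tests: lambda estimate is unstable", length(p))
  }
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  if (method == "median") {
    stats::median(chi) / stats::qchisq(0.5, df = 1)
  } else {
    m <- length(p)
    expected <- stats::qchisq((seq_len(m) - 0.5) / m, df = 1,
                              lower.tail = FALSE)
    obs <- sort(chi, decreasing = TRUE)
    sum(expected * obs) / sum(expected^2)
  }
}
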