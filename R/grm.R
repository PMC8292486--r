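#' Centered genomic relationship matrix
#'
#' The default follows the printed formula verbatim:
#'
#'   G = (1/p) * sum_i (X_i - 1_n xbar_i)(X_i - 1_n xbar_i)'
#'
#' i.e. genotype columns are mean-centered, cross-multiplied and divided
#' by the marker count, with no per-marker variance scaling.
#' `method = "scaled"` instead divides the centered cross-product by
#' `sum(2 p_hat q_hat)` (the usual allele-frequency scaling), which gives
#' a mean diagonal near 1; this variant is what the synthetic-cohort
#' generator uses as its generative covariance.
#'
#' Missing dosages are mean-imputed per marker before centering.
#'
#' @param geno a [geno_matrix] or a bare n x p dosage matrix.
#' @param method `"centered"` (divide by p; the default) or `"scaled"`
#'   (divide by `sum(2 p q)`).
#' @return symmetric n x n matrix.
#' @export
grm_centered <- function(geno, method = c("centered", "scaled")) {
  method <- match.arg(method)
  X <- if (inherits(geno, "geno_matrix")) geno$dosage else as.matrix(geno)
  p <- ncol(X)
  if (p == 0L) stopf("no markers: cannot build a relationship matrix")
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  freq <- colMeans(X) / 2
  Xc <- sweep(X, 2L, 2 * freq, `-`)
  denom <- switch(method,
    centered = p,
    scaled = {
      s <- sum(2 * freq * (1 - freq))
      if (s <= 0) stopf("all markers monomorphic: scaled GRM undefined")
      s
    }
  )
  G <- tcrossprod(Xc) / denom
  (G + t(G)) / 2
}
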