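#' Round half away from zero
#'
#' Base `round()` rounds half to even; Mb display ranges in QTL tables use
#' conventional half-up rounding (18.145 -> 18.15), so it is done explicitly.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @keywords internal
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  # nudge by an ulp-scale epsilon so values stored just below .xx5 still round up
  floor(x * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Symmetric matrix square root via eigendecomposition
#'
#' Negative eigenvalues (numerical noise in rank-deficient relationship
#' matrices) are clipped at zero.
#'
#' @param K symmetric matrix.
#' @return matrix `S` with `S %*% S` approximately `K`.
#' @keywords internal
sym_sqrt <- function(K) {
  ee <- eigen(K, symmetric = TRUE)
  d <- pmax(ee$values, 0)
  ee$vectors %*% (sqrt(d) * t(ee$vectors))
}
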