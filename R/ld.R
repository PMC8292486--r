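# Two-locus linkage disequilibrium with D' confidence intervals.
#
# Block detection in the Gabriel style classifies marker pairs by a
# confidence interval on |D'|, obtained from the normalized likelihood
# profile of the data over D' in [0, 1] (the approach of the common
# Haploview/PLINK implementation): the haplotype-frequency likelihood is
# evaluated on a grid of D' values with the single-locus allele
# frequencies fixed at their sample estimates, normalized to a unit sum,
# and the central 90% interval (5% in each tail) is read off the
# cumulative profile.

.ld_grid <- seq(0, 1, length.out = 201L)

# profile log-likelihood over the D' grid given haplotype-class counts
# c11, c10, c01, c00 (phased chromosomes) OR a 3x3 genotype table
.ld_profile_ci <- function(pA, pB, d_sign, dmax, loglik_fun) {
  d_vals <- d_sign * .ld_grid * dmax
  ll <- vapply(d_vals, loglik_fun, numeric(1))
  ll <- ll - max(ll)
  lik <- exp(ll)
  cum <- cumsum(lik) / sum(lik)
  low <- .ld_grid[which(cum >= 0.05)[1]]
  high <- .ld_grid[which(cum >= 0.95)[1]]
  c(low = low, high = high)
}

#' Pairwise LD estimate with a D' confidence interval
#'
#' Haplotype frequencies are read directly from phase when strand data
#' are supplied, otherwise estimated by two-locus
#' expectation-maximization from the genotype table. D' is reported with
#' a 90% central confidence interval from the normalized likelihood
#' profile, plus the usual r-squared.
#'
#' @param a,b genotype dosage vectors (codes 0/1/2) for the two markers,
#'   or haplotype allele vectors (0/1 per chromosome) when
#'   `phased = TRUE`.
#' @param phased whether `a`, `b` are per-chromosome haplotype alleles.
#' @return list: `dprime`, `ci_low`, `ci_high`, `r2`, `informative`.
#' @export
ld_ci <- function(a, b, phased = FALSE) {
  if (phased) {
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    c11 <- sum(a == 1 & b == 1); c10 <- sum(a == 1 & b == 0)
    c01 <- sum(a == 0 & b == 1); c00 <- sum(a == 0 & b == 0)
    H <- length(a)
    pA <- (c11 + c10) / H
    pB <- (c11 + c01) / H
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
      return(list(dprime = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  r2 = NA_real_, informative = FALSE))
    }
    p11 <- c11 / H
    loglik_fun <- function(d) {
      h <- pmax(c(pA * pB + d, pA * (1 - pB) - d,
                  (1 - pA) * pB - d, (1 - pA) * (1 - pB) + d), 1e-12)
      c11 * log(h[1]) + c10 * log(h[2]) + c01 * log(h[3]) + c00 * log(h[4])
    }
  } else {
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    n <- length(a)
    pA <- mean(a) / 2
    pB <- mean(b) / 2
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
      return(list(dprime = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  r2 = NA_real_, informative = FALSE))
    }
    tab <- table(factor(a, 0:2), factor(b, 0:2))
    p11 <- .ld_em_p11(tab, pA, pB)
    loglik_fun <- function(d) .ld_geno_loglik(tab, pA, pB, d)
  }
  d <- p11 - pA * pB
  dmax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) {
    return(list(dprime = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                r2 = NA_real_, informative = FALSE))
  }
  dprime <- abs(d) / dmax
  ci <- .ld_profile_ci(pA, pB, sign(d) + (d == 0), dmax, loglik_fun)
  r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(dprime = dprime, ci_low = unname(ci["low"]),
       ci_high = unname(ci["high"]), r2 = r2, informative = TRUE)
}

# two-locus EM for the AB haplotype frequency from a 3x3 genotype table
.ld_em_p11 <- function(tab, pA, pB, max_iter = 100L, tol = 1e-10) {
  n <- sum(tab)
  p11 <- pA * pB
  for (it in seq_len(max_iter)) {
    p10 <- pA - p11; p01 <- pB - p11; p00 <- 1 - pA - pB + p11
    p10 <- max(p10, 1e-12); p01 <- max(p01, 1e-12)
    p00 <- max(p00, 1e-12); p11c <- max(p11, 1e-12)
    # expected AB count: unambiguous cells + split of the double
    # heterozygote between the cis and trans configurations
    dh <- tab[2, 2]
    cis <- p11c * p00 / (p11c * p00 + p10 * p01)
    nAB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + dh * cis
    p11_new <- nAB / (2 * n)
    if (abs(p11_new - p11) < tol) {
      p11 <- p11_new
      break
    }
    p11 <- p11_new
  }
  p11
}

# genotype-table log-likelihood at a fixed D (margins fixed)
.ld_geno_loglik <- function(tab, pA, pB, d) {
  h11 <- max(pA * pB + d, 1e-12)
  h10 <- max(pA * (1 - pB) - d, 1e-12)
  h01 <- max((1 - pA) * pB - d, 1e-12)
  h00 <- max((1 - pA) * (1 - pB) + d, 1e-12)
  # genotype-class probabilities from random union of gametes; the
  # double heterozygote mixes the cis and trans phases
  g <- matrix(0, 3, 3)
  g[1, 1] <- h00^2;        g[1, 2] <- 2 * h00 * h01; g[1, 3] <- h01^2
  g[2, 1] <- 2 * h00 * h10; g[2, 2] <- 2 * (h11 * h00 + h10 * h01)
  g[2, 3] <- 2 * h01 * h11
  g[3, 1] <- h10^2;        g[3, 2] <- 2 * h10 * h11; g[3, 3] <- h11^2
  sum(tab * log(pmax(g, 1e-300)))
}

# Vectorized phased-pair D' confidence intervals.
# S: chromosome x marker 0/1 strand matrix; pairs: 2-column index matrix.
# Returns a data.frame with dprime, ci_low, ci_high, r2, informative.
.ld_pairs_phased <- function(S, pairs, chunk = 20000L) {
  H <- nrow(S)
  cs <- colSums(S)
  np <- nrow(pairs)
  out_low <- out_high <- out_dp <- out_r2 <- rep(NA_real_, np)
  informative <- rep(FALSE, np)
  grid <- .ld_grid
  for (start in seq(1L, np, by = chunk)) {
    idx <- start:min(start + chunk - 1L, np)
    i <- pairs[idx, 1L]; j <- pairs[idx, 2L]
    c11 <- colSums(S[, i, drop = FALSE] * S[, j, drop = FALSE])
    c1dot <- cs[i]; cdot1 <- cs[j]
    c10 <- c1dot - c11
    c01 <- cdot1 - c11
    c00 <- H - c1dot - cdot1 + c11
    pA <- c1dot / H; pB <- cdot1 / H
    ok <- pA > 0 & pA < 1 & pB > 0 & pB < 1
    d <- c11 / H - pA * pB
    dmax <- ifelse(d >= 0, pmin(pA * (1 - pB), (1 - pA) * pB),
                   pmin(pA * pB, (1 - pA) * (1 - pB)))
    ok <- ok & dmax > 0
    informative[idx] <- ok
    if (!any(ok)) next
    sgn <- ifelse(d >= 0, 1, -1)
    # log-likelihood over the grid: matrix (pairs in chunk) x grid
    m <- sum(ok)
    dv <- (sgn[ok] * dmax[ok]) %o% grid
    h11 <- pmax(pA[ok] * pB[ok] + dv, 1e-12)
    h10 <- pmax(pA[ok] * (1 - pB[ok]) - dv, 1e-12)
    h01 <- pmax((1 - pA[ok]) * pB[ok] - dv, 1e-12)
    h00 <- pmax((1 - pA[ok]) * (1 - pB[ok]) + dv, 1e-12)
    ll <- c11[ok] * log(h11) + c10[ok] * log(h10) +
      c01[ok] * log(h01) + c00[ok] * log(h00)
    ll <- ll - apply(ll, 1L, max)
    lik <- exp(ll)
    cum <- t(apply(lik, 1L, cumsum)) / rowSums(lik)
    lo <- grid[max.col(cum >= 0.05, ties.method = "first")]
    hi <- grid[max.col(cum >= 0.95, ties.method = "first")]
    sel <- idx[ok]
    out_low[sel] <- lo
    out_high[sel] <- hi
    out_dp[sel] <- abs(d[ok]) / dmax[ok]
    out_r2[sel] <- d[ok]^2 /
      (pA[ok] * (1 - pA[ok]) * pB[ok] * (1 - pB[ok]))
  }
  data.frame(i = pairs[, 1L], j = pairs[, 2L], dprime = out_dp,
             ci_low = out_low, ci_high = out_high, r2 = out_r2,
             informative = informative)
}
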