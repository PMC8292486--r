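#' Fit the social genetic effects model by AI-REML
#'
#' Restricted maximum likelihood for
#' `y = Xb + Z_D a_D + Z_S a_S + W l + V g + e` with
#' `Var([a_D; a_S]) = C (x) K` (`C` the 2x2 direct/social genetic
#' (co)variance, `K` a relationship matrix), i.i.d. litter, pen and
#' residual terms. Updates are average-information Newton steps on the
#' variance parameters with step-halving into an EM-style fallback
#' whenever a step leaves the parameter space or decreases the restricted
#' likelihood, the standard AI-REML safeguard. Variances are floored at
#' `1e-10 * var(y)` and the genetic (co)variance is projected back onto
#' the PSD cone when an update overshoots.
#'
#' Convergence is declared when the largest relative parameter change
#' falls below `tol` (changes in parameters near zero are measured
#' against `0.001 * var(y)`) or the restricted log-likelihood stops
#' moving; the iteration cap is 200.
#'
#' Breeding values and their prediction-error variances come from the
#' mixed-model solution: `a_hat = G_a Z' P y` and
#' `PEV = diag(G_a - G_a Z' P Z G_a)`, algebraically the diagonal blocks
#' of the inverse mixed-model-equations coefficient matrix.
#'
#' @param design a [design_set] from [build_design()].
#' @param K relationship matrix over the records' individuals (genomic by
#'   default in this package's pipeline; a pedigree numerator matrix is
#'   equally valid). Bent by clipping negative eigenvalues when not PSD.
#' @param include_social,include_litter,include_group drop random terms
#'   from the model (the direct genetic and residual terms always stay).
#' @param fix_cov_zero constrain the direct-social genetic covariance to
#'   zero instead of estimating it.
#' @param max_iter,tol iteration cap and relative-change tolerance.
#' @param compute_ebv solve for EBVs and PEVs after convergence (skippable
#'   in replicate studies that only need variance components).
#' @param verbose print the parameter trajectory.
#' @return an object of class `social_model_fit`: `varcomps` (named
#'   vector sigma2_D, sigma2_S, sigma_DS, sigma2_litter, sigma2_group,
#'   sigma2_e), `fixed_effects`, `ebv_D`, `ebv_S`, `pev_D`, `pev_S`,
#'   `loglik`, `loglik_trace`, `converged`, `n_iter`, `ids`.
#' @export
reml_fit_social <- function(design, K, include_social = TRUE,
                            include_litter = TRUE, include_group = TRUE,
                            fix_cov_zero = FALSE, max_iter = 200L,
                            tol = 1e-8, compute_ebv = TRUE,
                            verbose = FALSE) {
  stopifnot(inherits(design, "design_set"))
  y <- design$y
  X <- design$X
  n <- length(y)
  if (n < ncol(X) + 10L) stopf("too few records for the fixed effects")
  if (!isTRUE(all.equal(dim(K), c(n, n)))) {
    stopf("K must be %d x %d to match the records", n, n)
  }
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(sum(ev), 1)) {
    ee <- eigen(K, symmetric = TRUE)
    K <- ee$vectors %*% (pmax(ee$values, 0) * t(ee$vectors))
    message(sprintf("bent K: clipped %d negative eigenvalues",
                    sum(ee$values < 0)))
  }

  KZDt <- K          # Z_D is the identity: K Z_D' = K
  KZSt <- K %*% t(design$Z_S)
  comps <- list(D = K)
  if (include_social) {
    comps$S <- design$Z_S %*% KZSt
    if (!fix_cov_zero) comps$DS <- t(KZSt) + KZSt
  }
  if (include_litter) comps$litter <- tcrossprod(design$W)
  if (include_group) comps$group <- tcrossprod(design$V)
  comps$e <- diag(n)
  nms <- names(comps)
  is_var <- nms != "DS"

  vp <- stats::var(y)
  if (vp <= 0) stopf("response has zero variance")
  floor_v <- 1e-10 * vp
  theta <- c(D = 0.2, S = 0.02, DS = 0, litter = 0.05, group = 0.05,
             e = 0.6)[nms] * vp

  project <- function(th) {
    th[is_var] <- pmax(th[is_var], floor_v)
    if ("DS" %in% nms) {
      lim <- 0.999 * sqrt(th["D"] * th["S"])
      th["DS"] <- sign(th["DS"]) * min(abs(th["DS"]), lim)
    }
    th
  }

  relik <- function(th) {
    Vm <- matrix(0, n, n)
    for (k in seq_along(comps)) Vm <- Vm + th[k] * comps[[k]]
    cV <- tryCatch(chol(Vm), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    Vinv <- chol2inv(cV)
    VX <- Vinv %*% X
    XtVX <- crossprod(X, VX)
    cXtVX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cXtVX)) {
      stopf("singular coefficient matrix: fixed effects (%s) confounded",
            paste(colnames(X), collapse = ", "))
    }
    P <- Vinv - VX %*% chol2inv(cXtVX) %*% t(VX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cXtVX))) +
                    sum(y * Py))
    list(ll = ll, Vinv = Vinv, P = P, Py = Py, XtVX = XtVX, VX = VX)
  }

  cur <- relik(theta)
  if (is.null(cur)) stopf("initial variance matrix not positive definite")
  ll_trace <- cur$ll
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    nk <- length(comps)
    Tm <- matrix(0, n, nk)
    score <- numeric(nk)
    for (k in seq_len(nk)) {
      tk <- comps[[k]] %*% cur$Py
      Tm[, k] <- tk
      score[k] <- -0.5 * (sum(cur$P * comps[[k]]) - sum(cur$Py * tk))
    }
    PT <- cur$P %*% Tm
    AI <- 0.5 * crossprod(Tm, PT)
    AI <- AI + diag(1e-10 * max(diag(AI)), nk)

    # active set: variances stuck at the floor with a downhill gradient
    # stay there, otherwise a clipped joint step stalls the others
    active <- !(is_var & theta <= floor_v * 1.01 & score < 0)
    if (!any(active)) {
      converged <- TRUE
      break
    }
    delta <- numeric(nk)
    delta[active] <- tryCatch(
      solve(AI[active, active, drop = FALSE], score[active]),
      error = function(e) score[active] * vp / n)

    # candidate steps, tried in order until one does not decrease the
    # restricted likelihood: full AI step, halved AI steps, then an
    # EM-REML step (guaranteed uphill for the variance parameters, with
    # a damped gradient move for the covariance)
    try_step <- function(cand) {
      cand <- project(cand)
      nxt <- relik(cand)
      if (!is.null(nxt) && is.finite(nxt$ll) &&
          nxt$ll >= cur$ll - 1e-12 * max(1, abs(cur$ll))) {
        list(cand = cand, nxt = nxt)
      } else NULL
    }
    got <- NULL
    step <- 1
    for (h in 1:10) {
      got <- try_step(theta + step * delta)
      if (!is.null(got)) break
      step <- step / 2
    }
    if (is.null(got)) {
      em <- theta
      for (k in seq_len(nk)) {
        if (is_var[k]) {
          # EM-REML: s2_new = s2 + s2^2/n * (y'P V_k P y - tr(P V_k))
          em[k] <- theta[k] +
            theta[k]^2 / n * (sum(cur$Py * Tm[, k]) -
                                sum(cur$P * comps[[k]]))
        } else {
          em[k] <- theta[k] + score[k] * theta["D"] * theta["S"] /
            max(vp^2, 1e-300) * vp / n
        }
      }
      for (h in 1:10) {
        got <- try_step(theta + (em - theta) / 2^(h - 1))
        if (!is.null(got)) break
      }
    }
    if (is.null(got)) {
      # no uphill step found: numerical local optimum
      converged <- TRUE
      break
    }
    cand <- got$cand
    nxt <- got$nxt
    rel <- max(abs(cand - theta) / pmax(abs(theta), 1e-3 * vp))
    ll_change <- abs(nxt$ll - cur$ll)
    theta <- cand
    cur <- nxt
    ll_trace <- c(ll_trace, cur$ll)
    if (verbose) {
      message(sprintf("iter %d  ll %.6f  %s", iter, cur$ll,
                      paste(sprintf("%s=%.4g", nms, theta), collapse = " ")))
    }
    if (rel < tol || ll_change < 1e-10 * max(1, abs(cur$ll))) {
      converged <- TRUE
      break
    }
  }

  vc <- c(sigma2_D = unname(theta["D"]),
          sigma2_S = if (include_social) unname(theta["S"]) else 0,
          sigma_DS = if (include_social && !fix_cov_zero)
            unname(theta["DS"]) else 0,
          sigma2_litter = if (include_litter) unname(theta["litter"]) else 0,
          sigma2_group = if (include_group) unname(theta["group"]) else 0,
          sigma2_e = unname(theta["e"]))

  b <- drop(solve(cur$XtVX, crossprod(cur$VX, y)))
  names(b) <- colnames(X)

  ebv_D <- ebv_S <- pev_D <- pev_S <- NULL
  if (compute_ebv) {
    if (include_social) {
      A <- rbind(vc["sigma2_D"] * KZDt + vc["sigma_DS"] * KZSt,
                 vc["sigma_DS"] * KZDt + vc["sigma2_S"] * KZSt)
      gdiag <- c(vc["sigma2_D"] * diag(K), vc["sigma2_S"] * diag(K))
    } else {
      A <- vc["sigma2_D"] * KZDt
      gdiag <- vc["sigma2_D"] * diag(K)
    }
    ahat <- drop(A %*% cur$Py)
    AP <- A %*% cur$P
    pev <- pmax(gdiag - rowSums(AP * A), 0)
    ebv_D <- ahat[seq_len(n)]
    pev_D <- pev[seq_len(n)]
    if (include_social) {
      ebv_S <- ahat[n + seq_len(n)]
      pev_S <- pev[n + seq_len(n)]
    }
  }

  structure(list(
    varcomps = vc, fixed_effects = b,
    ebv_D = ebv_D, ebv_S = ebv_S, pev_D = pev_D, pev_S = pev_S,
    loglik = cur$ll, loglik_trace = ll_trace,
    converged = converged, n_iter = iter, ids = design$ids
  ), class = "social_model_fit")
}

#' @export
print.social_model_fit <- function(x, ...) {
  cat("social genetic effects model (AI-REML)\n")
  cat(sprintf("  converged: %s after %d iterations, logL = %.4f\n",
              x$converged, x$n_iter, x$loglik))
  cat("  variance components:\n")
  for (nm in names(x$varcomps)) {
    cat(sprintf("    %-14s %.6g\n", nm, x$varcomps[nm]))
  }
  invisible(x)
}

#' EBV accuracy from prediction-error variance
#'
#' r = sqrt(1 - PEV / sigma2), with sigma2 the genetic variance of the
#' corresponding effect (direct or social). When PEV >= sigma2 the
#' accuracy is clamped to 0 and flagged in the `"clamped"` attribute.
#'
#' @param pev prediction-error variance(s), >= 0.
#' @param sigma2 the corresponding genetic variance, > 0.
#' @return numeric vector of accuracies in \[0, 1\] with a logical
#'   `"clamped"` attribute.
#' @export
accuracy_from_pev <- function(pev, sigma2) {
  if (any(sigma2 <= 0)) stopf("genetic variance must be > 0")
  if (any(pev < 0)) stopf("PEV must be >= 0")
  ratio <- pev / sigma2
  clamped <- ratio >= 1
  r <- sqrt(pmax(1 - ratio, 0))
  attr(r, "clamped") <- clamped
  r
}

#' Deregress EBVs
#'
#' dEBV = g / r^2. Records whose squared accuracy falls below
#' `r2_floor` are marked unusable (the deregression would blow up).
#'
#' @param ebv vector of EBVs.
#' @param r vector of accuracies in \[0, 1\].
#' @param r2_floor minimum usable squared accuracy.
#' @return data.frame with columns `ebv`, `accuracy`, `debv`, `usable`.
#' @export
deregress <- function(ebv, r, r2_floor = 0.01) {
  if (any(r < 0 | r > 1)) stopf("accuracies must lie in [0, 1]")
  usable <- r^2 >= r2_floor
  debv <- ifelse(usable, ebv / r^2, NA_real_)
  data.frame(ebv = ebv, accuracy = r, debv = debv, usable = usable)
}

#' Deregressed-EBV table for both effect types
#'
#' Applies [accuracy_from_pev()] and [deregress()] to the direct and
#' social EBVs of a fitted social model, with the effect-specific genetic
#' variance as the accuracy denominator.
#'
#' @param fit a `social_model_fit` with EBVs.
#' @param trait trait label for the output.
#' @param r2_floor passed to [deregress()].
#' @return data.frame keyed by `id`, `trait`, `effect` ("DGE"/"SGE") with
#'   `ebv`, `accuracy`, `debv`, `usable`.
#' @export
deregressed_ebv_table <- function(fit, trait = "y", r2_floor = 0.01) {
  stopifnot(inherits(fit, "social_model_fit"))
  if (is.null(fit$ebv_D)) stopf("fit carries no EBVs (compute_ebv = FALSE?)")
  rD <- accuracy_from_pev(fit$pev_D, fit$varcomps["sigma2_D"])
  out <- cbind(data.frame(id = fit$ids, trait = trait, effect = "DGE",
                          stringsAsFactors = FALSE),
               deregress(fit$ebv_D, as.numeric(rD), r2_floor))
  if (!is.null(fit$ebv_S) && fit$varcomps["sigma2_S"] > 0) {
    rS <- accuracy_from_pev(fit$pev_S, fit$varcomps["sigma2_S"])
    out <- rbind(out,
                 cbind(data.frame(id = fit$ids, trait = trait,
                                  effect = "SGE", stringsAsFactors = FALSE),
                       deregress(fit$ebv_S, as.numeric(rS), r2_floor)))
  }
  out
}
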