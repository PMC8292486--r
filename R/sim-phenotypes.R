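#' Simulate genetic effects, cohort structure and phenotypes
#'
#' Builds the generative counterpart of the social genetic effects model
#'
#'   y = Xb + Z_D a_D + Z_S a_S + W l + V g + e
#'
#' Direct (`a_D`) and social (`a_S`) breeding values are the sum of a
#' polygenic part, drawn as `K^{1/2} z` against the trace-normalised
#' genomic relationship matrix of the simulated markers, and a sparse QTL
#' part added on top; the totals are rescaled so their sample variances
#' hit `var_direct` and `var_social` exactly, and the polygenic draws are
#' correlated according to `cov_direct_social`. Each individual's
#' phenotype receives its own direct effect plus the sum of the social
#' effects of its pen mates (never its own), a litter effect, a pen
#' effect, small fixed-effect shifts (sex, test year-month by pen, birth
#' year-month by litter) and residual noise.
#'
#' Pens are filled sequentially with `group_size` animals; a final
#' incomplete pen is kept and its size recorded. Raw performance fields
#' (start/end weights, tested days, total feed intake, total feeder time,
#' backfat) are generated consistently with the phenotype so feeder-trait
#' derivation can be exercised end to end.
#'
#' @param geno a phased [geno_matrix] from [sim_genotypes()].
#' @param config the same [sim_config] used for the genotypes.
#' @return list with elements `cohort` (data.frame of per-individual
#'   metadata and raw performance fields), `traits` (data.frame `id`,
#'   `y`), and `truth` (a `sim_truth` list recording every generative
#'   component).
#' @export
sim_effects_and_phenotypes <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(geno$dosage)
  if (n != config$n_individuals) {
    stopf("genotype matrix has %d samples but config says %d",
          n, config$n_individuals)
  }
  C <- matrix(c(config$var_direct, config$cov_direct_social,
                config$cov_direct_social, config$var_social), 2, 2)
  if (det(C) < -1e-12 * max(1, C[1, 1] * C[2, 2]) || any(diag(C) < 0)) {
    stopf("genetic (co)variance matrix is not positive semidefinite")
  }
  set.seed(config$seed + 1L)

  # --- genetic effects -----------------------------------------------------
  K <- grm_centered(geno, method = "scaled")
  Ks <- sym_sqrt(K)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  rho <- if (config$var_direct > 0 && config$var_social > 0) {
    config$cov_direct_social / sqrt(config$var_direct * config$var_social)
  } else 0
  rho <- max(-1, min(1, rho))
  uD <- drop(Ks %*% z1)
  uS <- drop(Ks %*% (rho * z1 + sqrt(1 - rho^2) * z2))

  Xc <- scale(geno$dosage, center = TRUE, scale = FALSE)
  draw_qtl <- function(n_qtl) {
    if (n_qtl == 0L) {
      return(list(idx = integer(0), eff = numeric(0), part = numeric(n)))
    }
    idx <- sort(sample.int(ncol(Xc), min(n_qtl, ncol(Xc))))
    eff <- stats::rnorm(length(idx), 0, config$qtl_effect_sd)
    list(idx = idx, eff = eff, part = drop(Xc[, idx, drop = FALSE] %*% eff))
  }
  qD <- draw_qtl(config$n_qtl_direct)
  qS <- draw_qtl(config$n_qtl_social)

  rescale_to <- function(a, target_var) {
    if (target_var == 0) return(numeric(n))
    v <- stats::var(a)
    if (v < 1e-12) a <- stats::rnorm(n)  # degenerate panel: iid fallback
    a * sqrt(target_var / stats::var(a))
  }
  a_D <- rescale_to(uD + qD$part, config$var_direct)
  a_S <- rescale_to(uS + qS$part, config$var_social)

  # --- cohort structure ----------------------------------------------------
  # pens filled in a random order so litters spread across pens (litter
  # and pen would otherwise be confounded); last incomplete pen kept
  perm <- sample.int(n)
  pen <- integer(n)
  pen[perm] <- ceiling(seq_len(n) / config$group_size)
  n_pens <- max(pen)
  pen_sizes <- tabulate(pen, n_pens)
  litter <- attr(geno, "litter") %||%
    sample.int(config$n_litters, n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  test_ym <- sprintf("ty_%d", (pen - 1L) %% 4L + 1L)
  birth_ym <- sprintf("by_%d", (litter - 1L) %% 4L + 1L)

  sex_eff <- c(male = 0.10, female = -0.10)
  tym_eff <- stats::rnorm(4L, 0, 0.05)
  bym_eff <- stats::rnorm(4L, 0, 0.05)
  fixed_part <- sex_eff[sex] + tym_eff[(pen - 1L) %% 4L + 1L] +
    bym_eff[(litter - 1L) %% 4L + 1L]
  names(fixed_part) <- NULL

  l_eff <- stats::rnorm(config$n_litters, 0, sqrt(config$var_litter))
  g_eff <- stats::rnorm(n_pens, 0, sqrt(config$var_group))
  if (config$var_litter == 0) l_eff[] <- 0
  if (config$var_group == 0) g_eff[] <- 0
  e <- stats::rnorm(n, 0, sqrt(config$var_residual))
  if (config$var_residual == 0) e[] <- 0

  pen_sum_aS <- tapply(a_S, pen, sum)[as.character(pen)]
  social_sum <- as.numeric(pen_sum_aS) - a_S

  y <- fixed_part + a_D + social_sum + l_eff[litter] + g_eff[pen] + e

  # --- raw performance fields consistent with y ---------------------------
  tested_days <- sample(90:110, n, replace = TRUE)
  feed_days <- tested_days
  weight1 <- pmax(20, stats::rnorm(n, 30, 2))
  adg_true <- pmin(1.1, pmax(0.4, stats::rnorm(n, 0.74, 0.10)))
  weight2 <- weight1 + adg_true * tested_days
  y_std <- if (stats::sd(y) > 0) (y - mean(y)) / stats::sd(y) else y * 0
  adfi_target <- pmax(0.3, 1.87 + 0.34 * y_std)
  tfi <- adfi_target * feed_days
  tpd_target <- pmin(120, pmax(25, stats::rnorm(n, 64.5, 12)))
  total_time <- tpd_target * feed_days
  bft <- pmin(20, pmax(4, stats::rnorm(n, 9.3, 2.3)))

  cohort <- data.frame(
    id = geno$samples, sex = sex, litter = litter, pen = pen,
    pen_size = pen_sizes[pen], test_ym = test_ym, birth_ym = birth_ym,
    weight1 = weight1, weight2 = weight2, tested_days = tested_days,
    feed_days = feed_days, tfi = tfi, total_time = total_time, bft = bft,
    stringsAsFactors = FALSE
  )
  traits <- data.frame(id = geno$samples, y = y, stringsAsFactors = FALSE)
  truth <- structure(list(
    true_a_D = a_D, true_a_S = a_S,
    qtl_indices_direct = qD$idx, qtl_indices_social = qS$idx,
    qtl_effects_direct = qD$eff, qtl_effects_social = qS$eff,
    litter_effects = l_eff, group_effects = g_eff,
    fixed_part = fixed_part, residual = e,
    pen_sizes = pen_sizes, seed = config$seed
  ), class = "sim_truth")
  list(cohort = cohort, traits = traits, truth = truth)
}

#' Simulate raw feeder visit records
#'
#' Emulates electronic feeding-station records: each pig gets dated
#' feeder visits with a body weight following a linear gain trajectory
#' plus noise, and per-visit feed and feeder-time amounts drawn so their
#' totals reproduce the pig's total feed intake and total feeder time
#' exactly. Every pig receives at least two visits on distinct days (the
#' first and last test day are always visited) so the daily-gain
#' regression is defined.
#'
#' @param cohort cohort data.frame from [sim_effects_and_phenotypes()].
#' @param config the [sim_config] (its seed governs the visit draws).
#' @param visits_per_pig approximate number of visits simulated per pig.
#' @param bw_noise_sd kg standard deviation of visit body-weight noise.
#' @return data.frame with columns `id`, `day`, `bw`, `feed_kg`,
#'   `time_min`.
#' @export
sim_feeder_records <- function(cohort, config, visits_per_pig = 25L,
                               bw_noise_sd = 0.8) {
  set.seed(config$seed + 2L)
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    td <- cohort$tested_days[i]
    nv <- max(2L, min(as.integer(visits_per_pig), td + 1L))
    days <- sort(unique(c(0L, td,
                          sample.int(td - 1L, max(0L, nv - 2L)))))
    nv <- length(days)
    slope <- (cohort$weight2[i] - cohort$weight1[i]) / td
    bw <- cohort$weight1[i] + slope * days + stats::rnorm(nv, 0, bw_noise_sd)
    wf <- stats::rgamma(nv, shape = 5)
    feed <- cohort$tfi[i] * wf / sum(wf)
    wt <- stats::rgamma(nv, shape = 5)
    tim <- cohort$total_time[i] * wt / sum(wt)
    out[[i]] <- data.frame(id = cohort$id[i], day = days, bw = bw,
                           feed_kg = feed, time_min = tim,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
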