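# Replicate simulation studies. These are the package's standing
# verification experiments: parameter recovery for the social model,
# calibration and power of the association scan, and haplotype-locus
# power. Both the test suite and scripts/acceptance.R run them, so their
# designs live here rather than being re-assembled ad hoc.

#' Social-model parameter recovery study
#'
#' Replicates the default desk cohort (n = 600, pens of 10, variance
#' components 0.30/0.03/0/0.05/0.05/0.57), fits the social model by
#' AI-REML with the trace-normalised genomic relationship matrix, and
#' summarises the estimates.
#'
#' @param n_reps number of replicates.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return list: `est` (matrix of variance-component estimates, one
#'   column per replicate), `median_D`, `median_S`, `sd_S`,
#'   `n_converged`.
#' @export
study_reml_recovery <- function(n_reps = 20, seed = 500) {
  est <- vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(seed = seed + r)
    g <- sim_genotypes(cfg)
    sim <- sim_effects_and_phenotypes(g, cfg)
    K <- grm_centered(g, method = "scaled")
    fit <- reml_fit_social(build_design(sim$cohort, sim$traits), K,
                           compute_ebv = FALSE)
    c(fit$varcomps, converged = as.numeric(fit$converged))
  }, numeric(7))
  list(est = est,
       median_D = stats::median(est["sigma2_D", ]),
       median_S = stats::median(est["sigma2_S", ]),
       sd_S = stats::sd(est["sigma2_S", ]),
       n_converged = sum(est["converged", ]))
}

#' Null-social recovery study
#'
#' Replicates a cohort simulated with zero social genetic variance
#' (n = 400, pens of 8) and reports the estimated social variance
#' relative to the phenotypic variance.
#'
#' @inheritParams study_reml_recovery
#' @return list: `median_S`, `median_vp`, `est`.
#' @export
study_reml_null_social <- function(n_reps = 20, seed = 600) {
  est <- vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(n_individuals = 400, group_size = 8,
                      n_snps = 2000, n_ld_blocks = 200, n_litters = 40,
                      var_social = 0, seed = seed + r)
    g <- sim_genotypes(cfg)
    sim <- sim_effects_and_phenotypes(g, cfg)
    K <- grm_centered(g, method = "scaled")
    fit <- reml_fit_social(build_design(sim$cohort, sim$traits), K,
                           compute_ebv = FALSE)
    c(S = unname(fit$varcomps["sigma2_S"]), vp = stats::var(sim$traits$y))
  }, numeric(2))
  list(median_S = stats::median(est["S", ]),
       median_vp = stats::median(est["vp", ]), est = est)
}

#' Type-I error and inflation calibration of the association scan
#'
#' Simulates a null response (polygenic plus residual, no marker effect)
#' over 2,000 unlinked markers at n = 400 and reports the empirical
#' rejection rate at alpha = 0.05 together with the genomic inflation
#' factor.
#'
#' @param seed seed for the panel and response draws.
#' @return list: `rejection_rate`, `n_tests`, `lambda`, and the exact
#'   binomial 95% bounds `ci_low`, `ci_high` for a calibrated test.
#' @export
study_mlm_calibration <- function(seed = 900) {
  cfg <- sim_config(n_individuals = 400, n_snps = 2000,
                    n_ld_blocks = 2000, n_litters = 40, seed = seed)
  g <- sim_genotypes(cfg)
  G <- grm_centered(g)
  set.seed(seed + 1L)
  ee <- eigen(G / mean(diag(G)), symmetric = TRUE)
  y <- sqrt(0.5) * drop(ee$vectors %*% (sqrt(pmax(ee$values, 0)) *
                                          stats::rnorm(400))) +
    stats::rnorm(400, 0, sqrt(0.5))
  assoc <- wald_scan(g, fit_mlm_null(y, G))
  m <- sum(!is.na(assoc$p))
  rate <- mean(assoc$p < 0.05, na.rm = TRUE)
  list(rejection_rate = rate, n_tests = m,
       lambda = genomic_lambda(assoc$p),
       ci_low = stats::qbinom(0.025, m, 0.05) / m,
       ci_high = stats::qbinom(0.975, m, 0.05) / m)
}

#' Power study: planted causal SNP
#'
#' Each replicate simulates n = 600 animals (litters of two, so family
#' confounding is minimal), plants one common SNP explaining 5% of the
#' response variance on a polygenic background (25% polygenic, 70%
#' residual), and tests it in the mixed model with a
#' leave-one-chromosome-out GRM — the standard guard against the
#' polygenic term absorbing the tested locus. Detection means
#' `p < 1/3000`, the suggestive threshold for a 3,000-test scan.
#'
#' @inheritParams study_reml_recovery
#' @return list: `n_detected`, `n_reps`, `pvalues`.
#' @export
study_power_snp <- function(n_reps = 20, seed = 1000) {
  ps <- vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(n_individuals = 600, n_snps = 500,
                      n_ld_blocks = 100, n_litters = 300,
                      seed = seed + r)
    g <- sim_genotypes(cfg)
    set.seed(seed + 1000L + r)
    j <- which(geno_maf(g) > 0.2)[1]
    x <- g$dosage[, j]
    b <- sqrt(0.05 / (0.95 * stats::var(x)))
    K <- grm_centered(g, method = "scaled")
    ee <- eigen(K, symmetric = TRUE)
    eta <- sqrt(0.25) * drop(ee$vectors %*% (sqrt(pmax(ee$values, 0)) *
                                               stats::rnorm(600))) +
      stats::rnorm(600, 0, sqrt(0.70))
    y <- b * x + eta
    loco <- grm_centered(geno_subset(g, markers =
                                       which(g$map$chr != g$map$chr[j])))
    wald_scan(g$dosage[, j, drop = FALSE], fit_mlm_null(y, loco))$p
  }, numeric(1))
  list(n_detected = sum(ps < 1 / 3000, na.rm = TRUE), n_reps = n_reps,
       pvalues = ps)
}

#' Power study: planted causal haplotype allele
#'
#' Each replicate plants a 3-SNP haplotype locus whose rare allele
#' (frequency 0.05) shifts the response by 0.5 residual standard
#' deviations at n = 600, runs block detection and the haplotype scan
#' over a 20-block desk panel, and checks whether any allele of the
#' causal locus beats the scan's suggestive threshold (1 over the number
#' of alleles tested). The GRM excludes the causal chromosome.
#'
#' @inheritParams study_reml_recovery
#' @return list: `n_detected`, `n_reps`, `details` (per replicate:
#'   minimum causal-block p, threshold).
#' @export
study_power_hap <- function(n_reps = 20, seed = 3000) {
  details <- vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(n_individuals = 600, n_snps = 60, n_ld_blocks = 20,
                      n_litters = 300, seed = seed + r)
    g <- sim_genotypes(cfg)
    set.seed(seed + 1000L + r)
    cols <- which(g$map$block == 10L)[1:3]
    lab <- sample(1:3, 1200, replace = TRUE, prob = c(0.05, 0.55, 0.40))
    pat <- rbind(c(1L, 1L, 1L), c(0L, 0L, 0L), c(1L, 0L, 0L))
    hap <- pat[lab, ]
    g$strand1[, cols] <- hap[seq_len(600), ]
    g$strand2[, cols] <- hap[600 + seq_len(600), ]
    g$dosage[, cols] <- g$strand1[, cols] + g$strand2[, cols]
    causal <- (rowSums(g$strand1[, cols]) == 3) +
      (rowSums(g$strand2[, cols]) == 3)
    y <- 0.5 * causal + stats::rnorm(600)
    cchr <- g$map$chr[cols[1]]
    loco <- grm_centered(geno_subset(g, markers =
                                       which(g$map$chr != cchr)))
    hg <- hap_gwas(gabriel_blocks(g), g, fit_mlm_null(y, loco))
    near <- hg$assoc$chr == cchr &
      hg$assoc$pos >= g$map$pos[cols[1]] - 1000 &
      hg$assoc$pos <= g$map$pos[cols[3]]
    in_causal <- hg$assoc$block %in% unique(hg$assoc$block[near])
    pmin <- suppressWarnings(min(hg$assoc$p[in_causal], na.rm = TRUE))
    c(pmin = pmin, threshold = 1 / hg$n_tests)
  }, numeric(2))
  list(n_detected = sum(is.finite(details["pmin", ]) &
                          details["pmin", ] < details["threshold", ]),
       n_reps = n_reps, details = details)
}
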