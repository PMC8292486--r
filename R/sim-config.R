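#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic study: cohort and marker panel
#' sizes, LD-block structure, pen (group) and litter structure, the
#' generative variance components of the social genetic model, and QTL
#' placement. Defaults describe the desk-scale study conditions: 600
#' group-housed animals in pens of 10, a 3,000-SNP LD-blocked panel, a
#' direct genetic variance of 0.30 and a social genetic variance of 0.03
#' on a unit-phenotypic-variance scale, litter and pen variances of 0.05
#' each and a residual of 0.57. The commercial test station the model
#' emulates houses 20 pigs per pen; `group_size = 20` reproduces that
#' layout at full scale.
#'
#' @param n_individuals cohort size.
#' @param n_snps number of biallelic markers.
#' @param n_ld_blocks number of LD blocks the panel is divided into;
#'   markers within a block descend from a small founder haplotype pool,
#'   which is what induces within-block LD.
#' @param founder_haplotypes_per_block size of the founder pool per block
#'   (1 fixes the block: every animal homozygous and identical).
#' @param maf_min lower bound of the allele-frequency draw, in (0, 0.5].
#' @param group_size pen size (20 at full scale; desk default 10).
#' @param n_litters number of litters, assigned at random.
#' @param var_direct direct genetic variance (sigma2_D).
#' @param var_social social genetic variance (sigma2_S).
#' @param cov_direct_social direct-social genetic covariance (sigma_DS).
#' @param var_litter,var_group,var_residual litter, pen and residual
#'   variances.
#' @param n_qtl_direct,n_qtl_social number of QTL with direct / social
#'   effects layered on top of the polygenic background.
#' @param qtl_effect_sd standard deviation of per-QTL allele effects.
#' @param seed integer seed; every draw in the generator descends from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 600, n_snps = 3000, n_ld_blocks = 300,
                       founder_haplotypes_per_block = 8, maf_min = 0.05,
                       group_size = 10, n_litters = 60,
                       var_direct = 0.30, var_social = 0.03,
                       cov_direct_social = 0,
                       var_litter = 0.05, var_group = 0.05,
                       var_residual = 0.57,
                       n_qtl_direct = 5, n_qtl_social = 5,
                       qtl_effect_sd = 0.1, seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    n_ld_blocks = as.integer(n_ld_blocks),
    founder_haplotypes_per_block = as.integer(founder_haplotypes_per_block),
    maf_min = maf_min, group_size = as.integer(group_size),
    n_litters = as.integer(n_litters),
    var_direct = var_direct, var_social = var_social,
    cov_direct_social = cov_direct_social,
    var_litter = var_litter, var_group = var_group,
    var_residual = var_residual,
    n_qtl_direct = as.integer(n_qtl_direct),
    n_qtl_social = as.integer(n_qtl_social),
    qtl_effect_sd = qtl_effect_sd, seed = as.integer(seed)
  )
  counts <- c("n_individuals", "n_snps", "n_ld_blocks", "n_litters")
  for (nm in counts) {
    if (cfg[[nm]] < 1L) stopf("%s must be a positive count", nm)
  }
  if (cfg$group_size < 1L) stopf("group_size must be >= 1")
  if (cfg$founder_haplotypes_per_block < 1L) {
    stopf("founder_haplotypes_per_block must be >= 1")
  }
  if (!(cfg$maf_min > 0 && cfg$maf_min <= 0.5)) {
    stopf("maf_min must lie in (0, 0.5]")
  }
  vars <- c("var_direct", "var_social", "var_litter", "var_group",
            "var_residual")
  for (nm in vars) {
    if (cfg[[nm]] < 0) stopf("%s must be >= 0", nm)
  }
  C <- matrix(c(cfg$var_direct, cfg$cov_direct_social,
                cfg$cov_direct_social, cfg$var_social), 2, 2)
  if (det(C) < -1e-12 * max(1, cfg$var_direct * cfg$var_social)) {
    stopf("genetic (co)variance matrix [[%g, %g], [%g, %g]] is not PSD",
          C[1, 1], C[1, 2], C[2, 1], C[2, 2])
  }
  if (cfg$n_qtl_direct < 0L || cfg$n_qtl_social < 0L) {
    stopf("QTL counts must be >= 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: n=%d, %d SNPs in %d LD blocks (founder pool %d), ",
    "pens of %d, %d litters\n",
    "  varcomps D=%g S=%g DS=%g litter=%g pen=%g resid=%g; ",
    "QTL %d direct / %d social (sd %g); seed %d\n"),
    x$n_individuals, x$n_snps, x$n_ld_blocks,
    x$founder_haplotypes_per_block, x$group_size, x$n_litters,
    x$var_direct, x$var_social, x$cov_direct_social, x$var_litter,
    x$var_group, x$var_residual, x$n_qtl_direct, x$n_qtl_social,
    x$qtl_effect_sd, x$seed))
  invisible(x)
}
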