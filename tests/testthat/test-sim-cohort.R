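test_that("genotype simulation is seed-deterministic and phase-consistent", {
  cfg <- sim_config(n_individuals = 60, n_snps = 120, n_ld_blocks = 12,
                    n_litters = 12, seed = 7)
  g1 <- sim_genotypes(cfg)
  g2 <- sim_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$strand1, g2$strand1)
  expect_identical(g1$map, g2$map)
  # phase consistency at every cell
  expect_true(all(g1$strand1 + g1$strand2 == g1$dosage))
  # positions strictly increasing per chromosome
  for (ch in unique(g1$map$chr)) {
    expect_true(all(diff(g1$map$pos[g1$map$chr == ch]) > 0))
  }
})

test_that("a single founder haplotype fixes every block", {
  cfg <- sim_config(n_individuals = 40, n_snps = 60, n_ld_blocks = 6,
                    founder_haplotypes_per_block = 1, n_litters = 8,
                    seed = 3)
  g <- sim_genotypes(cfg)
  # all individuals homozygous and identical within each block
  expect_true(all(g$dosage %in% c(0, 2)))
  expect_true(all(apply(g$dosage, 2, function(x) length(unique(x)) == 1)))
})

test_that("within-block LD exceeds between-block LD", {
  cfg <- sim_config(n_individuals = 2000, n_snps = 60, n_ld_blocks = 6,
                    founder_haplotypes_per_block = 6, n_litters = 200,
                    seed = 5)
  g <- sim_genotypes(cfg)
  poly <- which(geno_maf(g) > 0.01)
  r2 <- cor(g$dosage[, poly])^2
  blk <- g$map$block[poly]
  same <- outer(blk, blk, `==`) & upper.tri(r2)
  diff_blk <- !outer(blk, blk, `==`) & upper.tri(r2)
  expect_gt(mean(r2[same]), mean(r2[diff_blk]))
  expect_gt(mean(r2[same]), 0.2)
})

test_that("pen assignment partitions the cohort and the last pen may be short", {
  s <- small_sim(seed = 21, n = 57, group_size = 10, litters = 10)
  pens <- table(s$cohort$pen)
  expect_equal(sum(pens), 57)
  expect_equal(sort(unique(as.integer(pens)), decreasing = TRUE)[1], 10L)
  expect_true(7L %in% as.integer(pens))   # 57 = 5*10 + 7
  expect_equal(unname(s$truth$pen_sizes[s$cohort$pen]), s$cohort$pen_size)
})

test_that("phenotypes decompose exactly into their generative components", {
  s <- small_sim(seed = 31)
  tr <- s$truth
  pen <- s$cohort$pen
  pen_sum <- tapply(tr$true_a_S, pen, sum)[as.character(pen)]
  social <- as.numeric(pen_sum) - tr$true_a_S
  recon <- tr$fixed_part + tr$true_a_D + social +
    tr$litter_effects[s$cohort$litter] + tr$group_effects[pen] +
    tr$residual
  expect_equal(s$traits$y, recon, tolerance = 1e-12)
})

test_that("zero variance components collapse the model to fixed + residual", {
  cfg <- sim_config(n_individuals = 80, n_snps = 60, n_ld_blocks = 6,
                    n_litters = 10, var_direct = 0, var_social = 0,
                    cov_direct_social = 0, var_litter = 0, var_group = 0,
                    seed = 9)
  g <- sim_genotypes(cfg)
  sim <- sim_effects_and_phenotypes(g, cfg)
  expect_equal(sim$traits$y,
               sim$truth$fixed_part + sim$truth$residual,
               tolerance = 1e-12)
  expect_true(all(sim$truth$true_a_D == 0))
  expect_true(all(sim$truth$true_a_S == 0))
})

test_that("non-PSD genetic covariance is rejected", {
  expect_error(sim_config(var_direct = 0.1, var_social = 0.1,
                          cov_direct_social = 0.2), "PSD")
})

test_that("realized phenotypic variance matches the analytic decomposition", {
  # Var(y) = s2_D + (g-1) s2_S + s2_litter + s2_group + s2_e plus a
  # small fixed-effect contribution; random penning makes the
  # direct-social cross terms vanish in expectation
  reps <- 10
  vs <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_individuals = 500, n_snps = 100, n_ld_blocks = 10,
                      group_size = 10, n_litters = 50, seed = 1000 + r)
    g <- sim_genotypes(cfg)
    sim <- sim_effects_and_phenotypes(g, cfg)
    vs[r] <- var(sim$traits$y)
  }
  analytic <- 0.30 + 9 * 0.03 + 0.05 + 0.05 + 0.57
  expect_lt(abs(mean(vs) - analytic) / analytic, 0.10)
})

test_that("realized genetic variance tracks its target across seeds", {
  ratios <- vapply(1:50, function(s) {
    cfg <- sim_config(n_individuals = 250, n_snps = 80, n_ld_blocks = 8,
                      n_litters = 25, seed = 2000 + s)
    g <- sim_genotypes(cfg)
    sim <- sim_effects_and_phenotypes(g, cfg)
    var(sim$truth$true_a_D) / 0.30
  }, numeric(1))
  expect_true(all(ratios > 0.8 & ratios < 1.2))
})

test_that("feeder records reproduce targets and support the gain regression", {
  s <- small_sim(seed = 41, n = 40, group_size = 8, litters = 8)
  v1 <- sim_feeder_records(s$cohort, s$cfg)
  v2 <- sim_feeder_records(s$cohort, s$cfg)
  expect_identical(v1, v2)                      # seeded determinism
  by_pig <- split(v1, v1$id)
  expect_true(all(vapply(by_pig, function(d) length(unique(d$day)) >= 2,
                         logical(1))))
  adfi_rec <- vapply(by_pig, function(d) sum(d$feed_kg), numeric(1))
  target <- s$cohort$tfi[match(names(by_pig), s$cohort$id)]
  expect_lt(max(abs(adfi_rec - target)), 1e-9)
  tpd_rec <- vapply(by_pig, function(d) sum(d$time_min), numeric(1))
  expect_lt(max(abs(tpd_rec -
                      s$cohort$total_time[match(names(by_pig),
                                                s$cohort$id)])), 1e-9)
})

test_that("cohort writers round-trip through the standard formats", {
  s <- small_sim(seed = 51, n = 30, p = 60, blocks = 6, litters = 6)
  v <- sim_feeder_records(s$cohort, s$cfg)
  dir <- withr::local_tempdir()
  paths <- write_sim_cohort(s$geno, s$cohort, v, s$cfg, dir)
  expect_true(all(file.exists(paste0(paths$plink, c(".bed", ".bim", ".fam")))))
  expect_true(file.exists(paths$vcf))
  back <- read_vcf(paths$vcf, require_phase = TRUE)
  expect_equal(unname(back$dosage), unname(s$geno$dosage),
               ignore_attr = TRUE)
  man <- jsonlite::read_json(paths$manifest, simplifyVector = TRUE)
  expect_equal(man$seed, s$cfg$seed)
})
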