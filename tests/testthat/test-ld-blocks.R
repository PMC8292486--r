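# stable data.frame form of a block list for identity checks
write_blocks_df <- function(blocks) {
  data.frame(
    chr = vapply(blocks, function(b) as.character(b$chr), character(1)),
    start = vapply(blocks, function(b) b$start, numeric(1)),
    end = vapply(blocks, function(b) b$end, numeric(1)),
    snps = vapply(blocks, function(b) paste(b$snps, collapse = ","),
                  character(1))
  )
}

test_that("complete disequilibrium and independence give D' = 1 and 0", {
  set.seed(19)
  h <- rbinom(400, 1, 0.35)
  perfect <- ld_ci(h, h, phased = TRUE)
  expect_equal(perfect$dprime, 1)
  expect_equal(perfect$r2, 1)
  expect_gt(perfect$ci_low, 0.9)
  # haplotype counts exactly at the product of the margins
  a <- rep(c(1, 1, 0, 0), each = 100)
  b <- rep(c(1, 0, 1, 0), each = 100)
  indep <- ld_ci(a, b, phased = TRUE)
  expect_equal(indep$dprime, 0)
  expect_equal(indep$r2, 0)
  # monomorphic marker is uninformative
  expect_false(ld_ci(rep(1, 400), h, phased = TRUE)$informative)
})

test_that("EM haplotype frequencies match exhaustive maximum likelihood", {
  hp <- draw_hap_pair(40, c(0.45, 0.15, 0.1, 0.3), seed = 23)
  g_a <- hp$a[1:20] + hp$a[21:40]
  g_b <- hp$b[1:20] + hp$b[21:40]
  pA <- mean(g_a) / 2; pB <- mean(g_b) / 2
  tab <- table(factor(g_a, 0:2), factor(g_b, 0:2))
  # independent grid/optimize oracle over the admissible p11 range
  geno_ll <- function(p11) {
    h11 <- p11; h10 <- pA - p11; h01 <- pB - p11
    h00 <- 1 - pA - pB + p11
    if (min(h11, h10, h01, h00) < 0) return(-Inf)
    pr <- matrix(0, 3, 3)
    pr[1, 1] <- h00^2; pr[1, 2] <- 2 * h00 * h01; pr[1, 3] <- h01^2
    pr[2, 1] <- 2 * h00 * h10
    pr[2, 2] <- 2 * (h11 * h00 + h10 * h01)
    pr[2, 3] <- 2 * h01 * h11
    pr[3, 1] <- h10^2; pr[3, 2] <- 2 * h10 * h11; pr[3, 3] <- h11^2
    sum(tab * log(pmax(pr, 1e-300)))
  }
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  opt <- optimize(geno_ll, c(lo, hi), maximum = TRUE, tol = 1e-10)
  p11_em <- sgegwas:::.ld_em_p11(tab, pA, pB)
  expect_equal(p11_em, opt$maximum, tolerance = 1e-6)
  # D' from the EM path equals the value implied by the ML frequency
  d_ml <- opt$maximum - pA * pB
  dmax <- if (d_ml >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  e_em <- ld_ci(g_a, g_b, phased = FALSE)
  expect_equal(e_em$dprime, abs(d_ml) / dmax, tolerance = 1e-4)
})

test_that("Gabriel blocks respect the span caps and SNP minimum", {
  # two markers 2,000 kb apart can never share a block
  set.seed(31)
  h <- rbinom(200, 1, 0.5)
  strand1 <- cbind(h[1:100], h[1:100])
  strand2 <- cbind(h[101:200], h[101:200])
  map <- data.frame(id = c("a", "b"), chr = 1L,
                    pos = c(1L, 2000001L), a1 = "A", a2 = "G",
                    stringsAsFactors = FALSE)
  g <- geno_matrix(strand1 + strand2, map, strand1 = strand1,
                   strand2 = strand2)
  expect_length(gabriel_blocks(g), 0)
  # a single qualifying SNP cannot form a block
  g1 <- geno_subset(g, markers = 1)
  expect_length(gabriel_blocks(g1), 0)
})

test_that("planted perfect-LD run is recovered exactly as by brute force", {
  g <- planted_ld_panel(n = 200, seed = 11)
  blocks <- gabriel_blocks(g)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$snps, 2:4)
  oracle <- brute_force_blocks(g)
  expect_length(oracle, 1)
  expect_equal(unname(oracle[[1]]), c(2, 4))
  # determinism and partition invariants
  blocks2 <- gabriel_blocks(g)
  expect_identical(write_blocks_df(blocks), write_blocks_df(blocks2))
})

test_that("a fully concordant span becomes one maximal block", {
  set.seed(37)
  H <- 400
  core <- rbinom(H, 1, 0.45)
  s <- matrix(core, H, 5)
  map <- data.frame(id = paste0("s", 1:5), chr = 2L,
                    pos = c(100L, 700L, 1500L, 2500L, 4000L),
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  g <- geno_matrix(s[1:200, ] + s[201:400, ], map,
                   strand1 = s[1:200, ], strand2 = s[201:400, ])
  blocks <- gabriel_blocks(g)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$snps, 1:5)
})

test_that("blocks on one chromosome never overlap", {
  cfg <- sim_config(n_individuals = 300, n_snps = 120, n_ld_blocks = 12,
                    founder_haplotypes_per_block = 4, n_litters = 50,
                    seed = 43)
  g <- sim_genotypes(cfg)
  blocks <- gabriel_blocks(g)
  expect_gt(length(blocks), 0)
  for (ch in unique(vapply(blocks, function(b) b$chr, numeric(1)))) {
    bs <- Filter(function(b) b$chr == ch, blocks)
    idx <- lapply(bs, function(b) b$snps)
    expect_equal(anyDuplicated(unlist(idx)), 0)
    expect_true(all(vapply(idx, function(i) all(diff(i) > 0), logical(1))))
  }
})

test_that("haplotype dosages count matching strands and sum to two", {
  # 4-individual hand fixture over a 3-SNP block
  strand1 <- rbind(c(1, 1, 1), c(0, 0, 0), c(1, 1, 1), c(1, 0, 1))
  strand2 <- rbind(c(1, 1, 1), c(1, 1, 1), c(0, 0, 0), c(1, 0, 1))
  map <- data.frame(id = paste0("s", 1:3), chr = 1L,
                    pos = c(100L, 200L, 300L),
                    a1 = "G", a2 = "A", stringsAsFactors = FALSE)
  g <- geno_matrix(strand1 + strand2, map, strand1 = strand1,
                   strand2 = strand2)
  blk <- structure(list(chr = 1L, start = 100L, end = 300L, snps = 1:3,
                        snp_ids = map$id), class = "haplotype_block")
  hd <- hap_allele_dosage(g, blk, allele_freq_min = 0)
  # hand tally: GGG x2, AAA+GGG, GGG+AAA, GAG x2
  expect_equal(sort(hd$alleles$allele), sort(c("GGG", "AAA", "GAG")))
  expect_equal(hd$alleles$freq[hd$alleles$allele == "GGG"], 4 / 8)
  expect_equal(unname(hd$dosage[1, "GGG"]), 2)   # both haplotypes GGG
  expect_equal(unname(hd$dosage[1, "AAA"]), 0)
  expect_equal(unname(hd$dosage[4, "GAG"]), 2)
  expect_equal(unname(rowSums(hd$dosage)), rep(2, 4))
  expect_equal(sum(hd$alleles$freq), 1)
  # frequency filter drops rare alleles from testing but not counting
  hd2 <- hap_allele_dosage(g, blk, allele_freq_min = 0.3)
  expect_equal(colnames(hd2$dosage), "GGG")
  expect_equal(sum(hd2$alleles$freq), 1)
  # unphased input is refused
  g_un <- geno_matrix(strand1 + strand2, map)
  expect_error(hap_allele_dosage(g_un, blk), "phase")
})

test_that("an allele matching a causal SNP reproduces its p-value", {
  g <- planted_ld_panel(n = 150, seed = 53)
  set.seed(54)
  y <- 0.6 * g$dosage[, 3] + rnorm(150)
  null <- fit_mlm_null(y, matrix(0, 150, 150))
  snp_p <- wald_scan(g$dosage[, 3, drop = FALSE], null)$p
  blocks <- gabriel_blocks(g)
  hg <- hap_gwas(blocks, g, null, allele_freq_min = 0)
  # the core alleles are copies of the causal dosage (or its mirror)
  expect_equal(min(hg$assoc$p, na.rm = TRUE), snp_p, tolerance = 1e-9)
  expect_equal(hg$n_tests, nrow(hg$assoc))
})
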