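# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no binary fixtures are stored.

# small default simulation used by several module tests
small_sim <- function(seed = 101, n = 120, p = 240, blocks = 24,
                      group_size = 6, litters = 20, ...) {
  cfg <- sim_config(n_individuals = n, n_snps = p, n_ld_blocks = blocks,
                    group_size = group_size, n_litters = litters,
                    seed = seed, ...)
  geno <- sim_genotypes(cfg)
  sim <- sim_effects_and_phenotypes(geno, cfg)
  list(cfg = cfg, geno = geno, cohort = sim$cohort, traits = sim$traits,
       truth = sim$truth)
}

# phased two-marker panel with haplotypes drawn from given frequencies
# (hAB, hAb, haB, hab); returns per-chromosome allele vectors
draw_hap_pair <- function(n_chrom, freqs, seed = 1) {
  set.seed(seed)
  stopifnot(length(freqs) == 4, abs(sum(freqs) - 1) < 1e-9)
  idx <- sample.int(4L, n_chrom, replace = TRUE, prob = freqs)
  # haplotype order: AB, Ab, aB, ab with allele "1" = A/B
  list(a = as.integer(idx %in% c(1L, 2L)),
       b = as.integer(idx %in% c(1L, 3L)))
}

# 6-SNP panel with a planted 3-SNP perfect-LD run (SNPs 2-4) flanked by
# independent markers; returns a phased geno_matrix
planted_ld_panel <- function(n = 200, seed = 11) {
  set.seed(seed)
  H <- 2L * n
  core <- rbinom(H, 1L, 0.4)           # shared strand for the LD run
  s <- cbind(rbinom(H, 1L, 0.5), core, core, core,
             rbinom(H, 1L, 0.5), rbinom(H, 1L, 0.5))
  strand1 <- s[seq_len(n), ]
  strand2 <- s[n + seq_len(n), ]
  map <- data.frame(id = paste0("s", 1:6), chr = 1L,
                    pos = c(1000L, 5000L, 6000L, 7000L, 60000L, 90000L),
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  geno_matrix(strand1 + strand2, map, strand1 = strand1,
              strand2 = strand2)
}

# brute-force Gabriel block finder: evaluates every contiguous span with
# the same pair rules; independent of the summed-area-table code path
brute_force_blocks <- function(geno, strong_low_ci = 0.8,
                               strong_high_ci = 0.98,
                               recomb_high_ci = 0.90,
                               strong_fraction = 0.95, max_kb = 1000) {
  m <- ncol(geno$dosage)
  pos <- geno$map$pos
  ha <- rbind(geno$strand1, geno$strand2)
  classify <- function(i, j) {
    e <- ld_ci(ha[, i], ha[, j], phased = TRUE)
    if (!e$informative) return("none")
    if (e$ci_low >= strong_low_ci && e$ci_high >= strong_high_ci)
      return("strong")
    if (e$ci_high < recomb_high_ci) return("recomb")
    "none"
  }
  cand <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (pos[j] - pos[i] > max_kb * 1000) next
      if (classify(i, j) != "strong") next   # outermost pair rule
      cls <- outer(i:j, i:j, Vectorize(function(a, b) {
        if (a < b) classify(a, b) else NA_character_
      }))
      cls <- cls[!is.na(cls)]
      ninf <- sum(cls != "none")
      if (ninf >= 1 && sum(cls == "strong") / ninf >= strong_fraction) {
        cand[[length(cand) + 1]] <- c(i = i, j = j, bp = pos[j] - pos[i])
      }
    }
  }
  if (!length(cand)) return(list())
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, "bp"], cand[, "i"]), , drop = FALSE]
  taken <- rep(FALSE, m)
  out <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, "i"]; j <- cand[r, "j"]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    out[[length(out) + 1]] <- c(start = i, end = j)
  }
  out[order(vapply(out, `[`, numeric(1), "start"))]
}
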