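#' Simulate LD-blocked phased genotypes
#'
#' Markers are partitioned into LD blocks. For each block a small pool of
#' founder haplotypes is drawn (per-marker allele frequencies uniform on
#' `[maf_min, 1 - maf_min]`), and each individual receives two whole-block
#' haplotypes copied from the pool. Copying entire founder haplotypes is
#' what induces strong within-block and near-zero between-block linkage
#' disequilibrium, mimicking the block structure of imputed, phased
#' genotype panels. Blocks are laid out contiguously over up to six
#' autosomes with ~100 kb inter-block gaps and sub-kb within-block
#' spacing; positions are 1-based bp, strictly increasing per chromosome.
#'
#' Individuals are organised into full-sib litters: each litter draws two
#' sire and two dam haplotype indices from the founder pool per block and
#' every litter member inherits one haplotype from each parent with
#' Mendelian sampling. Litter mates therefore show sib-level genomic
#' relatedness, giving the genomic relationship matrix the between-family
#' contrast that makes REML variance-component estimation well posed.
#' The litter assignment is returned in the `"litter"` attribute and
#' reused downstream.
#'
#' @param config a [sim_config].
#' @return a phased [geno_matrix] whose map carries a `block` column with
#'   the generating block index (ground truth for LD tests).
#' @export
sim_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  p <- config$n_snps
  nb <- min(config$n_ld_blocks, p)
  nf <- config$founder_haplotypes_per_block
  n_lit <- min(config$n_litters, n)
  litter <- rep_len(seq_len(n_lit), n)

  # block sizes: as even as possible
  sizes <- rep(p %/% nb, nb)
  extra <- p %% nb
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L

  # contiguous assignment of blocks to up to 6 autosomes
  n_chr <- min(6L, nb)
  chr_of_block <- sort(rep_len(seq_len(n_chr), nb))

  strand1 <- matrix(0L, n, p)
  strand2 <- matrix(0L, n, p)
  chr <- integer(p)
  pos <- integer(p)
  block_id <- integer(p)
  cur_pos <- integer(n_chr)  # running bp per chromosome

  col0 <- 0L
  for (b in seq_len(nb)) {
    m <- sizes[b]
    cols <- col0 + seq_len(m)
    col0 <- col0 + m
    ch <- chr_of_block[b]
    # founder haplotype pool: nf x m
    f <- stats::runif(m, config$maf_min, 1 - config$maf_min)
    pool <- matrix(stats::rbinom(nf * m, 1L, rep(f, each = nf)), nf, m)
    # per litter: two sire + two dam founder haplotypes; children inherit
    # one from each parent with Mendelian sampling
    sire <- matrix(sample.int(nf, 2L * n_lit, replace = TRUE), n_lit, 2L)
    dam <- matrix(sample.int(nf, 2L * n_lit, replace = TRUE), n_lit, 2L)
    pick1 <- sample(1:2, n, replace = TRUE)
    pick2 <- sample(1:2, n, replace = TRUE)
    i1 <- sire[cbind(litter, pick1)]
    i2 <- dam[cbind(litter, pick2)]
    strand1[, cols] <- pool[i1, , drop = FALSE]
    strand2[, cols] <- pool[i2, , drop = FALSE]
    # positions: 100 kb gap before the block, then 300-900 bp steps
    gap <- 100000L
    steps <- as.integer(stats::runif(m, 300, 900))
    pos[cols] <- cur_pos[ch] + gap + cumsum(steps)
    cur_pos[ch] <- pos[cols[m]]
    chr[cols] <- ch
    block_id[cols] <- b
  }

  map <- data.frame(
    id = sprintf("snp_%d_%d", chr, pos),
    chr = chr, pos = pos,
    a1 = "A", a2 = "G",
    block = block_id,
    stringsAsFactors = FALSE
  )
  out <- geno_matrix(dosage = strand1 + strand2, map = map,
                     samples = sprintf("pig_%04d", seq_len(n)),
                     strand1 = strand1, strand2 = strand2)
  attr(out, "litter") <- litter
  out
}
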