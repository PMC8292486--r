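#' Haplotype-allele dosages for one block
#'
#' Every distinct haplotype string over the block's member SNPs is an
#' allele of a multi-allelic pseudo-marker; an individual's dosage of
#' allele k is the number of its two phased haplotypes equal to k, so
#' dosages across all alleles of a block sum to 2 for every individual.
#' Alleles at frequency `allele_freq_min` or below are excluded from the
#' testing set (`kept = FALSE`) but still counted in the frequency table.
#' Allele strings spell each haplotype with the marker map's nucleotide
#' letters (`a1` for strand value 1, `a2` for 0).
#'
#' @param geno a phased [geno_matrix].
#' @param block a `haplotype_block` from [gabriel_blocks()].
#' @param allele_freq_min frequency at or below which an allele is
#'   dropped from testing.
#' @return list: `dosage` (n x kept-alleles matrix, columns named by
#'   allele string) and `alleles` (data.frame `allele`, `freq`, `kept`).
#' @export
hap_allele_dosage <- function(geno, block, allele_freq_min = 0.01) {
  if (!is.phased(geno)) {
    stopf("haplotype coding needs phase: supply a phased VCF")
  }
  cols <- block$snps
  a1 <- geno$map$a1[cols]; a2 <- geno$map$a2[cols]
  spell <- function(strand) {
    chars <- t(ifelse(t(strand) == 1L, a1, a2))
    apply(chars, 1L, paste, collapse = "")
  }
  h1 <- spell(geno$strand1[, cols, drop = FALSE])
  h2 <- spell(geno$strand2[, cols, drop = FALSE])
  n <- length(h1)
  freq_tab <- table(c(h1, h2))
  freq <- as.numeric(freq_tab) / (2 * n)
  alleles <- data.frame(allele = names(freq_tab), freq = freq,
                        kept = freq > allele_freq_min,
                        stringsAsFactors = FALSE)
  alleles <- alleles[order(-alleles$freq, alleles$allele), ]
  rownames(alleles) <- NULL
  kept <- alleles$allele[alleles$kept]
  dosage <- sapply(kept, function(al) (h1 == al) + (h2 == al))
  if (length(kept) == 1L) dosage <- matrix(dosage, ncol = 1L,
                                           dimnames = list(NULL, kept))
  list(dosage = dosage, alleles = alleles)
}

#' Haplotype-based association scan
#'
#' Codes every retained haplotype allele of every block as a biallelic
#' pseudo-marker (its dosage vector) and tests them through
#' [wald_scan()] under the supplied null model. The Bonferroni base for
#' thresholds is the number of retained alleles.
#'
#' @param blocks list of `haplotype_block`s.
#' @param geno the phased [geno_matrix] the blocks were detected in.
#' @param null an [mlm_null] on the same samples.
#' @param allele_freq_min passed to [hap_allele_dosage()].
#' @param mode passed to [wald_scan()].
#' @return list: `assoc` (an `assoc_table` with one row per tested
#'   allele: block coordinates, allele string, effect, SE, p),
#'   `n_tests`, `thresholds` (from [bonferroni_thresholds()]).
#' @export
hap_gwas <- function(blocks, geno, null, allele_freq_min = 0.01,
                     mode = "p3d") {
  if (!length(blocks)) {
    out <- data.frame(id = character(0), chr = character(0),
                      pos = integer(0), block = integer(0),
                      allele = character(0), freq = numeric(0),
                      beta = numeric(0), se = numeric(0), p = numeric(0),
                      reason = character(0), stringsAsFactors = FALSE)
    class(out) <- c("assoc_table", "data.frame")
    return(list(assoc = out, n_tests = 0L, thresholds = NULL))
  }
  dos_list <- vector("list", length(blocks))
  meta <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    hd <- hap_allele_dosage(geno, blocks[[b]], allele_freq_min)
    kept <- hd$alleles[hd$alleles$kept, , drop = FALSE]
    if (!nrow(kept)) next
    dos_list[[b]] <- hd$dosage
    meta[[b]] <- data.frame(
      id = sprintf("hap_%s_%d_%s", blocks[[b]]$chr, blocks[[b]]$start,
                   kept$allele),
      chr = blocks[[b]]$chr, pos = blocks[[b]]$start,
      block = b, allele = kept$allele, freq = kept$freq,
      stringsAsFactors = FALSE
    )
  }
  keep <- !vapply(dos_list, is.null, logical(1))
  dosage <- do.call(cbind, dos_list[keep])
  meta <- do.call(rbind, meta[keep])
  n_tests <- ncol(dosage)
  assoc <- wald_scan(dosage, null, mode = mode,
                     map = data.frame(id = meta$id, chr = meta$chr,
                                      pos = meta$pos,
                                      stringsAsFactors = FALSE))
  assoc$block <- meta$block
  assoc$allele <- meta$allele
  assoc$freq <- meta$freq
  list(assoc = assoc, n_tests = n_tests,
       thresholds = bonferroni_thresholds(n_tests))
}
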