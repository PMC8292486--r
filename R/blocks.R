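#' Detect haplotype blocks (Gabriel confidence-interval method)
#'
#' Marker pairs are classified from their D' confidence interval:
#' "strong LD" when the lower bound is at least `strong_low_ci` and the
#' upper bound at least `strong_high_ci`; "strong recombination" when
#' the upper bound falls below `recomb_high_ci`; anything else (and any
#' pair involving a monomorphic marker) is uninformative. A candidate
#' span of two or more markers becomes a block when at least
#' `strong_fraction` of its informative pairs are strong and (following
#' the common Gabriel implementation) its outermost pair is itself in
#' strong LD; spans are capped at `max_kb` and at `max_span_snps`
#' markers. Overlapping
#' candidates are resolved longest-first (bp span), ties by leftmost
#' start, which makes the output deterministic. Markers with missingness
#' above `marker_missing_max` are excluded before pairing.
#'
#' Phased input uses a vectorized strand-counting path; unphased input
#' falls back to per-pair EM haplotype frequencies.
#'
#' @param geno a [geno_matrix] with markers sorted by position within
#'   chromosome.
#' @param strong_low_ci,strong_high_ci strong-LD bounds on the D' CI.
#' @param recomb_high_ci upper-CI bound below which a pair counts as
#'   strong recombination.
#' @param strong_fraction minimum fraction of informative pairs in
#'   strong LD.
#' @param max_kb maximum block span in kb.
#' @param marker_missing_max maximum per-marker missingness.
#' @param max_span_snps cap on the number of markers per block.
#' @param require_endpoint_strong require the span's outermost pair to be
#'   strong (prevents uninformative flanking pairs from extending a
#'   block across a recombination gap).
#' @return list of `haplotype_block` objects (possibly empty): each has
#'   `chr`, `start`, `end`, `snps` (global marker indices), `snp_ids`,
#'   and, for phased input, `alleles` and `frequencies`.
#' @export
gabriel_blocks <- function(geno, strong_low_ci = 0.8,
                           strong_high_ci = 0.98, recomb_high_ci = 0.90,
                           strong_fraction = 0.95, max_kb = 1000,
                           marker_missing_max = 0.1,
                           max_span_snps = 60L,
                           require_endpoint_strong = TRUE) {
  stopifnot(inherits(geno, "geno_matrix"))
  miss <- colMeans(is.na(geno$dosage))
  usable <- unname(which(miss <= marker_missing_max))
  blocks <- list()
  for (ch in unique(geno$map$chr)) {
    on_chr <- usable[geno$map$chr[usable] == ch]
    on_chr <- on_chr[order(geno$map$pos[on_chr])]
    m <- length(on_chr)
    if (m < 2L) next
    pos <- geno$map$pos[on_chr]

    # candidate pair set within the span caps
    pr <- list()
    for (i in seq_len(m - 1L)) {
      jmax <- min(m, i + max_span_snps)
      js <- (i + 1L):jmax
      js <- js[pos[js] - pos[i] <= max_kb * 1000]
      if (length(js)) pr[[i]] <- cbind(i, js)
    }
    if (!length(pr)) next
    pairs <- do.call(rbind, pr)

    if (is.phased(geno)) {
      S <- rbind(geno$strand1[, on_chr, drop = FALSE],
                 geno$strand2[, on_chr, drop = FALSE])
      ld <- .ld_pairs_phased(S, pairs)
    } else {
      ld <- data.frame(i = pairs[, 1], j = pairs[, 2],
                       dprime = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, r2 = NA_real_,
                       informative = FALSE)
      for (r in seq_len(nrow(pairs))) {
        e <- ld_ci(geno$dosage[, on_chr[pairs[r, 1]]],
                   geno$dosage[, on_chr[pairs[r, 2]]], phased = FALSE)
        ld[r, 3:7] <- e[c("dprime", "ci_low", "ci_high", "r2",
                          "informative")]
      }
    }

    strong <- ld$informative & ld$ci_low >= strong_low_ci &
      ld$ci_high >= strong_high_ci
    info <- ld$informative & (strong | ld$ci_high < recomb_high_ci)

    # summed-area tables for O(1) span queries
    Sm <- matrix(0, m, m); Im <- matrix(0, m, m)
    Sm[cbind(ld$i, ld$j)] <- as.numeric(strong)
    Im[cbind(ld$i, ld$j)] <- as.numeric(info)
    Scum <- apply(apply(Sm, 2L, cumsum), 1L, cumsum)  # transposed SAT
    Icum <- apply(apply(Im, 2L, cumsum), 1L, cumsum)
    span_sum <- function(cum, i, j) {
      tot <- cum[j, j]
      if (i > 1L) tot <- tot - cum[j, i - 1L] - cum[i - 1L, j] +
          cum[i - 1L, i - 1L]
      tot
    }

    cand <- list()
    for (i in seq_len(m - 1L)) {
      jmax <- min(m, i + max_span_snps)
      for (j in (i + 1L):jmax) {
        if (pos[j] - pos[i] > max_kb * 1000) break
        if (require_endpoint_strong && Sm[i, j] == 0) next
        ninf <- span_sum(Icum, i, j)
        if (ninf < 1) next
        if (span_sum(Scum, i, j) / ninf >= strong_fraction) {
          cand[[length(cand) + 1L]] <-
            c(i = i, j = j, bp = pos[j] - pos[i])
        }
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, "bp"], cand[, "i"]), , drop = FALSE]
    taken <- rep(FALSE, m)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, "i"]; j <- cand[r, "j"]
      if (any(taken[i:j])) next
      taken[i:j] <- TRUE
      idx <- on_chr[i:j]
      blk <- structure(list(
        chr = ch, start = pos[i], end = pos[j], snps = idx,
        snp_ids = geno$map$id[idx]
      ), class = "haplotype_block")
      if (is.phased(geno)) {
        hb <- hap_allele_dosage(geno, blk, allele_freq_min = 0)
        blk$alleles <- hb$alleles$allele
        blk$frequencies <- hb$alleles$freq
      }
      blocks[[length(blocks) + 1L]] <- blk
    }
  }
  # deterministic order: chromosome, then start
  if (length(blocks)) {
    ord <- order(vapply(blocks, function(b) as.character(b$chr),
                        character(1)),
                 vapply(blocks, function(b) b$start, numeric(1)))
    blocks <- blocks[ord]
  }
  blocks
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat(sprintf("haplotype_block chr%s:%d-%d, %d SNPs%s\n",
              x$chr, x$start, x$end, length(x$snps),
              if (!is.null(x$alleles))
                sprintf(", %d alleles", length(x$alleles)) else ""))
  invisible(x)
}

#' Write blocks in a text "blocks" format
#'
#' One row per block: chromosome, start, end, number of member SNPs, and
#' the member SNP id list separated by `|`.
#'
#' @param blocks list of `haplotype_block`s.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  df <- data.frame(
    chr = vapply(blocks, function(b) as.character(b$chr), character(1)),
    start = vapply(blocks, function(b) b$start, numeric(1)),
    end = vapply(blocks, function(b) b$end, numeric(1)),
    nsnps = vapply(blocks, function(b) length(b$snps), numeric(1)),
    snps = vapply(blocks, function(b) paste(b$snp_ids, collapse = "|"),
                  character(1)),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
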