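#' 1-Mb QTL region around a significant marker
#'
#' The window spans 500 kb either side of the anchor position. The
#' display range in Mb is rounded half-up to 2 decimals, matching the
#' convention of published QTL tables. Anchors within 500 kb of the
#' chromosome start are clamped to a window starting at 1 bp with the
#' 1 Mb width preserved to the right (and a message logged).
#'
#' @param chrom chromosome label.
#' @param pos anchor position, bp.
#' @param anchor_id optional anchor marker id.
#' @return object of class `qtl_region`: `chr`, `lower`, `upper` (bp),
#'   `anchor_id`, `anchor_pos`, `display` ("xx.xx-yy.yy" Mb string),
#'   `lower_mb`, `upper_mb`.
#' @export
qtl_region <- function(chrom, pos, anchor_id = NA_character_) {
  half <- 500000
  if (pos <= half) {
    message(sprintf("anchor %s:%d within 500 kb of chromosome start: window clamped",
                    chrom, pos))
    lower <- 1
    upper <- 1 + 2 * half
  } else {
    lower <- pos - half
    upper <- pos + half
  }
  lower_mb <- round_half_up(lower / 1e6, 2L)
  upper_mb <- round_half_up(upper / 1e6, 2L)
  structure(list(
    chr = chrom, lower = lower, upper = upper,
    anchor_id = anchor_id, anchor_pos = pos,
    lower_mb = lower_mb, upper_mb = upper_mb,
    display = sprintf("%.2f-%.2f", lower_mb, upper_mb)
  ), class = "qtl_region")
}

#' @export
print.qtl_region <- function(x, ...) {
  cat(sprintf("QTL region chr%s: %s Mb (anchor %s at %d)\n",
              x$chr, x$display,
              ifelse(is.na(x$anchor_id), "-", x$anchor_id), x$anchor_pos))
  invisible(x)
}

#' Tier significant association hits
#'
#' Splits an association table into genome-wide (`p < 0.05/N`) and
#' suggestive (`p < 1/N`) tiers using strict inequalities; a p-value
#' exactly at a threshold is not significant. Genome-wide rows are a
#' subset of the suggestive rows by construction; the output labels each
#' retained row with its strongest tier and sorts by p.
#'
#' @param assoc an `assoc_table` from [wald_scan()] or [hap_gwas()].
#' @param thresholds a [bonferroni_thresholds()] object.
#' @return data.frame of suggestive-or-better rows with a `tier` column
#'   (`"genome-wide"` or `"suggestive"`), sorted by p.
#' @export
significant_hits <- function(assoc, thresholds) {
  stopifnot(inherits(thresholds, "bonf_thresholds"))
  keep <- !is.na(assoc$p) & assoc$p < thresholds$suggestive
  out <- assoc[keep, , drop = FALSE]
  out$tier <- ifelse(out$p < thresholds$genome_wide, "genome-wide",
                     "suggestive")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  out
}

#' Partition hits shared between the direct and social scans
#'
#' Exact set algebra on hit keys: hits found for both direct and social
#' genetic effects, direct-only, and social-only. SNP hits are keyed by
#' (chromosome, position) since marker ids differ across panels;
#' haplotype hits can be keyed by block id/allele.
#'
#' @param hits_dge,hits_sge data.frames of hits.
#' @param key character vector of key columns present in both tables.
#' @return list of data.frames `common`, `dge_only`, `sge_only` (rows
#'   taken from the DGE table for `common`).
#' @export
overlap_hits <- function(hits_dge, hits_sge, key = c("chr", "pos")) {
  mk <- function(df) {
    k <- do.call(paste, c(df[key], sep = ":"))
    if (anyDuplicated(k)) {
      warnf("duplicate hit keys de-duplicated")
      df <- df[!duplicated(k), , drop = FALSE]
      k <- k[!duplicated(k)]
    }
    list(df = df, k = k)
  }
  d <- mk(hits_dge); s <- mk(hits_sge)
  list(common = d$df[d$k %in% s$k, , drop = FALSE],
       dge_only = d$df[!(d$k %in% s$k), , drop = FALSE],
       sge_only = s$df[!(s$k %in% d$k), , drop = FALSE])
}

#' Plot-ready Manhattan/QQ export
#'
#' Adds -log10(p) and a cumulative genome coordinate to an association
#' table so any plotting layer can draw a Manhattan plot directly.
#'
#' @param assoc an `assoc_table`.
#' @return data.frame `chr`, `pos`, `log10p`, `cum_pos`.
#' @export
manhattan_table <- function(assoc) {
  a <- assoc[!is.na(assoc$p), , drop = FALSE]
  a <- a[order(a$chr, a$pos), , drop = FALSE]
  offsets <- c(0, cumsum(tapply(as.numeric(a$pos), a$chr, max)))
  chr_index <- as.integer(factor(a$chr, levels = unique(a$chr)))
  data.frame(chr = a$chr, pos = a$pos,
             log10p = -log10(a$p),
             cum_pos = as.numeric(a$pos) + offsets[chr_index])
}
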