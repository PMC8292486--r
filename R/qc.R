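#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: given the observed allele counts, the p-value is
#' the summed probability of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count (the standard
#' genotype-QC exact test). Monomorphic input has a single possible
#' configuration, hence p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stopf("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stopf("no observations")
  n_A <- 2L * n_AA + n_Aa
  n_a <- 2L * n_aa + n_Aa
  rare <- min(n_A, n_a)
  if (rare == 0L) return(1)
  # possible heterozygote counts share the parity of the rare allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # conditional probability of each het count given allele counts:
  # P(h) = n! / (n_hom_rare! h! n_hom_common!) * 2^h * nA! na! / (2n)!
  hom_rare <- (rare - hets) / 2
  hom_common <- (n - hets - hom_rare)
  logp <- lfactorial(n) - lfactorial(hom_rare) - lfactorial(hets) -
    lfactorial(hom_common) + hets * log(2) +
    lfactorial(n_A) + lfactorial(n_a) - lfactorial(2L * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_Aa)
  if (length(obs) == 0L) stopf("observed heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-7)]))
}

#' Chip bookkeeping replay
#'
#' Arithmetic of a marker-panel accounting: markers in, markers removed
#' for missing position / sex-chromosome location, markers removed by the
#' statistical QC filters, markers retained.
#'
#' @param n_input markers on the chip.
#' @param n_removed_map removed for no position information or
#'   sex-chromosome location (pooled, as chips report it).
#' @param n_removed_qc removed by call-rate/MAF/HWE filtering.
#' @return integer count of retained markers.
#' @export
qc_bookkeeping <- function(n_input, n_removed_map, n_removed_qc) {
  out <- n_input - n_removed_map - n_removed_qc
  if (out < 0) stopf("more markers removed than supplied")
  as.integer(out)
}

#' Marker quality control
#'
#' Applies the standard chip QC filters in a fixed order so that each
#' marker is attributed to exactly one filter: (1) no position or
#' non-autosomal; (2) per-marker quality score (e.g. imputation
#' R-squared); (3) call rate; (4) minor allele frequency; (5) exact HWE.
#' All removals use strict inequalities (a marker with MAF exactly equal
#' to `maf_min` is retained).
#'
#' @param geno a [geno_matrix].
#' @param call_rate_min minimum fraction of non-missing genotypes.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_min minimum exact-test HWE p-value.
#' @param quality_min optional minimum per-marker quality score; only
#'   applied when both the threshold and a `quality` map column exist.
#' @param autosomes_only drop markers on sex chromosomes (chr coded
#'   X/Y/23/24/25) or without a positive position.
#' @return list with elements `geno` (filtered [geno_matrix]) and
#'   `report` (a `qc_report` with per-filter tallies).
#' @export
qc_markers <- function(geno, call_rate_min = 0.90, maf_min = 0.05,
                       hwe_min = 1e-6, quality_min = NULL,
                       autosomes_only = TRUE) {
  stopifnot(inherits(geno, "geno_matrix"))
  p <- ncol(geno$dosage)
  state <- rep(NA_character_, p)  # first filter that rejects

  if (autosomes_only) {
    chr <- as.character(geno$map$chr)
    bad_pos <- is.na(geno$map$pos) | geno$map$pos < 1
    sexchr <- chr %in% c("X", "Y", "XY", "MT", "23", "24", "25")
    state[is.na(state) & (bad_pos | sexchr)] <- "position_or_sex_chr"
  }
  if (!is.null(quality_min) && !is.null(geno$map$quality)) {
    q <- geno$map$quality
    state[is.na(state) & !is.na(q) & q < quality_min] <- "quality"
  }
  call_rate <- colMeans(!is.na(geno$dosage))
  state[is.na(state) & call_rate < call_rate_min] <- "callrate"
  maf <- geno_maf(geno)
  state[is.na(state) & (is.na(maf) | maf < maf_min)] <- "maf"
  todo <- which(is.na(state))
  if (length(todo)) {
    hwe_p <- vapply(todo, function(j) {
      d <- geno$dosage[, j]
      d <- d[!is.na(d)]
      hwe_exact(sum(d == 2), sum(d == 1), sum(d == 0))
    }, numeric(1))
    state[todo[hwe_p < hwe_min]] <- "hwe"
  }

  keep <- is.na(state)
  if (!any(keep)) stopf("quality control removed every marker")
  report <- structure(list(
    n_input = p,
    n_removed_no_position_or_sex_chr = sum(state == "position_or_sex_chr", na.rm = TRUE),
    n_removed_quality = sum(state == "quality", na.rm = TRUE),
    n_removed_callrate = sum(state == "callrate", na.rm = TRUE),
    n_removed_maf = sum(state == "maf", na.rm = TRUE),
    n_removed_hwe = sum(state == "hwe", na.rm = TRUE),
    n_retained = sum(keep)
  ), class = "qc_report")
  stopifnot(report$n_input - report$n_removed_no_position_or_sex_chr -
              report$n_removed_quality - report$n_removed_callrate -
              report$n_removed_maf - report$n_removed_hwe ==
              report$n_retained)
  list(geno = geno_subset(geno, markers = which(keep)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "marker QC: %d in; removed %d position/sex-chr, %d quality, ",
    "%d call rate, %d MAF, %d HWE; %d retained\n"),
    x$n_input, x$n_removed_no_position_or_sex_chr, x$n_removed_quality,
    x$n_removed_callrate, x$n_removed_maf, x$n_removed_hwe, x$n_retained))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(field = names(unclass(report)),
                   count = unlist(unclass(report)), row.names = NULL)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
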