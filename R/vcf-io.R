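#' Write a phased VCF (v4.2, GT field)
#'
#' The counted allele `a1` is written as ALT and `a2` as REF, so a GT
#' allele index of 1 corresponds to one copy of `a1` and the dosage is
#' recoverable as the sum of the two phased alleles. Per-marker quality
#' scores, when present in the map, are emitted as an `R2` INFO field.
#'
#' @param geno a phased [geno_matrix].
#' @param path output `.vcf` path (plain text).
#' @return the path, invisibly.
#' @export
write_phased_vcf <- function(geno, path) {
  if (!is.phased(geno)) stopf("genotype matrix carries no phase")
  n <- nrow(geno$dosage); p <- ncol(geno$dosage)
  gt <- matrix(paste0(t(geno$strand1), "|", t(geno$strand2)), nrow = p)
  gt[is.na(t(geno$dosage))] <- ".|."
  info <- if (!is.null(geno$map$quality)) {
    sprintf("R2=%.4f", geno$map$quality)
  } else rep(".", p)
  body <- paste(geno$map$chr, geno$map$pos, geno$map$id, geno$map$a2,
                geno$map$a1, ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sgegwas",
    '##INFO=<ID=R2,Number=1,Type=Float,Description="Imputation quality score">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Only biallelic SNP records are kept. The counted allele (`a1`, whose
#' copies the dosage reports) is ALT. An `R2` INFO field, when present,
#' populates the map's `quality` column.
#'
#' @param path VCF file (plain text or gzipped).
#' @param require_phase error on any unphased ("/") genotype; otherwise
#'   phase is populated only when every genotype is phased.
#' @return a [geno_matrix].
#' @export
read_vcf <- function(path, require_phase = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  if (!any(snp)) stopf("no biallelic SNP records in %s", path)
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  gt_t <- t(gt)                      # samples x markers
  sep_bar <- grepl("|", gt_t, fixed = TRUE)
  sep_slash <- grepl("/", gt_t, fixed = TRUE)
  if (require_phase && any(sep_slash)) {
    stopf("unphased '/' genotypes present but phase was requested")
  }
  a_first <- suppressWarnings(as.integer(substr(gt_t, 1L, 1L)))
  a_second <- suppressWarnings(as.integer(substr(gt_t, 3L, 3L)))
  dosage <- matrix(a_first + a_second, nrow = nrow(gt_t),
                   dimnames = NULL)
  phased <- all(sep_bar | is.na(gt_t))
  quality <- NULL
  if (any(grepl("R2=", fix$INFO, fixed = TRUE))) {
    m <- regmatches(fix$INFO, regexpr("R2=[0-9.eE+-]+", fix$INFO))
    quality <- rep(NA_real_, nrow(fix))
    quality[grepl("R2=", fix$INFO, fixed = TRUE)] <-
      as.numeric(sub("R2=", "", m))
  }
  map <- data.frame(id = fix$ID, chr = fix$CHROM,
                    pos = as.integer(fix$POS),
                    a1 = fix$ALT, a2 = fix$REF, stringsAsFactors = FALSE)
  if (!is.null(quality)) map$quality <- quality
  geno_matrix(
    dosage, map, samples = colnames(gt),
    strand1 = if (phased) matrix(a_first, nrow = nrow(gt_t)),
    strand2 = if (phased) matrix(a_second, nrow = nrow(gt_t))
  )
}

#' Load genotypes from PLINK binary or VCF
#'
#' @param path file path: a prefix for `format = "plink-bed"`, a `.vcf`
#'   for `format = "vcf"`.
#' @param format input format.
#' @param require_phase for VCF input, insist on phased genotypes.
#' @return a [geno_matrix].
#' @export
load_genotypes <- function(path, format = c("plink-bed", "vcf"),
                           require_phase = FALSE) {
  format <- match.arg(format)
  switch(format,
    "plink-bed" = read_plink(sub("\\.bed$", "", path)),
    "vcf" = read_vcf(path, require_phase = require_phase)
  )
}
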