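#' Genotype matrix container
#'
#' Holds an n x p dosage matrix (codes 0/1/2/NA counting copies of allele
#' `a1`), an optional pair of haplotype strand matrices for phased data, a
#' marker map, and sample ids. The strand matrices satisfy
#' `strand1 + strand2 == dosage` wherever the dosage is non-missing.
#'
#' @param dosage n x p numeric matrix of allele counts in \{0, 1, 2, NA\}.
#' @param map data.frame with columns `id`, `chr`, `pos` (1-based bp),
#'   `a1`, `a2` and optionally `quality` (per-marker score in \[0, 1\],
#'   e.g. an imputation R-squared).
#' @param samples character vector of sample ids (length n).
#' @param strand1,strand2 optional n x p 0/1 matrices giving the two
#'   phased haplotypes; both or neither must be supplied.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map, samples = NULL,
                        strand1 = NULL, strand2 = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  p <- ncol(dosage)
  if (is.null(samples)) samples <- sprintf("ind_%04d", seq_len(n))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  req <- c("id", "chr", "pos", "a1", "a2")
  if (!all(req %in% names(map))) {
    stopf("marker map must have columns %s", paste(req, collapse = ", "))
  }
  if (nrow(map) != p) stopf("map has %d rows but dosage has %d markers", nrow(map), p)
  if (length(samples) != n) stopf("sample id length != n")
  if (is.null(strand1) != is.null(strand2)) {
    stopf("supply both strand matrices or neither")
  }
  if (!is.null(strand1)) {
    strand1 <- as.matrix(strand1); strand2 <- as.matrix(strand2)
    if (!all(dim(strand1) == dim(dosage)) || !all(dim(strand2) == dim(dosage))) {
      stopf("strand matrices must match dosage dimensions")
    }
    ok <- is.na(dosage) | (strand1 + strand2 == dosage)
    if (!all(ok)) stopf("strand1 + strand2 != dosage at %d cells", sum(!ok))
  }
  structure(
    list(dosage = dosage, strand1 = strand1, strand2 = strand2,
         map = map, samples = as.character(samples)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d markers (%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              if (is.phased(x)) "phased" else "unphased"))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$map$chr), collapse = ", ")))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Test whether a genotype matrix carries phase
#' @param geno a [geno_matrix].
#' @return logical.
#' @export
is.phased <- function(geno) !is.null(geno$strand1)

#' Subset a genotype matrix by markers and/or samples
#'
#' @param geno a [geno_matrix].
#' @param markers integer or logical index over markers.
#' @param samples integer or logical index over samples.
#' @return a [geno_matrix].
#' @export
geno_subset <- function(geno, markers = NULL, samples = NULL) {
  mi <- markers %||% seq_len(ncol(geno$dosage))
  si <- samples %||% seq_len(nrow(geno$dosage))
  geno_matrix(
    dosage = geno$dosage[si, mi, drop = FALSE],
    map = geno$map[mi, , drop = FALSE],
    samples = geno$samples[si],
    strand1 = if (is.phased(geno)) geno$strand1[si, mi, drop = FALSE],
    strand2 = if (is.phased(geno)) geno$strand2[si, mi, drop = FALSE]
  )
}

#' Per-marker minor allele frequency
#' @param geno a [geno_matrix].
#' @return numeric vector of MAFs (NA for fully missing markers).
#' @export
geno_maf <- function(geno) {
  f <- colMeans(geno$dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}
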