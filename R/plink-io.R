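# PLINK 1 binary genotype trio (.bed/.bim/.fam), SNP-major layout.
# .bed starts with magic bytes 0x6c 0x1b then 0x01 (SNP-major); each marker
# occupies ceiling(n/4) bytes, two bits per sample, least significant pair
# first: 00 = homozygous a1, 01 = missing, 10 = heterozygous,
# 11 = homozygous a2. Dosage counts copies of a1, so 00 -> 2, 10 -> 1,
# 11 -> 0.

# dosage value indexed by two-bit code + 1
.bed_code_to_dosage <- c(2L, NA_integer_, 1L, 0L)
# two-bit code indexed by dosage: 0 -> 11, 1 -> 10, 2 -> 00, NA -> 01
.bed_dosage_to_code <- function(d) {
  code <- integer(length(d))
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L
  code  # d == 2 stays 0L
}

#' Write a genotype matrix as a PLINK binary trio
#'
#' @param geno a [geno_matrix].
#' @param prefix path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  n <- nrow(geno$dosage); p <- ncol(geno$dosage)
  bpm <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  shift <- 4L^(0:3)
  for (j in seq_len(p)) {
    code <- .bed_dosage_to_code(geno$dosage[, j])
    length(code) <- bpm * 4L          # pad with 0 (= hom a1, ignored on read)
    code[is.na(code)] <- 0L
    bytes <- colSums(matrix(code * shift, nrow = 4L))
    writeBin(as.raw(bytes), con)
  }
  bim <- data.frame(chr = geno$map$chr, id = geno$map$id, cm = 0,
                    pos = geno$map$pos, a1 = geno$map$a1, a2 = geno$map$a2)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE)
  fam <- data.frame(fid = geno$samples, iid = geno$samples,
                    pat = 0, mat = 0, sex = 0, pheno = -9)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK binary trio
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` files.
#' @return an unphased [geno_matrix] (the bed format carries no phase).
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  for (ext in c(".bed", ".bim", ".fam")) {
    if (!file.exists(paste0(prefix, ext))) stopf("missing %s%s", prefix, ext)
  }
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = list(character = 1:2))
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE,
                           colClasses = list(character = c(2, 5, 6)))
  n <- nrow(fam); p <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stopf("%s is not a PLINK .bed file (bad magic bytes)", bed_path)
  }
  if (raw[3] != as.raw(0x01)) stopf("only SNP-major .bed files are supported")
  bpm <- ceiling(n / 4)
  if (length(raw) - 3L != bpm * p) {
    stopf(".bed payload (%d bytes) inconsistent with %d samples x %d markers",
          length(raw) - 3L, n, p)
  }
  bytes <- as.integer(raw[-(1:3)])
  # expand each byte into its 4 two-bit codes (least significant pair first)
  codes <- rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                 (bytes %/% 16L) %% 4L, bytes %/% 64L)
  dosage <- matrix(.bed_code_to_dosage[codes + 1L], nrow = bpm * 4L)[
    seq_len(n), , drop = FALSE]
  map <- data.frame(id = bim$V2, chr = bim$V1, pos = bim$V4,
                    a1 = bim$V5, a2 = bim$V6, stringsAsFactors = FALSE)
  geno_matrix(dosage, map, samples = fam$V2)
}
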