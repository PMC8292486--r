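#!/usr/bin/env Rscript
# Stage 4: single-locus mixed-model GWAS on the deregressed EBVs.
#
# One scan per effect type (direct, social) with the centered GRM as
# polygenic covariance, Bonferroni thresholds from the marker count, and
# the genomic inflation factor as the stratification diagnostic.

library(sgegwas)

run <- "results/run"
geno <- read_vcf(file.path(run, "genotypes.vcf"), require_phase = TRUE)
qc <- qc_markers(geno, maf_min = 0.025)
debv <- as.data.frame(data.table::fread(file.path(run, "deregressed_ebv.tsv")))
G <- grm_centered(qc$geno)
thr <- bonferroni_thresholds(ncol(qc$geno$dosage))
print(thr)

for (eff in c("DGE", "SGE")) {
  tab <- debv[debv$effect == eff & debv$usable, ]
  idx <- match(tab$id, qc$geno$samples)
  null <- fit_mlm_null(tab$debv, G[idx, idx])
  assoc <- wald_scan(qc$geno$dosage[idx, ], null, map = qc$geno$map)
  lam <- genomic_lambda(assoc$p)
  hits <- significant_hits(assoc, thr)
  tag <- tolower(eff)
  data.table::fwrite(assoc, file.path(run, sprintf("assoc_snp_%s.tsv", tag)),
                     sep = "\t")
  data.table::fwrite(manhattan_table(assoc),
                     file.path(run, sprintf("manhattan_snp_%s.tsv", tag)),
                     sep = "\t")
  data.table::fwrite(hits, file.path(run, sprintf("hits_snp_%s.tsv", tag)),
                     sep = "\t")
  cat(sprintf("%s scan: %d markers, lambda %.3f, %d suggestive (%d genome-wide)\n",
              eff, sum(!is.na(assoc$p)), lam, nrow(hits),
              sum(hits$tier == "genome-wide")))
}
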