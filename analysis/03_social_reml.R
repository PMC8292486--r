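#!/usr/bin/env Rscript
# Stage 3: fit the social genetic effects model and deregress EBVs.
#
# Marker QC, the trace-normalised genomic relationship matrix, the
# AI-REML fit of y = Xb + Z_D a_D + Z_S a_S + Wl + Vg + e, accuracies
# from prediction-error variances, and deregressed EBVs for both effect
# types.

library(sgegwas)

run <- "results/run"
geno <- read_vcf(file.path(run, "genotypes.vcf"), require_phase = TRUE)
cohort <- as.data.frame(data.table::fread(file.path(run, "cohort.tsv")))
traits <- as.data.frame(data.table::fread(file.path(run, "traits.tsv")))

qc <- qc_markers(geno, maf_min = 0.025)
print(qc$report)
write_qc_report(qc$report, file.path(run, "qc_report.tsv"))

K <- grm_centered(qc$geno, method = "scaled")
design <- build_design(cohort, traits, "y")
fit <- reml_fit_social(design, K)
print(fit)
writeLines(capture.output(print(fit)), file.path(run, "reml_fit.txt"))

debv <- deregressed_ebv_table(fit, trait = "y")
data.table::fwrite(debv, file.path(run, "deregressed_ebv.tsv"), sep = "\t")
for (eff in unique(debv$effect)) {
  d <- debv[debv$effect == eff, ]
  cat(sprintf("%s: mean accuracy %.2f, %d of %d usable for GWAS\n",
              eff, mean(d$accuracy), sum(d$usable), nrow(d)))
}

truth_path <- file.path(run, "sim_truth.rds")
if (file.exists(truth_path)) {
  truth <- readRDS(truth_path)
  cat(sprintf("EBV vs truth: cor(DGE) = %.2f, cor(SGE) = %.2f\n",
              cor(fit$ebv_D, truth$true_a_D),
              cor(fit$ebv_S, truth$true_a_S)))
}
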