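#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Desk-scale defaults: 600 pigs in pens of 10, 60 litters, 3,000 SNPs in
# 300 LD blocks, variance components (D, S, DS, litter, pen, resid) =
# (0.30, 0.03, 0, 0.05, 0.05, 0.57). Writes the genotypes (PLINK trio +
# phased VCF), cohort table, feeder visit records and a manifest under
# results/run/.

library(sgegwas)

out <- "results/run"
cfg <- sim_config(seed = 1)
print(cfg)

geno <- sim_genotypes(cfg)
sim <- sim_effects_and_phenotypes(geno, cfg)
visits <- sim_feeder_records(sim$cohort, cfg)
paths <- write_sim_cohort(geno, sim$cohort, visits, cfg, out)
saveRDS(sim$truth, file.path(out, "sim_truth.rds"))  # scratch ground truth
data.table::fwrite(sim$traits, file.path(out, "traits.tsv"), sep = "\t")

cat(sprintf("cohort: %d pigs, %d pens (sizes %s), %d litters\n",
            nrow(sim$cohort), length(unique(sim$cohort$pen)),
            paste(range(table(sim$cohort$pen)), collapse = "-"),
            length(unique(sim$cohort$litter))))
cat(sprintf("genotypes: %d markers on %d chromosomes, written to %s\n",
            ncol(geno$dosage), length(unique(geno$map$chr)), out))
cat(sprintf("phenotype: mean %.3f, variance %.3f (analytic %.3f)\n",
            mean(sim$traits$y), var(sim$traits$y),
            0.30 + 9 * 0.03 + 0.05 + 0.05 + 0.57))
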