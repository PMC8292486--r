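#!/usr/bin/env Rscript
# Stage 2: derive the performance traits from raw records.
#
# ADG comes from the OLS regression of visit body weight on day, ADFI
# and TPD from totals over feed days, FS from their ratio, and FCR,
# D100, B100, RFI from the weight standardisation formulas. Checks that
# the feeder-derived traits agree with the generator's targets.

library(sgegwas)

run <- "results/run"
cohort <- as.data.frame(data.table::fread(file.path(run, "cohort.tsv")))
visits <- as.data.frame(data.table::fread(file.path(run, "visits.tsv")))

derived <- derive_traits(cohort, visits)
data.table::fwrite(derived, file.path(run, "derived_traits.tsv"),
                   sep = "\t")

adfi_err <- max(abs(derived$ADFI - cohort$tfi / cohort$feed_days))
cat(sprintf("derived %d trait rows; ADFI reconstruction error %.2e\n",
            nrow(derived), adfi_err))
cat("trait summary:\n")
print(round(vapply(derived[, -1], mean, numeric(1)), 3))
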