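#!/usr/bin/env Rscript
# Stage 6: reporting — QTL regions and direct/social overlap.
#
# 1-Mb windows centered on each suggestive-or-better SNP (displayed in
# Mb, half-up at 2 decimals), and the partition of hits into common,
# direct-only and social-only sets keyed by (chromosome, position).

library(sgegwas)

run <- "results/run"
hits_d <- as.data.frame(data.table::fread(file.path(run, "hits_snp_dge.tsv")))
hits_s <- as.data.frame(data.table::fread(file.path(run, "hits_snp_sge.tsv")))

ov <- overlap_hits(hits_d, hits_s)
cat(sprintf("SNP hits: %d DGE, %d SGE, %d common, %d DGE-only, %d SGE-only\n",
            nrow(hits_d), nrow(hits_s), nrow(ov$common),
            nrow(ov$dge_only), nrow(ov$sge_only)))
data.table::fwrite(ov$common, file.path(run, "hits_common.tsv"), sep = "\t")

regions <- if (nrow(hits_d)) do.call(rbind, lapply(seq_len(nrow(hits_d)),
  function(r) {
    q <- qtl_region(hits_d$chr[r], hits_d$pos[r], hits_d$id[r])
    data.frame(chr = q$chr, anchor = q$anchor_id, anchor_pos = q$anchor_pos,
               lower = q$lower, upper = q$upper, display = q$display)
  })) else data.frame(chr = character(0), anchor = character(0),
                      anchor_pos = numeric(0), lower = numeric(0),
                      upper = numeric(0), display = character(0))
data.table::fwrite(regions, file.path(run, "qtl_regions_dge.tsv"), sep = "\t")
if (nrow(regions)) {
  cat("DGE QTL regions (Mb):\n")
  print(unique(regions[, c("chr", "display")]), row.names = FALSE)
}
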