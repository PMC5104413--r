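#!/usr/bin/env Rscript
# Stage 3: pass-1 dual-metric hit selection.  Hits exceed (strictly) the
# mean + 2 SD of all test pools, computed separately on raw normalized
# luciferase and on the per-cell metric; the union goes forward.

library(nrf2screen)

st1 <- readRDS("scratch/analysis/01_screen.rds")
st2 <- readRDS("scratch/analysis/02_normalized.rds")

pass1 <- select_pass1_hits(st2$entity_tbl)
cts <- attr(pass1, "counts")
cat(sprintf("pass-1 thresholds: raw %.1f%%, per-cell %.1f%%\n",
            attr(pass1, "threshold_raw"), attr(pass1, "threshold_per_cell")))
cat(sprintf("hits: %d raw, %d per-cell, %d overlap -> %d genes forward\n",
            cts["n_raw"], cts["n_per_cell"], cts["n_overlap"], cts["n_union"]))

planted <- st1$sim$truth$gene$gene_id[st1$sim$truth$gene$activation_fold > 1]
cat(sprintf("planted-activator recall: %.2f\n",
            mean(planted %in% pass1$gene_id)))

write_results(pass1, "results/analysis/pass1_hits.tsv")
saveRDS(pass1, "scratch/analysis/03_pass1.rds")
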