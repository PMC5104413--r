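#!/usr/bin/env Rscript
# Stage 2: QC-gated field averaging, intra-plate percent-of-control
# normalization and inter-plate replicate aggregation; reports the
# coefficient-of-variation profile (expected: ~80% of replicate CVs below
# 10%) and the per-plate QC table.

library(nrf2screen)
suppressMessages(library(dplyr))

st <- readRDS("scratch/analysis/01_screen.rds")

wells <- aggregate_image_fields(st$sim$measurements)
qc <- plate_qc_report(wells, st$sim$layout)
normalized <- intraplate_normalize(wells, st$sim$layout)
summaries <- aggregate_replicates(normalized)
entity_tbl <- per_cell_normalize(summaries)

cvp <- cv_fraction_below(filter(summaries, role == "test"), 0.10)
cat("fraction of replicate CVs below 10%:\n")
print(as.data.frame(cvp))

ctrl <- entity_tbl |>
  filter(role %in% c("keap1_control", "cul3_control", "plk1_control")) |>
  select(entity_id, luc_mean_pct, luc_sd_pct, nuc_mean_pct)
cat("\ncontrol pool performance (percent of negative controls):\n")
print(as.data.frame(ctrl), digits = 4)

write_results(qc, "results/analysis/plate_qc.tsv")
write_results(cvp, "results/analysis/cv_profile.tsv")
saveRDS(list(normalized = normalized, summaries = summaries,
             entity_tbl = entity_tbl),
        "scratch/analysis/02_normalized.rds")
cat("state -> scratch/analysis/02_normalized.rds\n")
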