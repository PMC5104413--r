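#!/usr/bin/env Rscript
# Stage 6: CSE-survival follow-up in primary bronchial epithelial cell
# plates.  Plates count only when siKEAP1 shows >= 3-fold the siControl
# ATP level; plates are acquired until at least 4 biological replicates
# pass; per-siRNA normalized means are tested against transfection-reagent
# controls with a two-sided Student's t-test.

library(nrf2screen)
suppressMessages(library(dplyr))

st1 <- readRDS("scratch/analysis/01_screen.rds")
st5 <- readRDS("scratch/analysis/05_qpcr.rds")

genes <- head(sort(st5$gene_calls$gene_id[st5$gene_calls$confirmed]), 48)
sirnas <- st5$p3$truth |>
  filter(gene_id %in% genes) |>
  mutate(protection_fold = ifelse(effective, 1 + (realized_fold - 1) * 2, 1)) |>
  select(sirna_id, gene_id, protection_fold)

sv <- simulate_survival(st1$config, sirnas, seed = st1$seed)
validity <- plate_validity(sv$atp, sv$layout)
cat(sprintf("survival plates: %d acquired, %d passed the 3-fold KEAP1 gate\n",
            nrow(validity), sum(validity$valid)))

nz <- normalize_survival(sv$atp, sv$layout)
res <- tolerance_test(nz) |>
  left_join(sv$truth |> select(entity_id = sirna_id, protection_fold),
            by = "entity_id")
sig_genes <- res |>
  filter(significant) |>
  distinct(gene_id)
support <- stratify_support(
  res |> group_by(gene_id) |>
    summarise(support_count = sum(significant),
              confirmed = any(significant), .groups = "drop"))
cat(sprintf("%d siRNAs improved CSE tolerance significantly (%d genes; support 1/2/3: %d/%d/%d)\n",
            sum(res$significant), nrow(sig_genes),
            support["1"], support["2"], support["3"]))

write_results(res, "results/analysis/survival_results.tsv")
saveRDS(res, "scratch/analysis/06_survival.rds")
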