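#!/usr/bin/env Rscript
# Stage 4: pass-2 deconvolution.  The three constituent siRNAs of every
# pass-1 hit pool are re-screened individually (384-well, same replicate
# structure); genes are confirmed when at least one siRNA reaches >= 130%
# of negative controls on the raw or per-cell metric, and stratified by
# how many independent siRNAs support them.  Pools are also compared with
# their best single siRNA by a two-sided Welch t-test.

library(nrf2screen)
suppressMessages(library(dplyr))

st1 <- readRDS("scratch/analysis/01_screen.rds")
st2 <- readRDS("scratch/analysis/02_normalized.rds")
pass1 <- readRDS("scratch/analysis/03_pass1.rds")

genes <- unique(pass1$gene_id)
deco <- simulate_deconvolution(st1$config, genes, st1$sim$truth$sirna,
                               seed = st1$seed)
deco_norm <- intraplate_normalize(aggregate_image_fields(deco$measurements),
                                  deco$layout)
deco_tbl <- per_cell_normalize(aggregate_replicates(deco_norm))

pass2 <- confirm_deconvolution(deco_tbl, genes = genes)
support <- stratify_support(pass2)
cat(sprintf("pass-2: %d/%d genes confirmed (support 1/2/3: %d/%d/%d)\n",
            sum(pass2$confirmed), length(genes),
            support["1"], support["2"], support["3"]))

# pool vs best single siRNA, on per-replicate normalized luciferase values
pool_vals <- st2$normalized |>
  filter(channel == "luminescence", gene_id %in% genes, role == "test")
single_vals <- deco_norm |>
  filter(channel == "luminescence", role == "test")
cmp <- bind_rows(lapply(genes, function(g) {
  compare_pool_vs_single(
    pool_vals$value_pct[pool_vals$gene_id == g],
    single_vals |> filter(gene_id == g) |>
      transmute(sirna_id = entity_id, value = value_pct),
    gene_id = g)
}))
cat(sprintf("pool vs best single: %d weaker, %d stronger, %d indistinguishable\n",
            sum(cmp$verdict == "pool_weaker"),
            sum(cmp$verdict == "pool_stronger"),
            sum(cmp$verdict == "indistinguishable")))

write_results(pass2, "results/analysis/pass2_calls.tsv")
write_results(cmp, "results/analysis/pool_vs_single.tsv")
saveRDS(list(deco = deco, deco_tbl = deco_tbl, pass2 = pass2),
        "scratch/analysis/04_deconvolution.rds")
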