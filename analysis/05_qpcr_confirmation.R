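#!/usr/bin/env Rscript
# Stage 5: 96-well pass-3 re-test of the confirmed genes' single siRNAs,
# then qPCR confirmation of endogenous target-gene expression: standard-
# curve relative quantification, housekeeping normalization, and hit
# calling at fold >= 1.30 with p < 0.05; concordance between reporter
# induction and expression is summarized as Pearson r on log2 ratios.

library(nrf2screen)
suppressMessages(library(dplyr))

st1 <- readRDS("scratch/analysis/01_screen.rds")
st4 <- readRDS("scratch/analysis/04_deconvolution.rds")

confirmed <- st4$pass2$gene_id[st4$pass2$confirmed]
p3 <- simulate_deconvolution(st1$config, confirmed, st1$sim$truth$sirna,
                             seed = st1$seed + 1L, format = 96)
p3_tbl <- summarise_screen(p3$measurements, p3$layout)
pass3 <- confirm_deconvolution(p3_tbl, pass_number = 3L, genes = confirmed)
s3 <- stratify_support(pass3)
cat(sprintf("pass-3 (96-well): %d/%d genes confirmed (support 1/2/3: %d/%d/%d)\n",
            sum(pass3$confirmed), length(confirmed), s3["1"], s3["2"], s3["3"]))

# qPCR follow-up on every pass-3 single siRNA
sirnas <- p3$truth |>
  mutate(expression_fold = 1 + 0.6 * (realized_fold - 1))
q <- simulate_qpcr(st1$config,
                   sirnas |> select(sample_id = sirna_id, expression_fold),
                   seed = st1$seed)
curve <- fit_standard_curve(q$standards)
cat(sprintf("standard curve: slope %.4f, efficiency %.4f\n",
            curve$slope, curve$efficiency))
quant <- q$cts |> mutate(quantity = relative_quantity(ct, curve))
expr <- normalized_fold_change(
  quant |> filter(gene == "target") |> select(sample_id, replicate, quantity),
  quant |> filter(gene == "housekeeping") |> select(sample_id, replicate, quantity),
  q$control_samples)
calls <- qpcr_hit_call(expr) |>
  left_join(p3$truth |> select(sample_id = sirna_id, gene_id), by = "sample_id")
gene_calls <- calls |>
  filter(!is.na(gene_id)) |>
  group_by(gene_id) |>
  summarise(support_count = sum(hit), confirmed = any(hit), .groups = "drop")
cat(sprintf("qPCR: %d hit siRNAs across %d confirmed genes\n",
            sum(calls$hit), sum(gene_calls$confirmed)))

paired <- p3_tbl |> inner_join(expr, by = c(entity_id = "sample_id"))
conc <- concordance(paired$luc_mean_pct / 100, paired$fold_vs_control)
cat(sprintf("reporter/expression concordance: r = %.3f (p = %.2g, n = %d)\n",
            conc$r, conc$p_value, conc$n))

write_results(pass3, "results/analysis/pass3_calls.tsv")
write_results(calls, "results/analysis/qpcr_calls.tsv")
write_results(conc, "results/analysis/concordance.tsv")
saveRDS(list(pass3 = pass3, p3 = p3, qpcr_calls = calls,
             gene_calls = gene_calls),
        "scratch/analysis/05_qpcr.rds")
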