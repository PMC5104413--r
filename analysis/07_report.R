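#!/usr/bin/env Rscript
# Stage 7: assemble the cascade report.  Counts are recomputed from the
# stage tables written by scripts 02-06 (no hidden state) and checked for
# the cascade's defining property: gene sets shrink or stay equal as the
# confirmation passes proceed.

library(nrf2screen)
suppressMessages(library(dplyr))

pass1 <- read_results("results/analysis/pass1_hits.tsv")
pass2 <- read_results("results/analysis/pass2_calls.tsv")
pass3 <- read_results("results/analysis/pass3_calls.tsv")
qpcr <- read_results("results/analysis/qpcr_calls.tsv")
surv <- read_results("results/analysis/survival_results.tsv")
cvp <- read_results("results/analysis/cv_profile.tsv")

p1 <- unique(pass1$gene_id)
p2 <- pass2$gene_id[pass2$confirmed]
p3 <- pass3$gene_id[pass3$confirmed]
pq <- unique(qpcr$gene_id[qpcr$hit & !is.na(qpcr$gene_id)])
ps <- unique(surv$gene_id[surv$significant])

stopifnot(all(p2 %in% p1), all(p3 %in% p2), all(pq %in% p3))

report <- tibble::tibble(
  stage = c("pass1_union", "pass2_confirmed", "pass3_confirmed",
            "qpcr_confirmed", "survival_significant"),
  genes = c(length(p1), length(p2), length(p3), length(pq), length(ps)))
cat("confirmation cascade (genes):\n")
print(as.data.frame(report))
cat(sprintf("\nluciferase replicate CVs below 10%%: %.1f%%\n",
            100 * cvp$fraction_below[cvp$channel == "luminescence"]))

write_results(report, "results/analysis/cascade_report.tsv")
cat("report -> results/analysis/cascade_report.tsv\n")
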