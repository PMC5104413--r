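#!/usr/bin/env Rscript
# Stage 1: draw the synthetic primary screen at the study conditions --
# 4995 druggable-genome siRNA pools randomly distributed over 19 source
# plates in 384-well format, triplicate luciferase and triplicate imaging
# replicate plates, intra-plate control quadruplicates, and 50 planted
# true activators (fold 1.3-3x) plus 25 proliferation suppressors.
#
# Well-level data go to scratch/analysis (bulky, regenerable); the ground
# truth summary goes to results/analysis.

library(nrf2screen)

seed <- 1
dir.create("scratch/analysis", recursive = TRUE, showWarnings = FALSE)
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config()
sim <- simulate_primary_screen(cfg, seed = seed)

cat(sprintf("simulated %d gene pools on %d source plates: %d measurement rows\n",
            cfg$n_genes, cfg$n_source_plates, nrow(sim$measurements)))
cat(sprintf("planted: %d activators (fold %.1f-%.1f), %d proliferation suppressors\n",
            sum(sim$truth$gene$activation_fold > 1),
            min(cfg$activator_fold_range), max(cfg$activator_fold_range),
            sum(sim$truth$gene$proliferation_fold < 1)))

saveRDS(list(config = cfg, sim = sim, seed = seed),
        "scratch/analysis/01_screen.rds")
write_results(sim$truth$gene[sim$truth$gene$activation_fold > 1 |
                               sim$truth$gene$proliferation_fold < 1, ],
              "results/analysis/planted_truth.tsv")
cat("state -> scratch/analysis/01_screen.rds\n")
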