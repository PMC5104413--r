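## End-to-end cascade orchestration: simulate (or ingest) -> normalize ->
## pass-1 hit selection -> pass-2 deconvolution -> pass-3 re-test ->
## qPCR confirmation -> CSE survival, with a run report holding every
## stage-level count, the thresholds used and the seed.

#' Summarise a screen dataset to the wide per-entity table
#'
#' Convenience composition of the normalization chain: QC-gated field
#' averaging, intra-plate percent-of-control normalization, inter-plate
#' replicate aggregation and the per-cell metric.
#'
#' @param measurements long measurement tibble (see [as_measurements()]).
#' @param layout matching [plate_layout()].
#' @return Wide entity table as returned by [per_cell_normalize()].
#' @export
summarise_screen <- function(measurements, layout) {
  wells <- aggregate_image_fields(measurements)
  normalized <- intraplate_normalize(wells, layout)
  summaries <- aggregate_replicates(normalized)
  per_cell_normalize(summaries)
}

#' Run the full screening cascade on a synthetic screen
#'
#' Executes every stage of the multi-pass workflow on data drawn from
#' [sim_config()] conditions: primary screen normalization and dual-metric
#' pass-1 selection, 384-well pass-2 deconvolution, 96-well pass-3 re-test,
#' qPCR confirmation of endogenous target-gene expression for the pass-3
#' confirmed genes, and the CSE-survival assay for up to
#' `survival_max_genes` confirmed genes.
#'
#' @param config a [sim_config()].
#' @param seed integer seed governing every stage.
#' @param sd_mult pass-1 SD multiplier (default 2).
#' @param confirm_pct pass-2/3 confirmation threshold in percent
#'   (default 130).
#' @param qpcr_fold_threshold qPCR hit fold boundary (default 1.30,
#'   inclusive).
#' @param alpha significance level for qPCR, pool-vs-single and survival
#'   tests (default 0.05).
#' @param survival_max_genes cap on genes carried into the survival assay
#'   (default 48).
#' @param outdir optional directory; when given, every stage table is
#'   written there as TSV plus a `run_report.md`.
#' @return A `screen_run_report` list: `counts` (named stage-level counts),
#'   `thresholds`, `seed`, and the per-stage tables (`entity_table`,
#'   `pass1_hits`, `pass2_calls`, `pass3_calls`, `qpcr_results`,
#'   `survival_results`, `cv_profile`, `truth`).
#' @export
run_pipeline <- function(config = sim_config(), seed = 1, sd_mult = 2,
                         confirm_pct = 130, qpcr_fold_threshold = 1.30,
                         alpha = 0.05, survival_max_genes = 48,
                         outdir = NULL) {
  ## stage 1: primary screen
  prim <- simulate_primary_screen(config, seed)
  entity_tbl <- summarise_screen(prim$measurements, prim$layout)
  cv_profile <- cv_fraction_below(
    aggregate_replicates(
      intraplate_normalize(aggregate_image_fields(prim$measurements),
                           prim$layout)) |>
      dplyr::filter(.data$role == "test"),
    threshold = 0.10)
  pass1 <- select_pass1_hits(entity_tbl, sd_mult = sd_mult)
  p1_counts <- attr(pass1, "counts")

  ## stage 2: 384-well deconvolution of pass-1 hit genes
  p1_genes <- unique(pass1$gene_id)
  deco <- simulate_deconvolution(config, p1_genes, prim$truth$sirna,
                                 seed = seed, format = 384)
  deco_tbl <- summarise_screen(deco$measurements, deco$layout)
  pass2 <- confirm_deconvolution(deco_tbl, threshold_pct = confirm_pct,
                                 pass_number = 2L, genes = p1_genes)
  p2_confirmed <- pass2$gene_id[pass2$confirmed]
  p2_support <- stratify_support(pass2)

  ## stage 3: 96-well re-test of the confirmed genes' single siRNAs
  p3 <- simulate_deconvolution(config, p2_confirmed, prim$truth$sirna,
                               seed = seed + 1L, format = 96)
  p3_tbl <- summarise_screen(p3$measurements, p3$layout)
  pass3 <- confirm_deconvolution(p3_tbl, threshold_pct = confirm_pct,
                                 pass_number = 3L, genes = p2_confirmed)
  p3_confirmed <- pass3$gene_id[pass3$confirmed]
  p3_support <- stratify_support(pass3)

  ## stage 4: qPCR confirmation, one sample per single siRNA of the pass-3
  ## confirmed genes; planted expression folds follow the reporter truth
  qpcr_sirnas <- p3$truth |>
    dplyr::filter(.data$gene_id %in% p3_confirmed) |>
    dplyr::mutate(expression_fold = 1 + 0.6 * (.data$realized_fold - 1)) |>
    dplyr::select(sample_id = "sirna_id", "expression_fold")
  qpcr_sim <- simulate_qpcr(config, qpcr_sirnas, seed = seed)
  curve <- fit_standard_curve(qpcr_sim$standards)
  quant <- qpcr_sim$cts |>
    dplyr::mutate(quantity = relative_quantity(.data$ct, curve))
  expr <- normalized_fold_change(
    target = quant |> dplyr::filter(.data$gene == "target") |>
      dplyr::select("sample_id", "replicate", "quantity"),
    housekeeping = quant |> dplyr::filter(.data$gene == "housekeeping") |>
      dplyr::select("sample_id", "replicate", "quantity"),
    control_samples = qpcr_sim$control_samples)
  qpcr_calls <- qpcr_hit_call(expr, fold_threshold = qpcr_fold_threshold,
                              alpha = alpha) |>
    dplyr::left_join(p3$truth |> dplyr::select(sample_id = "sirna_id", "gene_id"),
                     by = "sample_id")
  qpcr_gene_calls <- qpcr_calls |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(support_count = sum(.data$hit),
                     confirmed = any(.data$hit), .groups = "drop")
  qpcr_support <- stratify_support(qpcr_gene_calls)
  qpcr_genes <- qpcr_gene_calls$gene_id[qpcr_gene_calls$confirmed]

  ## stage 5: CSE survival for up to survival_max_genes confirmed genes
  surv_genes <- head(sort(qpcr_genes), survival_max_genes)
  surv_results <- NULL
  surv_sig_sirnas <- 0L
  surv_sig_genes <- 0L
  if (length(surv_genes) > 0) {
    surv_sirnas <- p3$truth |>
      dplyr::filter(.data$gene_id %in% surv_genes) |>
      dplyr::mutate(protection_fold = ifelse(.data$effective,
                                             1 + (.data$realized_fold - 1) * 2,
                                             1)) |>
      dplyr::select("sirna_id", "gene_id", "protection_fold")
    surv <- simulate_survival(config, surv_sirnas, seed = seed)
    surv_norm <- normalize_survival(surv$atp, surv$layout)
    surv_results <- tolerance_test(surv_norm, alpha = alpha)
    surv_sig_sirnas <- sum(surv_results$significant)
    surv_sig_genes <- length(unique(
      surv_results$gene_id[surv_results$significant]))
  }

  counts <- c(
    genes_screened = config$n_genes,
    pass1_raw = unname(p1_counts["n_raw"]),
    pass1_per_cell = unname(p1_counts["n_per_cell"]),
    pass1_overlap = unname(p1_counts["n_overlap"]),
    pass1_union = unname(p1_counts["n_union"]),
    pass2_confirmed = length(p2_confirmed),
    pass2_support1 = unname(p2_support["1"]),
    pass2_support2 = unname(p2_support["2"]),
    pass2_support3 = unname(p2_support["3"]),
    pass3_confirmed = length(p3_confirmed),
    pass3_support1 = unname(p3_support["1"]),
    pass3_support2 = unname(p3_support["2"]),
    pass3_support3 = unname(p3_support["3"]),
    qpcr_hit_sirnas = sum(qpcr_calls$hit),
    qpcr_confirmed_genes = length(qpcr_genes),
    survival_tested_genes = length(surv_genes),
    survival_significant_sirnas = surv_sig_sirnas,
    survival_significant_genes = surv_sig_genes)

  report <- structure(
    list(counts = counts,
         thresholds = c(pass1_raw_pct = attr(pass1, "threshold_raw"),
                        pass1_per_cell_pct = attr(pass1, "threshold_per_cell"),
                        confirm_pct = confirm_pct,
                        qpcr_fold = qpcr_fold_threshold,
                        alpha = alpha),
         seed = seed,
         cv_profile = cv_profile,
         entity_table = entity_tbl,
         pass1_hits = pass1,
         pass2_calls = pass2,
         pass3_calls = pass3,
         qpcr_results = qpcr_calls,
         survival_results = surv_results,
         truth = prim$truth),
    class = "screen_run_report")
  if (!is.null(outdir)) write_run_report(report, outdir)
  report
}

#' Write every stage table and a human-readable report
#'
#' @param report a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return `report`, invisibly.
#' @export
write_run_report <- function(report, outdir) {
  stopifnot(inherits(report, "screen_run_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("cv_profile", "entity_table", "pass1_hits", "pass2_calls",
            "pass3_calls", "qpcr_results", "survival_results")
  for (tb in tabs) {
    if (!is.null(report[[tb]])) {
      write_results(report[[tb]], file.path(outdir, paste0(tb, ".tsv")))
    }
  }
  counts_tbl <- tibble::tibble(quantity = names(report$counts),
                               value = unname(report$counts))
  write_results(counts_tbl, file.path(outdir, "run_counts.tsv"))
  md <- c("# Screen run report", "",
          sprintf("Seed: %d", report$seed), "",
          "## Thresholds", "",
          sprintf("- %s: %.4g", names(report$thresholds),
                  report$thresholds),
          "", "## Stage counts", "",
          sprintf("- %s: %d", names(report$counts), report$counts))
  writeLines(md, file.path(outdir, "run_report.md"))
  invisible(report)
}

#' @export
print.screen_run_report <- function(x, ...) {
  cat("<screen_run_report>  seed", x$seed, "\n")
  cat(sprintf("  pass-1 threshold (raw): %.1f%%  (per-cell): %.1f%%\n",
              x$thresholds["pass1_raw_pct"], x$thresholds["pass1_per_cell_pct"]))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-28s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}
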