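## Hit selection: pass-1 dual-metric mean + 2 SD thresholding, pass-2/3
## single-siRNA deconvolution with support counting, and the
## pool-versus-best-single comparison.
##
## Boundary semantics follow the screen's definitions exactly: pass 1 calls
## hits strictly GREATER than mean + 2 SD of all test pools; passes 2 and 3
## use an inclusive >= 130% confirmation threshold.

#' Mean + k SD hit-selection threshold
#'
#' Computed over the test-pool population only (controls excluded upstream);
#' SD uses the n - 1 denominator.
#'
#' @param values numeric vector of per-pool normalized means (percent).
#' @param sd_mult SD multiplier (default 2).
#' @return Threshold in percent.
#' @export
pass1_threshold <- function(values, sd_mult = 2) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop_validation("need at least 2 pool values to place a mean + k SD threshold")
  }
  mean(values) + sd_mult * sd(values)
}

#' Pass-1 dual-metric hit selection
#'
#' Thresholds the raw normalized luciferase metric and the per-cell metric
#' independently at mean + `sd_mult` SD of all test pools (strict `>`), and
#' returns the union with overlap bookkeeping.  Control pools are excluded
#' from both the threshold population and the hit list.
#'
#' @param entity_tbl wide entity table from [per_cell_normalize()].
#' @param sd_mult SD multiplier (default 2).
#' @return Hit-call tibble (`gene_id, entity_id, pass_number, route,
#'   mean_pct, per_cell_pct, confirmed, threshold_used`) where `route` is
#'   `"raw"` (raw metric only), `"per_cell"` (per-cell metric only) or
#'   `"union"` (both).  Attributes: `threshold_raw`, `threshold_per_cell`,
#'   `counts` (n_raw, n_per_cell, n_overlap, n_union).
#' @export
select_pass1_hits <- function(entity_tbl, sd_mult = 2) {
  pools <- entity_tbl |> dplyr::filter(.data$role == "test")
  thr_raw <- pass1_threshold(pools$luc_mean_pct, sd_mult)
  thr_pc <- pass1_threshold(pools$per_cell_pct, sd_mult)
  raw_hit <- !is.na(pools$luc_mean_pct) & pools$luc_mean_pct > thr_raw
  pc_hit <- !is.na(pools$per_cell_pct) & pools$per_cell_pct > thr_pc

  hits <- pools[raw_hit | pc_hit, ]
  r <- raw_hit[raw_hit | pc_hit]
  p <- pc_hit[raw_hit | pc_hit]
  out <- tibble::tibble(
    gene_id = hits$gene_id,
    entity_id = hits$entity_id,
    pass_number = 1L,
    route = dplyr::case_when(r & p ~ "union", r ~ "raw", TRUE ~ "per_cell"),
    mean_pct = hits$luc_mean_pct,
    per_cell_pct = hits$per_cell_pct,
    confirmed = TRUE,
    threshold_used = ifelse(r, thr_raw, thr_pc))
  attr(out, "threshold_raw") <- thr_raw
  attr(out, "threshold_per_cell") <- thr_pc
  attr(out, "counts") <- c(n_raw = sum(raw_hit), n_per_cell = sum(pc_hit),
                           n_overlap = sum(raw_hit & pc_hit),
                           n_union = sum(raw_hit | pc_hit))
  out
}

#' Deconvolution confirmation with per-gene support counting
#'
#' Per gene, counts the single siRNAs whose normalized luciferase mean is
#' greater than or equal to `threshold_pct` (inclusive).  A parallel
#' per-cell route confirms genes whose per-cell metric passes the same
#' threshold even when the raw metric does not.  A gene is confirmed when
#' at least one siRNA passes on either route.  The same logic serves the
#' 384-well pass 2 and the 96-well pass 3.
#'
#' @param single_tbl wide per-siRNA entity table from [per_cell_normalize()]
#'   (one row per single siRNA, `gene_id` shared within a gene).
#' @param threshold_pct confirmation threshold in percent (default 130).
#' @param pass_number 2 or 3, recorded in the output.
#' @param genes optional candidate gene list; genes with no siRNA records
#'   are skipped with a warning.
#' @return Per-gene hit-call tibble: `gene_id, pass_number, route,
#'   support_count, support_raw, support_per_cell, confirmed,
#'   threshold_used`.
#' @export
confirm_deconvolution <- function(single_tbl, threshold_pct = 130,
                                  pass_number = 2L, genes = NULL) {
  dat <- single_tbl |> dplyr::filter(.data$role == "test")
  if (!is.null(genes)) {
    absent <- setdiff(genes, unique(dat$gene_id))
    if (length(absent) > 0) {
      warn(sprintf("%d candidate gene(s) have no siRNA records and are skipped",
                   length(absent)), class = "nrf2screen_missing_entity")
    }
  }
  out <- dat |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      support_raw = sum(!is.na(.data$luc_mean_pct) &
                          .data$luc_mean_pct >= threshold_pct),
      support_per_cell = sum(!is.na(.data$per_cell_pct) &
                               .data$per_cell_pct >= threshold_pct),
      .groups = "drop") |>
    dplyr::mutate(
      confirmed = .data$support_raw >= 1L | .data$support_per_cell >= 1L,
      route = dplyr::case_when(
        .data$support_raw >= 1L & .data$support_per_cell >= 1L ~ "union",
        .data$support_raw >= 1L ~ "raw",
        .data$support_per_cell >= 1L ~ "per_cell",
        TRUE ~ NA_character_),
      support_count = ifelse(.data$support_raw >= 1L, .data$support_raw,
                             .data$support_per_cell),
      pass_number = as.integer(pass_number),
      threshold_used = threshold_pct) |>
    dplyr::select("gene_id", "pass_number", "route", "support_count",
                  "support_raw", "support_per_cell", "confirmed",
                  "threshold_used")
  out
}

#' Stratify confirmed genes by siRNA support
#'
#' @param hit_calls per-gene tibble from [confirm_deconvolution()] (or any
#'   table with `confirmed` and `support_count`).
#' @return Named integer vector with counts of confirmed genes supported by
#'   exactly 1, 2 and 3 independent siRNAs.
#' @export
stratify_support <- function(hit_calls) {
  conf <- hit_calls[hit_calls$confirmed & !is.na(hit_calls$support_count), ]
  counts <- table(factor(conf$support_count, levels = 1:3))
  stats::setNames(as.integer(counts), c("1", "2", "3"))
}

#' Compare a siRNA pool with its best single siRNA
#'
#' The best single is the constituent siRNA with the highest normalized
#' mean (ties broken by lower siRNA identifier).  Pool and best-single
#' replicate values are compared with a two-sided t-test (Welch by
#' default); the verdict follows the sign of the mean difference when
#' p < `alpha`, else `indistinguishable`.
#'
#' @param pool_values numeric vector of the pool's normalized replicate
#'   values (percent).
#' @param single_values data frame with columns `sirna_id, value` holding
#'   each constituent siRNA's normalized replicate values.
#' @param gene_id gene label carried into the output.
#' @param alpha significance level (default 0.05).
#' @param var_equal use the classical equal-variance t-test instead of
#'   Welch.
#' @return One-row tibble: `gene_id, pool_mean_pct, best_sirna_id,
#'   best_single_mean_pct, p_value, verdict, flagged`.
#' @export
compare_pool_vs_single <- function(pool_values, single_values,
                                   gene_id = NA_character_, alpha = 0.05,
                                   var_equal = FALSE) {
  means <- single_values |>
    dplyr::group_by(.data$sirna_id) |>
    dplyr::summarise(m = mean(.data$value), n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$m), .data$sirna_id)
  best <- means$sirna_id[1]
  best_vals <- single_values$value[single_values$sirna_id == best]

  flagged <- length(pool_values) < 2 || length(best_vals) < 2
  identical_samples <- !flagged &&
    length(pool_values) == length(best_vals) &&
    all(sort(pool_values) == sort(best_vals))
  if (flagged || identical_samples ||
      (sd(pool_values) == 0 && sd(best_vals) == 0)) {
    p <- if (!flagged && mean(pool_values) != mean(best_vals)) 0 else NA_real_
  } else {
    p <- t.test(pool_values, best_vals, var.equal = var_equal)$p.value
  }
  verdict <- if (flagged || is.na(p) || p >= alpha) {
    "indistinguishable"
  } else if (mean(pool_values) < mean(best_vals)) {
    "pool_weaker"
  } else {
    "pool_stronger"
  }
  tibble::tibble(
    gene_id = gene_id,
    pool_mean_pct = mean(pool_values),
    best_sirna_id = best,
    best_single_mean_pct = means$m[1],
    p_value = p,
    verdict = verdict,
    flagged = flagged)
}
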