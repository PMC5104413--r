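## CSE-tolerance survival assay for 96-well primary-cell plates:
## KEAP1-based plate validity gating, siControl normalization, the
## >= 4-valid-replicates rule and significance testing against
## transfection-reagent controls.

#' Plate validity from the KEAP1 positive control
#'
#' A survival plate counts as a biological replicate only when the mean ATP
#' of its KEAP1-knockdown wells is at least 3-fold (inclusive) the mean ATP
#' of its siControl wells.
#'
#' @param atp well-level tibble (`plate_id, well, value`; channel `atp`).
#' @param layout matching [plate_layout()] with roles `neg_control`
#'   (siControl), `keap1_control`, `reagent_only` and `test`.
#' @param min_fold validity boundary (default 3, inclusive).
#' @return Tibble per plate: `plate_id, keap1_fold, valid`.
#' @export
plate_validity <- function(atp, layout, min_fold = 3) {
  joined <- dplyr::inner_join(
    atp, layout[, c("plate_id", "well", "role")],
    by = c("plate_id", "well"))
  out <- joined |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(
      n_keap1 = sum(.data$role == "keap1_control"),
      n_ctrl = sum(.data$role == "neg_control"),
      keap1_fold = mean(.data$value[.data$role == "keap1_control"]) /
        mean(.data$value[.data$role == "neg_control"]),
      .groups = "drop")
  if (any(out$n_keap1 == 0 | out$n_ctrl == 0)) {
    stop_validation("every survival plate needs siKEAP1 and siControl wells")
  }
  out |>
    dplyr::mutate(valid = .data$keap1_fold >= min_fold) |>
    dplyr::select("plate_id", "keap1_fold", "valid")
}

#' Normalize survival ATP values to the siControl mean
#'
#' Per valid plate, the mean of each test siRNA's intra-plate duplicates
#' (and of the reagent-only wells) is divided by the plate's siControl
#' mean.  Invalid plates contribute nothing downstream.
#'
#' @inheritParams plate_validity
#' @return Tibble `plate_id, entity_id, gene_id, role, normalized_mean,
#'   n_wells` over valid plates only; attribute `validity` holds the
#'   per-plate gating table.
#' @export
normalize_survival <- function(atp, layout, min_fold = 3) {
  validity <- plate_validity(atp, layout, min_fold)
  keep <- validity$plate_id[validity$valid]
  joined <- dplyr::inner_join(
    atp, layout[, c("plate_id", "well", "role", "entity_id", "gene_id")],
    by = c("plate_id", "well")) |>
    dplyr::filter(.data$plate_id %in% keep)
  out <- joined |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::mutate(ctrl_mean = mean(.data$value[.data$role == "neg_control"])) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$role %in% c("test", "reagent_only")) |>
    dplyr::group_by(.data$plate_id, .data$entity_id, .data$gene_id, .data$role) |>
    dplyr::summarise(
      normalized_mean = mean(.data$value) / .data$ctrl_mean[1],
      n_wells = dplyr::n(),
      .groups = "drop")
  attr(out, "validity") <- validity
  out
}

#' CSE-tolerance significance test
#'
#' Per siRNA, the grand mean over per-plate normalized means is compared
#' with the per-plate normalized means of the transfection-reagent controls
#' by a two-sided Student's t-test (equal-variance by default).  Reagent
#' controls are taken from the same plates the siRNA was measured on (its
#' own biological replicates), so independent experiment batches stay
#' independent.  A siRNA is eligible for a significance call only with at
#' least `min_replicates` valid biological replicate plates; otherwise it
#' is reported as underpowered.
#'
#' @param normalized tibble from [normalize_survival()] (valid plates only).
#' @param min_replicates minimum valid plates per siRNA (default 4).
#' @param alpha significance level (default 0.05).
#' @param var_equal classical equal-variance t-test (default `TRUE`);
#'   set `FALSE` for Welch.
#' @return Tibble per test siRNA: `entity_id, gene_id, grand_mean,
#'   n_valid_replicates, p_value, significant, underpowered`.
#' @export
tolerance_test <- function(normalized, min_replicates = 4, alpha = 0.05,
                           var_equal = TRUE) {
  reagent <- normalized |>
    dplyr::filter(.data$role == "reagent_only") |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(reagent_value = mean(.data$normalized_mean),
                     .groups = "drop")
  if (nrow(reagent) < 2) {
    stop_validation("need reagent-only controls on at least 2 valid plates")
  }
  normalized |>
    dplyr::filter(.data$role == "test") |>
    dplyr::left_join(reagent, by = "plate_id") |>
    dplyr::group_by(.data$entity_id, .data$gene_id) |>
    dplyr::summarise(
      grand_mean = mean(.data$normalized_mean),
      n_valid_replicates = dplyr::n(),
      p_value = {
        ref <- .data$reagent_value[!is.na(.data$reagent_value)]
        if (dplyr::n() >= 2 && length(ref) >= 2 &&
            (sd(.data$normalized_mean) > 0 || sd(ref) > 0))
          t.test(.data$normalized_mean, ref,
                 var.equal = var_equal)$p.value else NA_real_
      },
      .groups = "drop") |>
    dplyr::mutate(
      underpowered = .data$n_valid_replicates < min_replicates,
      significant = !.data$underpowered & !is.na(.data$p_value) &
        .data$p_value < alpha)
}
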