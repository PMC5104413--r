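## Intra-plate normalization, QC gating and replicate aggregation.
##
## The screen's calculation workflow: per-field image values are QC-filtered
## and averaged to well level; every well on an experimental plate is then
## expressed as percent of the mean of that plate's 12 intra-plate
## negative-control wells; means, SDs and CVs are computed between
## inter-plate replicates per entity and channel.

#' Average image fields to well level with QC gating
#'
#' Imaging channels carry up to four fields per well, each with a boolean
#' `qc_pass` (focus/background/artifact gating performed upstream by the
#' imaging software).  Fields failing QC are dropped; wells whose fields all
#' fail are marked excluded.  Non-imaging rows pass through, with a failed
#' `qc_pass` marking the well excluded.
#'
#' @param measurements measurement tibble (see [as_measurements()]).
#' @return Well-level tibble: `plate_id, well, channel, replicate, value,
#'   excluded`.
#' @export
aggregate_image_fields <- function(measurements) {
  if (!is.data.frame(measurements) || nrow(measurements) == 0) {
    stop_validation("no measurement rows supplied")
  }
  img <- measurements[measurements$channel %in% .imaging_channels, ]
  rest <- measurements[!measurements$channel %in% .imaging_channels, ]

  out_img <- NULL
  if (nrow(img) > 0) {
    out_img <- img |>
      dplyr::group_by(.data$plate_id, .data$well, .data$channel, .data$replicate) |>
      dplyr::summarise(
        value = if (any(.data$qc_pass)) mean(.data$value[.data$qc_pass]) else NA_real_,
        excluded = !any(.data$qc_pass),
        .groups = "drop"
      )
  }
  out_rest <- NULL
  if (nrow(rest) > 0) {
    out_rest <- rest |>
      dplyr::mutate(excluded = !.data$qc_pass,
                    value = ifelse(.data$qc_pass, .data$value, NA_real_)) |>
      dplyr::select("plate_id", "well", "channel", "replicate", "value", "excluded")
  }
  dplyr::bind_rows(out_img, out_rest)
}

#' Intra-plate percent-of-control normalization
#'
#' Divides every (non-excluded) well value by the mean of the plate's
#' usable negative-control wells and multiplies by 100, separately per
#' channel and replicate plate.  Controls are normalized too, so the mean
#' of the negative-control wells is 100% by construction.  Plate-replicates
#' whose negative controls are all excluded are rejected: their wells are
#' dropped and listed in the `rejected` attribute.
#'
#' @param well_values well-level tibble from [aggregate_image_fields()].
#' @param layout [plate_layout()] assigning each well a role and entity.
#' @return Tibble of normalized wells: `plate_id, well, role, entity_id,
#'   gene_id, channel, replicate, value_pct`; attribute `rejected` holds a
#'   tibble of rejected plate/channel/replicate combinations.
#' @export
intraplate_normalize <- function(well_values, layout) {
  joined <- dplyr::inner_join(
    well_values,
    layout[, c("plate_id", "well", "role", "entity_id", "gene_id")],
    by = c("plate_id", "well"))
  if (nrow(joined) == 0) {
    stop_validation("no measurement wells match the layout")
  }
  normed <- joined |>
    dplyr::group_by(.data$plate_id, .data$channel, .data$replicate) |>
    dplyr::mutate(
      neg_mean = {
        ok <- .data$role == "neg_control" & !.data$excluded
        if (any(ok)) mean(.data$value[ok]) else NA_real_
      }
    ) |>
    dplyr::ungroup()

  rejected <- normed |>
    dplyr::filter(is.na(.data$neg_mean)) |>
    dplyr::distinct(.data$plate_id, .data$channel, .data$replicate)
  if (nrow(rejected) > 0) {
    warn(sprintf(
      "rejecting %d plate/channel/replicate combination(s) with no usable negative controls",
      nrow(rejected)), class = "nrf2screen_plate_rejected")
  }
  out <- normed |>
    dplyr::filter(!is.na(.data$neg_mean), !.data$excluded) |>
    dplyr::mutate(value_pct = 100 * .data$value / .data$neg_mean) |>
    dplyr::select("plate_id", "well", "role", "entity_id", "gene_id",
                  "channel", "replicate", "value_pct")
  attr(out, "rejected") <- rejected
  out
}

#' Per-plate QC report
#'
#' @param well_values well-level tibble from [aggregate_image_fields()].
#' @param layout matching [plate_layout()].
#' @return Tibble with one row per plate/channel/replicate: usable
#'   negative-control count and number of excluded wells.
#' @export
plate_qc_report <- function(well_values, layout) {
  dplyr::inner_join(
    well_values,
    layout[, c("plate_id", "well", "role")],
    by = c("plate_id", "well")) |>
    dplyr::group_by(.data$plate_id, .data$channel, .data$replicate) |>
    dplyr::summarise(
      usable_neg_controls = sum(.data$role == "neg_control" & !.data$excluded),
      excluded_wells = sum(.data$excluded),
      n_wells = dplyr::n(),
      .groups = "drop")
}

#' Aggregate normalized wells across replicate plates
#'
#' Sample mean, sample SD (n - 1 denominator) and CV per entity and channel
#' over inter-plate replicates.  Entities observed in a single replicate get
#' `sd_pct = NA` and `cv = NA`.  QC-excluded wells were already dropped and
#' simply reduce `n_replicates`.
#'
#' @param normalized tibble from [intraplate_normalize()].
#' @param expected_entities optional character vector; entities listed here
#'   but absent from `normalized` trigger a warning.
#' @return Entity summary tibble: `entity_id, gene_id, role, channel,
#'   mean_pct, sd_pct, cv, n_replicates`.
#' @export
aggregate_replicates <- function(normalized, expected_entities = NULL) {
  dat <- normalized |> dplyr::filter(!is.na(.data$entity_id))
  if (!is.null(expected_entities)) {
    missing_ent <- setdiff(expected_entities, unique(dat$entity_id))
    if (length(missing_ent) > 0) {
      warn(sprintf("%d expected entity(ies) absent from all plates: %s",
                   length(missing_ent),
                   paste(head(missing_ent, 5), collapse = ", ")),
           class = "nrf2screen_missing_entity")
    }
  }
  dat |>
    dplyr::group_by(.data$entity_id, .data$gene_id, .data$role, .data$channel) |>
    dplyr::summarise(
      mean_pct = mean(.data$value_pct),
      sd_pct = if (dplyr::n() > 1) sd(.data$value_pct) else NA_real_,
      n_replicates = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(cv = ifelse(.data$mean_pct > 0,
                              .data$sd_pct / .data$mean_pct, NA_real_)) |>
    dplyr::select("entity_id", "gene_id", "role", "channel",
                  "mean_pct", "sd_pct", "cv", "n_replicates")
}

#' Per-cell (proliferation-corrected) luciferase metric
#'
#' Divides each entity's normalized luciferase percent by its normalized
#' nuclei percent, x 100 — the ratio of two intra-plate-normalized
#' percentages, so plate effects cancel and the result is dimensionless.
#' Entities without a usable nuclei value are flagged and get `NA`.
#'
#' @param summaries entity summary tibble from [aggregate_replicates()]
#'   containing `luminescence` and (where imaged) `nuclei_count` rows.
#' @return Wide entity table: one row per entity with
#'   `luc_mean_pct, luc_sd_pct, luc_cv, luc_n, nuc_mean_pct, nuc_sd_pct,
#'   nuc_cv, nuc_n, per_cell_pct, per_cell_flag`.
#' @export
per_cell_normalize <- function(summaries) {
  luc <- summaries |>
    dplyr::filter(.data$channel == "luminescence") |>
    dplyr::select("entity_id", "gene_id", "role",
                  luc_mean_pct = "mean_pct", luc_sd_pct = "sd_pct",
                  luc_cv = "cv", luc_n = "n_replicates")
  nuc <- summaries |>
    dplyr::filter(.data$channel == "nuclei_count") |>
    dplyr::select("entity_id",
                  nuc_mean_pct = "mean_pct", nuc_sd_pct = "sd_pct",
                  nuc_cv = "cv", nuc_n = "n_replicates")
  out <- dplyr::left_join(luc, nuc, by = "entity_id")
  out |>
    dplyr::mutate(
      per_cell_pct = ifelse(!is.na(.data$nuc_mean_pct) & .data$nuc_mean_pct > 0,
                            100 * .data$luc_mean_pct / .data$nuc_mean_pct,
                            NA_real_),
      per_cell_flag = is.na(.data$per_cell_pct))
}

#' Fraction of entities with replicate CV below a threshold
#'
#' The screen's reproducibility metric: the share of entity-level
#' coefficients of variation (across inter-plate replicates) falling below
#' `threshold`, per channel.
#'
#' @param summaries entity summary tibble from [aggregate_replicates()].
#' @param threshold CV threshold as a fraction (default 0.10).
#' @return Tibble `channel, fraction_below, n`.
#' @export
cv_fraction_below <- function(summaries, threshold = 0.10) {
  dat <- summaries |> dplyr::filter(!is.na(.data$cv))
  if (nrow(dat) == 0) stop_validation("no entities with a defined CV")
  dat |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(fraction_below = mean(.data$cv < threshold),
                     n = dplyr::n(), .groups = "drop")
}
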