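## Long-format well measurements and result tables.
##
## One canonical long schema serves every readout of the cascade:
## plate_id, well, channel, replicate, field_index, value, qc_pass.
## Imaging channels (nuclei_count, condensation_fraction) carry one row per
## image field (up to 4 per well); all other channels one row per well.

#' Read well measurements from a delimited file
#'
#' @param path TSV/CSV with columns `plate_id, well, channel, replicate,
#'   field_index, value, qc_pass` (`field_index` and `qc_pass` optional;
#'   `qc_pass` defaults to `TRUE`).
#' @param format plate format used to validate well addresses (384 or 96).
#' @return Tibble of typed well measurements.
#' @export
read_measurements <- function(path, format = 384) {
  df <- read_delim_auto(path)
  as_measurements(df, format = format)
}

#' Coerce and validate a measurement table
#'
#' @param df data frame in the long measurement schema.
#' @inheritParams read_measurements
#' @return Validated measurement tibble.
#' @export
as_measurements <- function(df, format = 384) {
  req <- c("plate_id", "well", "channel", "replicate", "value")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop_parse(paste("measurement table is missing column(s):",
                     paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(df)
  out$plate_id <- as.character(out$plate_id)
  out$well <- parse_well(out$well, format)
  out$channel <- as.character(out$channel)
  out$replicate <- as.integer(out$replicate)
  out$value <- as.numeric(out$value)
  if (!"field_index" %in% names(out)) out$field_index <- NA_integer_
  out$field_index <- as.integer(out$field_index)
  if (!"qc_pass" %in% names(out)) out$qc_pass <- TRUE
  out$qc_pass <- as.logical(out$qc_pass)

  bad_chan <- setdiff(unique(out$channel), .channels)
  if (length(bad_chan) > 0) {
    stop_validation(paste("unknown channel(s):", paste(bad_chan, collapse = ", ")))
  }
  if (any(is.na(out$value) | out$value < 0)) {
    stop_validation(sprintf("%d measurement value(s) are negative or missing",
                            sum(is.na(out$value) | out$value < 0)))
  }
  cf <- out$channel == "condensation_fraction"
  if (any(out$value[cf] > 1)) {
    stop_validation("condensation_fraction values must lie in [0, 1]")
  }
  if (any(is.na(out$replicate) | out$replicate < 1L)) {
    stop_validation("replicate indices must be integers >= 1")
  }
  img <- out$channel %in% .imaging_channels
  if (any(img & is.na(out$field_index))) {
    stop_validation("imaging-channel rows require a field_index")
  }
  if (any(!img & !is.na(out$field_index))) {
    stop_validation("field_index is only meaningful for imaging channels")
  }
  out[, c("plate_id", "well", "channel", "replicate", "field_index",
          "value", "qc_pass")]
}

#' Write a result or hit table to TSV
#'
#' Columns are emitted in a stable order so files round-trip through
#' [read_results()] without loss.  An empty input still writes the header
#' (with a warning).
#'
#' @param rows tibble of results (e.g. entity summaries or hit calls).
#' @param path output path.
#' @return `rows`, invisibly.
#' @export
write_results <- function(rows, path) {
  if (!is.data.frame(rows)) stop_parse("write_results() expects a data frame")
  if (nrow(rows) == 0) {
    warn("writing an empty result table (header only)",
         class = "nrf2screen_empty_output")
  }
  readr::write_tsv(tibble::as_tibble(rows), path, progress = FALSE)
  invisible(rows)
}

#' Read back a result table written by [write_results()]
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Import per-gene / per-siRNA screen results from a supplementary table
#'
#' Mapping-driven importer for externally published screen summaries whose
#' column names are not fixed: `mapping` names the canonical result fields
#' and gives the source column for each.  Delimited text is read directly;
#' `.xlsx`/`.xls` files are read through the readxl package when installed.
#'
#' @param path file path (TSV/CSV, or xlsx/xls if readxl is available).
#' @param mapping named character vector mapping canonical fields
#'   (`entity_id`, `gene_id`, `normalized_mean`, and optionally
#'   `normalized_sd`, `cv`, `n_replicates`, `channel`) to source column
#'   names.
#' @param channel constant channel label used when `mapping` has no
#'   `channel` entry.
#' @param sheet sheet name or index for spreadsheet input.
#' @return Tibble in the canonical result schema.
#' @export
read_supplementary_results <- function(path, mapping,
                                       channel = "luminescence",
                                       sheet = 1) {
  need <- c("entity_id", "gene_id", "normalized_mean")
  if (!all(need %in% names(mapping))) {
    stop_parse(paste("mapping must name at least:", paste(need, collapse = ", ")))
  }
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_parse("spreadsheet input requires the readxl package")
    }
    readxl::read_excel(path, sheet = sheet)
  } else {
    read_delim_auto(path)
  }
  absent <- setdiff(unname(mapping), names(df))
  if (length(absent) > 0) {
    stop_parse(paste("source column(s) not found:", paste(absent, collapse = ", ")))
  }
  out <- tibble::tibble(
    entity_id = as.character(df[[mapping[["entity_id"]]]]),
    gene_id = as.character(df[[mapping[["gene_id"]]]]),
    channel = if ("channel" %in% names(mapping))
      as.character(df[[mapping[["channel"]]]]) else channel,
    normalized_mean = as.numeric(df[[mapping[["normalized_mean"]]]]),
    normalized_sd = if ("normalized_sd" %in% names(mapping))
      as.numeric(df[[mapping[["normalized_sd"]]]]) else NA_real_,
    cv = if ("cv" %in% names(mapping))
      as.numeric(df[[mapping[["cv"]]]]) else NA_real_,
    n_replicates = if ("n_replicates" %in% names(mapping))
      as.integer(df[[mapping[["n_replicates"]]]]) else NA_integer_
  )
  ## derive cv when sd and mean are present but cv is not
  fix <- is.na(out$cv) & !is.na(out$normalized_sd) & out$normalized_mean > 0
  out$cv[fix] <- out$normalized_sd[fix] / out$normalized_mean[fix]
  out
}
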