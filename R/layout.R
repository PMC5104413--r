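## Plate geometry and layout tables.
##
## A plate layout is a tibble with one row per well and columns
## plate_id, well, role, entity_id, gene_id, pool_index, plus a "format"
## attribute (384 or 96).  Screening layouts in 384-well format carry the
## fixed control architecture of the screen: three negative-control siRNA
## pools and the KEAP1 / CUL3 / PLK1 positive-control pools, each as an
## intra-plate quadruplicate (12 negative-control wells in total).

plate_dims <- function(format) {
  format <- as.integer(format)
  if (format == 384L) list(rows = LETTERS[1:16], cols = 1:24)
  else if (format == 96L) list(rows = LETTERS[1:8], cols = 1:12)
  else stop_validation(sprintf("unsupported plate format '%s'", format))
}

#' Well addresses of a plate format
#'
#' @param format plate format, 384 or 96.
#' @return Character vector of addresses in row-major order (A1, A2, ...).
#' @export
well_addresses <- function(format) {
  d <- plate_dims(format)
  as.vector(t(outer(d$rows, d$cols, paste0)))
}

## parse "B2"-style addresses; case-insensitive, zero padding tolerated
parse_well <- function(well, format) {
  d <- plate_dims(format)
  w <- toupper(trimws(as.character(well)))
  m <- regmatches(w, regexec("^([A-Z])0*([0-9]+)$", w))
  bad <- vapply(m, length, 1L) != 3L
  row <- vapply(m, function(x) if (length(x) == 3L) x[2] else NA_character_, "")
  col <- suppressWarnings(as.integer(
    vapply(m, function(x) if (length(x) == 3L) x[3] else NA_character_, "")))
  bad <- bad | !(row %in% d$rows) | is.na(col) | col < 1L | col > max(d$cols)
  if (any(bad)) {
    stop_parse(sprintf(
      "invalid well address(es) for %s-well format: %s",
      format, paste(unique(w[bad]), collapse = ", ")),
      rows = which(bad))
  }
  paste0(row, col)
}

#' Construct a validated plate layout
#'
#' @param df data frame with columns plate_id, well, role, entity_id,
#'   gene_id, pool_index (the last three may be NA where not applicable).
#' @param format plate format, 384 or 96.
#' @param screening logical; enforce the screening control architecture
#'   (12 negative-control wells, quadruplicate positive controls) on each
#'   384-well plate.  Default: `TRUE` when the layout contains test wells
#'   in 384-well format.
#' @return A `plate_layout` tibble (attribute `format` holds the format).
#' @export
plate_layout <- function(df, format = 384, screening = NULL) {
  req <- c("plate_id", "well", "role")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop_parse(paste("layout is missing column(s):",
                     paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(df)
  for (col in c("entity_id", "gene_id")) {
    if (!col %in% names(out)) out[[col]] <- NA_character_
    out[[col]] <- as.character(out[[col]])
  }
  if (!"pool_index" %in% names(out)) out$pool_index <- NA_integer_
  out$pool_index <- as.integer(out$pool_index)
  out$plate_id <- as.character(out$plate_id)
  out$role <- as.character(out$role)
  out$well <- parse_well(out$well, format)
  out <- out[, c("plate_id", "well", "role", "entity_id", "gene_id", "pool_index")]
  attr(out, "format") <- as.integer(format)
  class(out) <- c("plate_layout", class(out))
  if (is.null(screening)) {
    screening <- as.integer(format) == 384L && any(out$role == "test")
  }
  validate_layout(out, screening = screening)
  out
}

#' Validate a plate layout
#'
#' Checks role vocabulary, per-plate well uniqueness, entity presence on
#' test wells and (for screening layouts) the control architecture: exactly
#' 12 negative-control wells (3 pools x intra-plate quadruplicates) and a
#' quadruplicate of each positive-control pool per plate.
#'
#' @param layout a [plate_layout()].
#' @param screening enforce the screening control counts.
#' @return `layout`, invisibly.
#' @export
validate_layout <- function(layout, screening = TRUE) {
  bad_role <- setdiff(unique(layout$role), .roles)
  if (length(bad_role) > 0) {
    stop_validation(paste("unknown role(s):", paste(bad_role, collapse = ", ")))
  }
  dup <- layout |>
    dplyr::count(.data$plate_id, .data$well) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_validation(sprintf(
      "duplicate well assignment(s): %s",
      paste(paste0(dup$plate_id, ":", dup$well), collapse = ", ")))
  }
  no_entity <- layout$role == "test" & (is.na(layout$entity_id) | layout$entity_id == "")
  if (any(no_entity)) {
    stop_validation(sprintf("%d test well(s) lack an entity_id", sum(no_entity)))
  }
  has_entity <- layout$role == "empty" & !is.na(layout$entity_id)
  if (any(has_entity)) {
    stop_validation("empty wells must not carry an entity_id")
  }
  if (isTRUE(screening)) {
    counts <- layout |>
      dplyr::count(.data$plate_id, .data$role) |>
      tidyr::pivot_wider(names_from = "role", values_from = "n", values_fill = 0L)
    for (i in seq_len(nrow(counts))) {
      neg <- if ("neg_control" %in% names(counts)) counts$neg_control[i] else 0L
      if (neg != 12L) {
        stop_validation(sprintf(
          "plate %s has %d negative-control wells; a screening plate must have 12 (3 pools x 4)",
          counts$plate_id[i], neg))
      }
      for (ctl in c("keap1_control", "cul3_control", "plk1_control")) {
        nctl <- if (ctl %in% names(counts)) counts[[ctl]][i] else 0L
        if (nctl != 4L) {
          stop_validation(sprintf(
            "plate %s has %d %s wells; expected an intra-plate quadruplicate",
            counts$plate_id[i], nctl, ctl))
        }
      }
    }
  }
  invisible(layout)
}

#' Read a plate map from a delimited file
#'
#' Expects a TSV/CSV with header columns `plate_id, well, role, entity_id,
#' gene_id, pool_index` (delimiter sniffed from the first line).  Well
#' addresses are case-insensitive and normalized to upper case.
#'
#' @param path file path.
#' @param format plate format (384 or 96) or `"auto"` to infer: 96 when all
#'   addresses fit an 8 x 12 grid, else 384.
#' @inheritParams plate_layout
#' @return A validated [plate_layout()].
#' @export
read_plate_map <- function(path, format = "auto", screening = NULL) {
  df <- read_delim_auto(path)
  if (identical(format, "auto")) {
    w <- toupper(trimws(as.character(df$well)))
    rowl <- substr(w, 1, 1)
    coln <- suppressWarnings(as.integer(sub("^[A-Za-z]0*", "", w)))
    format <- if (all(rowl %in% LETTERS[1:8], na.rm = TRUE) &&
                  all(coln <= 12L, na.rm = TRUE)) 96L else 384L
  }
  plate_layout(df, format = format, screening = screening)
}

## delimiter-sniffing reader shared by the table importers
read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, na = c("", "NA"))
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d-well format, %d plate(s), %d wells\n",
              attr(x, "format"), length(unique(x$plate_id)), nrow(x)))
  NextMethod()
}
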