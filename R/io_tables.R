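#' @name io_tables
#' @title Tabular input/output for tracked objects
#'
#' @description
#' The pipeline consumes long-format per-object time series exported from
#' image-analysis software. Two on-disk dialects are supported:
#'
#' * `"long"` — one CSV, one row per object per time point, with the
#'   canonical column names documented in [read_track_table()].
#' * `"imaris_split"` — a directory of one-statistic-per-file CSVs (the
#'   layout produced by common commercial tracking software), joined on
#'   shared object id and time columns through a configurable alias table.
#'
#' Time is always converted to minutes; coordinates are isotropic microns.
NULL

track_mandatory_cols <- c("experiment_id", "well_id", "cell_id", "t",
                          "x", "y", "z", "speed", "sq_displacement")
track_optional_cols <- c("population", "dye_intensity", "dist_organoid",
                         "dist_tcell", "marker_intensity")
organoid_mandatory_cols <- c("experiment_id", "well_id", "organoid_id", "t",
                             "area", "volume", "dye_intensity")
organoid_optional_cols <- c("x", "y", "z", "dye_rescaled")

#' Default column alias table for the split-file dialect
#'
#' Maps one-statistic-per-file CSV stems and their value columns onto the
#' canonical long-format schema. Vendors differ in export naming, so the
#' table is user-overridable: supply a data frame with columns `file_stem`
#' (CSV file name without extension), `value_col` (column holding the
#' statistic in that file) and `canonical` (target column name).
#'
#' @return a tibble with columns `file_stem`, `value_col`, `canonical`.
#' @export
imaris_alias_table <- function() {
  tibble::tribble(
    ~file_stem,            ~value_col,        ~canonical,
    "Position",            "Position X",      "x",
    "Position",            "Position Y",      "y",
    "Position",            "Position Z",      "z",
    "Speed",               "Speed",           "speed",
    "Displacement_2",      "Displacement^2",  "sq_displacement",
    "Intensity_Mean_Ch3",  "Intensity Mean",  "dye_intensity",
    "Distance_to_Organoid","Distance",        "dist_organoid",
    "Distance_to_TCell",   "Distance",        "dist_tcell",
    "Area",                "Area",            "area",
    "Volume",              "Volume",          "volume"
  )
}

validate_keys <- function(tbl, id_col, what) {
  dup <- tbl |>
    dplyr::count(.data$experiment_id, .data$well_id,
                 .data[[id_col]], .data$t) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop_cotrack(
      sprintf("duplicated (%s, t) keys in %s: e.g. %s=%s t=%s",
              id_col, what, id_col, dup[[id_col]][1], dup$t[1]),
      "cotrack_integrity_error"
    )
  }
  invisible(tbl)
}

# all present time points within one (experiment, well) must sit on one
# uniform frame grid; dt is undefined for single-frame groups
check_frame_interval <- function(tbl) {
  bad <- tbl |>
    dplyr::distinct(.data$experiment_id, .data$well_id, .data$t) |>
    dplyr::group_by(.data$experiment_id, .data$well_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      dt = if (dplyr::n() > 1) min(diff(sort(unique(.data$t)))) else NA_real_,
      ok = dplyr::n() <= 1 ||
        all(abs(((sort(unique(.data$t)) - min(.data$t)) / dt) -
                  round((sort(unique(.data$t)) - min(.data$t)) / dt)) < 1e-6),
      offending = paste(head(sort(unique(.data$t)), 8), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0L) {
    stop_cotrack(
      sprintf("non-uniform frame interval in well %s/%s (times %s)",
              bad$experiment_id[1], bad$well_id[1], bad$offending[1]),
      "cotrack_integrity_error"
    )
  }
  invisible(tbl)
}

require_cols <- function(tbl, cols, what) {
  miss <- setdiff(cols, names(tbl))
  if (length(miss) > 0L) {
    stop_cotrack(
      sprintf("missing mandatory column(s) in %s: %s",
              what, paste(miss, collapse = ", ")),
      "cotrack_schema_error"
    )
  }
  invisible(tbl)
}

finalize_track_table <- function(tbl) {
  require_cols(tbl, track_mandatory_cols, "track table")
  for (col in track_optional_cols) {
    if (!col %in% names(tbl)) {
      tbl[[col]] <- if (col == "population") NA_character_ else NA_real_
    }
  }
  tbl <- tbl |>
    dplyr::mutate(
      population = dplyr::coalesce(as.character(.data$population), "unknown"),
      dplyr::across(dplyr::all_of(c("t", "x", "y", "z", "speed",
                                    "sq_displacement", "dye_intensity",
                                    "dist_organoid", "dist_tcell",
                                    "marker_intensity")), as.numeric),
      cell_id = as.integer(.data$cell_id)
    ) |>
    dplyr::select(dplyr::all_of(c(
      "experiment_id", "well_id", "cell_id", "population", "t",
      "x", "y", "z", "speed", "sq_displacement", "dye_intensity",
      "dist_organoid", "dist_tcell", "marker_intensity"
    ))) |>
    dplyr::arrange(.data$experiment_id, .data$well_id, .data$cell_id, .data$t)
  num <- tbl$speed[!is.na(tbl$speed)]
  sqd <- tbl$sq_displacement[!is.na(tbl$sq_displacement)]
  if (any(!is.finite(num)) || any(!is.finite(sqd))) {
    stop_cotrack("non-finite speed or sq_displacement values",
                 "cotrack_integrity_error")
  }
  if (any(num < 0) || any(sqd < 0)) {
    stop_cotrack("negative speed or sq_displacement values",
                 "cotrack_integrity_error")
  }
  validate_keys(tbl, "cell_id", "track table")
  check_frame_interval(tbl)
  tbl
}

finalize_organoid_table <- function(tbl) {
  require_cols(tbl, organoid_mandatory_cols, "organoid table")
  for (col in organoid_optional_cols) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_real_
  }
  tbl <- tbl |>
    dplyr::mutate(
      dplyr::across(dplyr::all_of(c("t", "x", "y", "z", "area", "volume",
                                    "dye_intensity", "dye_rescaled")),
                    as.numeric),
      organoid_id = as.integer(.data$organoid_id)
    ) |>
    dplyr::select(dplyr::all_of(c(
      "experiment_id", "well_id", "organoid_id", "t", "x", "y", "z",
      "area", "volume", "dye_intensity", "dye_rescaled"
    ))) |>
    dplyr::arrange(.data$experiment_id, .data$well_id,
                   .data$organoid_id, .data$t)
  if (any(tbl$area <= 0, na.rm = TRUE) || any(tbl$volume <= 0, na.rm = TRUE)) {
    stop_cotrack("organoid area and volume must be > 0",
                 "cotrack_integrity_error")
  }
  validate_keys(tbl, "organoid_id", "organoid table")
  check_frame_interval(tbl)
  tbl
}

read_split_dir <- function(path, aliases, id_col, time_unit) {
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0L) {
    stop_cotrack(sprintf("no CSV files in split directory %s", path),
                 "cotrack_io_error")
  }
  stems <- sub("\\.csv$", "", basename(files))
  pieces <- purrr::map2(files, stems, function(f, stem) {
    raw <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    map <- aliases[aliases$file_stem == stem, , drop = FALSE]
    if (nrow(map) == 0L) return(NULL)
    keep <- intersect(map$value_col, names(raw))
    key_cols <- intersect(c("experiment_id", "well_id", "ID", "Time"),
                          names(raw))
    out <- raw[, c(key_cols, keep), drop = FALSE]
    for (k in seq_along(keep)) {
      names(out)[names(out) == keep[k]] <-
        map$canonical[map$value_col == keep[k]]
    }
    out
  })
  pieces <- purrr::compact(pieces)
  if (length(pieces) == 0L) {
    stop_cotrack("no split files matched the alias table",
                 "cotrack_schema_error")
  }
  joined <- purrr::reduce(pieces, dplyr::full_join,
                          by = intersect(c("experiment_id", "well_id",
                                           "ID", "Time"),
                                         names(pieces[[1]])))
  joined |>
    dplyr::rename(t = "Time") |>
    dplyr::mutate(t = .data$t * time_unit) |>
    dplyr::rename(!!id_col := "ID")
}

#' Read a tracked T cell table
#'
#' @param path a CSV file (`dialect = "long"`) or a directory of
#'   one-statistic-per-file CSVs (`dialect = "imaris_split"`).
#' @param dialect `"long"` or `"imaris_split"`.
#' @param aliases alias table for the split dialect; see
#'   [imaris_alias_table()].
#' @param time_unit minutes per unit of the on-disk time column (use e.g.
#'   `30` when the export counts frames at a 30-min interval). Default 1
#'   (time already in minutes).
#' @return a validated track tibble with columns `experiment_id`,
#'   `well_id`, `cell_id`, `population`, `t` (minutes), `x`, `y`, `z`
#'   (microns), `speed` (um/min), `sq_displacement` (um^2),
#'   `dye_intensity`, `dist_organoid`, `dist_tcell`, `marker_intensity`.
#'   Missing optional columns are filled with `NA`.
#' @export
read_track_table <- function(path, dialect = c("long", "imaris_split"),
                             aliases = imaris_alias_table(), time_unit = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_cotrack(sprintf("path does not exist: %s", path), "cotrack_io_error")
  }
  tbl <- switch(dialect,
    long = readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
      dplyr::mutate(t = .data$t * time_unit),
    imaris_split = read_split_dir(path, aliases, "cell_id", time_unit)
  )
  if (dialect == "imaris_split") {
    if (!"experiment_id" %in% names(tbl)) tbl$experiment_id <- "exp1"
    if (!"well_id" %in% names(tbl)) tbl$well_id <- "w1"
  }
  finalize_track_table(tibble::as_tibble(tbl))
}

#' Read a tracked organoid table
#'
#' @inheritParams read_track_table
#' @return a validated organoid tibble with columns `experiment_id`,
#'   `well_id`, `organoid_id`, `t` (minutes), `x`, `y`, `z`, `area`
#'   (um^2), `volume` (um^3), `dye_intensity`, `dye_rescaled`.
#' @export
read_organoid_table <- function(path, dialect = c("long", "imaris_split"),
                                aliases = imaris_alias_table(),
                                time_unit = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_cotrack(sprintf("path does not exist: %s", path), "cotrack_io_error")
  }
  tbl <- switch(dialect,
    long = readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
      dplyr::mutate(t = .data$t * time_unit),
    imaris_split = read_split_dir(path, aliases, "organoid_id", time_unit)
  )
  if (dialect == "imaris_split") {
    if (!"experiment_id" %in% names(tbl)) tbl$experiment_id <- "exp1"
    if (!"well_id" %in% names(tbl)) tbl$well_id <- "w1"
  }
  finalize_organoid_table(tibble::as_tibble(tbl))
}

#' Write a validated table to disk
#'
#' Columns are written in the canonical order, UTF-8 encoded, with missing
#' values as empty fields, so that `read_*(write_table(x))` round-trips.
#'
#' @param table a track or organoid tibble.
#' @param path output file path.
#' @param format currently only `"csv"`.
#' @return the path, invisibly.
#' @export
write_table <- function(table, path, format = "csv") {
  if (!identical(format, "csv")) {
    stop_cotrack(sprintf("unknown format '%s'", format), "cotrack_io_error")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop_cotrack(sprintf("directory does not exist: %s", dir),
                 "cotrack_io_error")
  }
  readr::write_csv(table, path, na = "", progress = FALSE)
  invisible(path)
}
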