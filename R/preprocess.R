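#' @name preprocess
#' @title From raw tracks to fixed-length binarized feature series
#'
#' @description
#' The behavioral atlas and classifier operate on fixed-length multivariate
#' series with five channels per frame: speed (um/min), square displacement
#' (um^2), organoid contact (0/1), T cell interaction (0/1) and death
#' (0/1, absorbing). This module linearly interpolates interior gaps on the
#' numeric source channels, binarizes distances and dye against thresholds,
#' and cuts tracks to a common window (3.3 h by default).
NULL

#' Linearly interpolate interior gaps in tracks
#'
#' Missing frames strictly between a cell's first and last observation are
#' filled on the uniform frame grid; numeric channels are interpolated
#' piecewise-linearly. Distances and dye are interpolated on the numeric
#' source, before any binarization. Leading/trailing missing frames are
#' never extrapolated. Tracks with fewer than two observed frames are
#' passed through unchanged with a warning.
#'
#' @param tracks a track tibble (see [read_track_table()]).
#' @param dt frame interval in minutes; if `NULL`, inferred per
#'   (experiment, well) as the minimal observed time difference.
#' @return the track tibble with interior gap rows added.
#' @export
interpolate_gaps <- function(tracks, dt = NULL) {
  num_cols <- c("x", "y", "z", "speed", "sq_displacement", "dye_intensity",
                "dist_organoid", "dist_tcell", "marker_intensity")
  num_cols <- intersect(num_cols, names(tracks))
  short <- 0L
  out <- tracks |>
    dplyr::group_by(.data$experiment_id, .data$well_id, .data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2L) {
        short <<- short + 1L
        return(df)
      }
      step <- dt %||% min(diff(sort(df$t)))
      grid <- seq(min(df$t), max(df$t), by = step)
      if (length(grid) == nrow(df)) return(df)  # no interior gaps
      filled <- tibble::tibble(t = grid)
      for (col in setdiff(names(df), "t")) {
        if (col %in% num_cols) {
          obs <- !is.na(df[[col]])
          filled[[col]] <- if (sum(obs) >= 2) {
            approx(df$t[obs], df[[col]][obs], xout = grid, rule = 1)$y
          } else {
            rep(if (sum(obs) == 1) df[[col]][obs] else NA_real_,
                length(grid))
          }
        } else {
          filled[[col]] <- df[[col]][1]
        }
      }
      filled[, names(df)]
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(names(tracks)))
  if (short > 0L) {
    warn(sprintf("%d track(s) with < 2 frames left uninterpolated", short))
  }
  out
}

#' Binarize distance and dye channels
#'
#' Adds the binary behavioral channels to a track tibble:
#' * `contact` = 1 iff `dist_organoid <= contact_thresh`;
#' * `tcell_interaction` = 1 iff `dist_tcell <= interaction_thresh`;
#' * `death` = 1 from the first frame with
#'   `dye_intensity >= death_dye_thresh` onward (death is absorbing, so
#'   monotonicity is enforced within each track).
#'
#' Tracks whose distance channel is entirely missing get `contact` (or
#' `tcell_interaction`) set to `NA` and are flagged in the
#' `"flagged_cells"` attribute.
#'
#' @param tracks track tibble.
#' @param contact_thresh contact threshold on `dist_organoid`, um
#'   (default 5, surface-to-surface).
#' @param interaction_thresh threshold on `dist_tcell`, um (default 10,
#'   center-to-center).
#' @param death_dye_thresh dead-cell dye intensity threshold (a.u.).
#' @return the tibble with `contact`, `tcell_interaction`, `death` columns.
#' @export
binarize_tracks <- function(tracks, contact_thresh = 5,
                            interaction_thresh = 10,
                            death_dye_thresh = 20) {
  stopifnot(contact_thresh > 0, interaction_thresh > 0, death_dye_thresh > 0)
  out <- tracks |>
    dplyr::group_by(.data$experiment_id, .data$well_id, .data$cell_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(
      contact = as.integer(.data$dist_organoid <= contact_thresh),
      tcell_interaction = as.integer(.data$dist_tcell <= interaction_thresh),
      death = as.integer(cummax(dplyr::coalesce(
        as.integer(.data$dye_intensity >= death_dye_thresh), 0L))),
      .all_na_contact = all(is.na(.data$dist_organoid))
    ) |>
    dplyr::ungroup()
  flagged <- out |>
    dplyr::filter(.data$.all_na_contact) |>
    dplyr::distinct(.data$experiment_id, .data$well_id, .data$cell_id)
  out <- dplyr::select(out, -".all_na_contact")
  attr(out, "flagged_cells") <- flagged
  out
}

#' Two-threshold marker gating
#'
#' Tri-state gate on a marker intensity (e.g. a surface-marker prelabel):
#' values at or below `low` are negative, at or above `high` positive, and
#' values between the two thresholds are indeterminate, ensuring that only
#' confidently negative/positive cells are called.
#'
#' @param intensity numeric vector of marker intensities.
#' @param low,high gate thresholds, `0 < low < high`.
#' @return factor with levels `neg`, `indeterminate`, `pos`.
#' @export
#' @examples
#' gate_marker(c(2, 7, 12), low = 5, high = 10)
gate_marker <- function(intensity, low, high) {
  stopifnot(low > 0, high > low)
  out <- dplyr::case_when(
    intensity <= low ~ "neg",
    intensity >= high ~ "pos",
    is.na(intensity) ~ NA_character_,
    TRUE ~ "indeterminate"
  )
  factor(out, levels = c("neg", "indeterminate", "pos"))
}

#' Rescale dead-cell dye to a 0-100 range per experiment
#'
#' Affine min-max rescaling within each `experiment_id`, normalizing for
#' between-experiment variation in absolute dye intensity. A constant dye
#' channel (zero range) maps to all zeros with a warning.
#'
#' @param tbl a tibble with `experiment_id` and the dye column.
#' @param col name of the dye column (default `"dye_intensity"`).
#' @param out_col name of the rescaled output column.
#' @return the tibble with `out_col` added.
#' @export
rescale_dye <- function(tbl, col = "dye_intensity",
                        out_col = "dye_rescaled") {
  out <- tbl |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::mutate(
      .rng = diff(range(.data[[col]], na.rm = TRUE)),
      !!out_col := dplyr::if_else(
        .data$.rng > 0,
        100 * (.data[[col]] - min(.data[[col]], na.rm = TRUE)) / .data$.rng,
        0
      )
    ) |>
    dplyr::ungroup()
  if (any(out$.rng == 0, na.rm = TRUE)) {
    warn("constant dye channel in at least one experiment; rescaled to 0")
  }
  dplyr::select(out, -".rng")
}

#' Cut tracks to a fixed-length window
#'
#' Cuts each track to `L = floor(window_h * 60 / dt) + 1` frames taken
#' from the start of the track, so that series of equal length can be
#' compared by dynamic time warping. Tracks shorter than `L` frames are
#' discarded; the number discarded is recorded in the `"n_discarded"`
#' attribute.
#'
#' @param tracks track tibble with binary channels (see
#'   [binarize_tracks()]); frame interval must be uniform within each
#'   experiment.
#' @param window_h window length in hours (default 3.3).
#' @param dt frame interval in minutes; inferred if `NULL`.
#' @return a feature-series tibble: one row per cell per frame with
#'   `frame` (1..L) plus the five behavioral channels; attribute
#'   `"frames_per_track"` holds L and `"dt"` the frame interval.
#' @export
cut_to_window <- function(tracks, window_h = 3.3, dt = NULL) {
  dt <- dt %||% {
    ts <- tracks |>
      dplyr::distinct(.data$experiment_id, .data$well_id, .data$t)
    tt <- sort(unique(ts$t))
    if (length(tt) < 2) stop_cotrack("cannot infer dt from a single frame",
                                     "cotrack_config_error")
    min(diff(tt))
  }
  L <- floor(window_h * 60 / dt) + 1L
  if (L < 2L) {
    stop_cotrack(sprintf("window of %.2f h covers < 2 frames at dt = %g min",
                         window_h, dt), "cotrack_config_error")
  }
  out <- tracks |>
    dplyr::group_by(.data$experiment_id, .data$well_id, .data$cell_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(frame = dplyr::row_number(), .n = dplyr::n()) |>
    dplyr::ungroup()
  n_discarded <- out |>
    dplyr::filter(.data$.n < L) |>
    dplyr::distinct(.data$experiment_id, .data$well_id, .data$cell_id) |>
    nrow()
  out <- out |>
    dplyr::filter(.data$.n >= L, .data$frame <= L) |>
    dplyr::select(-".n")
  attr(out, "frames_per_track") <- L
  attr(out, "dt") <- dt
  attr(out, "n_discarded") <- n_discarded
  out
}

#' Full preprocessing: interpolate, binarize, cut
#'
#' Convenience wrapper chaining [interpolate_gaps()], [binarize_tracks()]
#' and [cut_to_window()] with shared defaults.
#'
#' @inheritParams interpolate_gaps
#' @inheritParams binarize_tracks
#' @inheritParams cut_to_window
#' @return a feature-series tibble (see [cut_to_window()]).
#' @export
preprocess_tracks <- function(tracks, dt = NULL, window_h = 3.3,
                              contact_thresh = 5, interaction_thresh = 10,
                              death_dye_thresh = 20) {
  tracks |>
    interpolate_gaps(dt = dt) |>
    binarize_tracks(contact_thresh = contact_thresh,
                    interaction_thresh = interaction_thresh,
                    death_dye_thresh = death_dye_thresh) |>
    cut_to_window(window_h = window_h, dt = dt)
}

# internal: split a feature-series tibble into a named list of L x C
# matrices (one per cell), in a stable cell order
series_matrices <- function(series,
                            channels = c("speed", "sq_displacement",
                                         "contact", "tcell_interaction",
                                         "death")) {
  miss <- setdiff(channels, names(series))
  if (length(miss) > 0) {
    stop_cotrack(sprintf("missing channel(s): %s",
                         paste(miss, collapse = ", ")),
                 "cotrack_schema_error")
  }
  split_df <- series |>
    dplyr::arrange(.data$experiment_id, .data$well_id, .data$cell_id,
                   .data$frame)
  lens <- split_df |>
    dplyr::count(.data$experiment_id, .data$well_id, .data$cell_id)
  if (length(unique(lens$n)) > 1) {
    stop_cotrack("series have unequal lengths; run cut_to_window() first",
                 "cotrack_integrity_error")
  }
  # count() orders groups exactly as group_map() below does
  keys <- dplyr::select(lens, -"n")
  mats <- split_df |>
    dplyr::group_by(.data$experiment_id, .data$well_id, .data$cell_id) |>
    dplyr::group_map(~ as.matrix(.x[, channels, drop = FALSE]))
  names(mats) <- paste(keys$experiment_id, keys$well_id, keys$cell_id,
                       sep = "/")
  list(matrices = mats, keys = keys, channels = channels)
}
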