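#' @name engagement
#' @title Cluster-specific T cell engagement and killing correlation
#'
#' @description
#' To relate single-organoid death dynamics to behavior-specific T cell
#' engagement, each labelled T cell frame is assigned to its nearest
#' organoid (within a contact threshold), contacts are accumulated per
#' organoid per signature over time, and a trailing sliding-window
#' Pearson correlation relates the cumulative contact count to the
#' frame-to-frame increase in rescaled dead-cell dye.
NULL

#' Cumulative per-signature organoid contacts
#'
#' For each organoid frame, counts the T cells of each signature whose
#' position lies within `contact_thresh` of the organoid center and for
#' which this organoid is the nearest, then accumulates counts over time.
#' Track frames are matched to the organoid time grid by nearest frame
#' when the grids differ (reported via message).
#'
#' @param organoids organoid tibble with positions and `dye_rescaled`.
#' @param tracks track tibble with positions.
#' @param labels tibble with key columns and `signature` (e.g. from
#'   [classify_tracks()]).
#' @param contact_thresh contact radius in um (default 50; center-to-center
#'   distances are larger than the surface-to-surface distances used for
#'   track binarization).
#' @return a `contact_ledger` tibble: `experiment_id`, `well_id`,
#'   `organoid_id`, `t`, `signature`, `contacts` (instantaneous),
#'   `cum_contacts` (non-decreasing), `dye_increase` (first difference of
#'   `dye_rescaled`, floored at 0).
#' @export
cumulative_contacts <- function(organoids, tracks, labels,
                                contact_thresh = 50) {
  by_cols <- intersect(c("experiment_id", "well_id", "cell_id"),
                       names(labels))
  tr <- tracks |>
    dplyr::inner_join(
      dplyr::select(labels, dplyr::all_of(c(by_cols, "signature"))),
      by = by_cols
    )
  grids_differ <- FALSE
  ledger <- organoids |>
    dplyr::group_by(.data$experiment_id, .data$well_id) |>
    dplyr::group_modify(function(org, key) {
      cells <- tr |>
        dplyr::filter(.data$experiment_id == key$experiment_id,
                      .data$well_id == key$well_id)
      org_t <- sort(unique(org$t))
      if (nrow(cells) > 0 && !all(cells$t %in% org_t)) {
        grids_differ <<- TRUE
        cells$t <- vapply(cells$t,
                          function(ti) org_t[which.min(abs(org_t - ti))],
                          numeric(1))
      }
      sigs <- sort(unique(tr$signature))
      grid <- tidyr::expand_grid(
        organoid_id = sort(unique(org$organoid_id)),
        t = org_t, signature = sigs
      )
      if (nrow(cells) == 0) {
        counts <- grid |> dplyr::mutate(contacts = 0L)
      } else {
        org_pos <- org |>
          dplyr::select(dplyr::all_of(c("organoid_id", "t", "x", "y", "z")))
        hits <- cells |>
          dplyr::inner_join(org_pos, by = "t", suffix = c("", ".org"),
                            relationship = "many-to-many") |>
          dplyr::mutate(d = sqrt((.data$x - .data$x.org)^2 +
                                   (.data$y - .data$y.org)^2 +
                                   (.data$z - .data$z.org)^2)) |>
          dplyr::group_by(.data$cell_id, .data$t) |>
          dplyr::slice_min(.data$d, n = 1, with_ties = FALSE) |>
          dplyr::ungroup() |>
          dplyr::filter(.data$d <= contact_thresh)
        counts <- hits |>
          dplyr::count(.data$organoid_id, .data$t, .data$signature,
                       name = "contacts") |>
          dplyr::right_join(grid,
                            by = c("organoid_id", "t", "signature")) |>
          dplyr::mutate(contacts = dplyr::coalesce(.data$contacts, 0L))
      }
      dye <- org |>
        dplyr::group_by(.data$organoid_id) |>
        dplyr::arrange(.data$t, .by_group = TRUE) |>
        dplyr::mutate(dye_increase = pmax(0, .data$dye_rescaled -
                                            dplyr::lag(.data$dye_rescaled,
                                                       default = NA))) |>
        dplyr::ungroup() |>
        dplyr::select(dplyr::all_of(c("organoid_id", "t", "dye_increase")))
      counts |>
        dplyr::group_by(.data$organoid_id, .data$signature) |>
        dplyr::arrange(.data$t, .by_group = TRUE) |>
        dplyr::mutate(cum_contacts = cumsum(.data$contacts)) |>
        dplyr::ungroup() |>
        dplyr::left_join(dye, by = c("organoid_id", "t"))
    }) |>
    dplyr::ungroup()
  if (grids_differ) {
    message("track and organoid time grids differ; ",
            "tracks snapped to the organoid grid")
  }
  class(ledger) <- c("contact_ledger", class(ledger))
  ledger
}

#' Sliding-window correlation between engagement and dying
#'
#' At every trailing window of `window_h` hours ending at time t, the
#' Pearson correlation between the window's cumulative contact counts and
#' its dye increases is computed per organoid and signature. Windows in
#' which either variable is constant yield `NA`. The per-time-point mean
#' across organoids (ignoring `NA`) summarizes each signature's
#' engagement-killing coupling over time.
#'
#' @param ledger a `contact_ledger` from [cumulative_contacts()].
#' @param window_h window length in hours (default 3).
#' @param dt frame interval in minutes; inferred from the ledger grid if
#'   `NULL`.
#' @return list with `per_organoid` (organoid x signature x window-end r)
#'   and `mean_r` (`signature`, `t`, `mean_r`, `n_organoids`); class
#'   `engagement_correlation`.
#' @export
sliding_window_correlation <- function(ledger, window_h = 3, dt = NULL) {
  tt <- sort(unique(ledger$t))
  if (length(tt) < 2) {
    warn("fewer than 2 frames in ledger; empty result")
    return(structure(list(per_organoid = tibble::tibble(),
                          mean_r = tibble::tibble()),
                     class = "engagement_correlation"))
  }
  dt <- dt %||% min(diff(tt))
  w <- floor(window_h * 60 / dt) + 1L
  if (w > length(tt)) {
    warn("window longer than the observed series; empty result")
    return(structure(list(per_organoid = tibble::tibble(),
                          mean_r = tibble::tibble()),
                     class = "engagement_correlation"))
  }
  per_organoid <- ledger |>
    dplyr::filter(!is.na(.data$dye_increase)) |>
    dplyr::group_by(.data$experiment_id, .data$well_id, .data$organoid_id,
                    .data$signature) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < w) return(tibble::tibble(t = numeric(0), r = numeric(0)))
      ends <- w:n
      r <- vapply(ends, function(i) {
        xs <- df$cum_contacts[(i - w + 1):i]
        ys <- df$dye_increase[(i - w + 1):i]
        if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
        cor(xs, ys)
      }, numeric(1))
      tibble::tibble(t = df$t[ends], r = r)
    }) |>
    dplyr::ungroup()
  mean_r <- per_organoid |>
    dplyr::group_by(.data$signature, .data$t) |>
    dplyr::summarise(mean_r = if (all(is.na(.data$r))) NA_real_ else
                       mean(.data$r, na.rm = TRUE),
                     n_organoids = sum(!is.na(.data$r)),
                     .groups = "drop")
  structure(list(per_organoid = per_organoid, mean_r = mean_r),
            class = "engagement_correlation")
}

#' @export
print.engagement_correlation <- function(x, ...) {
  cat("<engagement_correlation>\n")
  if (nrow(x$mean_r) > 0) {
    smry <- x$mean_r |>
      dplyr::group_by(.data$signature) |>
      dplyr::summarise(mean_r = mean(.data$mean_r, na.rm = TRUE),
                       .groups = "drop")
    print(smry)
  } else {
    cat("  (empty)\n")
  }
  invisible(x)
}

#' @export
tidy.engagement_correlation <- function(x, ...) x$mean_r

#' @export
autoplot.engagement_correlation <- function(object, ...) {
  ggplot2::ggplot(object$mean_r,
                  ggplot2::aes(.data$t / 60, .data$mean_r,
                               color = .data$signature)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window end (h)", y = "mean Pearson r",
                  color = "signature") +
    ggplot2::theme_minimal()
}
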