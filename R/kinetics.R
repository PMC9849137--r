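#' @name organoid_kinetics
#' @title Organoid killing dynamics from dead-cell dye
#'
#' @description
#' After rescaling the per-organoid dead-cell dye to 0-100 within each
#' experiment ([rescale_dye()]), an organoid is called dying from the
#' first time its rescaled dye crosses a threshold (default 50, the
#' midpoint of the normalized range). The population readout is the
#' cumulative percentage of dying organoids over time, optionally
#' corrected for a control (mock effector) condition.
NULL

#' Percentage of dying organoids over time
#'
#' @param organoids organoid tibble with `dye_rescaled` (see
#'   [rescale_dye()]), optionally a `condition` column.
#' @param die_thresh threshold on the 0-100 rescaled dye (default 50).
#' @param cumulative if `TRUE` (default) an organoid counts as dying from
#'   its first threshold crossing onward; if `FALSE` the per-frame
#'   fraction above threshold is reported instead.
#' @return a `killing_curve` tibble: `condition` (if present), `t`,
#'   `pct_dying`, `n_organoids`; attribute `"n_excluded"` counts
#'   organoids with < 2 frames, which are excluded.
#' @export
percent_dying_curve <- function(organoids, die_thresh = 50,
                                cumulative = TRUE) {
  if (!"dye_rescaled" %in% names(organoids) ||
      all(is.na(organoids$dye_rescaled))) {
    stop_cotrack("dye_rescaled missing; run rescale_dye() first",
                 "cotrack_schema_error")
  }
  has_cond <- "condition" %in% names(organoids)
  if (!has_cond) organoids$condition <- "all"
  frames_per <- organoids |>
    dplyr::count(.data$condition, .data$experiment_id, .data$well_id,
                 .data$organoid_id)
  n_excluded <- sum(frames_per$n < 2)
  keep <- dplyr::filter(frames_per, .data$n >= 2)
  org <- dplyr::semi_join(
    organoids, keep,
    by = c("condition", "experiment_id", "well_id", "organoid_id")
  )
  curve <- if (cumulative) {
    death_t <- org |>
      dplyr::group_by(.data$condition, .data$experiment_id, .data$well_id,
                      .data$organoid_id) |>
      dplyr::summarise(
        death_t = if (any(.data$dye_rescaled >= die_thresh, na.rm = TRUE)) {
          min(.data$t[which(.data$dye_rescaled >= die_thresh)])
        } else Inf,
        .groups = "drop"
      )
    grid <- org |> dplyr::distinct(.data$condition, .data$t)
    grid |>
      dplyr::group_by(.data$condition) |>
      dplyr::arrange(.data$t, .by_group = TRUE) |>
      dplyr::ungroup() |>
      dplyr::left_join(
        death_t |> dplyr::count(.data$condition, name = "n_organoids"),
        by = "condition"
      ) |>
      dplyr::rowwise() |>
      dplyr::mutate(pct_dying = 100 * mean(
        death_t$death_t[death_t$condition == .data$condition] <= .data$t
      )) |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(c("condition", "t", "pct_dying",
                                    "n_organoids")))
  } else {
    org |>
      dplyr::group_by(.data$condition, .data$t) |>
      dplyr::summarise(
        pct_dying = 100 * mean(.data$dye_rescaled >= die_thresh,
                               na.rm = TRUE),
        n_organoids = dplyr::n(), .groups = "drop"
      )
  }
  if (!has_cond) curve$condition <- NULL
  curve <- dplyr::arrange(curve, dplyr::across(dplyr::any_of("condition")),
                          .data$t)
  attr(curve, "n_excluded") <- n_excluded
  class(curve) <- c("killing_curve", class(curve))
  curve
}

#' Correct a killing curve for control effector responses
#'
#' Pointwise `max(0, treatment - control)`; the control curve is linearly
#' interpolated onto the treatment time grid if the grids differ.
#'
#' @param treatment,control `killing_curve` tibbles (single condition
#'   each).
#' @return corrected `killing_curve` with attribute `"corrected" = TRUE`.
#' @export
control_correction <- function(treatment, control) {
  if (max(control$t) < min(treatment$t) ||
      min(control$t) > max(treatment$t)) {
    stop_cotrack("treatment and control time ranges do not overlap",
                 "cotrack_config_error")
  }
  ctrl_at <- approx(control$t, control$pct_dying, xout = treatment$t,
                    rule = 2)$y
  out <- treatment |>
    dplyr::mutate(pct_dying = pmax(0, .data$pct_dying - ctrl_at))
  attr(out, "corrected") <- TRUE
  out
}

#' @export
autoplot.killing_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$t / 60, .data$pct_dying))
  if ("condition" %in% names(object)) {
    p <- p + ggplot2::aes(color = .data$condition)
  }
  p + ggplot2::geom_step() +
    ggplot2::labs(x = "time (h)", y = "% dying organoids") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Initial-size dependence of organoid killing
#'
#' Compares the initial (first-frame) area of organoids killed by
#' `kill_time_h` against those still alive then, with a two-sided
#' Wilcoxon rank-sum test and a standardized mean difference.
#'
#' @param organoids organoid tibble with `dye_rescaled`.
#' @param kill_time_h time point (hours from the first frame) at which
#'   killed/alive status is assessed (default 10).
#' @param die_thresh dye threshold defining death (default 50).
#' @return one-row tibble: `n_killed`, `n_alive`, `mean_area_killed`,
#'   `mean_area_alive`, `effect_size` (Cohen's d), `p.value` (Wilcoxon).
#'   Empty groups yield `NA` statistics with a warning.
#' @export
size_dependence <- function(organoids, kill_time_h = 10, die_thresh = 50) {
  per_org <- organoids |>
    dplyr::group_by(.data$experiment_id, .data$well_id,
                    .data$organoid_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::summarise(
      area0 = dplyr::first(.data$area),
      t0 = dplyr::first(.data$t),
      death_t = if (any(.data$dye_rescaled >= die_thresh, na.rm = TRUE)) {
        min(.data$t[which(.data$dye_rescaled >= die_thresh)])
      } else Inf,
      .groups = "drop"
    ) |>
    dplyr::mutate(killed = .data$death_t <= .data$t0 + kill_time_h * 60)
  a <- per_org$area0[per_org$killed]
  b <- per_org$area0[!per_org$killed]
  if (length(a) == 0 || length(b) == 0) {
    warn("one of the killed/alive groups is empty; no test performed")
    return(tibble::tibble(
      n_killed = length(a), n_alive = length(b),
      mean_area_killed = if (length(a)) mean(a) else NA_real_,
      mean_area_alive = if (length(b)) mean(b) else NA_real_,
      effect_size = NA_real_, p.value = NA_real_
    ))
  }
  pooled_sd <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                      (length(a) + length(b) - 2))
  wt <- suppressWarnings(wilcox.test(a, b))
  tibble::tibble(
    n_killed = length(a), n_alive = length(b),
    mean_area_killed = mean(a), mean_area_alive = mean(b),
    effect_size = if (is.finite(pooled_sd) && pooled_sd > 0) {
      (mean(a) - mean(b)) / pooled_sd
    } else NA_real_,
    p.value = wt$p.value
  )
}
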