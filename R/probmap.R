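#' @name probmap
#' @title Mapping behavioral signatures onto transcriptomic clusters
#'
#' @description
#' Imaging and transcriptomics observe different cell states: behavioral
#' signatures (from tracking) and cluster assignments of sequenced cells.
#' They are bridged by the experimental engagement state, a population
#' label available on both sides. Given the conditional distribution of
#' signatures per engagement state (the priors, estimated from imaging)
#' and the empirical engagement-state composition of each transcriptomic
#' cluster, the per-cell signature distribution follows by transitivity:
#'
#' \deqn{p(B | U) = \sum_{E} p(B | E) \, p(E | U)}
#'
#' where B is the behavioral signature, E the engagement state and U the
#' cluster. Clustering is repeated at several resolutions (runs) and the
#' per-cell probability vectors are averaged across runs.
NULL

#' In-silico engagement states from contact history
#'
#' Rule-based reproduction of the experimental engagement-state sort on
#' imaging data, evaluated on each cell's organoid-contact history up to
#' the harvest time:
#' * `super engaged`: contact fraction >= `super_frac` over the final
#'   `super_window_h` hours;
#' * `engaged`: in contact at harvest, or cumulative contact >=
#'   `engaged_min` minutes, and not super engaged;
#' * `nonengaged`: some contact but less than `engaged_min` minutes;
#' * `nonengaged-enriched`: zero contact over the entire record;
#' * `no-target control`: assigned only via `control_wells` (wells
#'   cultured without organoids).
#'
#' The rule thresholds are configuration, not measured constants.
#'
#' @param series feature-series (or binarized track) tibble with a
#'   `contact` channel and `t`.
#' @param harvest_t harvest time in minutes (default: last frame).
#' @param super_frac,super_window_h,engaged_min rule thresholds.
#' @param control_wells optional tibble (`experiment_id`, `well_id`) of
#'   no-organoid control wells.
#' @return tibble with key columns, `state` and `short_record` flag
#'   (track shorter than the super-engagement horizon).
#' @export
infer_engagement_states <- function(series, harvest_t = NULL,
                                    super_frac = 0.75, super_window_h = 2,
                                    engaged_min = 30,
                                    control_wells = NULL) {
  harvest_t <- harvest_t %||% max(series$t)
  out <- series |>
    dplyr::filter(.data$t <= harvest_t) |>
    dplyr::group_by(.data$experiment_id, .data$well_id, .data$cell_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::summarise(
      dt = if (dplyr::n() > 1) min(diff(.data$t)) else NA_real_,
      contact_min = sum(.data$contact, na.rm = TRUE) *
        dplyr::coalesce(dt, 0),
      at_harvest = dplyr::last(.data$contact) == 1,
      final_frac = {
        w <- .data$t > (max(.data$t) - super_window_h * 60)
        mean(.data$contact[w], na.rm = TRUE)
      },
      short_record = (max(.data$t) - min(.data$t)) < super_window_h * 60,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      state = dplyr::case_when(
        final_frac >= super_frac & contact_min > 0 ~ "super engaged",
        at_harvest | contact_min >= engaged_min ~ "engaged",
        contact_min > 0 ~ "nonengaged",
        TRUE ~ "nonengaged-enriched"
      )
    ) |>
    dplyr::select(-dplyr::all_of(c("dt", "contact_min", "at_harvest",
                                   "final_frac")))
  if (!is.null(control_wells)) {
    out <- out |>
      dplyr::mutate(state = dplyr::if_else(
        paste(.data$experiment_id, .data$well_id) %in%
          paste(control_wells$experiment_id, control_wells$well_id),
        "no-target control", .data$state
      ))
  }
  dplyr::relocate(out, "state", .after = "cell_id")
}

#' Estimate signature priors per engagement state
#'
#' Empirical conditional frequencies p(B | E): for each engagement state,
#' the distribution of behavioral signatures among its cells. Signatures
#' never seen in a state get probability 0; rows are normalized to sum
#' to 1. Optionally computed separately per T cell subset.
#'
#' @param states tibble with `state` and `signature` per cell (join of
#'   [infer_engagement_states()] and [classify_tracks()] output), and
#'   optionally `subset`.
#' @param signatures signature vocabulary defining the column set.
#' @param by_subset compute per `subset` (default `FALSE`).
#' @return a `signature_priors` tibble: (`subset`,) `state`, one column
#'   per signature; rows sum to 1.
#' @export
estimate_signature_priors <- function(states,
                                      signatures = signature_levels(TRUE),
                                      by_subset = FALSE) {
  grp <- if (by_subset) c("subset", "state") else "state"
  n_per <- states |> dplyr::count(dplyr::across(dplyr::all_of(grp)))
  if (any(n_per$n == 0)) {
    stop_cotrack("empty engagement state", "cotrack_config_error")
  }
  out <- states |>
    dplyr::count(dplyr::across(dplyr::all_of(c(grp, "signature")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(p = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "signature", values_from = "p",
                       values_fill = 0)
  for (sig in setdiff(signatures, names(out))) out[[sig]] <- 0
  out <- out[, c(grp, intersect(signatures, names(out))), drop = FALSE]
  class(out) <- c("signature_priors", class(out))
  out
}

prior_matrix <- function(priors) {
  pm <- as.matrix(priors[, setdiff(names(priors), c("subset", "state")),
                         drop = FALSE])
  rownames(pm) <- priors$state
  if (any(abs(rowSums(pm) - 1) > 1e-9)) {
    stop_cotrack("prior rows must sum to 1", "cotrack_integrity_error")
  }
  pm
}

#' Map behavioral-signature probabilities onto cells
#'
#' For each clustering run, the engagement-state composition of each
#' cluster is estimated empirically, multiplied through the signature
#' priors (the transitivity product), and assigned to every cell of the
#' cluster; per-cell vectors are then averaged over runs. Cells in the
#' `"no-target control"` state are forcibly assigned the dedicated
#' no-target-control signature. Optionally, values above a per-signature
#' quantile are capped and the vectors renormalized (a display-oriented
#' refinement; off by default so probabilities stay exact).
#'
#' @param cells tibble with `cell_id`, `state`, `pseudotime` and run
#'   columns `run_1 ... run_R` holding cluster ids.
#' @param priors a `signature_priors` tibble (single subset).
#' @param runs run column names (default: all `run_*` columns).
#' @param cap_quantile numeric in (0, 1\] or `NULL` (default) to disable
#'   capping.
#' @return the `cells` tibble with one probability column per signature
#'   (`p_<signature>`); rows sum to 1.
#' @export
map_behavior_probability <- function(cells, priors, runs = NULL,
                                     cap_quantile = NULL) {
  pm <- prior_matrix(priors)
  runs <- runs %||% grep("^run_", names(cells), value = TRUE)
  if (length(runs) < 1) {
    stop_cotrack("need at least one clustering run column",
                 "cotrack_config_error")
  }
  sigs <- colnames(pm)
  acc <- matrix(0, nrow(cells), length(sigs),
                dimnames = list(NULL, sigs))
  for (r in runs) {
    cl <- cells[[r]]
    p_b_u <- matrix(NA_real_, nrow(cells), length(sigs))
    for (u in unique(cl)) {
      idx <- which(cl == u)
      if (length(idx) == 0) {
        warn(sprintf("cluster %s in %s has size 0; skipped", u, r))
        next
      }
      st <- cells$state[idx]
      absent <- setdiff(unique(st), rownames(pm))
      if (length(absent) > 0) {
        stop_cotrack(sprintf("state(s) absent from priors: %s",
                             paste(absent, collapse = ", ")),
                     "cotrack_config_error")
      }
      p_e_u <- table(factor(st, levels = rownames(pm))) / length(st)
      p_b_u[idx, ] <- matrix(as.numeric(p_e_u) %*% pm, length(idx),
                             length(sigs), byrow = TRUE)
    }
    acc <- acc + p_b_u
  }
  prob <- acc / length(runs)
  # no-target control cells carry the dedicated control signature
  ctrl <- cells$state == "no-target control"
  if (any(ctrl)) {
    if (!"no-target control" %in% sigs) {
      stop_cotrack(
        "priors lack a 'no-target control' signature column but control cells are present",
        "cotrack_config_error"
      )
    }
    prob[ctrl, ] <- 0
    prob[ctrl, "no-target control"] <- 1
  }
  if (!is.null(cap_quantile)) {
    caps <- apply(prob, 2, quantile, probs = cap_quantile)
    prob <- sweep(prob, 2, caps, pmin)
    prob <- prob / rowSums(prob)
  }
  probs <- tibble::as_tibble(prob, .name_repair = "minimal")
  names(probs) <- paste0("p_", sigs)
  dplyr::bind_cols(cells, probs)
}

#' Offset pseudotime of a disconnected control partition
#'
#' When trajectory inference places no-target control cells in a separate
#' partition, their pseudotime lives on its own scale. To obtain a single
#' spectrum, the maximum control pseudotime is added to all non-control
#' cells' pseudotime, placing controls first.
#'
#' @param cells tibble with `state` and `pseudotime`.
#' @return the tibble with adjusted `pseudotime`.
#' @export
offset_pseudotime <- function(cells) {
  ctrl <- cells$state == "no-target control"
  if (!any(ctrl) || !any(!ctrl)) return(cells)
  offset <- max(cells$pseudotime[ctrl])
  cells |>
    dplyr::mutate(pseudotime = dplyr::if_else(
      .data$state == "no-target control",
      .data$pseudotime, .data$pseudotime + offset
    ))
}

stage_of_group <- c(
  "no-target control" = "baseline",
  "nonengaged" = "environmental stimuli",
  "engagement" = "short engagement",
  "super engager" = "prolonged engagement"
)

signature_group <- function(sig) {
  dplyr::case_when(
    sig == "no-target control" ~ "no-target control",
    sig == "super engager" ~ "super engager",
    sig %in% c("engager", "tickler") ~ "engagement",
    TRUE ~ "nonengaged"
  )
}

#' Partition pseudotime into targeting stages
#'
#' Bins pseudotime, computes the dominant merged signature group per bin
#' (no-target control; merged nonengaged signatures; tickler/engager;
#' super engager), smooths dominance with a centered 3-bin majority vote,
#' and labels each bin with the targeting stage of its dominant group:
#' baseline, environmental stimuli, short engagement, prolonged
#' engagement. All cells in a bin inherit its stage.
#'
#' @param cells output of [map_behavior_probability()] with `pseudotime`.
#' @param n_bins number of pseudotime bins (default 50).
#' @return the tibble with `stage` (ordered factor) added; attribute
#'   `"stage_bins"` maps bins to stages.
#' @export
partition_stages <- function(cells, n_bins = 50) {
  pcols <- grep("^p_", names(cells), value = TRUE)
  stopifnot(length(pcols) > 0, all(is.finite(cells$pseudotime)))
  groups <- signature_group(sub("^p_", "", pcols))
  brks <- seq(min(cells$pseudotime), max(cells$pseudotime),
              length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(cells$pseudotime, brks,
                                rightmost.closed = TRUE), 1L), n_bins)
  # total probability mass per bin and signature, then merged into groups
  bin_mass <- rowsum(as.matrix(cells[, pcols]), bin)
  grp_names <- unique(groups)
  grp_mass <- sapply(grp_names, function(g) {
    rowSums(bin_mass[, groups == g, drop = FALSE])
  })
  if (is.null(dim(grp_mass))) grp_mass <- matrix(grp_mass, nrow = 1,
                                                 dimnames = list(
                                                   rownames(bin_mass),
                                                   grp_names))
  dominant <- grp_names[max.col(grp_mass, ties.method = "first")]
  occupied <- as.integer(rownames(bin_mass))
  # 3-bin centered majority smoothing
  smooth_dom <- dominant
  if (length(dominant) >= 3) {
    for (i in 2:(length(dominant) - 1)) {
      nb <- dominant[(i - 1):(i + 1)]
      tb <- table(nb)
      if (max(tb) >= 2) smooth_dom[i] <- names(tb)[which.max(tb)]
    }
  }
  stage_levels <- c("baseline", "environmental stimuli",
                    "short engagement", "prolonged engagement")
  bin_stage <- unname(stage_of_group[smooth_dom])
  # warn if the stage sequence regresses after smoothing
  ord <- match(bin_stage, stage_levels)
  if (any(diff(ord) < 0)) {
    warn("non-monotone stage dominance after smoothing; using first crossings")
  }
  stage_map <- setNames(bin_stage, occupied)
  cells$stage <- factor(unname(stage_map[as.character(bin)]),
                        levels = stage_levels, ordered = TRUE)
  attr(cells, "stage_bins") <-
    tibble::tibble(bin = occupied, lower = brks[occupied],
                   upper = brks[occupied + 1], stage = bin_stage)
  cells
}

#' Smooth gene dynamics over pseudotime and cluster patterns
#'
#' Each gene's expression is smoothed over pseudotime (cubic smoothing
#' spline on pseudotime-ordered cells, evaluated on a common grid),
#' z-scored, and the smoothed curves are k-means clustered into
#' `k_patterns` pattern groups. Genes with (near-)zero expression
#' variance are assigned the pattern `"flat"` outside k-means.
#'
#' @param expression gene x cell numeric matrix (genes in rows).
#' @param pseudotime numeric vector, one value per cell (column).
#' @param k_patterns number of pattern clusters (default 8).
#' @param grid_n evaluation grid size (default 100).
#' @param seed integer seed for k-means.
#' @return list of class `gene_dynamics`: `patterns` (tibble `gene`,
#'   `pattern`), `curves` (gene x grid matrix of z-scored smoothed
#'   values), `grid` (pseudotime grid).
#' @export
smooth_gene_dynamics <- function(expression, pseudotime, k_patterns = 8,
                                 grid_n = 100, seed = 1) {
  expression <- as.matrix(expression)
  stopifnot(ncol(expression) == length(pseudotime))
  ord <- order(pseudotime)
  pt <- pseudotime[ord]
  grid <- seq(min(pt), max(pt), length.out = grid_n)
  curves <- t(apply(expression[, ord, drop = FALSE], 1, function(y) {
    if (var(y) < .Machine$double.eps) return(rep(NA_real_, grid_n))
    fit <- smooth.spline(pt, y, cv = FALSE)
    predict(fit, grid)$y
  }))
  flat <- apply(curves, 1, function(z) any(!is.finite(z)) || sd(z) == 0)
  z <- curves
  z[!flat, ] <- t(scale(t(curves[!flat, , drop = FALSE])))
  genes <- rownames(expression) %||% as.character(seq_len(nrow(expression)))
  pattern <- rep(NA_character_, nrow(expression))
  pattern[flat] <- "flat"
  if (any(!flat)) {
    kk <- min(k_patterns, sum(!flat))
    if (kk >= sum(!flat)) {
      pattern[!flat] <- as.character(seq_len(sum(!flat)))
    } else {
      set.seed(seed)
      km <- kmeans(z[!flat, , drop = FALSE], centers = kk, nstart = 10,
                   iter.max = 100)
      pattern[!flat] <- as.character(km$cluster)
    }
  }
  structure(
    list(patterns = tibble::tibble(gene = genes, pattern = pattern),
         curves = z, grid = grid),
    class = "gene_dynamics"
  )
}

#' @export
tidy.gene_dynamics <- function(x, ...) x$patterns

#' @export
autoplot.gene_dynamics <- function(object, ...) {
  df <- tibble::as_tibble(object$curves, .name_repair = "minimal")
  names(df) <- as.character(seq_along(object$grid))
  df$gene <- object$patterns$gene
  df$pattern <- object$patterns$pattern
  long <- tidyr::pivot_longer(df, -dplyr::all_of(c("gene", "pattern")),
                              names_to = "i", values_to = "z") |>
    dplyr::mutate(pseudotime = object$grid[as.integer(.data$i)])
  ggplot2::ggplot(long, ggplot2::aes(.data$pseudotime, .data$z,
                                     group = .data$gene)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~pattern) +
    ggplot2::labs(y = "z-scored smoothed expression") +
    ggplot2::theme_minimal()
}
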