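#' @name classify
#' @title Random-forest classification of track behavior
#'
#' @description
#' For standardized integration of new experiments, each fixed-length
#' feature series is reduced to a small set of descriptive statistics and
#' classified into the atlas signatures with a random forest (100 trees,
#' stratified 95/5 train/test split). The T cell interaction channel is
#' excluded by default so that experiments run at a lower
#' effector-to-target ratio, where interaction frequency shifts for purely
#' compositional reasons, remain comparable.
NULL

#' Descriptive-statistic features per track
#'
#' Numeric channels (speed, square displacement) yield mean, median, 90th
#' percentile (linear-interpolation quantile) and standard deviation;
#' binary channels (death, organoid contact, and T cell interaction when
#' `include_interaction = TRUE`) yield the mean plus the mean and maximum
#' of the cumulative sum, capturing both how often and for how long the
#' state was occupied.
#'
#' @param series feature-series tibble of uniform length (see
#'   [cut_to_window()]).
#' @param include_interaction include the `tcell_interaction` channel
#'   (default `FALSE`).
#' @return tibble: key columns + 14 (or 17) feature columns.
#' @export
featurize_tracks <- function(series, include_interaction = FALSE) {
  numeric_ch <- c("speed", "sq_displacement")
  binary_ch <- c("contact", "death")
  if (include_interaction) binary_ch <- c(binary_ch, "tcell_interaction")
  miss <- setdiff(c(numeric_ch, binary_ch), names(series))
  if (length(miss) > 0) {
    stop_cotrack(sprintf("missing channel(s): %s",
                         paste(miss, collapse = ", ")),
                 "cotrack_schema_error")
  }
  series |>
    dplyr::group_by(.data$experiment_id, .data$well_id, .data$cell_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      dplyr::across(
        dplyr::all_of(numeric_ch),
        list(mean = ~ mean(.x), median = ~ median(.x),
             p90 = ~ unname(quantile(.x, 0.9, type = 7)),
             sd = ~ sd(.x)),
        .names = "{.col}_{.fn}"
      ),
      dplyr::across(
        dplyr::all_of(binary_ch),
        list(mean = ~ mean(.x), cummean = ~ mean(cumsum(.x)),
             cummax = ~ max(cumsum(.x))),
        .names = "{.col}_{.fn}"
      ),
      .groups = "drop"
    )
}

feature_cols <- function(features) {
  setdiff(names(features), c("experiment_id", "well_id", "cell_id",
                             "population", "signature"))
}

#' Train the behavioral signature classifier
#'
#' Random forest over track descriptive statistics, with a stratified
#' train/test split by label so that every signature is represented in
#' training. Held-out accuracy and the per-signature confusion matrix are
#' recorded on the model.
#'
#' @param features feature tibble from [featurize_tracks()].
#' @param labels character/factor vector of signatures, one per row of
#'   `features`.
#' @param n_trees number of trees (default 100).
#' @param train_fraction fraction of tracks used for training
#'   (default 0.95, stratified per label).
#' @param seed integer seed.
#' @return a `behavior_classifier`: list with `forest`, `feature_schema`,
#'   `label_set`, `split`, `heldout_accuracy`, `heldout_confusion`, `seed`.
#' @export
train_classifier <- function(features, labels, n_trees = 100,
                             train_fraction = 0.95, seed = 1) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(features))
  if (length(unique(labels)) < 2) {
    stop_cotrack("need at least 2 distinct labels", "cotrack_config_error")
  }
  cols <- feature_cols(features)
  x <- as.data.frame(features[, cols])
  if (any(!is.finite(as.matrix(x)))) {
    stop_cotrack("non-finite feature values", "cotrack_integrity_error")
  }
  set.seed(seed)
  train_idx <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
    n_tr <- max(1L, floor(length(ix) * train_fraction))
    sample(ix, n_tr)
  }), use.names = FALSE)
  absent <- setdiff(unique(labels), unique(labels[train_idx]))
  if (length(absent) > 0) {
    stop_cotrack(sprintf("label(s) absent from training split: %s",
                         paste(absent, collapse = ", ")),
                 "cotrack_config_error")
  }
  lv <- sort(unique(labels))
  y <- factor(labels, levels = lv)
  forest <- randomForest::randomForest(
    x = x[train_idx, , drop = FALSE], y = y[train_idx], ntree = n_trees
  )
  test_idx <- setdiff(seq_along(labels), train_idx)
  if (length(test_idx) > 0) {
    pred <- predict(forest, x[test_idx, , drop = FALSE])
    confusion <- table(truth = y[test_idx], predicted = pred)
    acc <- mean(pred == y[test_idx])
  } else {
    confusion <- table(truth = y[0], predicted = y[0])
    acc <- NA_real_
  }
  structure(
    list(forest = forest, feature_schema = cols, label_set = lv,
         split = train_fraction, heldout_accuracy = acc,
         heldout_confusion = confusion, n_trees = n_trees, seed = seed),
    class = "behavior_classifier"
  )
}

#' @export
print.behavior_classifier <- function(x, ...) {
  cat("<behavior_classifier>\n")
  cat("  features: ", length(x$feature_schema), "\n")
  cat("  labels:   ", paste(x$label_set, collapse = ", "), "\n")
  cat("  trees:    ", x$n_trees, "\n")
  cat("  held-out accuracy:", format(x$heldout_accuracy, digits = 3), "\n")
  invisible(x)
}

#' @export
tidy.behavior_classifier <- function(x, ...) {
  as.data.frame(x$heldout_confusion) |>
    tibble::as_tibble() |>
    dplyr::rename(n = "Freq")
}

#' @export
glance.behavior_classifier <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_schema),
    n_labels = length(x$label_set),
    n_trees = x$n_trees,
    train_fraction = x$split,
    heldout_accuracy = x$heldout_accuracy
  )
}

#' Classify feature series into behavioral signatures
#'
#' @param model a `behavior_classifier`.
#' @param series feature-series tibble, or a precomputed feature tibble
#'   carrying the model's feature schema.
#' @param include_interaction passed to [featurize_tracks()] when
#'   featurizing raw series.
#' @return tibble: key columns, `signature`, and one probability column
#'   per signature (`p_<signature>`, rows summing to 1).
#' @export
classify_tracks <- function(model, series, include_interaction = FALSE) {
  stopifnot(inherits(model, "behavior_classifier"))
  features <- if (all(model$feature_schema %in% names(series))) {
    series
  } else {
    featurize_tracks(series, include_interaction = include_interaction)
  }
  miss <- setdiff(model$feature_schema, names(features))
  if (length(miss) > 0) {
    stop_cotrack(sprintf("features missing from input: %s",
                         paste(miss, collapse = ", ")),
                 "cotrack_schema_error")
  }
  keys <- features[, intersect(c("experiment_id", "well_id", "cell_id"),
                               names(features)), drop = FALSE]
  if (nrow(features) == 0) {
    return(dplyr::bind_cols(keys,
                            tibble::tibble(signature = character(0))))
  }
  x <- as.data.frame(features[, model$feature_schema])
  prob <- predict(model$forest, x, type = "prob")
  pred <- model$label_set[max.col(prob, ties.method = "first")]
  probs <- tibble::as_tibble(prob, .name_repair = "minimal")
  names(probs) <- paste0("p_", colnames(prob))
  dplyr::bind_cols(keys, tibble::tibble(signature = pred), probs)
}

#' Composition of behavioral signatures across conditions
#'
#' Per condition, the percentage of tracks per signature (summing to 100),
#' with a chi-squared test on the condition-by-signature count table.
#' Optionally: per-signature differences between two named conditions
#' tested on replicate-level (per-well) percentages with Welch's t, and
#' the Pearson correlation between per-condition signature size and a
#' per-condition scalar such as the percentage of dying organoids.
#'
#' @param labels tibble with `condition`, `signature`, and optionally
#'   `well_id` (replicates).
#' @param compare optional character vector of two condition names for
#'   per-signature difference tests.
#' @param condition_scalar optional named numeric: one value per
#'   condition to correlate with signature sizes.
#' @return a `composition_stats` list: `composition` (condition,
#'   signature, n, pct), `chisq` (tidy tibble + validity flag),
#'   `pairwise` (per-signature Welch t, if `compare` given),
#'   `correlation` (per-signature Pearson r and p, if `condition_scalar`
#'   given).
#' @export
composition_stats <- function(labels, compare = NULL,
                              condition_scalar = NULL) {
  stopifnot(all(c("condition", "signature") %in% names(labels)))
  composition <- labels |>
    dplyr::count(.data$condition, .data$signature) |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  counts <- composition |>
    tidyr::pivot_wider(id_cols = "condition", names_from = "signature",
                       values_from = "n", values_fill = 0L)
  cm <- as.matrix(counts[, -1, drop = FALSE])
  chisq <- NULL
  if (nrow(cm) >= 2 && ncol(cm) >= 2) {
    ct <- suppressWarnings(chisq.test(cm, correct = FALSE))
    valid <- mean(ct$expected < 1) <= 0.2
    if (!valid) warn("chi-squared validity: > 20% of expected counts < 1")
    chisq <- tibble::tibble(statistic = unname(ct$statistic),
                            df = unname(ct$parameter),
                            p.value = ct$p.value, valid = valid)
  }
  pairwise <- NULL
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2, "well_id" %in% names(labels))
    base_pct <- labels |>
      dplyr::filter(.data$condition %in% compare) |>
      dplyr::count(.data$condition, .data$well_id, .data$signature) |>
      dplyr::group_by(.data$condition, .data$well_id) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
    grid <- tidyr::expand_grid(
      dplyr::distinct(base_pct, .data$condition, .data$well_id),
      signature = unique(labels$signature)
    )
    well_pct <- grid |>
      dplyr::left_join(base_pct,
                       by = c("condition", "well_id", "signature")) |>
      dplyr::mutate(pct = dplyr::coalesce(.data$pct, 0))
    pairwise <- well_pct |>
      dplyr::group_by(.data$signature) |>
      dplyr::group_modify(function(df, key) {
        a <- df$pct[df$condition == compare[1]]
        b <- df$pct[df$condition == compare[2]]
        if (length(a) < 2 || length(b) < 2 ||
            (var(a) == 0 && var(b) == 0)) {
          return(tibble::tibble(diff = mean(a) - mean(b),
                                statistic = NA_real_, p.value = NA_real_))
        }
        tt <- t.test(a, b)
        tibble::tibble(diff = mean(a) - mean(b),
                       statistic = unname(tt$statistic),
                       p.value = tt$p.value)
      }) |>
      dplyr::ungroup()
  }
  correlation <- NULL
  if (!is.null(condition_scalar)) {
    sc <- tibble::tibble(condition = names(condition_scalar),
                         scalar = unname(condition_scalar))
    correlation <- composition |>
      tidyr::complete(condition = sc$condition,
                      signature = unique(composition$signature),
                      fill = list(n = 0L, pct = 0)) |>
      dplyr::inner_join(sc, by = "condition") |>
      dplyr::group_by(.data$signature) |>
      dplyr::summarise(
        r = if (dplyr::n() >= 3 && sd(.data$pct) > 0 &&
                sd(.data$scalar) > 0) {
          cor(.data$pct, .data$scalar)
        } else NA_real_,
        p.value = if (dplyr::n() >= 3 && sd(.data$pct) > 0 &&
                      sd(.data$scalar) > 0) {
          stats::cor.test(.data$pct, .data$scalar)$p.value
        } else NA_real_,
        .groups = "drop"
      )
  }
  structure(list(composition = composition, chisq = chisq,
                 pairwise = pairwise, correlation = correlation),
            class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat("<composition_stats>\n")
  print(x$composition)
  if (!is.null(x$chisq)) {
    cat(sprintf("chi-squared: X2 = %.3f, df = %d, p = %.3g\n",
                x$chisq$statistic, x$chisq$df, x$chisq$p.value))
  }
  invisible(x)
}

#' @export
tidy.composition_stats <- function(x, ...) x$composition

#' @export
autoplot.composition_stats <- function(object, ...) {
  ggplot2::ggplot(object$composition,
                  ggplot2::aes(.data$condition, .data$pct,
                               fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of tracks", fill = "signature") +
    ggplot2::theme_minimal()
}
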