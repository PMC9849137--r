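#' @name atlas
#' @title The reference behavioral atlas
#'
#' @description
#' The atlas is built in four steps: (1) a dependent (joint-channel)
#' dynamic-time-warping cross-distance over the fixed-length multivariate
#' feature series; (2) a 2-D embedding of that distance matrix; (3)
#' k-means clustering on embedding coordinates with outlier flagging and
#' optional silhouette-based selection of k; (4) per-cluster relative
#' feature summaries from which canonical signature names are derived.
NULL

#' Multivariate DTW distance between two series
#'
#' Dependent DTW: the local cost between frame i of `a` and frame j of
#' `b` is the Euclidean distance between the two frame vectors; dynamic
#' programming runs over the full grid with no warping band, and the
#' distance is the minimal cumulative local cost over all monotone
#' warping paths.
#'
#' @param a,b numeric matrices, frames x channels (same channel count).
#' @return nonnegative DTW distance.
#' @export
#' @examples
#' dtw_distance(matrix(c(0, 0, 0)), matrix(c(1, 1, 1)))  # 3
dtw_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) {
    stop_cotrack("series have different channel counts",
                 "cotrack_schema_error")
  }
  .dtw_pair_cpp(a, b)
}

#' DTW cross-distance matrix over feature series
#'
#' Computes the symmetric matrix of pairwise dependent-DTW distances over
#' all series. Numeric channels (speed, square displacement) are first
#' z-normalized globally per channel when `normalize = TRUE`; binary
#' channels are kept on their 0/1 scale so that all channels contribute
#' comparably to the joint local cost.
#'
#' @param series a feature-series tibble (see [cut_to_window()]).
#' @param channels channels entering the distance.
#' @param numeric_channels subset of `channels` to z-normalize.
#' @param normalize z-normalize numeric channels (default `TRUE`).
#' @param log_channels channels log1p-transformed before normalization.
#'   Square displacement is heavy-tailed across cells (fast scanners
#'   disperse super-diffusively), and without variance stabilization this
#'   one channel dominates the joint local cost; default
#'   `"sq_displacement"`.
#' @return symmetric distance matrix with zero diagonal; row/column names
#'   are `experiment/well/cell` keys; attribute `"keys"` holds the key
#'   tibble.
#' @export
dtw_cross_distance <- function(series,
                               channels = c("speed", "sq_displacement",
                                            "contact", "tcell_interaction",
                                            "death"),
                               numeric_channels = c("speed",
                                                    "sq_displacement"),
                               normalize = TRUE,
                               log_channels = "sq_displacement") {
  parts <- series_matrices(series, channels)
  if (length(parts$matrices) < 2) {
    stop_cotrack("need at least 2 series", "cotrack_config_error")
  }
  mats <- parts$matrices
  for (i in match(intersect(log_channels, channels), channels)) {
    mats <- lapply(mats, function(m) { m[, i] <- log1p(m[, i]); m })
  }
  if (normalize) {
    idx <- match(intersect(numeric_channels, channels), channels)
    for (i in idx) {
      vals <- unlist(lapply(mats, function(m) m[, i]))
      mu <- mean(vals); s <- sd(vals)
      if (is.finite(s) && s > 0) {
        mats <- lapply(mats, function(m) { m[, i] <- (m[, i] - mu) / s; m })
      }
    }
  }
  d <- .dtw_cross_cpp(unname(mats))
  dimnames(d) <- list(names(parts$matrices), names(parts$matrices))
  attr(d, "keys") <- parts$keys
  d
}

#' Embed a distance matrix and cluster the embedding
#'
#' Computes a 2-D embedding of the precomputed DTW distance matrix (UMAP
#' by default, classical MDS as a deterministic alternative), then k-means
#' on the embedding coordinates. Series whose Euclidean distance to their
#' assigned centroid exceeds `mean + outlier_sd * sd` of within-cluster
#' centroid distances are flagged as outliers but keep their
#' nearest-centroid label, so downstream composition still sums to 100%.
#' With `k = "auto"`, k is selected over `k_range` by maximal mean
#' silhouette width on the embedding.
#'
#' @param dist_matrix symmetric distance matrix from
#'   [dtw_cross_distance()].
#' @param k integer number of clusters, or `"auto"`.
#' @param k_range candidate k values for `"auto"` (default `4:14`).
#' @param outlier_sd outlier threshold in within-cluster sd units
#'   (default 3; use `Inf` to disable).
#' @param method `"umap"` or `"mds"`.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param seed integer seed controlling embedding and k-means.
#' @return a tibble with the key columns, `dim1`, `dim2`, `cluster`
#'   (integer 1..k) and `outlier` (logical); attributes `"k"`,
#'   `"silhouette"` (mean widths per candidate k when `k = "auto"`).
#' @export
embed_and_cluster <- function(dist_matrix, k = "auto", k_range = 4:14,
                              outlier_sd = 3, method = c("umap", "mds"),
                              n_neighbors = 30, min_dist = 0.1, seed = 42) {
  method <- match.arg(method)
  n <- nrow(dist_matrix)
  if (any(!is.finite(dist_matrix))) {
    stop_cotrack("non-finite distances", "cotrack_integrity_error")
  }
  if (is.numeric(k) && k > n) {
    stop_cotrack("k exceeds the number of series", "cotrack_config_error")
  }
  set.seed(seed)
  emb <- if (method == "umap") {
    uwot::umap(stats::as.dist(dist_matrix),
               n_neighbors = min(n_neighbors, n - 1),
               min_dist = min_dist, n_threads = 1, n_sgd_threads = 0)
  } else {
    cmdscale(dist_matrix, k = 2)
  }
  colnames(emb) <- c("dim1", "dim2")

  km_at <- function(kk) {
    set.seed(seed + kk)
    kmeans(emb, centers = kk, nstart = 25, iter.max = 100)
  }
  sil_means <- NULL
  if (identical(k, "auto")) {
    k_range <- k_range[k_range < n]
    sil_means <- vapply(k_range, function(kk) {
      cl <- km_at(kk)$cluster
      mean(cluster::silhouette(cl, dist(emb))[, "sil_width"])
    }, numeric(1))
    k <- k_range[which.max(sil_means)]
    names(sil_means) <- k_range
  }
  km <- if (k == 1) {
    list(cluster = rep(1L, n), centers = matrix(colMeans(emb), 1))
  } else {
    km_at(k)
  }
  cl <- as.integer(km$cluster)
  cdist <- sqrt(rowSums((emb - km$centers[cl, , drop = FALSE])^2))
  outlier <- rep(FALSE, n)
  for (g in unique(cl)) {
    idx <- cl == g
    mu <- mean(cdist[idx]); s <- sd(cdist[idx])
    if (is.finite(s) && s > 0) {
      outlier[idx] <- cdist[idx] > mu + outlier_sd * s
    }
  }
  keys <- attr(dist_matrix, "keys") %||%
    tibble::tibble(series_id = rownames(dist_matrix) %||%
                     as.character(seq_len(n)))
  out <- dplyr::bind_cols(
    keys,
    tibble::as_tibble(emb),
    tibble::tibble(cluster = cl, outlier = outlier)
  )
  attr(out, "k") <- as.integer(k)
  attr(out, "silhouette") <- sil_means
  out
}

#' Per-cluster relative feature summary
#'
#' For each cluster and channel, the mean over member series of the
#' track-mean channel value, then min-max rescaled across clusters to
#' \[0, 1\] per channel (so 1 marks the cluster with the highest value of
#' that feature and 0 the lowest). Column names use the conventional
#' abbreviations OC (organoid contact), Dis (square displacement), Sp
#' (speed), TI (T cell interaction), CD (cell death).
#'
#' @param series feature-series tibble.
#' @param clustering output of [embed_and_cluster()] (or any tibble with
#'   the key columns and `cluster`).
#' @return a tibble with `cluster`, `n` and columns `OC`, `Dis`, `Sp`,
#'   `TI`, `CD` in \[0, 1\]. A single cluster yields all zeros (degenerate
#'   min = max rule); empty clusters yield `NA` rows with a warning.
#' @export
summarize_clusters <- function(series, clustering) {
  chan_map <- c(OC = "contact", Dis = "sq_displacement", Sp = "speed",
                TI = "tcell_interaction", CD = "death")
  per_track <- series |>
    dplyr::group_by(.data$experiment_id, .data$well_id, .data$cell_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(unname(chan_map)),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::inner_join(
      dplyr::select(clustering, dplyr::all_of(c("experiment_id", "well_id",
                                                "cell_id", "cluster"))),
      by = c("experiment_id", "well_id", "cell_id")
    )
  per_cluster <- per_track |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(unname(chan_map)), mean),
                     .groups = "drop")
  all_k <- sort(unique(clustering$cluster))
  if (length(setdiff(all_k, per_cluster$cluster)) > 0) {
    warn("empty cluster(s): summary rows set to NA")
    per_cluster <- dplyr::left_join(tibble::tibble(cluster = all_k),
                                    per_cluster, by = "cluster")
  }
  # min-max across clusters, per channel; zero range maps to 0
  resc <- function(x) {
    r <- range(x, na.rm = TRUE)
    if (!all(is.finite(r)) || diff(r) == 0) return(rep(0, length(x)))
    (x - r[1]) / diff(r)
  }
  out <- per_cluster |>
    dplyr::mutate(dplyr::across(dplyr::all_of(unname(chan_map)), resc))
  names(out)[match(unname(chan_map), names(out))] <- names(chan_map)
  out
}

#' Name clusters from their relative feature summary
#'
#' Deterministic rule set applied in order to each cluster's relative
#' feature row:
#' 1. `CD >= 0.8` -> `"dying"`;
#' 2. `OC >= 0.8` and `Dis <= 0.3` -> `"super engager"`;
#' 3. `OC >= 0.5` -> `"engager"`;
#' 4. `OC >= 0.15` -> `"tickler"` (a tickler touching organoids ~15% of
#'    the time sits at relative OC ~0.19 when super engagers anchor the
#'    scale, so the gate sits just below that);
#' 5. remaining (motility) clusters are ranked by `Sp` and named
#'    `"static"`, `"lazy"`, `"slow scanner"`, `"medium scanner"`,
#'    `"super scanner"` by speed quantile order; with more than five such
#'    clusters the overflow is named `"scanner-N"`. Ties break by cluster
#'    index. Duplicate engagement names get a numeric suffix.
#'
#' @param cluster_summary output of [summarize_clusters()].
#' @return tibble with `cluster` and `signature`.
#' @export
name_clusters <- function(cluster_summary) {
  cs <- dplyr::arrange(cluster_summary, .data$cluster)
  nm <- rep(NA_character_, nrow(cs))
  nm[cs$CD >= 0.8] <- "dying"
  se <- is.na(nm) & cs$OC >= 0.8 & cs$Dis <= 0.3
  nm[se] <- "super engager"
  nm[is.na(nm) & cs$OC >= 0.5] <- "engager"
  nm[is.na(nm) & cs$OC >= 0.15] <- "tickler"
  motility_names <- c("static", "lazy", "slow scanner", "medium scanner",
                      "super scanner")
  rest <- which(is.na(nm))
  if (length(rest) > 0) {
    ord <- rest[order(cs$Sp[rest], cs$cluster[rest])]
    m <- length(ord)
    if (m <= 5) {
      picks <- motility_names[round(seq(1, 5, length.out = m))]
    } else {
      picks <- c(motility_names, paste0("scanner-", seq_len(m - 5)))
    }
    nm[ord] <- picks
  }
  # disambiguate duplicates from the engagement rules
  dup <- duplicated(nm)
  while (any(dup)) {
    i <- which(dup)[1]
    nm[i] <- paste(nm[i], sum(nm[seq_len(i)] == nm[i]), sep = " ")
    dup <- duplicated(nm)
  }
  tibble::tibble(cluster = cs$cluster, signature = nm)
}

#' Build the full behavioral atlas
#'
#' Chains [dtw_cross_distance()], [embed_and_cluster()],
#' [summarize_clusters()] and [name_clusters()] into a `behavior_atlas`
#' object.
#'
#' @inheritParams dtw_cross_distance
#' @inheritParams embed_and_cluster
#' @return a `behavior_atlas` object: list with `distance`, `clustering`
#'   (keys + embedding + cluster + outlier + signature), `summary`,
#'   `names`, `k`, `seed`.
#' @export
build_atlas <- function(series, k = "auto", k_range = 4:14, outlier_sd = 3,
                        method = "umap", n_neighbors = 30, min_dist = 0.1,
                        seed = 42,
                        channels = c("speed", "sq_displacement", "contact",
                                     "tcell_interaction", "death"),
                        normalize = TRUE) {
  d <- dtw_cross_distance(series, channels = channels, normalize = normalize)
  clustering <- embed_and_cluster(d, k = k, k_range = k_range,
                                  outlier_sd = outlier_sd, method = method,
                                  n_neighbors = n_neighbors,
                                  min_dist = min_dist, seed = seed)
  cs <- summarize_clusters(series, clustering)
  cn <- name_clusters(cs)
  clustering <- dplyr::left_join(clustering, cn, by = "cluster")
  structure(
    list(distance = d, clustering = clustering, summary = cs, names = cn,
         k = attr(clustering, "k") %||% length(unique(clustering$cluster)),
         silhouette = attr(clustering, "silhouette"), seed = seed),
    class = "behavior_atlas"
  )
}

#' @export
print.behavior_atlas <- function(x, ...) {
  cat("<behavior_atlas>\n")
  cat("  series:   ", nrow(x$clustering), "\n")
  cat("  clusters: ", x$k, "\n")
  cat("  outliers: ", sum(x$clustering$outlier), "\n")
  cat("  signatures:", paste(x$names$signature, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.behavior_atlas <- function(x, ...) x$clustering

#' @export
glance.behavior_atlas <- function(x, ...) {
  tibble::tibble(
    n_series = nrow(x$clustering),
    k = x$k,
    n_outliers = sum(x$clustering$outlier),
    mean_silhouette = if (!is.null(x$silhouette)) {
      max(x$silhouette)
    } else NA_real_
  )
}

#' @export
autoplot.behavior_atlas <- function(object, ...) {
  ggplot2::ggplot(object$clustering,
                  ggplot2::aes(.data$dim1, .data$dim2,
                               color = .data$signature)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$outlier), size = 1.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::labs(x = "dim 1", y = "dim 2", color = "signature",
                  shape = "outlier") +
    ggplot2::theme_minimal()
}

#' Back-project cluster labels onto per-frame track coordinates
#'
#' Writes each labelled cell's signature onto its per-frame positions so
#' the clustering can be overlaid on the imaging data in an external
#' viewer. Unlabelled cells are omitted; the count is reported in the
#' `"n_unlabelled"` attribute.
#'
#' @param atlas a `behavior_atlas`, or a clustering tibble with key
#'   columns, `cluster`, `outlier` and `signature`.
#' @param tracks the source track tibble.
#' @return tibble (experiment_id, well_id, cell_id, t, x, y, z, cluster,
#'   signature, outlier).
#' @export
backproject <- function(atlas, tracks) {
  labels <- if (inherits(atlas, "behavior_atlas")) atlas$clustering else atlas
  out <- tracks |>
    dplyr::select(dplyr::all_of(c("experiment_id", "well_id", "cell_id",
                                  "t", "x", "y", "z"))) |>
    dplyr::inner_join(
      dplyr::select(labels, dplyr::all_of(c("experiment_id", "well_id",
                                            "cell_id", "cluster",
                                            "signature", "outlier"))),
      by = c("experiment_id", "well_id", "cell_id")
    )
  n_unlab <- nrow(dplyr::anti_join(
    dplyr::distinct(tracks, .data$experiment_id, .data$well_id,
                    .data$cell_id),
    labels, by = c("experiment_id", "well_id", "cell_id")
  ))
  attr(out, "n_unlabelled") <- n_unlab
  out
}
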