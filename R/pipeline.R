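#' @name pipeline
#' @title End-to-end orchestration
#'
#' @description
#' Two entry points cover the standard workflow: [run_reference_build()]
#' turns a reference track table into a behavioral atlas plus a trained
#' signature classifier, and [run_prediction()] applies a trained
#' classifier to new experiments and computes composition, killing
#' kinetics and engagement correlation. Both record a manifest (seeds,
#' input hashes, stage parameters) so reruns are verifiable.
NULL

manifest_entry <- function(...) {
  args <- list(...)
  args$package_version <- as.character(utils::packageVersion("cotrack"))
  args
}

#' Build the reference atlas and classifier
#'
#' preprocess -> DTW -> embed/cluster -> summarize/name -> featurize ->
#' train, on a single reference track table.
#'
#' @param tracks reference track tibble.
#' @param dt frame interval in minutes (`NULL` to infer).
#' @param window_h analysis window in hours.
#' @param contact_thresh,interaction_thresh,death_dye_thresh binarization
#'   thresholds (see [binarize_tracks()]).
#' @param k clusters (integer or `"auto"`).
#' @param seed master seed; stage seeds are derived from it.
#' @param ... further arguments to [build_atlas()].
#' @return list of class `reference_build`: `atlas`
#'   (`behavior_atlas`), `classifier` (`behavior_classifier`), `series`
#'   (feature-series tibble with signatures), `manifest`.
#' @export
run_reference_build <- function(tracks, dt = NULL, window_h = 3.3,
                                contact_thresh = 5,
                                interaction_thresh = 10,
                                death_dye_thresh = 20, k = "auto",
                                seed = 42, ...) {
  series <- preprocess_tracks(tracks, dt = dt, window_h = window_h,
                              contact_thresh = contact_thresh,
                              interaction_thresh = interaction_thresh,
                              death_dye_thresh = death_dye_thresh)
  atlas <- build_atlas(series, k = k, seed = seed, ...)
  features <- featurize_tracks(series)
  labelled <- dplyr::inner_join(
    features,
    dplyr::select(atlas$clustering,
                  dplyr::all_of(c("experiment_id", "well_id", "cell_id",
                                  "signature"))),
    by = c("experiment_id", "well_id", "cell_id")
  )
  classifier <- train_classifier(
    labelled[, setdiff(names(labelled), "signature")],
    labelled$signature, seed = seed + 1
  )
  manifest <- manifest_entry(
    stage = "reference_build", seed = seed,
    input_hash = rlang::hash(tracks), n_tracks = nrow(atlas$clustering),
    dt = attr(series, "dt"), window_h = window_h,
    frames_per_track = attr(series, "frames_per_track"),
    k = atlas$k, heldout_accuracy = classifier$heldout_accuracy
  )
  structure(list(atlas = atlas, classifier = classifier, series = series,
                 manifest = manifest),
            class = "reference_build")
}

#' @export
print.reference_build <- function(x, ...) {
  cat("<reference_build>\n")
  print(x$atlas)
  print(x$classifier)
  invisible(x)
}

#' Classify a new experiment and quantify killing
#'
#' classify -> composition (-> kinetics -> correlation where organoid
#' data are supplied).
#'
#' @param reference a `reference_build` (or bare `behavior_classifier`).
#' @param tracks new track tibble.
#' @param organoids optional organoid tibble (enables kinetics and, with
#'   positions, engagement correlation).
#' @param condition condition label for the run.
#' @param dt,window_h,contact_thresh,interaction_thresh,death_dye_thresh
#'   preprocessing parameters (match the reference build).
#' @param die_thresh dying threshold on rescaled dye.
#' @param correlate compute sliding-window engagement correlation
#'   (default `TRUE` when organoid positions are present).
#' @param window_corr_h correlation window, hours.
#' @return list of class `prediction_run`: `labels`, `composition`,
#'   `kinetics`, `correlation` (NULL where not computed), `manifest`.
#' @export
run_prediction <- function(reference, tracks, organoids = NULL,
                           condition = "new", dt = NULL, window_h = 3.3,
                           contact_thresh = 5, interaction_thresh = 10,
                           death_dye_thresh = 20, die_thresh = 50,
                           correlate = TRUE, window_corr_h = 3) {
  classifier <- if (inherits(reference, "reference_build")) {
    reference$classifier
  } else reference
  stopifnot(inherits(classifier, "behavior_classifier"))
  if (nrow(tracks) == 0) {
    return(structure(list(labels = tibble::tibble(),
                          composition = NULL, kinetics = NULL,
                          correlation = NULL,
                          manifest = manifest_entry(stage = "prediction",
                                                    n_tracks = 0)),
                     class = "prediction_run"))
  }
  series <- preprocess_tracks(tracks, dt = dt, window_h = window_h,
                              contact_thresh = contact_thresh,
                              interaction_thresh = interaction_thresh,
                              death_dye_thresh = death_dye_thresh)
  labels <- classify_tracks(classifier, series)
  composition <- composition_stats(
    dplyr::mutate(labels, condition = condition)
  )
  kinetics <- NULL
  correlation <- NULL
  if (!is.null(organoids)) {
    org <- if (!"dye_rescaled" %in% names(organoids) ||
               all(is.na(organoids$dye_rescaled))) {
      rescale_dye(organoids)
    } else organoids
    kinetics <- percent_dying_curve(org, die_thresh = die_thresh)
    if (correlate && !all(is.na(org$x))) {
      ledger <- cumulative_contacts(org, tracks, labels,
                                    contact_thresh = contact_thresh)
      correlation <- sliding_window_correlation(ledger,
                                                window_h = window_corr_h)
    }
  }
  manifest <- manifest_entry(
    stage = "prediction", input_hash = rlang::hash(tracks),
    organoid_hash = if (!is.null(organoids)) rlang::hash(organoids) else NULL,
    n_tracks = nrow(labels), condition = condition,
    die_thresh = die_thresh
  )
  structure(list(labels = labels, composition = composition,
                 kinetics = kinetics, correlation = correlation,
                 manifest = manifest),
            class = "prediction_run")
}

#' @export
print.prediction_run <- function(x, ...) {
  cat("<prediction_run>\n")
  cat("  classified tracks:", nrow(x$labels), "\n")
  if (!is.null(x$composition)) print(x$composition)
  invisible(x)
}
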