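#' @name synthetic
#' @title Seeded synthetic co-culture generator
#'
#' @description
#' Generates tracked-object tables with known ground truth for every
#' pipeline stage: archetype-structured T cell tracks (contact bouts as a
#' two-state Markov chain, truncated-Gaussian speeds, persistent-random-
#' walk positions, absorbing death driving the dye up), organoid dye
#' trajectories whose death hazard is coupled to signature-specific
#' engager contact, and cell-state tables with a known analytic
#' signature-probability vector per cell. All generators are
#' deterministic under a fixed seed.
NULL

#' The default archetype library
#'
#' One row per canonical behavioral signature with the generator
#' parameters that realize it: `speed_mean`/`speed_sd` (um/min),
#' `displacement_scale` (target square displacement over the window,
#' um^2), `contact_fraction` (stationary fraction of frames in organoid
#' contact), `contact_bout_min` (mean contact bout length, minutes),
#' `interaction_rate` (fraction of frames in T cell interaction) and
#' `death_rate` (per-hour death hazard). The super engager's contact
#' fraction of 0.8 corresponds to 48 min of organoid contact per hour,
#' with long bouts and low displacement; engager and tickler step down in
#' contact fraction and bout length; the scanner family spans increasing
#' speed at zero contact.
#'
#' @return tibble of archetype parameters, one row per signature.
#' @export
archetype_library <- function() {
  tibble::tribble(
    ~name,            ~speed_mean, ~speed_sd, ~displacement_scale,
      ~contact_fraction, ~contact_bout_min, ~interaction_rate, ~death_rate,
    "dying",            0.4,  0.15,   20,  0.02,  4,  0.02, 1.5,
    "static",           0.25, 0.12,   10,  0,     4,  0.02, 0.01,
    "lazy",             1.0,  0.2,   150,  0,     4,  0.04, 0.01,
    "slow scanner",     2.2,  0.3,   900,  0,     4,  0.08, 0.01,
    "medium scanner",   4.5,  0.4,  4000,  0,     4,  0.10, 0.01,
    "super scanner",    9.0,  0.6, 16000,  0,     4,  0.12, 0.01,
    "tickler",          3.2,  0.4,  2000,  0.15,  4,  0.08, 0.01,
    "engager",          1.9,  0.3,   400,  0.5,  15,  0.05, 0.01,
    "super engager",    0.8,  0.2,    60,  0.8,  40,  0.03, 0.01
  )
}

# two-state Markov chain hitting stationary fraction f with mean bout
# length `bout` frames; returns 0/1 vector of length n
simulate_bouts <- function(n, f, bout) {
  if (f <= 0) return(integer(n))
  if (f >= 1) return(rep(1L, n))
  p_leave <- min(1, 1 / bout)
  p_enter <- min(1, f * p_leave / (1 - f))
  s <- integer(n)
  s[1] <- rbinom(1, 1, f)  # start in the stationary distribution
  for (i in 2:n) {
    s[i] <- if (s[i - 1] == 1) rbinom(1, 1, 1 - p_leave)
            else rbinom(1, 1, p_enter)
  }
  s
}

# persistence giving approximately the target square displacement for a
# 2-D persistent random walk with n steps of length v*dt:
# MSD ~ n (v dt)^2 (1 + rho) / (1 - rho)
persistence_for <- function(scale, v, dt, n) {
  base <- n * (v * dt)^2
  if (base <= 0) return(0)
  rho <- (scale - base) / (scale + base)
  min(max(rho, 0), 0.98)
}

simulate_one_track <- function(arch, n_frames, dt, contact_thresh = 5,
                               interaction_thresh = 10, dye_thresh = 20) {
  in_contact <- simulate_bouts(n_frames, arch$contact_fraction,
                               max(1, arch$contact_bout_min / dt))
  # T cell encounters are sparse, bout-like events at a 1:25-1:30 E:T
  # ratio; model them with the same two-state chain as organoid contact
  interacting <- simulate_bouts(n_frames, arch$interaction_rate,
                                max(1, 4 / dt))
  speed <- pmax(0, rnorm(n_frames, arch$speed_mean, arch$speed_sd))
  # absorbing death
  p_die <- 1 - exp(-arch$death_rate * dt / 60)
  death_at <- which(runif(n_frames) < p_die)
  death <- integer(n_frames)
  if (length(death_at) > 0) death[death_at[1]:n_frames] <- 1L
  speed[death == 1] <- pmax(0, rnorm(sum(death), 0.05, 0.03))
  # positions: persistent random walk in the xy plane, slowed in contact
  rho <- persistence_for(arch$displacement_scale, arch$speed_mean, dt,
                         n_frames)
  theta <- numeric(n_frames)
  theta[1] <- runif(1, 0, 2 * pi)
  turn_sd <- sqrt(-2 * log(max(rho, 1e-6)))
  for (i in 2:n_frames) theta[i] <- theta[i - 1] + rnorm(1, 0, turn_sd)
  step <- speed * dt * ifelse(in_contact == 1, 0.15, 1)
  x <- cumsum(c(0, (step * cos(theta))[-n_frames]))
  y <- cumsum(c(0, (step * sin(theta))[-n_frames]))
  z <- cumsum(c(0, rnorm(n_frames - 1, 0, 0.5)))
  sq_disp <- x^2 + y^2 + z^2
  dist_organoid <- ifelse(in_contact == 1,
                          runif(n_frames, 0, 0.8 * contact_thresh),
                          runif(n_frames, 2 * contact_thresh, 100))
  dist_tcell <- ifelse(interacting == 1,
                       runif(n_frames, 0, 0.8 * interaction_thresh),
                       runif(n_frames, 2 * interaction_thresh, 150))
  dye <- pmax(0, rnorm(n_frames, 5, 1.5))
  if (any(death == 1)) {
    k <- which(death == 1)[1]
    rise <- 2 * dye_thresh /
      (1 + exp(-(seq_len(n_frames - k + 1) - 3) / 1.5))
    dye[k:n_frames] <- dye[k:n_frames] + rise
  }
  tibble::tibble(
    t = (seq_len(n_frames) - 1) * dt, x = x, y = y, z = z,
    speed = speed, sq_displacement = sq_disp, dye_intensity = dye,
    dist_organoid = dist_organoid, dist_tcell = dist_tcell
  )
}

#' Simulate archetype-structured T cell tracks
#'
#' @param archetype_mix named integer vector: tracks per archetype name
#'   (names must exist in `archetypes$name`).
#' @param dt frame interval in minutes (2 and 30 are the typical imaging
#'   modes).
#' @param duration_h track duration in hours (default 3.4, slightly more
#'   than the 3.3-h analysis window).
#' @param seed integer seed.
#' @param archetypes archetype parameter tibble (default
#'   [archetype_library()]).
#' @param experiment_id,well_id metadata stamped on the tracks.
#' @return list with `tracks` (a validated track tibble) and `truth`
#'   (`cell_id`, `archetype`).
#' @export
simulate_tcell_tracks <- function(archetype_mix, dt = 2, duration_h = 3.4,
                                  seed = 1,
                                  archetypes = archetype_library(),
                                  experiment_id = "sim",
                                  well_id = "w1") {
  if (any(archetype_mix < 0)) {
    stop_cotrack("negative archetype counts", "cotrack_config_error")
  }
  bad <- setdiff(names(archetype_mix), archetypes$name)
  if (length(bad) > 0) {
    stop_cotrack(sprintf("unknown archetype(s): %s",
                         paste(bad, collapse = ", ")),
                 "cotrack_config_error")
  }
  n_frames <- floor(duration_h * 60 / dt) + 1L
  set.seed(seed)
  cell_id <- 0L
  out <- vector("list", sum(archetype_mix))
  truth <- vector("list", sum(archetype_mix))
  k <- 0L
  for (nm in names(archetype_mix)) {
    arch <- archetypes[archetypes$name == nm, ]
    for (i in seq_len(archetype_mix[[nm]])) {
      cell_id <- cell_id + 1L
      k <- k + 1L
      tr <- simulate_one_track(arch, n_frames, dt)
      tr$cell_id <- cell_id
      out[[k]] <- tr
      truth[[k]] <- tibble::tibble(cell_id = cell_id, archetype = nm)
    }
  }
  if (k == 0L) {
    tracks <- finalize_track_table(tibble::tibble(
      experiment_id = character(0), well_id = character(0),
      cell_id = integer(0), t = numeric(0), x = numeric(0),
      y = numeric(0), z = numeric(0), speed = numeric(0),
      sq_displacement = numeric(0)
    ))
    return(list(tracks = tracks,
                truth = tibble::tibble(cell_id = integer(0),
                                       archetype = character(0))))
  }
  tracks <- dplyr::bind_rows(out) |>
    dplyr::mutate(experiment_id = experiment_id, well_id = well_id,
                  population = "unknown")
  list(tracks = finalize_track_table(tracks),
       truth = dplyr::bind_rows(truth))
}

#' Default organoid killing model
#'
#' Per-frame organoid death hazard is `baseline_hazard` plus the sum of
#' per-contact multipliers of the signatures currently in contact; the
#' super engager multiplier dominates, the engager is intermediate and
#' the tickler small, encoding that prolonged contact drives killing.
#' Dye rises sigmoidally after death with Gaussian noise.
#'
#' @param baseline_hazard per-frame death probability without contact.
#' @param multipliers named per-contact per-frame hazard increments.
#' @param rise_mid_min,rise_scale_min midpoint and scale of the
#'   sigmoidal dye rise after death, in minutes. Organoid cells die
#'   progressively, so the dye climbs over hours rather than stepping;
#'   the defaults keep killed organoids in the rising phase for most of
#'   a short imaging session.
#' @param noise_sd dye noise standard deviation (raw units).
#' @return list of class `killing_model`.
#' @export
killing_model <- function(baseline_hazard = 0.0005,
                          multipliers = c("super engager" = 0.02,
                                          "engager" = 0.005,
                                          "tickler" = 0.001),
                          rise_mid_min = 120, rise_scale_min = 40,
                          noise_sd = 0.3) {
  stopifnot(baseline_hazard >= 0, baseline_hazard <= 1,
            all(multipliers >= 0), all(multipliers <= 1))
  structure(list(baseline_hazard = baseline_hazard,
                 multipliers = multipliers,
                 rise_mid_min = rise_mid_min,
                 rise_scale_min = rise_scale_min, noise_sd = noise_sd),
            class = "killing_model")
}

#' Simulate organoid killing coupled to T cell contact
#'
#' Each T cell is assigned to one organoid (round robin); organoid
#' centers sit on a wide spatial grid and the assigned cells' positions
#' are shifted near their organoid, so that nearest-organoid contact
#' assignment recovers the truth. At each frame the organoid's death
#' hazard is the model baseline plus the per-signature multipliers of the
#' cells currently in contact; death is absorbing and the dead-cell dye
#' rises sigmoidally after it.
#'
#' @param n_organoids number of organoids.
#' @param tracks track tibble (e.g. from [simulate_tcell_tracks()]).
#' @param labels tibble (`cell_id`, `signature`) — typically the
#'   generator truth with archetype as signature.
#' @param model a [killing_model()].
#' @param seed integer seed.
#' @param contact_thresh distance defining contact, um (default 5;
#'   matches the track generator's contact emission).
#' @return list with `organoids` (validated organoid tibble with
#'   `dye_rescaled`), `tracks` (input tracks with positions shifted to
#'   their organoid), `assignment` (`cell_id`, `organoid_id`) and
#'   `death_times` (`organoid_id`, `death_t`; `Inf` = survived).
#' @export
simulate_organoid_killing <- function(n_organoids, tracks, labels, model,
                                      seed = 1, contact_thresh = 5) {
  stopifnot(inherits(model, "killing_model"), n_organoids >= 1)
  set.seed(seed)
  cells <- sort(unique(tracks$cell_id))
  assignment <- tibble::tibble(
    cell_id = cells,
    organoid_id = rep(seq_len(n_organoids), length.out = length(cells))
  )
  spacing <- 600
  centers <- tibble::tibble(
    organoid_id = seq_len(n_organoids),
    cx = spacing * ((seq_len(n_organoids) - 1) %% 10),
    cy = spacing * ((seq_len(n_organoids) - 1) %/% 10),
    cz = 0
  )
  tt <- sort(unique(tracks$t))
  # place each cell on the +x axis of its organoid at exactly its
  # emitted organoid distance, so nearest-organoid contact assignment
  # recovers the generator's contact channel (organoid spacing is far
  # larger than any contact threshold)
  shifted <- tracks |>
    dplyr::inner_join(assignment, by = "cell_id") |>
    dplyr::inner_join(centers, by = "organoid_id") |>
    dplyr::mutate(x = .data$cx + .data$dist_organoid,
                  y = .data$cy, z = .data$cz)
  contact_tbl <- shifted |>
    dplyr::inner_join(labels, by = "cell_id") |>
    dplyr::filter(.data$dist_organoid <= contact_thresh) |>
    dplyr::count(.data$organoid_id, .data$t, .data$signature,
                 name = "contacts")
  mult <- model$multipliers
  hazard <- contact_tbl |>
    dplyr::mutate(h = .data$contacts *
                    dplyr::coalesce(mult[.data$signature], 0)) |>
    dplyr::group_by(.data$organoid_id, .data$t) |>
    dplyr::summarise(h = sum(.data$h), .groups = "drop")
  exp_id <- tracks$experiment_id[1] %||% "sim"
  well <- tracks$well_id[1] %||% "w1"
  org_rows <- vector("list", n_organoids)
  death_times <- numeric(n_organoids)
  for (o in seq_len(n_organoids)) {
    hz <- hazard |> dplyr::filter(.data$organoid_id == o)
    h <- rep(model$baseline_hazard, length(tt))
    h[match(hz$t, tt)] <- h[match(hz$t, tt)] + hz$h
    h <- pmin(h, 1)
    u <- runif(length(tt))
    hit <- which(u < h)
    death_times[o] <- if (length(hit) > 0) tt[hit[1]] else Inf
    dye <- pmax(0, rnorm(length(tt), 3, model$noise_sd))
    if (is.finite(death_times[o])) {
      k <- which(tt == death_times[o])
      since <- tt[k:length(tt)] - tt[k]
      rise <- 60 / (1 + exp(-(since - model$rise_mid_min) /
                              model$rise_scale_min))
      dye[k:length(tt)] <- dye[k:length(tt)] + rise
    }
    area0 <- runif(1, 800, 4000)
    org_rows[[o]] <- tibble::tibble(
      experiment_id = exp_id, well_id = well, organoid_id = o, t = tt,
      x = centers$cx[o], y = centers$cy[o], z = 0,
      area = area0 * (1 + 0.02 * seq_along(tt) / length(tt)),
      volume = area0^1.5 / 50, dye_intensity = dye
    )
  }
  organoids <- dplyr::bind_rows(org_rows) |>
    finalize_organoid_table() |>
    rescale_dye()
  list(
    organoids = organoids,
    tracks = finalize_track_table(
      dplyr::select(shifted, dplyr::all_of(names(tracks)))
    ),
    assignment = assignment,
    death_times = tibble::tibble(organoid_id = seq_len(n_organoids),
                                 death_t = death_times)
  )
}

#' Default signature priors for simulation
#'
#' A plausible p(signature | engagement state) table linking the sorted
#' engagement populations to the signatures enriched in them: super
#' engaged cells are dominated by super engagers, engaged cells by
#' engagers/ticklers, nonengaged cells by the motility signatures, and
#' no-target control cells carry their dedicated control signature.
#'
#' @return a `signature_priors` tibble (5 states x 10 signatures).
#' @export
default_signature_priors <- function() {
  sigs <- signature_levels(TRUE)
  m <- rbind(
    "no-target control" = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1),
    "nonengaged-enriched" = c(0.08, 0.22, 0.25, 0.20, 0.15, 0.10, 0, 0, 0, 0),
    "nonengaged" = c(0.05, 0.12, 0.18, 0.20, 0.20, 0.15, 0.07, 0.03, 0, 0),
    "engaged" = c(0.02, 0.03, 0.05, 0.05, 0.05, 0.02, 0.28, 0.40, 0.10, 0),
    "super engaged" = c(0.01, 0.02, 0.02, 0, 0, 0, 0.05, 0.15, 0.75, 0)
  )
  colnames(m) <- sigs
  out <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(tibble::tibble(state = rownames(m)), out)
  class(out) <- c("signature_priors", class(out))
  out
}

#' Random cluster structure for simulation
#'
#' For each of `n_runs` clustering runs, draws a number of clusters and a
#' random stochastic p(state | cluster) matrix plus cluster weights —
#' emulating repeated graph-based clustering at different resolutions.
#'
#' @param n_runs number of runs (default 7).
#' @param k_range candidate cluster counts per run.
#' @param states state vocabulary.
#' @param seed integer seed.
#' @return list of runs, each with `k`, `p_state_given_cluster`
#'   (k x states, rows sum to 1) and `weights` (cluster sizes, sum 1).
#' @export
random_cluster_structure <- function(n_runs = 7, k_range = 3:9,
                                     states = engagement_levels(),
                                     seed = 1, informative = TRUE) {
  set.seed(seed)
  lapply(seq_len(n_runs), function(r) {
    k <- sample(k_range, 1)
    m <- matrix(stats::rgamma(k * length(states), shape = 0.8), k,
                dimnames = list(NULL, states))
    if (informative) {
      # transcriptomic clusters track engagement: each cluster leans
      # towards a home state, as real expression clusters do
      home <- sample(length(states), k, replace = TRUE)
      m[cbind(seq_len(k), home)] <- m[cbind(seq_len(k), home)] +
        stats::rgamma(k, shape = 8)
    }
    m <- m / rowSums(m)
    w <- stats::rgamma(k, shape = 2)
    list(k = k, p_state_given_cluster = m, weights = w / sum(w))
  })
}

#' Simulate a cell-state table with known signature probabilities
#'
#' Draws sequenced-cell records consistent with a given prior table and
#' per-run cluster structure: each cell gets an engagement state from the
#' run-1 marginal, per-run cluster assignments by Bayes inversion of
#' p(state | cluster), and a pseudotime from state-ordered distributions
#' (control < nonengaged-enriched < nonengaged < engaged < super
#' engaged). The analytic per-cell probability vector — the transitivity
#' product averaged over runs, computed from the true matrices — is
#' returned alongside for oracle comparison.
#'
#' @param n_cells number of cells.
#' @param priors a `signature_priors` tibble.
#' @param cluster_structure output of [random_cluster_structure()].
#' @param state_probs engagement-state composition of the sorted pool
#'   (named, summing to 1); default: equal proportions of the five
#'   sorted populations.
#' @param seed integer seed.
#' @return list: `cells` (tibble `cell_id`, `subset`, `state`,
#'   `pseudotime`, `run_1..run_R`), `analytic` (cell x signature matrix
#'   of true mapped probabilities).
#' @export
simulate_cell_states <- function(n_cells, priors = default_signature_priors(),
                                 cluster_structure =
                                   random_cluster_structure(),
                                 state_probs = NULL, seed = 1) {
  pm <- prior_matrix(priors)
  states <- rownames(pm)
  for (run in cluster_structure) {
    m <- run$p_state_given_cluster
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
      stop_cotrack("p(state | cluster) rows must be stochastic",
                   "cotrack_config_error")
    }
  }
  set.seed(seed)
  marg <- setNames(rep(1 / length(states), length(states)), states)
  if (!is.null(state_probs)) {
    stopifnot(all(names(state_probs) %in% states),
              abs(sum(state_probs) - 1) < 1e-9)
    marg[] <- 0
    marg[names(state_probs)] <- state_probs
  }
  marg <- as.numeric(marg)
  state <- sample(states, n_cells, replace = TRUE, prob = marg)
  pt_means <- setNames(seq(1, 7, length.out = length(states)), states)
  pseudotime <- pmax(0, rnorm(n_cells, pt_means[state], 0.5))
  cells <- tibble::tibble(
    cell_id = seq_len(n_cells),
    subset = sample(c("CD4", "CD8"), n_cells, replace = TRUE),
    state = state, pseudotime = pseudotime
  )
  analytic <- matrix(0, n_cells, ncol(pm),
                     dimnames = list(NULL, colnames(pm)))
  for (r in seq_along(cluster_structure)) {
    run <- cluster_structure[[r]]
    peu <- run$p_state_given_cluster[, states, drop = FALSE]
    # p(U | E) by Bayes with the run's cluster weights
    pue <- sweep(peu, 1, run$weights, `*`)
    pue <- sweep(pue, 2, colSums(pue), `/`)
    cl <- vapply(state, function(s) {
      sample(seq_len(run$k), 1, prob = pue[, s])
    }, integer(1))
    cells[[paste0("run_", r)]] <- cl
    # the p(state | cluster) actually realized by the sampling: states
    # are drawn once from the pool composition, so Bayes-invert back
    # with that marginal
    joint <- sweep(pue, 2, marg, `*`)          # clusters x states
    implied_peu <- joint / rowSums(joint)
    analytic <- analytic + implied_peu[cl, , drop = FALSE] %*% pm
  }
  analytic <- analytic / length(cluster_structure)
  ctrl <- state == "no-target control"
  if (any(ctrl) && "no-target control" %in% colnames(pm)) {
    analytic[ctrl, ] <- 0
    analytic[ctrl, "no-target control"] <- 1
  }
  list(cells = cells, analytic = analytic)
}
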