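# Shared fixtures and independent oracles, built in code at test time.

# minimal valid track tibble: one well, `cells` tracks on a uniform grid
make_tracks <- function(cells = 1:2, times = c(0, 2, 4), speed = 1,
                        dist_organoid = 20, dist_tcell = 30,
                        dye = 1, experiment_id = "e1", well_id = "w1") {
  g <- expand.grid(t = times, cell_id = cells)[, c("cell_id", "t")]
  tibble::tibble(
    experiment_id = experiment_id, well_id = well_id,
    cell_id = as.integer(g$cell_id), population = "unknown", t = g$t,
    x = g$t, y = 0, z = 0, speed = speed, sq_displacement = g$t^2,
    dye_intensity = dye, dist_organoid = dist_organoid,
    dist_tcell = dist_tcell, marker_intensity = NA_real_
  )
}

make_organoids <- function(orgs = 1:2, times = c(0, 30, 60),
                           area = 1000, dye = 1,
                           experiment_id = "e1", well_id = "w1") {
  g <- expand.grid(t = times, organoid_id = orgs)[, c("organoid_id", "t")]
  tibble::tibble(
    experiment_id = experiment_id, well_id = well_id,
    organoid_id = as.integer(g$organoid_id), t = g$t,
    x = 0, y = 0, z = 0, area = area, volume = area * 10,
    dye_intensity = dye, dye_rescaled = NA_real_
  )
}

# a hand-built feature-series tibble (one cell per column set)
make_series <- function(channel_list, dt = 2, experiment_id = "e1",
                        well_id = "w1") {
  purrr::imap_dfr(channel_list, function(ch, i) {
    L <- length(ch$speed)
    tibble::tibble(
      experiment_id = experiment_id, well_id = well_id,
      cell_id = as.integer(i), frame = seq_len(L), t = (seq_len(L) - 1) * dt,
      speed = ch$speed,
      sq_displacement = ch$sq_displacement %||% rep(0, L),
      contact = ch$contact %||% rep(0L, L),
      tcell_interaction = ch$tcell_interaction %||% rep(0L, L),
      death = ch$death %||% rep(0L, L)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent DTW oracle: exhaustive recursion over all monotone warping
# paths, no memoization, Euclidean local cost
dtw_brute <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a); m <- nrow(b)
  cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  rec <- function(i, j) {
    if (i == n && j == m) return(cost(i, j))
    opts <- c()
    if (i < n) opts <- c(opts, rec(i + 1, j))
    if (j < m) opts <- c(opts, rec(i, j + 1))
    if (i < n && j < m) opts <- c(opts, rec(i + 1, j + 1))
    cost(i, j) + min(opts)
  }
  rec(1, 1)
}
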