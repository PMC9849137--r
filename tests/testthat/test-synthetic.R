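test_that("track generator is seeded, validated and sized correctly", {
  mix <- c(static = 3, engager = 2)
  a <- simulate_tcell_tracks(mix, dt = 30, duration_h = 2, seed = 5)
  b <- simulate_tcell_tracks(mix, dt = 30, duration_h = 2, seed = 5)
  expect_identical(a, b)  # bit-reproducible
  expect_equal(dplyr::n_distinct(a$tracks$cell_id), 5)
  expect_equal(nrow(a$tracks), 5 * 5)  # 2 h at 30 min = 5 frames

  # generated tables pass validation silently
  expect_silent(cotrack:::finalize_track_table(a$tracks))

  empty <- simulate_tcell_tracks(c(static = 0), dt = 30, duration_h = 2)
  expect_equal(nrow(empty$tracks), 0)

  expect_error(simulate_tcell_tracks(c(static = -1)),
               class = "cotrack_config_error")
  expect_error(simulate_tcell_tracks(c(ghost = 3)),
               class = "cotrack_config_error")
})

test_that("super engager cohort realizes 48 contact-minutes per hour", {
  sim <- simulate_tcell_tracks(c("super engager" = 500), dt = 2,
                               duration_h = 3.3, seed = 13)
  s <- preprocess_tracks(sim$tracks, dt = 2)
  per_track <- dplyr::summarise(
    dplyr::group_by(s, cell_id),
    min_per_h = mean(contact) * 60
  )
  target <- 48
  sem <- sd(per_track$min_per_h) / sqrt(nrow(per_track))
  expect_lt(abs(mean(per_track$min_per_h) - target), 2 * sem + 0.5)
})

test_that("organoid deaths follow the per-frame hazard (geometric oracle)", {
  # constant contact by one super engager with multiplier 0.05/frame:
  # death time ~ geometric(p = 0.05 + baseline) in frames
  n_org <- 400
  dt <- 2
  frames <- 100
  tracks <- purrr::map_dfr(seq_len(n_org), function(i) {
    tibble::tibble(
      experiment_id = "sim", well_id = "w1", cell_id = i,
      population = "unknown", t = (seq_len(frames) - 1) * dt,
      x = 0, y = 0, z = 0, speed = 1, sq_displacement = 1,
      dye_intensity = 0, dist_organoid = 1, dist_tcell = 50,
      marker_intensity = NA_real_
    )
  })
  labels <- tibble::tibble(cell_id = seq_len(n_org),
                           signature = "super engager")
  model <- killing_model(baseline_hazard = 0,
                         multipliers = c("super engager" = 0.05))
  kill <- simulate_organoid_killing(n_org, tracks, labels, model,
                                    seed = 17)
  dtimes <- kill$death_times$death_t
  expect_true(all(is.finite(dtimes) | dtimes == Inf))
  med_frames <- median(dtimes[is.finite(dtimes)]) / dt + 1
  # geometric median = ceiling(-1 / log2(1 - p)) ~ 14 frames at p = 0.05
  geo_med <- ceiling(-1 / log2(1 - 0.05))
  expect_lt(abs(med_frames - geo_med), 3)

  # zero hazards: no deaths, dye stays flat and noisy
  none <- simulate_organoid_killing(
    20, tracks[tracks$cell_id <= 20, ],
    labels[1:20, ], killing_model(baseline_hazard = 0,
                                  multipliers = c("super engager" = 0)),
    seed = 18
  )
  expect_true(all(none$death_times$death_t == Inf))
  expect_lt(max(none$organoids$dye_intensity), 10)

  # seed determinism
  again <- simulate_organoid_killing(n_org, tracks, labels, model,
                                     seed = 17)
  expect_identical(kill$death_times, again$death_times)
})

test_that("archetypes are separable in DTW space", {
  mix <- setNames(rep(12L, 9), signature_levels())
  sim <- simulate_tcell_tracks(mix, dt = 2, duration_h = 3.4, seed = 19)
  s <- preprocess_tracks(sim$tracks)
  d <- dtw_cross_distance(s)
  keys <- attr(d, "keys")
  arch <- sim$truth$archetype[match(keys$cell_id, sim$truth$cell_id)]
  within <- numeric(0)
  for (a in unique(arch)) {
    da <- d[arch == a, arch == a]
    within <- c(within, median(da[upper.tri(da)]))
  }
  # between-archetype centroid distance exceeds within-archetype spread
  meds <- sapply(unique(arch), function(a) {
    sapply(unique(arch), function(b) median(d[arch == a, arch == b]))
  })
  between <- meds[upper.tri(meds)]
  expect_gt(min(between), max(within) * 0.9)
  expect_gt(median(between), max(within))
})

test_that("simulated cell states reproduce their specification", {
  # point-mass structure: deterministic table
  priors <- default_signature_priors()
  one_run <- list(list(
    k = 1L,
    p_state_given_cluster = matrix(c(0, 0, 0, 1, 0), 1,
                                   dimnames = list(NULL,
                                                   engagement_levels())),
    weights = 1
  ))
  cs <- simulate_cell_states(50, priors, one_run,
                             state_probs = c("engaged" = 1), seed = 23)
  expect_true(all(cs$cells$state == "engaged"))
  expect_true(all(cs$cells$run_1 == 1L))

  # large n: empirical state frequencies converge to the composition
  big <- simulate_cell_states(20000, priors, seed = 29)
  freq <- table(big$cells$state) / 20000
  expect_lt(max(abs(freq - 0.2)), 0.02)

  # non-stochastic matrix is rejected
  bad <- list(list(k = 1L,
                   p_state_given_cluster = matrix(2, 1, 5,
                                                  dimnames = list(NULL,
                                                                  engagement_levels())),
                   weights = 1))
  expect_error(simulate_cell_states(10, priors, bad),
               class = "cotrack_config_error")
})
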