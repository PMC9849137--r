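test_that("interior gaps are filled by linear interpolation", {
  tr <- make_tracks(cells = 1, times = c(0, 2, 4))
  tr$speed <- c(2, NA, 4)
  tr <- tr[tr$t != 2, ]  # one missing interior frame
  out <- interpolate_gaps(tr, dt = 2)
  expect_equal(out$t, c(0, 2, 4))
  expect_equal(out$speed[out$t == 2], 3)  # midpoint

  # no gaps: identity
  full <- make_tracks(cells = 1:2, times = c(0, 2, 4))
  expect_equal(as.data.frame(interpolate_gaps(full, dt = 2)),
               as.data.frame(full))
})

test_that("interpolation matches the closed-form line through two gaps", {
  tr <- make_tracks(cells = 1, times = c(0, 2, 4, 6, 8))
  tr$speed <- c(1, NA, NA, NA, 9)
  tr$dist_organoid <- c(10, NA, NA, NA, 2)
  tr <- tr[tr$t %in% c(0, 8), ]
  out <- interpolate_gaps(tr, dt = 2)
  # independent piecewise-linear oracle: y(t) = y0 + (y1 - y0) * t / 8
  expect_equal(out$speed, 1 + (9 - 1) * out$t / 8)
  expect_equal(out$dist_organoid, 10 + (2 - 10) * out$t / 8)
})

test_that("tracks with < 2 frames are passed through with a warning", {
  tr <- make_tracks(cells = 1, times = 0)
  expect_warning(out <- interpolate_gaps(tr, dt = 2), "< 2 frames")
  expect_equal(nrow(out), 1)
})

test_that("cut_to_window yields L = floor(window*60/dt) + 1 frames", {
  tr <- binarize_tracks(make_tracks(cells = 1, times = seq(0, 238, by = 2)))
  s <- cut_to_window(tr, window_h = 3.3, dt = 2)
  expect_equal(attr(s, "frames_per_track"), 100L)
  expect_equal(nrow(s), 100)

  # dt = 30: L = 7; a 10-frame track keeps frames 1..7
  tr30 <- binarize_tracks(make_tracks(cells = 1, times = seq(0, 270, 30)))
  s30 <- cut_to_window(tr30, window_h = 3.3, dt = 30)
  expect_equal(attr(s30, "frames_per_track"), 7L)
  expect_equal(s30$t, seq(0, 180, 30))

  # a 5-frame track at dt = 30 is too short and is discarded, counted
  short <- binarize_tracks(make_tracks(cells = 1, times = seq(0, 120, 30)))
  s_short <- cut_to_window(short, window_h = 3.3, dt = 30)
  expect_equal(nrow(s_short), 0)
  expect_equal(attr(s_short, "n_discarded"), 1L)

  expect_error(cut_to_window(tr30, window_h = 0.2, dt = 30),
               class = "cotrack_config_error")
})

test_that("binarization thresholds distances and enforces absorbing death", {
  tr <- make_tracks(cells = 1, times = c(0, 2, 4))
  tr$dist_organoid <- c(1, 6, 2)
  tr$dye_intensity <- c(0, 10, 3)
  out <- binarize_tracks(tr, contact_thresh = 5, death_dye_thresh = 8)
  expect_equal(out$contact, c(1L, 0L, 1L))
  expect_equal(out$death, c(0L, 1L, 1L))  # monotone fill after crossing

  # idempotence of the death channel: rebinarizing the dye again cannot
  # lower death, and the channel is monotone in every track
  again <- binarize_tracks(out, contact_thresh = 5, death_dye_thresh = 8)
  expect_equal(again$death, out$death)
  expect_false(is.unsorted(out$death))

  # all-missing distances flag the track
  nd <- make_tracks(cells = 1, times = c(0, 2))
  nd$dist_organoid <- NA_real_
  flagged <- binarize_tracks(nd)
  expect_equal(nrow(attr(flagged, "flagged_cells")), 1)
})

test_that("two-threshold marker gate is tri-state", {
  g <- gate_marker(c(2, 7, 12, NA), low = 5, high = 10)
  expect_equal(as.character(g), c("neg", "indeterminate", "pos", NA))
})

test_that("dye rescaling is an affine 0-100 map within experiment", {
  tb <- tibble::tibble(experiment_id = "e1",
                       dye_intensity = c(10, 20, 30))
  expect_equal(rescale_dye(tb)$dye_rescaled, c(0, 50, 100))

  const <- tibble::tibble(experiment_id = "e1", dye_intensity = c(5, 5))
  expect_warning(out <- rescale_dye(const), "constant")
  expect_equal(out$dye_rescaled, c(0, 0))

  # two experiments rescale independently and each spans [0, 100];
  # within-experiment rank order is preserved
  two <- tibble::tibble(experiment_id = rep(c("a", "b"), each = 4),
                        dye_intensity = c(1, 7, 3, 5, 100, 400, 250, 300))
  out2 <- rescale_dye(two)
  for (e in c("a", "b")) {
    v <- out2$dye_rescaled[out2$experiment_id == e]
    raw <- out2$dye_intensity[out2$experiment_id == e]
    expect_equal(range(v), c(0, 100))
    expect_equal(order(v), order(raw))
  }
})
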