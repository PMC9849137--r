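test_that("track features match direct arithmetic", {
  s <- make_series(list(list(
    speed = rep(2, 5),
    contact = c(0L, 1L, 1L, 0L, 1L)
  )))
  f <- featurize_tracks(s)
  expect_equal(f$speed_mean, 2)
  expect_equal(f$speed_median, 2)
  expect_equal(f$speed_p90, 2)
  expect_equal(f$speed_sd, 0)
  expect_equal(f$contact_mean, 0.6)
  expect_equal(f$contact_cummean, mean(c(0, 1, 2, 2, 3)))  # 1.6
  expect_equal(f$contact_cummax, 3)
})

test_that("features equal an independent per-feature recomputation", {
  set.seed(21)
  sim <- simulate_tcell_tracks(c(engager = 6, lazy = 6), dt = 30,
                               duration_h = 3.5, seed = 21)
  s <- preprocess_tracks(sim$tracks, dt = 30)
  f <- featurize_tracks(s, include_interaction = TRUE)
  raw <- split(s, s$cell_id)
  for (cid in names(raw)) {
    df <- raw[[cid]][order(raw[[cid]]$frame), ]
    g <- f[f$cell_id == as.integer(cid), ]
    expect_equal(g$speed_mean, mean(df$speed))
    expect_equal(g$speed_p90, unname(quantile(df$speed, 0.9)))
    expect_equal(g$sq_displacement_sd, sd(df$sq_displacement))
    expect_equal(g$death_cummax, max(cumsum(df$death)))
    expect_equal(g$tcell_interaction_cummean,
                 mean(cumsum(df$tcell_interaction)))
  }
  expect_error(featurize_tracks(dplyr::select(s, -"contact")),
               class = "cotrack_schema_error")
})

test_that("classifier separates disjoint-support features almost perfectly", {
  set.seed(31)
  n <- 120
  feats <- tibble::tibble(
    experiment_id = "e1", well_id = "w1", cell_id = seq_len(2 * n),
    speed_mean = c(rnorm(n, 0, 0.1), rnorm(n, 10, 0.1)),
    contact_mean = c(runif(n, 0, 0.1), runif(n, 0.9, 1))
  )
  labels <- rep(c("a", "b"), each = n)
  m <- train_classifier(feats, labels, train_fraction = 0.8, seed = 1)
  expect_gte(m$heldout_accuracy, 0.95)
  expect_equal(sum(m$heldout_confusion),
               2 * n - length(m$forest$y))

  # training tracks classify at least as well as held-out
  pred <- classify_tracks(m, feats)
  expect_gte(mean(pred$signature == labels), m$heldout_accuracy)

  # probability rows sum to one
  probs <- as.matrix(pred[, grep("^p_", names(pred))])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))

  # order invariance: permuting input rows permutes output rows
  perm <- sample(nrow(feats))
  pred2 <- classify_tracks(m, feats[perm, ])
  expect_equal(pred2$signature, pred$signature[perm])
})

test_that("degenerate classifier inputs error or stay at chance", {
  feats <- tibble::tibble(cell_id = 1:10, speed_mean = rnorm(10))
  expect_error(train_classifier(feats, rep("a", 10)),
               class = "cotrack_config_error")

  # permuted labels: held-out accuracy compatible with chance (1/k)
  set.seed(41)
  n <- 90
  k <- 9
  feats <- tibble::tibble(cell_id = seq_len(n * k),
                          f1 = rnorm(n * k), f2 = rnorm(n * k))
  labels <- sample(rep(letters[1:k], n))
  m <- train_classifier(feats, labels, train_fraction = 0.5, seed = 2)
  n_test <- sum(m$heldout_confusion)
  p0 <- 1 / k
  tol <- 3 * sqrt(p0 * (1 - p0) / n_test)
  expect_lt(abs(m$heldout_accuracy - p0), tol)

  # empty input classifies to an empty tibble
  expect_equal(nrow(classify_tracks(m, feats[0, ])), 0)
  expect_error(classify_tracks(m, dplyr::select(feats, -"f1")),
               class = "cotrack_schema_error")
})

test_that("composition percentages, chi-squared and correlations", {
  one <- tibble::tibble(condition = "c1",
                        signature = rep("super engager", 10))
  cs <- composition_stats(one)
  expect_equal(cs$composition$pct, 100)

  # hand-computed 2x2 chi-squared with expected counts of 5: X2 = 20
  lab <- tibble::tibble(
    condition = rep(c("A", "B"), each = 10),
    signature = c(rep("x", 10), rep("y", 10))
  )
  expect_equal(composition_stats(lab)$chisq$statistic, 20)

  # identical compositions give statistic 0
  same <- tibble::tibble(condition = rep(c("A", "B"), each = 10),
                         signature = rep(c("x", "y"), 10))
  expect_equal(composition_stats(same)$chisq$statistic, 0)

  # percentages sum to 100 per condition
  set.seed(51)
  many <- tibble::tibble(
    condition = sample(c("A", "B", "C"), 300, TRUE),
    well_id = sample(c("w1", "w2", "w3"), 300, TRUE),
    signature = sample(signature_levels(), 300, TRUE)
  )
  cmp <- composition_stats(many, compare = c("A", "B"),
                           condition_scalar = c(A = 10, B = 50, C = 90))
  sums <- tapply(cmp$composition$pct, cmp$composition$condition, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_true(all(c("diff", "p.value") %in% names(cmp$pairwise)))
  expect_true(all(is.na(cmp$correlation$r) |
                    abs(cmp$correlation$r) <= 1))
})
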