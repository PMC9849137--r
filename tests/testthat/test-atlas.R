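test_that("DTW distance matches hand-computed and degenerate cases", {
  a <- matrix(c(0, 0, 0))
  b <- matrix(c(1, 1, 1))
  expect_equal(dtw_distance(a, b), 3)  # diagonal path, unit cost per step
  expect_equal(dtw_distance(a, a), 0)
  expect_error(dtw_distance(a, matrix(1, 3, 2)),
               class = "cotrack_schema_error")
})

test_that("DTW equals exhaustive path enumeration on short series", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    a <- matrix(rnorm(n * 2), n, 2)
    b <- matrix(rnorm(m * 2), m, 2)
    expect_equal(dtw_distance(a, b), dtw_brute(a, b), tolerance = 1e-12)
  }
})

test_that("cross-distance matrix is symmetric with zero diagonal", {
  sim <- simulate_tcell_tracks(c(static = 4, `super scanner` = 4),
                               dt = 30, duration_h = 3.5, seed = 3)
  s <- preprocess_tracks(sim$tracks, dt = 30)
  d <- dtw_cross_distance(s)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, nrow(d)))
  expect_true(all(d >= 0))
})

test_that("two separable archetypes are recovered perfectly at k = 2", {
  sim <- simulate_tcell_tracks(c(static = 12, `super scanner` = 12),
                               dt = 30, duration_h = 3.5, seed = 5)
  s <- preprocess_tracks(sim$tracks, dt = 30)
  d <- dtw_cross_distance(s)
  cl <- embed_and_cluster(d, k = 2, seed = 1)
  j <- dplyr::inner_join(cl, sim$truth, by = "cell_id")
  tab <- table(j$archetype, j$cluster)
  # adjusted agreement 1.0: each archetype maps to exactly one cluster
  expect_equal(sort(apply(tab, 1, max)), sort(rowSums(tab)))

  # fixed seed reproduces the clustering bit for bit
  cl2 <- embed_and_cluster(d, k = 2, seed = 1)
  expect_identical(cl, cl2)

  # k = 1 puts everything in one cluster with no outliers at sd = Inf
  cl1 <- embed_and_cluster(d, k = 1, outlier_sd = Inf, seed = 1)
  expect_equal(unique(cl1$cluster), 1L)
  expect_false(any(cl1$outlier))

  expect_error(embed_and_cluster(d, k = 500), class = "cotrack_config_error")
})

test_that("cluster summaries are min-max rescaled per channel", {
  s <- make_series(list(
    list(speed = rep(1, 5)), list(speed = rep(1.1, 5)),
    list(speed = rep(3, 5)), list(speed = rep(2.9, 5))
  ))
  clustering <- tibble::tibble(
    experiment_id = "e1", well_id = "w1", cell_id = 1:4,
    cluster = c(1L, 1L, 2L, 2L)
  )
  cs <- summarize_clusters(s, clustering)
  expect_equal(cs$Sp, c(0, 1))          # slow cluster 0, fast cluster 1
  expect_true(all(cs[, c("OC", "Dis", "Sp", "TI", "CD")] >= 0 &
                    cs[, c("OC", "Dis", "Sp", "TI", "CD")] <= 1))

  # a single cluster degenerates to all zeros (min = max rule)
  one <- summarize_clusters(s, dplyr::mutate(clustering, cluster = 1L))
  expect_equal(unlist(one[, c("OC", "Dis", "Sp", "TI", "CD")]),
               setNames(rep(0, 5), c("OC", "Dis", "Sp", "TI", "CD")))
})

test_that("naming rules assign canonical signatures", {
  row <- function(OC, Dis, Sp, TI, CD, cluster = 1L) {
    tibble::tibble(cluster = cluster, n = 10L, OC = OC, Dis = Dis,
                   Sp = Sp, TI = TI, CD = CD)
  }
  expect_equal(name_clusters(row(1, 0.1, 0.2, 0.3, 0.1))$signature,
               "super engager")
  expect_equal(name_clusters(row(0.1, 0.5, 0.5, 0.5, 1))$signature, "dying")
  expect_equal(name_clusters(row(0.6, 0.5, 0.5, 0.5, 0.2))$signature,
               "engager")
  expect_equal(name_clusters(row(0.3, 0.5, 0.5, 0.5, 0.2))$signature,
               "tickler")

  # five zero-contact clusters rank by speed into the motility ladder
  five <- dplyr::bind_rows(lapply(1:5, function(i) {
    row(0, 0.2, c(0.9, 0.1, 0.5, 0.3, 0.7)[i], 0.2, 0.1, cluster = i)
  }))
  nm <- name_clusters(five)
  expect_equal(nm$signature[order(five$Sp)],
               c("static", "lazy", "slow scanner", "medium scanner",
                 "super scanner"))

  # more motility clusters than names: overflow named scanner-N
  six <- dplyr::bind_rows(lapply(1:6, function(i) {
    row(0, 0.2, i / 6, 0.2, 0.1, cluster = i)
  }))
  expect_true(any(grepl("^scanner-", name_clusters(six)$signature)))
})

test_that("back-projection carries labels onto every labelled frame", {
  sim <- simulate_tcell_tracks(c(static = 3, engager = 2), dt = 30,
                               duration_h = 3.5, seed = 9)
  s <- preprocess_tracks(sim$tracks, dt = 30)
  d <- dtw_cross_distance(s)
  cl <- embed_and_cluster(d, k = 2, seed = 1)
  cl$signature <- c("static", "engager")[cl$cluster]
  bp <- backproject(cl, sim$tracks)
  # row count equals total frames of labelled cells
  expect_equal(nrow(bp), nrow(sim$tracks))
  expect_true(all(c("signature", "outlier") %in% names(bp)))

  # unlabelled cells are omitted and counted
  bp2 <- backproject(cl[-1, ], sim$tracks)
  expect_equal(attr(bp2, "n_unlabelled"), 1)
  expect_lt(nrow(bp2), nrow(sim$tracks))
})
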