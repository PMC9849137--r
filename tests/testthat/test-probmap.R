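test_that("engagement-state rules evaluate contact histories", {
  # contact throughout the final 2 h: super engaged
  s1 <- make_series(list(list(speed = rep(1, 12),
                              contact = rep(1L, 12))), dt = 30)
  st1 <- infer_engagement_states(s1)
  expect_equal(st1$state, "super engaged")

  # zero contact over the whole record: nonengaged-enriched
  s2 <- make_series(list(list(speed = rep(1, 12),
                              contact = rep(0L, 12))), dt = 30)
  expect_equal(infer_engagement_states(s2)$state, "nonengaged-enriched")

  # an hour of contact ending well before harvest: engaged (>= 30 min
  # cumulative, not in contact at harvest, below the super fraction)
  contact <- rep(0L, 14)
  contact[2:3] <- 1L  # 2 frames x 30 min / ... 60 min total
  s3 <- make_series(list(list(speed = rep(1, 14), contact = contact)),
                    dt = 30)
  expect_equal(infer_engagement_states(s3)$state, "engaged")

  # brief historical contact < 30 min: nonengaged
  brief <- rep(0L, 14)
  brief[2] <- 1L
  s4 <- make_series(list(list(speed = rep(1, 14), contact = brief)),
                    dt = 2)
  expect_equal(infer_engagement_states(s4)$state, "nonengaged")

  # control wells override by condition metadata
  st5 <- infer_engagement_states(
    s2, control_wells = tibble::tibble(experiment_id = "e1",
                                       well_id = "w1"))
  expect_equal(st5$state, "no-target control")
})

test_that("signature priors are empirical conditional frequencies", {
  states <- tibble::tibble(
    state = c(rep("engaged", 4), rep("super engaged", 2)),
    signature = c("engager", "engager", "engager", "tickler",
                  "super engager", "super engager")
  )
  pr <- estimate_signature_priors(states)
  eng <- pr[pr$state == "engaged", ]
  expect_equal(eng$engager, 0.75)
  expect_equal(eng$tickler, 0.25)
  se <- pr[pr$state == "super engaged", ]
  expect_equal(se$`super engager`, 1)  # point mass
  pm <- as.matrix(pr[, signature_levels(TRUE)])
  expect_true(all(abs(rowSums(pm) - 1) < 1e-9))
})

test_that("priors converge to the generator's emission table", {
  set.seed(81)
  pm <- prior_matrix(default_signature_priors())
  n <- 20000
  st <- sample(rownames(pm), n, replace = TRUE)
  sig <- vapply(st, function(s) {
    sample(colnames(pm), 1, prob = pm[s, ])
  }, character(1))
  est <- estimate_signature_priors(
    tibble::tibble(state = st, signature = sig)
  )
  est_m <- as.matrix(est[, colnames(pm)])
  rownames(est_m) <- est$state
  expect_lt(max(abs(est_m[rownames(pm), ] - pm)), 0.02)
})

worked_case <- function() {
  # 2 states x 2 signatures, one cluster mixing the states 50/50
  priors <- tibble::tibble(state = c("engaged", "nonengaged"),
                           a = c(0.8, 0.1), b = c(0.2, 0.9))
  class(priors) <- c("signature_priors", class(priors))
  cells <- tibble::tibble(
    cell_id = 1:2, state = c("engaged", "nonengaged"),
    pseudotime = c(1, 2), run_1 = 1L
  )
  list(priors = priors, cells = cells)
}

test_that("the transitivity product reproduces the worked case", {
  w <- worked_case()
  out <- map_behavior_probability(w$cells, w$priors)
  expect_equal(out$p_a, c(0.45, 0.45))
  expect_equal(out$p_b, c(0.55, 0.55))
})

test_that("degenerate and multi-run mappings behave exactly", {
  # single state, point-mass prior: probability 1 everywhere
  priors <- tibble::tibble(state = "engaged", a = 1, b = 0)
  class(priors) <- c("signature_priors", class(priors))
  cells <- tibble::tibble(cell_id = 1:5, state = "engaged",
                          pseudotime = 1:5, run_1 = c(1L, 1L, 2L, 2L, 2L))
  out <- map_behavior_probability(cells, priors)
  expect_equal(out$p_a, rep(1, 5))

  # R identical runs equal the single-run result exactly
  w <- worked_case()
  multi <- dplyr::mutate(w$cells, run_2 = run_1, run_3 = run_1)
  expect_equal(
    map_behavior_probability(multi, w$priors)[, c("p_a", "p_b")],
    map_behavior_probability(w$cells, w$priors)[, c("p_a", "p_b")]
  )

  # unknown state errors
  bad <- dplyr::mutate(w$cells, state = c("engaged", "mystery"))
  expect_error(map_behavior_probability(bad, w$priors),
               class = "cotrack_config_error")
})

test_that("probability conservation holds through random matrices", {
  set.seed(91)
  for (i in 1:50) {
    n_states <- sample(2:5, 1)
    n_sigs <- sample(2:6, 1)
    pm <- matrix(rgamma(n_states * n_sigs, 1), n_states)
    pm <- pm / rowSums(pm)
    priors <- tibble::as_tibble(pm, .name_repair = "minimal")
    names(priors) <- paste0("s", seq_len(n_sigs))
    priors <- dplyr::bind_cols(
      tibble::tibble(state = paste0("e", seq_len(n_states))), priors)
    class(priors) <- c("signature_priors", class(priors))
    cells <- tibble::tibble(
      cell_id = 1:40,
      state = sample(priors$state, 40, replace = TRUE),
      pseudotime = runif(40),
      run_1 = sample(1:3, 40, replace = TRUE),
      run_2 = sample(1:2, 40, replace = TRUE)
    )
    out <- map_behavior_probability(cells, priors)
    probs <- as.matrix(out[, grep("^p_", names(out))])
    expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  }
})

test_that("sampling error shrinks like n^(-1/2) and runs average", {
  errs <- vapply(c(200, 3200), function(n) {
    cs <- simulate_cell_states(n, seed = 101)
    mapped <- map_behavior_probability(cs$cells,
                                       default_signature_priors())
    probs <- as.matrix(mapped[, grep("^p_", names(mapped))])
    mean(abs(probs - cs$analytic))
  }, numeric(1))
  # 16x the cells: expect roughly 4x less error; allow half that
  expect_lt(errs[2], errs[1] / 2)
})

test_that("pseudotime offset places controls first", {
  cells <- tibble::tibble(
    state = c("no-target control", "no-target control", "engaged"),
    pseudotime = c(1, 3, 0.5)
  )
  out <- offset_pseudotime(cells)
  expect_equal(out$pseudotime, c(1, 3, 3.5))
})

test_that("stage partition follows dominance switches", {
  # probabilities hard-switching at pseudotime quartiles
  n <- 400
  pt <- seq(0, 1, length.out = n)
  grp <- cut(pt, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
             labels = c("ctrl", "non", "eng", "sup"))
  cells <- tibble::tibble(
    cell_id = seq_len(n), pseudotime = pt,
    `p_no-target control` = as.numeric(grp == "ctrl"),
    p_static = as.numeric(grp == "non"),
    p_engager = as.numeric(grp == "eng"),
    `p_super engager` = as.numeric(grp == "sup")
  )
  out <- partition_stages(cells, n_bins = 20)
  bins <- attr(out, "stage_bins")
  # each stage starts at its quartile boundary, within one bin
  starts <- vapply(split(bins$bin, bins$stage), min, numeric(1))
  expected <- c("baseline" = 1, "environmental stimuli" = 6,
                "short engagement" = 11, "prolonged engagement" = 16)
  expect_true(all(abs(starts[names(expected)] - expected) <= 1))
  expect_equal(as.character(out$stage[1]), "baseline")
  expect_equal(as.character(out$stage[n]), "prolonged engagement")

  # all-control input collapses to a single baseline stage
  ctrl <- dplyr::mutate(cells, p_static = 0, p_engager = 0,
                        `p_super engager` = 0,
                        `p_no-target control` = 1)
  expect_equal(unique(as.character(partition_stages(ctrl)$stage)),
               "baseline")
})

test_that("gene templates are recovered as patterns over pseudotime", {
  set.seed(111)
  n <- 250
  pt <- sort(runif(n, 0, 10))
  mk <- function(f) t(vapply(1:8, function(i) f(pt) + rnorm(n, 0, 0.4),
                             numeric(n)))
  expr <- rbind(mk(function(p) p / 2),
                mk(function(p) 5 - p / 2),
                mk(function(p) 4 * exp(-(p - 5)^2 / 2)))
  rownames(expr) <- paste0("g", 1:24)
  gd <- smooth_gene_dynamics(expr, pt, k_patterns = 3, seed = 1)
  truth <- rep(1:3, each = 8)
  tab <- table(truth, gd$patterns$pattern)
  # each template maps to one pattern: adjusted agreement >= 0.9 means
  # at most a couple of genes stray
  expect_gte(sum(apply(tab, 1, max)), 0.9 * 24)

  # constant gene: flat, outside k-means
  expr2 <- rbind(expr, flat = rep(2, n))
  gd2 <- smooth_gene_dynamics(expr2, pt, k_patterns = 3, seed = 1)
  expect_equal(gd2$patterns$pattern[25], "flat")

  # k = 1 puts all varying genes in one pattern
  gd1 <- smooth_gene_dynamics(expr, pt, k_patterns = 1, seed = 1)
  expect_equal(unique(gd1$patterns$pattern), "1")
})
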