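# Adaptation analyses: distance and overlap recovery, joint model,
# dimension controls, subsampling control.

test_that("distance beta is linear in the simulated adaptation gain", {
  d <- generate_task1_session(seed = 41)
  a <- sample_assignment(41)
  ev <- events_for_run(d, 1, a)
  dbar <- mean(d$trials$length)
  gains <- c(0, 0.1, 0.2, 0.3)
  betas <- vapply(gains, function(g) {
    m <- quiet_model("hpc", n_voxels = 2L, gamma_d = g, seed = 3)
    run <- simulate_run(ev, m, d$n_scans, d$tr, seed = 5, mean_distance = dbar)
    unname(distance_analysis(list(run))$beta)
  }, numeric(1L))
  expect_equal(betas, gains / dbar, tolerance = 1e-8)  # exact noiseless slope
})

test_that("task-2 colour conditions absorb colour-specific offsets", {
  a <- sample_assignment(42)
  d2 <- generate_task2_session(seed = 42, assignment = a)
  ev <- events_for_run(d2, 1)
  m <- quiet_model("hpc", n_voxels = 2L, gamma_d = 0.25, seed = 4)
  run <- simulate_run(ev, m, d2$n_scans, d2$tr, seed = 6)
  base <- distance_analysis(list(run), task = 2L)

  # inject per-colour baseline shifts at both stimulus positions
  run2 <- run
  set.seed(7)
  for (col in ball_colors()) {
    off <- rnorm(1, 0, 0.5)
    for (tt in c("stim1", "stim2")) {
      sel <- ev$trial_type == tt &
        (if (tt == "stim1") ev$color1 else ev$color2) == col
      x <- actmap:::hrf_regressor(ev$onset[sel], ev$duration[sel], off,
                                  d2$n_scans, d2$tr)
      run2$Y <- run2$Y + matrix(x, ncol = ncol(run2$Y), nrow = length(x))
    }
  }
  shifted <- distance_analysis(list(run2), task = 2L)
  expect_lt(abs(shifted$beta - base$beta), 1e-8)
})

test_that("overlap gain propagates with its sign through the pipeline", {
  d <- generate_task1_session(seed = 43)
  a <- sample_assignment(43)
  runs <- lapply(1:2, function(r) {
    ev <- events_for_run(d, r, a)
    m <- quiet_model("sma", n_voxels = 2L, seed = 5)
    simulate_run(ev, m, d$n_scans, d$tr, seed = r, mean_distance = mean(d$trials$length))
  })
  res <- overlap_analysis(runs)
  expect_equal(unname(res$beta), 0.3, tolerance = 1e-8)

  # suppression with similarity flips the sign
  runs_neg <- lapply(1:2, function(r) {
    ev <- events_for_run(d, r, a)
    m <- quiet_model("sma", n_voxels = 2L, gamma_a = -0.3, seed = 5)
    simulate_run(ev, m, d$n_scans, d$tr, seed = r, mean_distance = mean(d$trials$length))
  })
  expect_equal(unname(overlap_analysis(runs_neg)$beta), -0.3, tolerance = 1e-8)

  # degenerate modulator raises with the run index
  bad <- runs[[1L]]
  bad$events$overlap[bad$events$trial_type == "stim2"] <- 0L
  expect_error(overlap_analysis(list(bad)), "run 1")
})

test_that("joint model separates distance and overlap effects", {
  d <- generate_task1_session(seed = 44)
  a <- sample_assignment(44)
  ev <- events_for_run(d, 1, a)
  dbar <- mean(d$trials$length)
  m <- quiet_model("hpc", n_voxels = 2L, gamma_d = 0.3, gamma_a = 0.2, seed = 6)
  run <- simulate_run(ev, m, d$n_scans, d$tr, seed = 9, mean_distance = dbar)
  jt <- joint_analysis(list(run))
  expect_equal(unname(jt$beta["distance"]), 0.3 / dbar, tolerance = 1e-6)
  expect_equal(unname(jt$beta["overlap"]), 0.2, tolerance = 1e-6)

  # nested-model identity: no overlap effect -> joint overlap beta ~ 0 and
  # the distance beta matches its marginal fit
  m0 <- quiet_model("hpc", n_voxels = 2L, gamma_d = 0.3, seed = 6)
  run0 <- simulate_run(ev, m0, d$n_scans, d$tr, seed = 9, mean_distance = dbar)
  jt0 <- joint_analysis(list(run0))
  expect_lt(abs(jt0$beta["overlap"]), 1e-8)
  expect_equal(unname(jt0$beta["distance"]),
               unname(distance_analysis(list(run0))$beta), tolerance = 1e-6)
})

test_that("conjunctive 2D adaptation dominates the one-dimensional controls", {
  betas <- vapply(1:10, function(i) {
    d <- generate_task1_session(seed = 500 + i)
    a <- sample_assignment(500 + i)
    ev <- events_for_run(d, 1, a)
    m <- quiet_model("hpc", n_voxels = 2L, gamma_d = 0.3, seed = 2)
    run <- simulate_run(ev, m, d$n_scans, d$tr, seed = i,
                        mean_distance = mean(d$trials$length))
    c(d2 = unname(distance_analysis(list(run))$beta),
      d1a = unname(distance_analysis(list(run), dimension = 1L)$beta),
      d1b = unname(distance_analysis(list(run), dimension = 2L)$beta))
  }, numeric(3L))
  # scaled by modulator sd (effect size per run): the 2D regressor dominates
  expect_gt(mean(betas["d2", ]), mean(betas["d1a", ]))
  expect_gt(mean(betas["d2", ]), mean(betas["d1b", ]))
})

test_that("subsampling control is a seeded no-op on balanced classes", {
  d <- generate_task1_session(seed = 45)
  a <- sample_assignment(45)
  ev <- events_for_run(d, 1, a)
  m <- quiet_model("hpc", n_voxels = 2L, gamma_d = 0.3, seed = 8)
  run <- simulate_run(ev, m, d$n_scans, d$tr, seed = 4,
                      mean_distance = mean(d$trials$length))
  s2 <- ev[ev$trial_type == "stim2", ]

  # balanced labels: nothing is dropped, result equals the plain analysis
  lab_bal <- rep(c("x", "y"), 12L)
  sub_bal <- subsample_equalize(list(run), list(lab_bal), n_iter = 2L, seed = 1)
  expect_equal(unname(sub_bal$beta), unname(distance_analysis(list(run))$beta),
               tolerance = 1e-10)

  # unbalanced: deterministic under seed, near the balanced estimate
  lab <- ifelse(actmap:::is_short_distance(s2$distance), "short", "long")
  sub1 <- subsample_equalize(list(run), list(lab), n_iter = 10L, seed = 2)
  sub2 <- subsample_equalize(list(run), list(lab), n_iter = 10L, seed = 2)
  expect_identical(sub1$beta, sub2$beta)
  expect_equal(unname(sub1$beta), 0.3 / mean(d$trials$length), tolerance = 0.02)

  # empty class
  expect_error(subsample_equalize(list(run), list(rep("x", 24L)), seed = 1),
               "two trial classes")
})
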