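# Design generation: displacement geometry, action assignments, balanced
# task-1/task-2 sequences, rating sets, overlap classification.

test_that("admissible displacements match the sampling geometry", {
  b0 <- admissible_displacements(0)
  expect_equal(b0$dx, c(4, 3, 2))
  expect_equal(b0$dy, c(0, 0, 0))
  expect_equal(b0$length, c(4, 3, 2))

  b90 <- admissible_displacements(90)
  expect_equal(b90$dx, c(0, 0, 0))
  expect_equal(b90$dy, c(4, 3, 2))

  b30 <- admissible_displacements(30)
  expect_equal(b30$dx, c(4, 3, 2))
  expect_equal(b30$dy, c(2, 2, 1))
  expect_equal(round(b30$angle, 2), c(26.57, 33.69, 26.57))
  expect_equal(b30$length, sqrt(c(20, 13, 5)))

  # every non-cardinal bin has exactly the three lengths within +-4 degrees
  for (nom in setdiff(seq(0, 330, 30), c(0, 90, 180, 270))) {
    d <- admissible_displacements(nom)
    expect_equal(sort(round(d$length^2)), c(5, 13, 20))
    expect_true(all(abs(actmap:::angle_diff(d$angle, nom)) <= 4))
  }
})

test_that("action assignments satisfy the dissimilarity constraint", {
  for (s in 1:25) {
    a <- sample_assignment(s)
    expect_true(all(a$sigma1 != a$sigma2))
    expect_equal(sort(unname(a$sigma1)), 0:4)
    expect_equal(sort(unname(a$sigma2)), 0:4)
    expect_equal(sort(unname(a$landmark_colors)), 1:6)
  }
  # determinism
  expect_identical(sample_assignment(7), sample_assignment(7))
})

test_that("number of admissible assignment pairs matches brute force", {
  # oracle: count permutation pairs with no positionwise agreement
  perms <- actmap:::all_permutations(5L)
  count <- 0L
  for (i in seq_len(nrow(perms))) {
    agree <- perms == matrix(perms[i, ], nrow(perms), 5L, byrow = TRUE)
    count <- count + sum(rowSums(agree) == 0L)
  }
  # for each sigma1 the admissible sigma2 are derangements relative to it
  expect_equal(count, 120L * 44L)
  # identity pair violates the constraint at every label
  expect_false(all(0:4 != 0:4))
})

test_that("task-1 sessions satisfy the protocol balance constraints", {
  for (s in 1:12) {
    d <- generate_task1_session(seed = s)
    tr <- d$trials
    expect_equal(nrow(tr), 144L)
    expect_equal(length(unique(tr$run)), 6L)

    # geometry: end = start + displacement, on the grid
    expect_equal(tr$end_i, tr$start_i + tr$dx)
    expect_true(all(tr$end_i >= 0 & tr$end_i <= 4))
    expect_true(all(tr$end_j >= 0 & tr$end_j <= 4))

    for (b in 0:11) {
      bt <- tr[tr$bin == b, ]
      expect_equal(nrow(bt), 12L)                         # 12 samples per bin
      expect_equal(nrow(unique(bt[, c("start_i", "start_j")])), 12L)
      for (r in 1:6) {
        rt <- bt[bt$run == r, ]
        expect_equal(nrow(rt), 2L)                        # twice per run
        expect_true(any(rt$trial <= 12) && any(rt$trial > 12))  # both halves
        expect_gt(abs(diff(rt$trial)), 1L)                # non-consecutive
      }
    }

    # alignment-class structure
    for (r in 1:6) {
      cls <- tr$aligned[tr$run == r]
      rl <- rle(cls)
      expect_lte(max(rl$lengths), 3L)
      trans <- table(factor(paste0(as.integer(cls[-24]), as.integer(cls[-1])),
                            levels = c("00", "01", "10", "11")))
      expect_true(all(trans >= 5L & trans <= 6L))
    }

    # distance bookkeeping
    st <- direction_statistics(d)
    expect_equal(st$n_short[st$nominal %% 90 == 0], rep(5L, 4L))
    expect_equal(st$n_longA[st$nominal %% 90 == 0], rep(3L, 4L))
    expect_equal(st$n_short[st$nominal %% 90 != 0], rep(6L, 8L))
    expect_equal(st$n_longA[st$nominal %% 90 != 0], rep(3L, 8L))

    # probe balance: 4 groups x 3 per alignment class per run
    grp <- tr$probe
    grp[grp %in% c("statement-oneFalse", "statement-bothFalse")] <- "statement-false"
    grp[grp == "statement-bothTrue"] <- "statement-true"
    for (r in 1:6) {
      tab <- table(grp[tr$run == r], tr$aligned[tr$run == r])
      expect_true(all(tab == 3L))
    }
  }
  # determinism
  expect_identical(generate_task1_session(seed = 3)$trials,
                   generate_task1_session(seed = 3)$trials)
})

test_that("per-bin occurrence counts hold across many seeds", {
  for (s in 101:200) {
    tr <- generate_task1_session(seed = s)$trials
    expect_equal(as.vector(table(tr$bin)), rep(12L, 12L))
    expect_equal(max(rle(tr$aligned[tr$run == 1])$lengths) <= 3, TRUE)
  }
})

test_that("realised angles deviate from nominal by 3.43 or 3.69 degrees", {
  tr <- generate_task1_session(seed = 5)$trials
  nc <- tr[tr$nominal %% 90 != 0, ]
  dev <- round(abs(actmap:::angle_diff(nc$angle, nc$nominal)), 2)
  expect_true(all(dev %in% c(3.43, 3.69)))
  card <- tr[tr$nominal %% 90 == 0, ]
  expect_true(all(abs(actmap:::angle_diff(card$angle, card$nominal)) < 1e-9))
})

test_that("direction statistics reproduce the printed mean angles and distances", {
  st <- direction_statistics(generate_task1_session(seed = 9))
  expect_equal(st$mean_angle,
               c(0, 28.35, 61.65, 90, 118.35, 151.65, 180,
                 208.35, 241.65, 270, 298.35, 331.65))
  noncard <- st$nominal %% 90 != 0
  expect_equal(st$mean_distance[noncard],
               rep(sqrt(5) / 2 + sqrt(20) / 4 + sqrt(13) / 4, 8),
               tolerance = 1e-12)
})

test_that("session-wise alignment transitions are near-balanced", {
  for (s in 1:10) {
    tr <- generate_task1_session(seed = s * 17)$trials
    counts <- c("00" = 0, "01" = 0, "10" = 0, "11" = 0)
    for (r in 1:6) {
      cls <- as.integer(tr$aligned[tr$run == r])
      tt <- table(factor(paste0(cls[-24], cls[-1]), levels = names(counts)))
      counts <- counts + tt
    }
    expect_lte(max(counts) - min(counts), 2L)
  }
})

test_that("task-2 sessions satisfy the pairing and adjacency rules", {
  for (s in 1:8) {
    a <- sample_assignment(s)
    d <- generate_task2_session(seed = s, assignment = a)
    tr <- d$trials
    expect_equal(nrow(tr), 150L)
    for (r in 1:5) {
      rt <- tr[tr$run == r, ]
      expect_equal(nrow(rt), 30L)
      # 15 unordered pairs twice, once per order
      key <- paste(pmin(rt$color1, rt$color2), pmax(rt$color1, rt$color2))
      expect_equal(as.vector(table(key)), rep(2L, 15L))
      okey <- paste(rt$color1, rt$color2)
      expect_equal(max(table(okey)), 1L)
      # adjacency rules
      expect_true(all(key[-1] != key[-30]))
      expect_true(all(rt$color1[-1] != rt$color2[-30]))
    }
    # distances come from the participant landmark map
    expect_true(all(tr$length > 0))
  }
})

test_that("rating sets present every pair twice, all pairs before repeats", {
  r8 <- generate_rating_set(8, seed = 1)
  expect_equal(nrow(r8), 56L)
  key <- paste(pmin(r8$item_a, r8$item_b), pmax(r8$item_a, r8$item_b))
  expect_equal(length(unique(key[1:28])), 28L)      # all pairs in block 1
  expect_equal(as.vector(table(key)), rep(2L, 28L))
  # each ordered pair exactly once
  expect_equal(max(table(paste(r8$item_a, r8$item_b))), 1L)

  r6 <- generate_rating_set(6, seed = 2)
  expect_equal(nrow(r6), 30L)
  expect_error(generate_rating_set(5), "must be 6 or 8")
})

test_that("overlap classification follows the shared-action rules", {
  expect_equal(overlap_count(c("right", "up"), c("right", "forward")), 1L)
  expect_equal(overlap_count(c("left", "up"), c("up", "left")), 2L)
  expect_equal(overlap_count(c("left", "up"), c("right", "forward")), 0L)
  # shared through different joysticks counts as one
  expect_equal(overlap_count(c("left", "up"), c("up", "forward")), 1L)
  expect_error(overlap_count(c("left", "up"), c("left", "up")), "identical")
})

test_that("events tables round-trip through TSV", {
  d <- generate_task1_session(seed = 2)
  a <- sample_assignment(2)
  ev <- events_for_run(d, 1, a)
  expect_equal(nrow(ev), 24L * 5L)
  expect_true(all(c("onset", "duration", "trial_type", "overlap") %in% names(ev)))
  expect_true(all(ev$overlap[ev$trial_type == "stim2"] %in% 0:2))
  tmp <- file.path(tempdir(), "actmap-events")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  paths <- write_events(d, tmp, assignment = a)
  back <- read_events(paths[1L])
  expect_equal(back$onset, ev$onset)
  expect_equal(back$trial_type, ev$trial_type)
})
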