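# RSA: pattern extraction, shrinkage covariance, Mahalanobis/crossnobis
# RDMs, periodicity and position models, model correlations.

test_that("condition patterns are run-averaged and z-scored per voxel", {
  beta1 <- matrix(1:48, 12L, 4L, dimnames = list(actmap:::direction_condition_names(), NULL))
  f1 <- structure(list(beta = beta1), class = "glm_fit")
  f2 <- structure(list(beta = beta1 + 12), class = "glm_fit")
  p <- condition_patterns(list(f1, f2), zscore = "none")
  expect_equal(unname(p), unname(beta1 + 6))  # average of runs

  pz <- condition_patterns(list(f1, f2))
  expect_equal(unname(colMeans(pz)), rep(0, 4L))
  expect_equal(unname(apply(pz, 2L, sd)), rep(1, 4L))

  # constant voxel dropped with warning
  beta3 <- beta1; beta3[, 2L] <- 5
  f3 <- structure(list(beta = beta3), class = "glm_fit")
  expect_warning(p3 <- condition_patterns(list(f3)), "constant")
  expect_equal(ncol(p3), 3L)

  # missing condition errors
  f4 <- structure(list(beta = beta1[-1L, , drop = FALSE]), class = "glm_fit")
  expect_error(condition_patterns(list(f4)), "missing direction")
})

test_that("shrinkage covariance interpolates between sample and diagonal", {
  set.seed(3)
  x <- matrix(rnorm(200 * 5), 200L, 5L)
  s0 <- shrink_cov(x, lambda = 0)
  expect_equal(unname(s0), unname(cov(x)), tolerance = 1e-12, ignore_attr = TRUE)
  s1 <- shrink_cov(x, lambda = 1)
  expect_equal(unname(s1), diag(diag(cov(x))), tolerance = 1e-12, ignore_attr = TRUE)
  sa <- shrink_cov(x)
  lam <- attr(sa, "lambda")
  expect_true(lam > 0 && lam < 1)
  expect_equal(diag(sa), diag(cov(x)), tolerance = 1e-12)
})

test_that("Mahalanobis RDM equals hand-computed quadratic forms", {
  p <- rbind(dir_a = c(1, 0), dir_b = c(0, 1), dir_c = c(2, 2))
  d <- neural_rdm(p)  # identity covariance: squared Euclidean / n_voxels
  expect_equal(d["dir_a", "dir_b"], 1)
  expect_equal(d["dir_a", "dir_c"], 2.5)
  expect_equal(d["dir_b", "dir_c"], 2.5)
  expect_equal(unname(diag(d)), rep(0, 3L))

  # with a known whitening matrix: d_ij = delta' W delta / V
  set.seed(9)
  res <- matrix(rnorm(500 * 2), 500L, 2L) %*% rbind(c(1, 0.6), c(0, 0.8))
  dW <- neural_rdm(p, residuals = res)
  W <- solve(shrink_cov(res))
  delta <- p[1L, ] - p[2L, ]
  expect_equal(dW["dir_a", "dir_b"],
               as.numeric(delta %*% W %*% delta) / 2, tolerance = 1e-10)
})

test_that("crossnobis is unbiased for identical condition patterns", {
  m <- region_model("control", n_voxels = 30L, sigma_p = 1, seed = 11)
  set.seed(11)
  means <- replicate(600, {
    p <- simulate_condition_patterns(m, n_runs = 3L)
    mean(actmap:::upper_tri(neural_rdm(p, method = "crossnobis")))
  })
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 2 * se)
  expect_true(any(means < 0))  # cross-validated distances may be negative
})

test_that("periodicity models encode the angular-remainder rule", {
  m6 <- model_rdm_periodicity(6)
  expect_equal(m6["dir_060", "dir_120"], 0)
  expect_equal(m6["dir_060", "dir_090"], 1)
  expect_equal(m6["dir_030", "dir_090"], 0)   # 60-degree difference
  m4 <- model_rdm_periodicity(4)
  expect_equal(m4["dir_000", "dir_090"], 0)
  expect_equal(m4["dir_000", "dir_030"], 1)
  # invariance to a global 60-degree relabelling
  m6_rot <- model_rdm_periodicity(6, angles = (seq(0, 330, 30) + 60) %% 360)
  expect_equal(unname(unclass(m6_rot)), unname(unclass(m6)))
  # k = 5 is constant off-diagonal at 30-degree sampling: untestable
  m5 <- model_rdm_periodicity(5)
  expect_true(all(actmap:::upper_tri(m5) == 1))
  expect_error(rdm_correlation(m6, m5), "constant")
})

test_that("position models follow the occupancy-correlation construction", {
  d <- generate_task1_session(seed = 33)
  for (w in c("start", "end", "both")) {
    m <- model_rdm_positions(d, w)
    expect_equal(unname(diag(m)), rep(0, 12L))
    expect_true(isSymmetric(unname(unclass(m))))
  }
  # hand oracle: dissimilarity = 1 - correlation of the 25-cell count vectors
  ms <- model_rdm_positions(d, "start")
  occ <- matrix(0, 12L, 25L)
  for (b in 0:11) {
    dd <- d$trials[d$trials$bin == b, ]
    for (k in seq_len(nrow(dd))) {
      cell <- dd$start_i[k] * 5L + dd$start_j[k] + 1L
      occ[b + 1L, cell] <- occ[b + 1L, cell] + 1L
    }
  }
  expect_equal(ms["dir_000", "dir_090"], 1 - cor(occ[1L, ], occ[4L, ]),
               tolerance = 1e-12)
  # opposite directions swap start/end cells: under the combined model they
  # are closer than orthogonal directions
  mb <- model_rdm_positions(d, "both")
  expect_lt(mb["dir_030", "dir_210"], mb["dir_030", "dir_090"])
})

test_that("model correlation has the documented sign convention", {
  m6 <- model_rdm_periodicity(6)
  noise <- matrix(0, 12, 12)
  noise[upper.tri(noise)] <- seq(-0.01, 0.01, length.out = 66)
  noise <- noise + t(noise)
  expect_equal(rdm_correlation(m6, m6), 1)
  inv <- 1 - unclass(m6); diag(inv) <- 0
  expect_equal(rdm_correlation(inv, m6), -1)
  # graded neural dissimilarity ranked consistently with the binary model
  expect_gt(rdm_correlation(unclass(m6) + noise, m6), 0.8)
})

test_that("noiseless hexadirectional data are best explained by the 6-fold model", {
  m <- quiet_model("ec", n_voxels = 200L, seed = 13)
  pats <- simulate_condition_patterns(m, n_runs = 2L)
  avg <- scale(apply(pats, c(2, 3), mean))
  rdm <- neural_rdm(avg)
  cors <- vapply(c(2, 3, 4, 6), function(k) {
    rdm_correlation(rdm, model_rdm_periodicity(k))
  }, numeric(1L))
  expect_equal(which.max(cors), 4L)           # the 6-fold model
  expect_lt(cors[3L], 0)                      # mismatched 4-fold
})

test_that("k-fold generative tuning is detected by the matching model only", {
  for (gen_k in c(4L, 6L)) {
    rs <- vapply(1:20, function(i) {
      m <- region_model("ec", n_voxels = 120L, k_fold = gen_k, sigma_p = 1,
                        seed = 700 + gen_k * 31 + i)
      pats <- simulate_condition_patterns(m, n_runs = 6L,
                                          seed = 900 + gen_k * 17 + i)
      rdm <- neural_rdm(scale(apply(pats, c(2, 3), mean)))
      c(match = rdm_correlation(rdm, model_rdm_periodicity(gen_k)),
        mismatch = rdm_correlation(rdm, model_rdm_periodicity(ifelse(gen_k == 6L, 4L, 6L))))
    }, numeric(2L))
    expect_true(all(rs["match", ] > 0.5))
    expect_lt(mean(rs["mismatch", ]), 0.05)
  }
})
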