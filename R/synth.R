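# Synthetic-participant simulator: hexadirectionally tuned multivoxel
# patterns, adaptation-scaled second-stimulus amplitudes, HRF-convolved BOLD
# with drift, confounds and AR(1) noise, condition-dependent inter-region
# coupling, and noisy monotone similarity ratings.

#' Generative model for one region of interest
#'
#' A population of voxels with a shared hexadirectional grid orientation and
#' random voxel phases: the response of voxel v to movement direction theta
#' is `b_v + a6 * cos(6 * (theta - phi) + psi_v)` plus pattern noise. The
#' shared-orientation/random-phase population is the minimal construct that
#' produces hexadirectional pattern similarity; it is a simulator stand-in,
#' not a biophysical claim. Adaptation gains scale the second-stimulus
#' response amplitude (see [stim2_amplitude()]).
#'
#' @param preset `"control"` (all effects zero), `"ec"` (grid amplitude
#'   only), `"hpc"` (distance-adaptation gain only), `"sma"` (overlap gain
#'   only).
#' @param n_voxels number of voxels.
#' @param a6 grid (hexadirectional) amplitude, >= 0.
#' @param k_fold angular periodicity of the directional tuning (6 for a
#'   hexadirectional grid code; other values support specificity checks).
#' @param phi grid orientation in degrees within `[0, 360/k_fold)`; drawn
#'   uniformly when `NULL`.
#' @param gamma_d distance-adaptation gain (positive: larger response for
#'   larger distances, i.e. adaptation for near pairs).
#' @param gamma_a overlap gain (positive: larger response for more shared
#'   actions, i.e. enhancement with similarity).
#' @param sigma_p pattern noise standard deviation.
#' @param sigma_b BOLD noise standard deviation (marginal).
#' @param rho AR(1) coefficient of the BOLD noise, `|rho| < 1`.
#' @param drift low-frequency drift amplitude.
#' @param baseline per-voxel baseline (scalar or vector).
#' @param seed integer seed for the voxel phases and orientation.
#' @return `region_model` list.
#' @export
region_model <- function(preset = c("control", "ec", "hpc", "sma"),
                         n_voxels = 200L, a6 = NULL, k_fold = 6L, phi = NULL,
                         gamma_d = NULL, gamma_a = NULL,
                         sigma_p = 1, sigma_b = 1, rho = 0.3,
                         drift = 1, baseline = 0, seed = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
                     control = list(a6 = 0,   gamma_d = 0,   gamma_a = 0),
                     ec      = list(a6 = 0.5, gamma_d = 0,   gamma_a = 0),
                     hpc     = list(a6 = 0,   gamma_d = 0.3, gamma_a = 0),
                     sma     = list(a6 = 0,   gamma_d = 0,   gamma_a = 0.3))
  a6 <- if (is.null(a6)) defaults$a6 else a6
  gamma_d <- if (is.null(gamma_d)) defaults$gamma_d else gamma_d
  gamma_a <- if (is.null(gamma_a)) defaults$gamma_a else gamma_a
  stopifnot(a6 >= 0, sigma_p >= 0, sigma_b >= 0, abs(rho) < 1)
  with_local_seed(seed, {
    if (is.null(phi)) phi <- stats::runif(1L, 0, 360 / k_fold)
    psi <- stats::runif(n_voxels, 0, 2 * pi)
    structure(list(n_voxels = as.integer(n_voxels), a6 = a6,
                   k_fold = as.integer(k_fold), phi = phi,
                   psi = psi, gamma_d = gamma_d, gamma_a = gamma_a,
                   sigma_p = sigma_p, sigma_b = sigma_b, rho = rho,
                   drift = drift,
                   baseline = rep_len(baseline, n_voxels)),
              class = "region_model")
  })
}

#' Multivoxel pattern evoked by a movement direction
#'
#' @param theta direction in degrees.
#' @param model a [region_model()].
#' @param sigma_p pattern noise; defaults to the model's.
#' @return numeric vector of length `n_voxels`.
#' @export
pattern_for_direction <- function(theta, model, sigma_p = model$sigma_p) {
  k <- model$k_fold %||% 6L
  mu <- model$baseline +
    model$a6 * cos(k * (theta - model$phi) * pi / 180 + model$psi)
  if (sigma_p > 0) mu <- mu + stats::rnorm(model$n_voxels, 0, sigma_p)
  mu
}

#' Second-stimulus response amplitude under adaptation and overlap gains
#'
#' `base * (1 + gamma_d * (d - dbar) / dbar + gamma_a * o)`: a positive
#' distance gain yields larger responses for pairs far apart in the space
#' (adaptation for near pairs); a positive overlap gain yields larger
#' responses for pairs sharing actions (enhancement with similarity).
#'
#' @param distance Euclidean distance d of the trial's pair.
#' @param overlap shared-action count o in `{0, 1, 2}`.
#' @param model a [region_model()].
#' @param mean_distance session mean distance dbar.
#' @param base baseline amplitude.
#' @return scalar (vectorised over trials).
#' @export
stim2_amplitude <- function(distance, overlap, model, mean_distance, base = 1) {
  base * (1 + model$gamma_d * (distance - mean_distance) / mean_distance +
            model$gamma_a * overlap)
}

# Default confound set: six slowly wandering motion-proxy time courses.
simulate_confounds <- function(n_scans, n = 6L) {
  conf <- vapply(seq_len(n), function(k) {
    cumsum(stats::rnorm(n_scans, 0, 0.05))
  }, numeric(n_scans))
  colnames(conf) <- paste0("motion_", seq_len(n))
  conf
}

#' Simulate one BOLD run for a region
#'
#' Per trial, the reflection period carries the direction-tuned multivoxel
#' pattern, the second stimulus carries the adaptation/overlap-scaled
#' amplitude, and the remaining events carry unit amplitudes. Event boxcars
#' are convolved with the canonical HRF and summed with low-frequency drift,
#' confound time courses (also returned, so a GLM can remove them exactly)
#' and AR(1) Gaussian noise.
#'
#' @param events an [events_for_run()] table (overlap column populated when
#'   the model has a non-zero overlap gain).
#' @param model a [region_model()].
#' @param n_scans,tr run geometry.
#' @param seed integer seed; the run is a pure function of (inputs, seed).
#' @param mean_distance session mean distance for amplitude centring;
#'   defaults to the mean over this run's trials.
#' @param n_confounds number of simulated motion-proxy confounds.
#' @return `bold_run`: list with `Y` (scans x voxels), `events`,
#'   `confounds` (data.frame), `tr`, `n_scans` and the per-event `truth`.
#' @export
simulate_run <- function(events, model, n_scans, tr = 1.5, seed = NULL,
                         mean_distance = NULL, n_confounds = 6L) {
  if (any(events$onset + events$duration > n_scans * tr + 1e-9)) {
    stop("events exceed run duration", call. = FALSE)
  }
  with_local_seed(seed, {
    V <- model$n_voxels
    s2 <- events[events$trial_type == "stim2", , drop = FALSE]
    if (is.null(mean_distance)) mean_distance <- mean(s2$distance)
    ov <- s2$overlap
    if (model$gamma_a != 0 && anyNA(ov)) {
      stop("overlap gain is non-zero but events carry no overlap values", call. = FALSE)
    }
    if (anyNA(ov)) ov <- rep(0, nrow(s2))
    amp2 <- stim2_amplitude(s2$distance, ov, model, mean_distance)

    # scalar-amplitude events share one convolved time course; reflection
    # events without a direction bin (task 2) carry unit amplitude too
    scalar_types <- events$trial_type %in% c("stim1", "question", "response") |
      (events$trial_type == "reflection" & is.na(events$bin))
    oth <- events[scalar_types, , drop = FALSE]
    y_scalar <- hrf_regressor(c(oth$onset, s2$onset),
                              c(oth$duration, s2$duration),
                              c(rep(1, nrow(oth)), amp2),
                              n_scans, tr)
    Y <- matrix(y_scalar, n_scans, V)

    refl <- events[events$trial_type == "reflection" & !is.na(events$bin), , drop = FALSE]
    patterns <- NULL
    if (nrow(refl) > 0L) {
      bins <- sort(unique(refl$bin))
      patterns <- matrix(NA_real_, length(bins), V,
                         dimnames = list(paste0("bin_", bins), NULL))
      for (k in seq_along(bins)) {
        sel <- refl$bin == bins[k]
        pat <- pattern_for_direction(refl$angle[which(sel)[1L]], model)
        patterns[k, ] <- pat
        y_bin <- hrf_regressor(refl$onset[sel], refl$duration[sel], 1, n_scans, tr)
        Y <- Y + tcrossprod(y_bin, pat)
      }
    }

    # drift: two slowest cosines of the high-pass set, random amplitudes
    drift_basis <- dct_basis(n_scans, tr)[, 1:2, drop = FALSE]
    Y <- Y + drift_basis %*% matrix(stats::rnorm(2L * V, 0, model$drift), 2L, V)

    conf <- simulate_confounds(n_scans, n_confounds)
    W <- matrix(stats::rnorm(ncol(conf) * V, 0, 0.5), ncol(conf), V)
    Y <- Y + conf %*% W

    if (model$sigma_b > 0) {
      innov <- matrix(stats::rnorm(n_scans * V, 0,
                                   model$sigma_b * sqrt(1 - model$rho^2)),
                      n_scans, V)
      noise <- apply(innov, 2L, function(e) {
        as.numeric(stats::filter(e, model$rho, method = "recursive"))
      })
      Y <- Y + noise
    }

    structure(list(Y = Y, events = events, confounds = as.data.frame(conf),
                   tr = tr, n_scans = n_scans,
                   truth = list(patterns = patterns, stim2_amplitude = amp2,
                                mean_distance = mean_distance)),
              class = "bold_run")
  })
}

#' Simulate run-wise direction-condition patterns
#'
#' Draws the 12 direction-evoked patterns for each run directly (one pattern
#' noise realisation per run and direction), the input expected by
#' [neural_rdm()]; a light-weight alternative to the full BOLD chain when
#' only the representational geometry matters.
#'
#' @param model a [region_model()].
#' @param n_runs number of runs.
#' @param seed integer seed.
#' @param angles direction angles in degrees; defaults to the 12 realised
#'   mean angles of the balanced design.
#' @return array `(runs, 12, voxels)`.
#' @export
simulate_condition_patterns <- function(model, n_runs = 6L, seed = NULL,
                                        angles = bin_mean_angles()) {
  with_local_seed(seed, {
    out <- array(NA_real_, c(n_runs, length(angles), model$n_voxels))
    for (r in seq_len(n_runs)) {
      for (a in seq_along(angles)) {
        out[r, a, ] <- pattern_for_direction(angles[a], model)
      }
    }
    dimnames(out) <- list(NULL, sprintf("dir_%03d", seq(0, 330, 30)), NULL)
    out
  })
}

#' Frequency-weighted mean realised angle per direction bin
#'
#' The design samples each non-cardinal bin at the short distance in half of
#' its trials and at each longer distance in a quarter, so the mean realised
#' angles are fixed by the admissible displacement geometry.
#'
#' @return numeric vector of 12 angles in degrees.
#' @export
bin_mean_angles <- function() {
  bins <- direction_bins()
  vapply(seq_len(12L), function(b) {
    d <- admissible_displacements(bins$nominal[b])
    w <- if (bins$cardinal[b]) c(3, 4, 5) / 12 else c(1, 1, 2) / 4
    a <- d$angle
    # weighted circular mean (all angles within +-4 deg of nominal)
    ref <- bins$nominal[b]
    (ref + sum(w * angle_diff(a, ref))) %% 360
  }, numeric(1L))
}

#' Simulate two coupled ROI time series
#'
#' The seed region is simulated as a single-voxel BOLD run; the target is
#' `alpha * seed + delta * (seed x convolved long-distance indicator)` plus
#' AR(1) noise, i.e. its coupling with the seed increases by `delta` during
#' long-distance trials.
#'
#' @param events an [events_for_run()] table for a task-1 run.
#' @param delta interaction (coupling-change) strength.
#' @param n_scans,tr run geometry.
#' @param seed integer seed.
#' @param alpha baseline coupling.
#' @param model single-voxel [region_model()] for the seed region.
#' @return list with `seed_ts`, `target_ts`, `long` (logical per trial),
#'   `events`, `confounds`.
#' @export
simulate_coupled_rois <- function(events, delta, n_scans, tr = 1.5,
                                  seed = NULL, alpha = 0.5,
                                  model = NULL) {
  with_local_seed(seed, {
    if (is.null(model)) {
      model <- region_model("control", n_voxels = 1L, sigma_p = 0,
                            seed = stats::runif(1L, 0, 1e6))
    }
    run <- simulate_run(events, model, n_scans, tr,
                        seed = stats::runif(1L, 0, 1e6))
    seed_ts <- as.numeric(run$Y[, 1L])
    s2 <- events[events$trial_type == "stim2", , drop = FALSE]
    long <- !is_short_distance(s2$distance)
    long_conv <- hrf_regressor(s2$onset[long], s2$duration[long], 1, n_scans, tr)
    innov <- stats::rnorm(n_scans, 0, model$sigma_b * sqrt(1 - model$rho^2))
    noise <- as.numeric(stats::filter(innov, model$rho, method = "recursive"))
    target <- alpha * seed_ts + delta * seed_ts * long_conv + noise
    list(seed_ts = seed_ts, target_ts = target, long = long,
         events = events, confounds = run$confounds)
  })
}

#' Simulate a similarity-rating dataset
#'
#' Rating = `1 - d / d_max + noise`, clipped to `[0, 1]`; every unordered
#' pair rated twice (independent noise per repetition), with presentation
#' orders as in [generate_rating_set()].
#'
#' @param positions items x 2 matrix of true grid positions.
#' @param sigma rating noise standard deviation.
#' @param seed integer seed.
#' @return data.frame with `trial`, `item_a`, `item_b`, `repeat_idx`,
#'   `rating`.
#' @export
simulate_ratings <- function(positions, sigma = 0, seed = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  with_local_seed(seed, {
    rs <- generate_rating_set(n, seed = stats::runif(1L, 0, 1e6))
    dmat <- as.matrix(stats::dist(positions))
    d <- dmat[cbind(rs$item_a, rs$item_b)]
    dmax <- max(dmat)
    rating <- 1 - d / dmax
    if (sigma > 0) rating <- rating + stats::rnorm(length(rating), 0, sigma)
    rs$rating <- pmin(1, pmax(0, rating))
    rs
  })
}

# short distance class: lengths 2 (cardinal) and sqrt(5) (non-cardinal)
is_short_distance <- function(length) {
  abs(length - 2) < 1e-9 | abs(length - sqrt(5)) < 1e-9
}
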