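# First-level GLM machinery: canonical HRF, event convolution, cosine
# high-pass drift set, and ordinary-least-squares estimation.

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response peak ~5 s, undershoot ~15 s,
#' undershoot ratio 1/6). The response to a unit impulse integrates to 5/6.
#'
#' @param t time in seconds (vector).
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t) {
  out <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  out[t < 0] <- 0
  out
}

# Convolve event boxcars with the HRF on an oversampled grid and sample at
# frame times. `heights` scales each event's boxcar.
hrf_regressor <- function(onsets, durations, heights, n_scans, tr, oversample = 8L) {
  dt <- tr / oversample
  ngrid <- n_scans * oversample
  u <- numeric(ngrid)
  durations <- rep_len(durations, length(onsets))
  heights <- rep_len(heights, length(onsets))
  for (k in seq_along(onsets)) {
    i0 <- floor(onsets[k] / dt) + 1L
    i1 <- max(i0, ceiling((onsets[k] + durations[k]) / dt))
    if (i0 > ngrid) stop("event exceeds run duration", call. = FALSE)
    i1 <- min(i1, ngrid)
    u[i0:i1] <- u[i0:i1] + heights[k]
  }
  h <- canonical_hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(u, rev(h), type = "open")[seq_len(ngrid)] * dt
  conv[seq.int(1L, ngrid, by = oversample)]
}

#' Orthonormal cosine drift basis for temporal high-pass filtering
#'
#' Discrete cosine set whose periods exceed `1 / cutoff` seconds; regressing
#' these out removes fluctuations below the cutoff frequency.
#'
#' @param n_scans number of volumes.
#' @param tr repetition time in seconds.
#' @param cutoff high-pass cutoff in Hz.
#' @return matrix with `floor(2 * duration * cutoff)` orthonormal columns.
#' @export
dct_basis <- function(n_scans, tr, cutoff = 0.01) {
  n_k <- floor(2 * n_scans * tr * cutoff)
  t_idx <- seq_len(n_scans) - 1L
  basis <- vapply(seq_len(n_k), function(k) {
    v <- cos(pi * (2 * t_idx + 1) * k / (2 * n_scans))
    v / sqrt(sum(v^2))
  }, numeric(n_scans))
  matrix(basis, nrow = n_scans, ncol = n_k,
         dimnames = list(NULL, if (n_k > 0) paste0("cosine_", seq_len(n_k))))
}

#' Build a first-level design matrix
#'
#' One HRF-convolved boxcar column per condition (`trial_type`), optional
#' parametric-modulator columns (per-run demeaned values scaling the boxcar
#' of their events before convolution), a cosine drift set below the
#' high-pass cutoff, unconvolved confound columns, and an intercept.
#'
#' @param events data.frame with `onset`, `duration`, `trial_type`.
#' @param n_scans number of volumes in the run.
#' @param tr repetition time in seconds.
#' @param modulators named list; each element is a list with `onsets`,
#'   `durations` and `values` (one value per event). Values are demeaned
#'   within the run before convolution.
#' @param confounds data.frame or matrix of nuisance time courses
#'   (`n_scans` rows), appended unconvolved.
#' @param hp_cutoff high-pass cutoff in Hz (drift columns below it).
#' @param oversample microtime resolution as a fraction of the TR.
#' @return `design_matrix`: list with the matrix `X` (named columns),
#'   `frame_times`, `condition_names`, `modulator_names`.
#' @export
build_design <- function(events, n_scans, tr, modulators = NULL,
                         confounds = NULL, hp_cutoff = 0.01, oversample = 8L) {
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(events)))
  if (any(events$onset + events$duration > n_scans * tr + 1e-9)) {
    stop("events exceed run duration", call. = FALSE)
  }
  conds <- unique(events$trial_type)
  cols <- list()
  for (cn in conds) {
    sel <- events$trial_type == cn
    cols[[cn]] <- hrf_regressor(events$onset[sel], events$duration[sel],
                                1, n_scans, tr, oversample)
  }
  mod_names <- character(0L)
  for (mn in names(modulators)) {
    m <- modulators[[mn]]
    if (length(m$values) != length(m$onsets)) {
      stop("modulator `", mn, "`: one value per event required", call. = FALSE)
    }
    nm <- paste0("mod_", mn)
    cols[[nm]] <- hrf_regressor(m$onsets, m$durations,
                                m$values - mean(m$values), n_scans, tr, oversample)
    mod_names <- c(mod_names, nm)
  }
  X <- do.call(cbind, cols)
  drift <- dct_basis(n_scans, tr, hp_cutoff)
  if (ncol(drift) > 0) X <- cbind(X, drift)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    stopifnot(nrow(confounds) == n_scans)
    if (is.null(colnames(confounds))) {
      colnames(confounds) <- paste0("confound_", seq_len(ncol(confounds)))
    }
    X <- cbind(X, confounds)
  }
  X <- cbind(X, intercept = 1)
  structure(list(X = X,
                 frame_times = (seq_len(n_scans) - 1L) * tr,
                 condition_names = conds,
                 modulator_names = mod_names,
                 n_scans = n_scans, tr = tr),
            class = "design_matrix")
}

#' Fit a first-level GLM by ordinary least squares
#'
#' @param run a `bold_run` (see [simulate_run()]) or a numeric matrix of
#'   voxel time courses (scans x voxels).
#' @param design a [build_design()] result.
#' @return `glm_fit`: list with `beta` (regressors x voxels, named rows),
#'   `residuals` (scans x voxels), `df` (residual degrees of freedom) and
#'   the design.
#' @export
fit_glm <- function(run, design) {
  Y <- if (inherits(run, "bold_run")) run$Y else as.matrix(run)
  X <- design$X
  if (nrow(Y) != nrow(X)) stop("time-series length does not match design", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrx, Y)
  res <- qr.resid(qrx, Y)
  beta <- matrix(beta, ncol = ncol(Y),
                 dimnames = list(colnames(X), colnames(Y)))
  structure(list(beta = beta, residuals = res,
                 df = nrow(Y) - qrx$rank, design = design),
            class = "glm_fit")
}

#' Mean parameter estimate over a voxel mask
#'
#' @param fit a [fit_glm()] result.
#' @param regressor regressor name (row of the beta matrix).
#' @param mask logical or integer voxel selector; default all voxels.
#' @return scalar mean beta.
#' @export
roi_mean_beta <- function(fit, regressor, mask = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  if (!regressor %in% rownames(fit$beta)) {
    stop("no regressor named `", regressor, "`", call. = FALSE)
  }
  b <- fit$beta[regressor, ]
  if (!is.null(mask)) b <- b[mask]
  if (length(b) == 0L) stop("empty voxel mask", call. = FALSE)
  mean(b)
}

#' Task-specific first-level design layouts
#'
#' Assembles the design matrix for the standard analyses:
#' \describe{
#'   \item{rsa}{4 no-interest conditions (stim1, stim2, question, response)
#'     plus 12 direction regressors modelling the reflection phase.}
#'   \item{adapt}{4 no-interest conditions plus a demeaned Euclidean-distance
#'     parametric modulator at the second stimulus.}
#'   \item{adapt1d}{as `adapt`, but the modulator is the absolute rank
#'     difference on a single outcome dimension (`which_dim`).}
#'   \item{overlap}{4 no-interest conditions plus a demeaned shared-action
#'     (0/1/2) modulator at the second stimulus.}
#'   \item{joint}{both the distance and the overlap modulators in one model.}
#'   \item{adapt2}{task-2 layout: question, response, 6 first-colour and 6
#'     second-colour conditions plus the distance modulator at the second
#'     stimulus.}
#' }
#'
#' @param events an [events_for_run()] table (with `overlap` populated where
#'   the layout needs it).
#' @param layout one of `"rsa"`, `"adapt"`, `"adapt1d"`, `"overlap"`,
#'   `"joint"`, `"adapt2"`.
#' @param n_scans,tr run geometry.
#' @param confounds nuisance time courses.
#' @param which_dim outcome dimension for `adapt1d` (1 or 2).
#' @param keep_trials logical selector over trials whose second-stimulus
#'   events enter the parametric modulator (used by the subsampling
#'   control); dropped trials keep their unmodulated stim2 boxcar.
#' @param ... passed to [build_design()].
#' @return a `design_matrix`.
#' @export
design_for_layout <- function(events, layout, n_scans, tr, confounds = NULL,
                              which_dim = 1L, keep_trials = NULL, ...) {
  ev <- events
  stim2 <- ev[ev$trial_type == "stim2", , drop = FALSE]
  if (is.null(keep_trials)) keep_trials <- rep(TRUE, nrow(stim2))
  s2 <- stim2[keep_trials, , drop = FALSE]

  mods <- NULL
  if (layout == "rsa") {
    refl <- ev$trial_type == "reflection"
    ev$trial_type[refl] <- sprintf("dir_%03d", ev$bin[refl] * 30L)
  } else if (layout %in% c("adapt", "adapt1d", "overlap", "joint", "adapt2")) {
    ev <- ev[ev$trial_type != "reflection", , drop = FALSE]
    dist_mod <- list(onsets = s2$onset, durations = s2$duration,
                     values = s2$distance)
    if (layout == "adapt1d") {
      dd <- if (which_dim == 1L) abs(s2$end_i - s2$start_i) else abs(s2$end_j - s2$start_j)
      mods <- list(distance1d = list(onsets = s2$onset, durations = s2$duration,
                                     values = dd))
    } else if (layout == "adapt" || layout == "adapt2") {
      mods <- list(distance = dist_mod)
    } else if (layout == "overlap") {
      if (anyNA(s2$overlap)) stop("overlap values missing from events", call. = FALSE)
      if (stats::sd(s2$overlap) == 0) {
        stop("all overlap values equal in this run: degenerate modulator", call. = FALSE)
      }
      mods <- list(overlap = list(onsets = s2$onset, durations = s2$duration,
                                  values = s2$overlap))
    } else if (layout == "joint") {
      if (anyNA(s2$overlap)) stop("overlap values missing from events", call. = FALSE)
      mods <- list(distance = dist_mod,
                   overlap = list(onsets = s2$onset, durations = s2$duration,
                                  values = s2$overlap))
    }
    if (layout == "adapt2") {
      s1i <- ev$trial_type == "stim1"
      s2i <- ev$trial_type == "stim2"
      ev$trial_type[s1i] <- paste0("c1_", ev$color1[s1i])
      ev$trial_type[s2i] <- paste0("c2_", ev$color2[s2i])
    }
  } else {
    stop("unknown layout `", layout, "`", call. = FALSE)
  }
  build_design(ev, n_scans, tr, modulators = mods, confounds = confounds, ...)
}
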