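# Generalized psychophysiological interaction: condition-dependent coupling
# between two regions during long- vs short-distance comparisons.

#' Split task-1 trials into long- and short-distance conditions
#'
#' Short = trials at the shortest distance class (2 units for cardinal,
#' sqrt(5) for non-cardinal directions); long = all longer classes. An
#' alternative median split is available.
#'
#' @param design a task-1 `session_design`, or an events table with a
#'   `distance` column for one run.
#' @param method `"class"` (shortest class vs rest) or `"median"`.
#' @return logical vector, TRUE for long-distance trials.
#' @export
split_conditions <- function(design, method = c("class", "median")) {
  method <- match.arg(method)
  len <- if (inherits(design, "session_design")) design$trials$length
  else design$distance[design$trial_type == "stim2"]
  long <- if (method == "class") !is_short_distance(len) else len > stats::median(len)
  if (all(long) || !any(long)) stop("one distance class is empty", call. = FALSE)
  long
}

#' Fit a directed gPPI model
#'
#' First-level model with five task regressors: the two HRF-convolved
#' condition indicators (long and short distance, modelled at the second
#' stimulus), the seed time series, and the two PPI terms (elementwise
#' product of the seed series with each convolved indicator; no
#' deconvolution). Drift, confounds and an intercept are appended. The
#' contrast is `beta_PPI_long - beta_PPI_short`.
#'
#' @param seed_ts,target_ts numeric time series of equal length.
#' @param events events table for the run (with `distance` at stim2).
#' @param tr repetition time.
#' @param confounds optional nuisance time courses.
#' @param method long/short split method, see [split_conditions()].
#' @return list with `contrast`, `betas` (the five task betas) and the fit.
#' @export
fit_gppi <- function(seed_ts, target_ts, events, tr = 1.5, confounds = NULL,
                     method = "class") {
  stopifnot(length(seed_ts) == length(target_ts))
  n_scans <- length(seed_ts)
  s2 <- events[events$trial_type == "stim2", , drop = FALSE]
  long <- split_conditions(events, method)
  x_long <- hrf_regressor(s2$onset[long], s2$duration[long], 1, n_scans, tr)
  x_short <- hrf_regressor(s2$onset[!long], s2$duration[!long], 1, n_scans, tr)
  ppi_long <- seed_ts * x_long
  ppi_short <- seed_ts * x_short
  X <- cbind(cond_long = x_long, cond_short = x_short, seed = seed_ts,
             ppi_long = ppi_long, ppi_short = ppi_short)
  if (abs(stats::cor(ppi_long, ppi_short)) > 0.999) {
    stop("PPI columns are collinear", call. = FALSE)
  }
  drift <- dct_basis(n_scans, tr)
  X <- cbind(X, drift)
  if (!is.null(confounds)) X <- cbind(X, as.matrix(confounds))
  X <- cbind(X, intercept = 1)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("gPPI design rank deficient", call. = FALSE)
  beta <- qr.coef(qrx, target_ts)
  list(contrast = unname(beta["ppi_long"] - beta["ppi_short"]),
       betas = beta[c("cond_long", "cond_short", "seed", "ppi_long", "ppi_short")])
}

#' Seed-symmetric gPPI contrast
#'
#' Because PPI carries no directional information, the analysis is run in
#' both directions (each region once as seed, once as target) and the two
#' directed contrasts are averaged per participant. Group inference on the
#' averaged contrast is two-sided.
#'
#' @param roi_a,roi_b numeric time series of the two regions.
#' @param events,tr,confounds,method as in [fit_gppi()].
#' @return `ppi_result`: list with `contrast_ab`, `contrast_ba` and their
#'   mean `contrast`.
#' @export
symmetric_gppi <- function(roi_a, roi_b, events, tr = 1.5, confounds = NULL,
                           method = "class") {
  ab <- fit_gppi(roi_a, roi_b, events, tr, confounds, method)
  ba <- fit_gppi(roi_b, roi_a, events, tr, confounds, method)
  structure(list(contrast_ab = ab$contrast, contrast_ba = ba$contrast,
                 contrast = mean(c(ab$contrast, ba$contrast))),
            class = "ppi_result")
}
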