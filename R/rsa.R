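# Representational similarity analysis over the 12 direction conditions:
# condition-pattern extraction, (cross-validated) Mahalanobis RDMs with
# shrinkage-regularised noise covariance, periodicity and position models.

direction_condition_names <- function() sprintf("dir_%03d", seq(0, 330, 30))

#' Extract direction-condition patterns from per-run GLM fits
#'
#' Averages the 12 direction betas across runs and z-scores each voxel
#' across the 12 conditions (configurable to z-scoring each condition across
#' voxels). Voxels constant across conditions are dropped with a warning.
#'
#' @param fits list of [fit_glm()] results, one per run, each containing the
#'   12 `dir_*` regressors.
#' @param zscore `"voxel"` (per voxel across conditions), `"condition"`
#'   (per condition across voxels), or `"none"`.
#' @param average average across runs (set `FALSE` to keep the run
#'   dimension, as required for the crossnobis estimator; no z-scoring is
#'   applied in that case).
#' @return conditions x voxels matrix (12 x V), or a `(runs, 12, V)` array
#'   when `average = FALSE`.
#' @export
condition_patterns <- function(fits, zscore = c("voxel", "condition", "none"),
                               average = TRUE) {
  zscore <- match.arg(zscore)
  conds <- direction_condition_names()
  per_run <- lapply(fits, function(f) {
    missing <- setdiff(conds, rownames(f$beta))
    if (length(missing) > 0L) {
      stop("missing direction conditions: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    f$beta[conds, , drop = FALSE]
  })
  if (!average) {
    V <- ncol(per_run[[1L]])
    arr <- array(NA_real_, c(length(fits), length(conds), V),
                 dimnames = list(NULL, conds, NULL))
    for (r in seq_along(per_run)) arr[r, , ] <- per_run[[r]]
    return(arr)
  }
  avg <- Reduce(`+`, per_run) / length(per_run)
  if (zscore == "voxel") {
    sds <- apply(avg, 2L, stats::sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " voxel(s) constant across conditions dropped",
              call. = FALSE)
      avg <- avg[, sds > 0, drop = FALSE]
    }
    avg <- scale(avg)
  } else if (zscore == "condition") {
    avg <- t(scale(t(avg)))
  }
  avg
}

#' Shrinkage-regularised covariance estimate
#'
#' Ledoit-Wolf-style shrinkage of the sample covariance towards its
#' diagonal, with a data-driven intensity (Schafer-Strimmer): off-diagonal
#' entries are damped in proportion to their estimation variance. Guarantees
#' a well-conditioned estimate even with fewer observations than variables.
#'
#' @param x observations x variables matrix (e.g. GLM residuals).
#' @param lambda shrinkage intensity in `[0, 1]`; estimated when `NULL`.
#' @return covariance matrix with attribute `lambda`.
#' @export
shrink_cov <- function(x, lambda = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  xc <- scale(x, scale = FALSE)
  s <- crossprod(xc) / (n - 1L)
  if (is.null(lambda)) {
    xc2 <- xc^2
    # var of each covariance entry: n/(n-1)^3 * sum((w - mean w)^2)
    w_bar <- s * (n - 1L) / n
    var_s <- (crossprod(xc2) - n * w_bar^2) * n / (n - 1L)^3
    off <- !diag(ncol(s))
    denom <- sum(s[off]^2)
    lambda <- if (denom > 0) sum(var_s[off]) / denom else 1
    lambda <- min(1, max(0, lambda))
  }
  out <- (1 - lambda) * s
  diag(out) <- diag(s)
  attr(out, "lambda") <- lambda
  out
}

#' Neural representational dissimilarity matrix
#'
#' Pairwise squared Mahalanobis distances between condition patterns,
#' whitened by a shrinkage-regularised noise covariance estimated from GLM
#' residuals (identity when no residuals are given), normalised per voxel.
#' The crossnobis variant computes cross-validated squared Mahalanobis
#' distances across runs, an unbiased estimator whose expectation is zero
#' for identical patterns (entries may be negative).
#'
#' @param patterns conditions x voxels matrix (`method = "mahalanobis"`) or
#'   a `(runs, conditions, voxels)` array (`method = "crossnobis"`).
#' @param residuals scans x voxels residual matrix (runs concatenated) for
#'   the noise covariance; `NULL` for identity whitening.
#' @param method `"mahalanobis"` or `"crossnobis"`.
#' @return `rdm`: symmetric conditions x conditions matrix with zero
#'   diagonal (Mahalanobis) and condition labels.
#' @export
neural_rdm <- function(patterns, residuals = NULL,
                       method = c("mahalanobis", "crossnobis")) {
  method <- match.arg(method)
  W <- NULL
  if (!is.null(residuals)) {
    sigma <- shrink_cov(residuals)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-12 * max(ev)) {
      stop("residual covariance is singular; use shrinkage (lambda > 0)",
           call. = FALSE)
    }
    W <- solve(sigma)
  }
  if (method == "mahalanobis") {
    p <- as.matrix(patterns)
    n <- nrow(p)
    V <- ncol(p)
    pw <- if (is.null(W)) p else p %*% t(chol(W))
    d2 <- as.matrix(stats::dist(pw))^2 / V
    dimnames(d2) <- list(rownames(p), rownames(p))
    return(structure(d2, class = c("rdm", "matrix")))
  }
  stopifnot(length(dim(patterns)) == 3L)
  R <- dim(patterns)[1L]
  n <- dim(patterns)[2L]
  V <- dim(patterns)[3L]
  if (R < 2L) stop("crossnobis needs at least 2 runs", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(dimnames(patterns)[[2L]],
                                       dimnames(patterns)[[2L]]))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      delta <- patterns[, i, ] - patterns[, j, ]  # R x V
      dw <- if (is.null(W)) delta else delta %*% W
      cross <- tcrossprod(dw, delta)  # R x R inner products
      val <- (sum(cross) - sum(diag(cross))) / (R * (R - 1L)) / V
      d[i, j] <- d[j, i] <- val
    }
  }
  structure(d, class = c("rdm", "matrix"))
}

#' Binary periodicity model RDM
#'
#' Entry 0 (predicted similar) where the pairwise angular difference between
#' nominal direction angles is a multiple of `360 / k` degrees, else 1. At
#' the 30-degree sampling of the design the k = 5 model is constant off the
#' diagonal and cannot be tested ([rdm_correlation()] will signal it).
#'
#' @param k periodicity (2-6; 6 is the hexadirectional model).
#' @param angles nominal direction angles in degrees.
#' @return `rdm` matrix (binary, symmetric, zero diagonal).
#' @export
model_rdm_periodicity <- function(k, angles = seq(0, 330, 30)) {
  stopifnot(k %in% 2:6)
  n <- length(angles)
  diff <- abs(outer(angles, angles, `-`)) %% (360 / k)
  m <- ifelse(pmin(diff, 360 / k - diff) < 1e-9, 0, 1)
  diag(m) <- 0
  dimnames(m) <- list(sprintf("dir_%03d", angles), sprintf("dir_%03d", angles))
  structure(m, class = c("rdm", "matrix"))
}

#' Start/end-position occupancy model RDM
#'
#' For each direction bin, a 25-long occupancy vector counts how often the
#' bin's trials start (or end, or either) in each grid cell over the
#' session; the model dissimilarity between two directions is one minus the
#' correlation of their occupancy vectors. Controls for directions sharing
#' starting (or ending) positions.
#'
#' @param design a task-1 `session_design`.
#' @param which `"start"`, `"end"`, or `"both"` (sum of both counts).
#' @return `rdm` matrix.
#' @export
model_rdm_positions <- function(design, which = c("start", "end", "both")) {
  which <- match.arg(which)
  stopifnot(inherits(design, "session_design"), design$task == 1L)
  tr <- design$trials
  occ <- matrix(0, 12L, 25L)
  cell <- function(i, j) i * 5L + j + 1L
  for (b in 0:11) {
    d <- tr[tr$bin == b, ]
    v <- numeric(25L)
    if (which %in% c("start", "both")) {
      t1 <- table(cell(d$start_i, d$start_j))
      v[as.integer(names(t1))] <- v[as.integer(names(t1))] + t1
    }
    if (which %in% c("end", "both")) {
      t2 <- table(cell(d$end_i, d$end_j))
      v[as.integer(names(t2))] <- v[as.integer(names(t2))] + t2
    }
    occ[b + 1L, ] <- v
  }
  if (any(apply(occ, 1L, stats::sd) == 0)) {
    stop("zero-variance occupancy vector", call. = FALSE)
  }
  r <- stats::cor(t(occ))
  m <- 1 - r
  diag(m) <- 0
  nm <- direction_condition_names()
  dimnames(m) <- list(nm, nm)
  structure(m, class = c("rdm", "matrix"))
}

#' Correlate a neural RDM with a model RDM
#'
#' Spearman correlation over the 66 upper-triangle entries; positive values
#' mean neural dissimilarity is higher where the model predicts
#' dissimilarity.
#'
#' @param neural,model conditions x conditions matrices with matching
#'   labels.
#' @return Spearman coefficient.
#' @export
rdm_correlation <- function(neural, model) {
  stopifnot(nrow(neural) == nrow(model))
  if (!is.null(rownames(neural)) && !is.null(rownames(model)) &&
      !identical(rownames(neural), rownames(model))) {
    model <- model[rownames(neural), rownames(neural)]
  }
  x <- upper_tri(as.matrix(neural))
  y <- upper_tri(as.matrix(model))
  if (stats::sd(y) == 0) stop("model RDM is constant; correlation undefined", call. = FALSE)
  if (stats::sd(x) == 0) stop("neural RDM is constant; correlation undefined", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}
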