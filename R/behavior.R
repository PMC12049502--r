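# Behavioural map reconstruction: similarity normalisation, metric-stress
# MDS, Procrustes fit, and the exhaustive shuffled-assignment null.

#' Normalise and average pairwise similarity ratings
#'
#' Ratings are rescaled to `[0, 1]` over the rater's observed range and the
#' two repetitions of each unordered pair are averaged.
#'
#' @param ratings data.frame with columns `item_a`, `item_b`, `rating` (and
#'   optionally `repeat_idx`); every unordered pair must be rated exactly
#'   twice.
#' @param n_items number of items (inferred from the labels by default).
#' @return symmetric `n_items` x `n_items` similarity matrix in `[0, 1]`
#'   with `NA` diagonal.
#' @export
normalize_average <- function(ratings, n_items = max(ratings$item_a, ratings$item_b)) {
  stopifnot(all(c("item_a", "item_b", "rating") %in% names(ratings)))
  r <- ratings$rating
  rng <- range(r)
  if (diff(rng) == 0) {
    stop("all ratings identical: degenerate rater, similarity undefined", call. = FALSE)
  }
  rn <- (r - rng[1L]) / diff(rng)
  a <- pmin(ratings$item_a, ratings$item_b)
  b <- pmax(ratings$item_a, ratings$item_b)
  key <- paste(a, b)
  counts <- table(key)
  if (any(counts != 2L) || length(counts) != choose(n_items, 2L)) {
    stop("every unordered pair must be rated exactly twice", call. = FALSE)
  }
  avg <- tapply(rn, key, mean)
  sim <- matrix(NA_real_, n_items, n_items)
  ij <- do.call(rbind, strsplit(names(avg), " "))
  ij <- apply(ij, 2L, as.integer)
  sim[ij] <- avg
  sim[ij[, 2:1]] <- avg
  sim
}

#' Correlate rated dissimilarity with distance in the action-outcome space
#'
#' Ratings are reverse-coded (dissimilarity = 1 - similarity) so that a
#' well-formed mental map yields a positive Spearman coefficient against the
#' Euclidean distances between the items' true positions.
#'
#' @param sim similarity matrix from [normalize_average()].
#' @param positions items x 2 matrix of true grid positions (row order
#'   matching the similarity matrix).
#' @return Spearman correlation coefficient.
#' @export
rating_distance_correlation <- function(sim, positions) {
  positions <- as.matrix(positions)
  stopifnot(nrow(sim) == nrow(positions))
  dis <- upper_tri(1 - sim)
  dst <- upper_tri(as.matrix(stats::dist(positions)))
  if (length(dis) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(dis) == 0 || stats::sd(dst) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(dis, dst, method = "spearman")
}

#' Embed a dissimilarity matrix in the plane by metric-stress MDS
#'
#' Minimises metric stress (root normalised residual sum of squares between
#' configuration distances and the target dissimilarities) by SMACOF
#' majorisation from random initial configurations, keeping the best of
#' `n_restarts` fits.
#'
#' @param dissimilarity symmetric non-negative matrix.
#' @param ndim embedding dimension (2 for a planar map).
#' @param seed integer seed for the random initial configurations.
#' @param n_restarts number of random restarts.
#' @param max_iter,tol majorisation iteration cap and stress-change
#'   convergence tolerance.
#' @return matrix of coordinates (items x ndim) with attributes `stress`
#'   (normalised metric stress) and `degenerate` (TRUE when the input had no
#'   variance and any configuration is stress-minimal).
#' @export
mds_embed <- function(dissimilarity, ndim = 2L, seed = NULL, n_restarts = 8L,
                      max_iter = 1000L, tol = 1e-9) {
  d <- as.matrix(dissimilarity)
  diag(d) <- 0
  if (anyNA(d)) stop("off-diagonal dissimilarities must not be missing", call. = FALSE)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  }
  if (any(d < 0)) stop("dissimilarities must be non-negative", call. = FALSE)
  n <- nrow(d)
  denom <- sum(d^2) / 2
  degenerate <- stats::sd(upper_tri(d)) == 0

  with_local_seed(seed, {
    best <- NULL
    best_stress <- Inf
    for (rs in seq_len(n_restarts)) {
      x <- matrix(stats::rnorm(n * ndim), n, ndim)
      stress_old <- Inf
      for (it in seq_len(max_iter)) {
        dx <- as.matrix(stats::dist(x))
        raw <- sum((d - dx)[upper.tri(d)]^2)
        stress <- if (denom > 0) sqrt(raw / denom) else 0
        if (is.finite(stress_old) && abs(stress_old - stress) < tol) break
        stress_old <- stress
        # Guttman transform
        b <- ifelse(dx > 0, -d / dx, 0)
        diag(b) <- 0
        diag(b) <- -rowSums(b)
        x <- (b %*% x) / n
      }
      if (stress < best_stress) {
        best <- x
        best_stress <- stress
      }
    }
    if (degenerate) {
      warning("dissimilarities have zero variance; embedding is degenerate",
              call. = FALSE)
    }
    structure(best, stress = best_stress, degenerate = degenerate)
  })
}

#' Procrustes distance between two planar configurations
#'
#' Normalised sum of squared errors after the optimal similarity transform
#' (translation, uniform scaling, rotation, and -- by default -- reflection)
#' mapping `source` onto `target`. The value is scale-free: 0 when the two
#' configurations are related by a similarity transform, at most 1.
#'
#' @param source,target n x k coordinate matrices, rows matched.
#' @param reflection allow reflections in the transform family.
#' @return scalar normalised SSE.
#' @export
procrustes_distance <- function(source, target, reflection = TRUE) {
  x <- as.matrix(source)
  y <- as.matrix(target)
  stopifnot(nrow(x) == nrow(y), ncol(x) == ncol(y))
  if (nrow(x) < 3L) stop("need at least 3 points", call. = FALSE)
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  nx <- sum(xc^2)
  ny <- sum(yc^2)
  if (nx == 0 || ny == 0) stop("degenerate configuration (all points equal)", call. = FALSE)
  sv <- svd(crossprod(xc, yc))
  s <- sv$d
  if (!reflection && det(sv$u %*% t(sv$v)) < 0) {
    s[length(s)] <- -s[length(s)]
  }
  traceTA <- sum(s)
  max(0, 1 - traceTA^2 / (nx * ny))
}

#' Full Procrustes superimposition
#'
#' @inheritParams procrustes_distance
#' @return list with the transformed source coordinates (`yhat`), rotation
#'   matrix, scale, translation, and the normalised SSE (`distance`).
#' @export
procrustes_fit <- function(source, target, reflection = TRUE) {
  x <- as.matrix(source)
  y <- as.matrix(target)
  mx <- colMeans(x); my <- colMeans(y)
  xc <- sweep(x, 2L, mx)
  yc <- sweep(y, 2L, my)
  nx <- sum(xc^2)
  sv <- svd(crossprod(xc, yc))
  s <- sv$d
  rot <- sv$u %*% t(sv$v)
  if (!reflection && det(rot) < 0) {
    u <- sv$u
    u[, ncol(u)] <- -u[, ncol(u)]
    rot <- u %*% t(sv$v)
    s[length(s)] <- -s[length(s)]
  }
  scl <- sum(s) / nx
  yhat <- scl * xc %*% rot
  yhat <- sweep(yhat, 2L, my, `+`)
  list(yhat = yhat, rotation = rot, scale = scl,
       translation = my - scl * as.numeric(mx %*% rot),
       distance = procrustes_distance(source, target, reflection))
}

#' Exhaustive shuffled-assignment Procrustes null and critical distance
#'
#' Fits the embedded coordinates to every possible item-to-position
#' assignment (all n! permutations of the true positions) by Procrustes
#' analysis, and thresholds the resulting null distribution of Procrustes
#' distances at its 5th percentile (the critical distance). A mapping is
#' judged reliable when the observed distance under the true assignment
#' falls below the critical distance. The identity assignment is a member
#' of the null, making the test exact.
#'
#' @param coords items x 2 embedded coordinates (e.g. from [mds_embed()]).
#' @param positions items x 2 true positions, rows matched to `coords`.
#' @param alpha percentile used for the threshold (0.05).
#' @param keep_null return the full null distribution.
#' @return `map_fit`: list with `observed`, `critical`, `n_perm`,
#'   `significant`, and optionally `null`.
#' @export
critical_distance <- function(coords, positions, alpha = 0.05, keep_null = FALSE) {
  x <- as.matrix(coords)
  y <- as.matrix(positions)
  n <- nrow(x)
  stopifnot(nrow(y) == n, ncol(x) == 2L, ncol(y) == 2L)
  if (n > 9L) stop("exhaustive enumeration limited to 9 items", call. = FALSE)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)

  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  nx <- sum(xc^2)
  ny <- sum(yc^2)
  if (nx == 0 || ny == 0) stop("degenerate configuration", call. = FALSE)

  perms <- all_permutations(n)
  # M(p) = t(xc) %*% yc[p, ]; for 2 columns, (sum of singular values)^2 =
  # ||M||_F^2 + 2|det M|, so the whole null is four mat-vec products.
  b1 <- matrix(yc[perms, 1L], nrow(perms), n)
  b2 <- matrix(yc[perms, 2L], nrow(perms), n)
  m11 <- as.numeric(b1 %*% xc[, 1L])
  m21 <- as.numeric(b1 %*% xc[, 2L])
  m12 <- as.numeric(b2 %*% xc[, 1L])
  m22 <- as.numeric(b2 %*% xc[, 2L])
  fro <- m11^2 + m12^2 + m21^2 + m22^2
  dt <- abs(m11 * m22 - m12 * m21)
  null <- pmax(0, 1 - (fro + 2 * dt) / (nx * ny))

  observed <- procrustes_distance(x, y)
  crit <- as.numeric(stats::quantile(null, alpha))
  structure(list(observed = observed, critical = crit,
                 n_perm = nrow(perms), alpha = alpha,
                 significant = observed < crit,
                 null = if (keep_null) null else NULL),
            class = "map_fit")
}

#' Behavioural map-reconstruction pipeline for one rater
#'
#' Convenience wrapper: normalise and average ratings, correlate with true
#' distances, embed by MDS, and run the exhaustive Procrustes null.
#'
#' @param ratings rating data.frame (see [normalize_average()]).
#' @param positions items x 2 true positions.
#' @param seed seed for the MDS restarts.
#' @param ... passed to [mds_embed()].
#' @return list with `similarity`, `spearman`, `coords`, `fit` (a `map_fit`).
#' @export
behavior_pipeline <- function(ratings, positions, seed = NULL, ...) {
  sim <- normalize_average(ratings, n_items = nrow(positions))
  rho <- rating_distance_correlation(sim, positions)
  coords <- mds_embed(1 - sim, seed = seed, ...)
  fit <- critical_distance(coords, positions)
  list(similarity = sim, spearman = rho, coords = coords, fit = fit)
}
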