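# Distance- and overlap-based fMRI-adaptation analyses: per-run parametric
# GLMs, voxel- and run-averaged parameter estimates, and the subsampling
# control for unbalanced trial classes.

# fit one run's layout and return the voxel-mean modulator betas
run_modulator_betas <- function(run, layout, which_dim = 1L, keep_trials = NULL,
                                mask = NULL) {
  dm <- design_for_layout(run$events, layout, run$n_scans, run$tr,
                          confounds = run$confounds, which_dim = which_dim,
                          keep_trials = keep_trials)
  fit <- fit_glm(run, dm)
  vapply(dm$modulator_names, function(nm) roi_mean_beta(fit, nm, mask),
         numeric(1L))
}

new_adaptation_result <- function(per_run, tag, n_iter = 1L) {
  structure(list(beta = colMeans(per_run), per_run = per_run,
                 tag = tag, n_iter = n_iter),
            class = "adaptation_result")
}

#' Distance-based adaptation analysis for one participant
#'
#' Fits, per run, a GLM with the task's no-interest conditions and a
#' run-wise demeaned Euclidean-distance parametric modulator aligned to the
#' second stimulus; the modulator beta is averaged over voxels and then over
#' runs. A positive beta indicates a response increasing with distance,
#' i.e. adaptation for near pairs (group inference is one-sided for a
#' positive effect). Task 2 uses the colour-split stimulus conditions so
#' colour-specific offsets cannot masquerade as distance effects.
#'
#' @param runs list of `bold_run` objects for one participant.
#' @param task 1 (action combinations) or 2 (coloured balls).
#' @param dimension `NULL` for the 2-D Euclidean distance, or 1/2 for the
#'   one-dimensional control distances (absolute rank difference).
#' @param mask optional voxel mask.
#' @return `adaptation_result` with the participant beta(s).
#' @export
distance_analysis <- function(runs, task = 1L, dimension = NULL, mask = NULL) {
  layout <- if (!is.null(dimension)) "adapt1d" else if (task == 2L) "adapt2" else "adapt"
  per_run <- matrix(vapply(runs, function(r) {
    if (is.null(r$events$distance)) stop("events carry no distance column", call. = FALSE)
    run_modulator_betas(r, layout, which_dim = dimension %||% 1L, mask = mask)
  }, numeric(1L)), ncol = 1L)
  colnames(per_run) <- if (!is.null(dimension)) "distance1d" else "distance"
  tag <- if (!is.null(dimension)) sprintf("dim%d-only", dimension)
  else sprintf("distance-task%d", task)
  new_adaptation_result(per_run, tag)
}

#' Overlap-based (action-similarity) adaptation analysis
#'
#' Parametric modulator is the demeaned shared-action count (0 = no shared
#' action, 1 = one shared action, 2 = both actions shared with joysticks
#' exchanged) at the second stimulus. Group inference is two-sided (no
#' directional hypothesis): a positive beta means the response grows with
#' action overlap (enhancement with similarity), a negative beta means
#' suppression.
#'
#' @inheritParams distance_analysis
#' @return `adaptation_result`.
#' @export
overlap_analysis <- function(runs, mask = NULL) {
  per_run <- matrix(vapply(seq_along(runs), function(k) {
    r <- runs[[k]]
    ov <- r$events$overlap[r$events$trial_type == "stim2"]
    if (anyNA(ov)) stop("run ", k, ": overlap values missing", call. = FALSE)
    if (stats::sd(ov) == 0) {
      stop("run ", k, ": all overlap values equal; modulator degenerate", call. = FALSE)
    }
    run_modulator_betas(r, "overlap", mask = mask)
  }, numeric(1L)), ncol = 1L)
  colnames(per_run) <- "overlap"
  new_adaptation_result(per_run, "overlap")
}

#' Joint distance + overlap adaptation analysis
#'
#' A single GLM per run with both demeaned parametric modulators, so each
#' effect is estimated controlling for the other. Errors when the two
#' modulators are nearly collinear (|r| > 0.95) in any run.
#'
#' @inheritParams distance_analysis
#' @return `adaptation_result` carrying both betas from the one fit.
#' @export
joint_analysis <- function(runs, mask = NULL) {
  per_run <- t(vapply(seq_along(runs), function(k) {
    r <- runs[[k]]
    s2 <- r$events[r$events$trial_type == "stim2", ]
    if (anyNA(s2$overlap)) stop("run ", k, ": overlap values missing", call. = FALSE)
    if (stats::sd(s2$overlap) > 0 && stats::sd(s2$distance) > 0 &&
        abs(stats::cor(s2$distance, s2$overlap)) > 0.95) {
      stop("run ", k, ": distance and overlap modulators nearly collinear",
           call. = FALSE)
    }
    run_modulator_betas(r, "joint", mask = mask)
  }, numeric(2L)))
  colnames(per_run) <- c("distance", "overlap")
  new_adaptation_result(per_run, "joint")
}

#' Subsampling control equalising two trial classes
#'
#' For designs where two trial classes have unequal counts, trials of the
#' larger class are dropped uniformly at random per run until the counts
#' match, the parametric GLM is refit on the retained trials, and the
#' procedure is iterated (default 10 times, as in the reference analysis)
#' with betas averaged across iterations. Optionally excludes trials (e.g.
#' the rare fully-reversed pairs) before balancing.
#'
#' @param runs list of `bold_run` objects.
#' @param class_labels list (one element per run) of per-trial labels with
#'   exactly two levels after exclusions.
#' @param n_iter number of subsampling iterations.
#' @param seed integer seed (the iteration stream is a pure function of it).
#' @param layout modulator layout passed to the per-run fit (`"adapt"` or
#'   `"overlap"`).
#' @param exclude optional list of logical vectors marking trials dropped
#'   from the modulator entirely.
#' @param mask optional voxel mask.
#' @return `adaptation_result` averaged over iterations.
#' @export
subsample_equalize <- function(runs, class_labels, n_iter = 10L, seed = NULL,
                               layout = c("adapt", "overlap"), exclude = NULL,
                               mask = NULL) {
  layout <- match.arg(layout)
  stopifnot(length(class_labels) == length(runs))
  with_local_seed(seed, {
    iters <- vector("list", n_iter)
    for (it in seq_len(n_iter)) {
      per_run <- matrix(vapply(seq_along(runs), function(k) {
        lab <- class_labels[[k]]
        keep <- rep(TRUE, length(lab))
        if (!is.null(exclude)) keep[exclude[[k]]] <- FALSE
        lv <- unique(lab[keep])
        if (length(lv) != 2L) {
          stop("run ", k, ": need exactly two trial classes", call. = FALSE)
        }
        n1 <- sum(lab == lv[1L] & keep)
        n2 <- sum(lab == lv[2L] & keep)
        if (n1 == 0L || n2 == 0L) {
          stop("run ", k, ": one trial class is empty", call. = FALSE)
        }
        target <- min(n1, n2)
        for (l in lv) {
          idx <- which(lab == l & keep)
          if (length(idx) > target) {
            keep[sample(idx, length(idx) - target)] <- FALSE
          }
        }
        run_modulator_betas(runs[[k]], layout, keep_trials = keep, mask = mask)
      }, numeric(1L)), ncol = 1L)
      iters[[it]] <- per_run
    }
    per_run <- Reduce(`+`, iters) / n_iter
    colnames(per_run) <- if (layout == "adapt") "distance" else "overlap"
    new_adaptation_result(per_run, paste0("subsampled-", layout), n_iter = n_iter)
  })
}
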