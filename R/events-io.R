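# Event-table extraction and tab-separated input/output
# (BIDS-events dialect: onset, duration, trial_type, + design columns).

#' Long-format event table for one run of a generated session
#'
#' Expands each trial into its component events: first stimulus, second
#' stimulus, reflection period, probe (question/statement) and response
#' (modelled at a nominal 1.5 s into the response window, duration 0).
#'
#' @param design a `session_design`.
#' @param run run index.
#' @param assignment optional [sample_assignment()]; if supplied, task-1
#'   events gain an `overlap` column (shared-action count per trial).
#' @return data.frame with columns `onset`, `duration`, `trial_type`,
#'   `trial`, `bin`, `angle`, `distance`, `overlap`, `probe`, `start_i`,
#'   `start_j`, `end_i`, `end_j` (and `color1`/`color2` for task 2).
#' @export
events_for_run <- function(design, run, assignment = NULL) {
  stopifnot(inherits(design, "session_design"))
  tr <- design$trials[design$trials$run == run, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no such run in this design", call. = FALSE)
  tm <- design$timing
  n <- nrow(tr)

  overlap <- rep(NA_integer_, n)
  if (!is.null(assignment) && design$task == 1L) {
    sub <- design
    sub$trials <- tr
    overlap <- trial_overlaps(sub, assignment)
  }

  base <- data.frame(trial = tr$trial,
                     bin = if (design$task == 1L) tr$bin else NA_integer_,
                     angle = if (design$task == 1L) tr$angle else NA_real_,
                     distance = tr$length,
                     overlap = overlap,
                     probe = tr$probe,
                     start_i = tr$start_i, start_j = tr$start_j,
                     end_i = tr$end_i, end_j = tr$end_j)
  if (design$task == 2L) {
    base$color1 <- tr$color1
    base$color2 <- tr$color2
  }

  mk <- function(type, onset, duration) {
    cbind(data.frame(onset = onset, duration = duration, trial_type = type), base)
  }
  ev <- rbind(mk("stim1", tr$stim1_onset, tm$stim),
              mk("stim2", tr$stim2_onset, tm$stim),
              mk("reflection", tr$reflection_onset, tm$reflection),
              mk("question", tr$probe_onset, tm$probe),
              mk("response", tr$probe_onset + 1.5, 0))
  ev <- ev[order(ev$onset, ev$trial_type), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Write/read event tables as tab-separated files
#'
#' One file per run, named `<prefix>_run-<r>_events.tsv`.
#'
#' @param design a `session_design`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix, e.g. `"task1"`.
#' @param assignment optional assignment forwarded to [events_for_run()].
#' @return invisibly, the written file paths.
#' @export
write_events <- function(design, dir, prefix = paste0("task", design$task),
                         assignment = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  runs <- sort(unique(design$trials$run))
  paths <- character(0L)
  for (r in runs) {
    ev <- events_for_run(design, r, assignment)
    p <- file.path(dir, sprintf("%s_run-%d_events.tsv", prefix, r))
    utils::write.table(ev, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_events
#' @param path a single events TSV path.
#' @export
read_events <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write/read rating tables as tab-separated files
#'
#' Columns: `item_a`, `item_b`, `side`, `repeat_idx`, `rating`.
#' @param ratings data.frame of ratings.
#' @param path file path.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.table(ratings, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Tabulate group-level results
#'
#' Collects [signflip_ttest()] results into the standard results table.
#'
#' @param results named list of `group_stat` objects.
#' @param roi optional character vector of region labels (recycled).
#' @return data.frame with columns `analysis`, `roi`, `t`, `p_perm`,
#'   `p_corrected`, `d`, `ci_low`, `ci_high`, `n`.
#' @export
results_table <- function(results, roi = NA_character_) {
  roi <- rep_len(roi, length(results))
  rows <- mapply(function(res, nm, r) {
    data.frame(analysis = nm, roi = r, t = res$t, p_perm = res$p,
               p_corrected = res$p_corrected %||% res$p,
               d = res$d, ci_low = res$ci[1L], ci_high = res$ci[2L],
               n = res$n)
  }, results, names(results), roi, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a plain key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and
#' `#` comments ignored. Numeric-looking values are converted.
#'
#' @param path file path.
#' @return named list.
#' @export
read_design_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[=:]", fixed = FALSE)[[1L]]
    if (length(parts) < 2L) next
    key <- trimws(parts[1L])
    val <- trimws(paste(parts[-1L], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write/read a simulated BOLD run as portable text tables
#'
#' The voxel time courses, events and confounds are written as three
#' tab-separated files (`<prefix>_bold.tsv`, `<prefix>_events.tsv`,
#' `<prefix>_confounds.tsv`). Optionally, the time courses are also exported
#' as a 4D NIfTI container (voxels along x) when the `RNifti` package is
#' available.
#'
#' @param run a `bold_run`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param nifti also write `<prefix>_bold.nii.gz` (requires `RNifti`).
#' @return invisibly, the written paths.
#' @export
write_bold_run <- function(run, dir, prefix = "run", nifti = FALSE) {
  stopifnot(inherits(run, "bold_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_bold <- file.path(dir, paste0(prefix, "_bold.tsv"))
  utils::write.table(run$Y, p_bold, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  p_ev <- file.path(dir, paste0(prefix, "_events.tsv"))
  utils::write.table(run$events, p_ev, sep = "\t", quote = FALSE, row.names = FALSE)
  p_conf <- file.path(dir, paste0(prefix, "_confounds.tsv"))
  utils::write.table(run$confounds, p_conf, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(p_bold, p_ev, p_conf)
  if (nifti) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("NIfTI export requires the RNifti package", call. = FALSE)
    }
    arr <- array(t(run$Y), c(ncol(run$Y), 1L, 1L, nrow(run$Y)))
    p_nii <- file.path(dir, paste0(prefix, "_bold.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(1, 1, 1, run$tr)), p_nii)
    paths <- c(paths, p_nii)
  }
  invisible(paths)
}

#' @rdname write_bold_run
#' @param tr repetition time of the stored run.
#' @export
read_bold_run <- function(dir, prefix = "run", tr = 1.5) {
  Y <- as.matrix(utils::read.table(file.path(dir, paste0(prefix, "_bold.tsv")),
                                   sep = "\t", header = FALSE))
  dimnames(Y) <- NULL
  events <- read_events(file.path(dir, paste0(prefix, "_events.tsv")))
  confounds <- utils::read.table(file.path(dir, paste0(prefix, "_confounds.tsv")),
                                 sep = "\t", header = TRUE)
  structure(list(Y = Y, events = events, confounds = confounds,
                 tr = tr, n_scans = nrow(Y), truth = NULL),
            class = "bold_run")
}

#' Write/read an RDM as a labelled tab-separated table
#'
#' @param rdm conditions x conditions matrix with row/column labels.
#' @param path file path.
#' @export
write_rdm <- function(rdm, path) {
  utils::write.table(as.matrix(rdm), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1L, check.names = FALSE))
  structure(m, class = c("rdm", "matrix"))
}
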