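# Balanced trial-sequence generation for the first comparison task
# (sequential pairs of action combinations in the scanner).

TASK1_TIMING <- list(stim = 3, gap = 1.5, reflection = 4.5, probe = 4)
TASK2_TIMING <- list(stim = 1.5, gap = 1.5, reflection = 4.5, probe = 4)
TR <- 1.5

probe_groups <- function() {
  c("question-dim1", "question-dim2", "statement-true", "statement-false")
}

# Distance-class schedule: for every bin, the two classes presented in each
# of the 6 runs. Non-cardinal bins are balanced (one short + one longer per
# run; the two longer lengths appear 3 times each over the session).
# Cardinal bins carry one fewer short: 5 runs (short, longer), one run
# (longA, longB); longer slots hold 3 x 4-unit and 4 x 3-unit vectors.
distance_schedule <- function(bins) {
  sched <- vector("list", 12L)
  for (b in seq_len(12L)) {
    if (bins$cardinal[b]) {
      r0 <- sample.int(6L, 1L)
      longer <- sample(c("longA", "longA", "longB", "longB", "longB"))
      runs <- vector("list", 6L)
      k <- 1L
      for (r in 1:6) {
        if (r == r0) {
          runs[[r]] <- sample(c("longA", "longB"))
        } else {
          runs[[r]] <- sample(c("short", longer[k]))
          k <- k + 1L
        }
      }
    } else {
      longer <- sample(rep(c("longA", "longB"), 3L))
      runs <- lapply(1:6, function(r) sample(c("short", longer[r])))
    }
    sched[[b]] <- runs
  }
  sched
}

# Alignment-class sequence for one run: 24 trials, 12 aligned (A) and 12
# misaligned (M), exactly 6 of each per run half, no more than 3 consecutive
# trials of the same class, and the four class transitions (AA, AM, MA, MM)
# occurring according to `quota` (three types 6 times, one type 5 times --
# 23 transitions in total). Constructed directly from block compositions:
# with k_A blocks of A, AA = 12 - k_A; the deficit type fixes the block
# counts and which class starts/ends the run, so only the block lengths
# (each 1-3, summing to 12) and the half-balance need sampling.
class_sequence <- function(quota, max_try = 2000L) {
  # block counts and endpoint classes implied by the quota
  k_a <- 12L - quota[["AA"]]
  k_m <- 12L - quota[["MM"]]
  if (k_a == k_m + 1L) {
    first <- "A"; last <- "A"
  } else if (k_m == k_a + 1L) {
    first <- "M"; last <- "M"
  } else if (quota[["AM"]] == k_a) {
    first <- "A"; last <- "M"
  } else {
    first <- "M"; last <- "A"
  }

  comp <- function(k) {
    # composition of 12 into k parts, each 1..3, by rejection
    for (i in 1:200) {
      parts <- sample(1:3, k, replace = TRUE)
      if (sum(parts) == 12L) return(parts)
    }
    NULL
  }
  for (try in seq_len(max_try)) {
    pa <- comp(k_a)
    pm <- comp(k_m)
    if (is.null(pa) || is.null(pm)) next
    blocks <- character(k_a + k_m)
    lens <- integer(k_a + k_m)
    ia <- if (first == "A") seq(1L, by = 2L, length.out = k_a) else seq(2L, by = 2L, length.out = k_a)
    im <- setdiff(seq_len(k_a + k_m), ia)
    blocks[ia] <- "A"; lens[ia] <- pa
    blocks[im] <- "M"; lens[im] <- pm
    seqv <- rep(blocks, lens)
    if (sum(seqv[1:12] == "A") == 6L) return(seqv)
  }
  NULL
}

# Place each bin once per run half into slots of its alignment class,
# avoiding the same bin on the two sides of the half boundary.
place_bins <- function(cls, bins) {
  aligned_bins <- bins$bin[bins$aligned]
  misaligned_bins <- bins$bin[!bins$aligned]
  h1 <- integer(12L); h2 <- integer(12L)
  h1[cls[1:12] == "A"] <- sample(aligned_bins)
  h1[cls[1:12] == "M"] <- sample(misaligned_bins)
  for (try in 1:50) {
    h2[cls[13:24] == "A"] <- sample(aligned_bins)
    h2[cls[13:24] == "M"] <- sample(misaligned_bins)
    if (h2[1L] != h1[12L]) return(c(h1, h2))
  }
  NULL
}

# Assign distinct start positions to the 12 session trials of one bin by
# randomised backtracking, most-constrained displacement first.
assign_starts <- function(disp_rows, disp_table) {
  feas <- lapply(seq_len(3L), function(k) {
    feasible_starts(disp_table$dx[k], disp_table$dy[k])
  })
  sizes <- vapply(feas, nrow, integer(1L))
  ord <- order(sizes[disp_rows])
  n <- length(disp_rows)
  chosen <- matrix(NA_integer_, n, 2L)
  used <- rep(FALSE, 25L)
  keys <- lapply(feas, function(f) f[, 1L] * 5L + f[, 2L] + 1L)

  rec <- function(t) {
    if (t > n) return(TRUE)
    k <- disp_rows[ord[t]]
    avail <- which(!used[keys[[k]]])
    for (a in avail[sample.int(length(avail))]) {
      key <- keys[[k]][a]
      chosen[ord[t], ] <<- feas[[k]][a, ]
      used[key] <<- TRUE
      if (rec(t + 1L)) return(TRUE)
      used[key] <<- FALSE
    }
    FALSE
  }
  if (!rec(1L)) return(NULL)
  chosen
}

#' Generate one balanced session of the first comparison task
#'
#' Produces 6 runs of 24 trials (144 trials). Every direction bin occurs 12
#' times over the session -- twice per run, once in each run half, never in
#' adjacent trials -- from 12 distinct starting positions. At most 3
#' consecutive trials share an alignment class, and the four class
#' transitions occur with near-equal frequency per run. Each non-cardinal
#' bin is sampled once per run at the short distance (sqrt(5)) and once at a
#' longer distance (sqrt(20)/sqrt(13), alternating across runs); cardinal
#' bins carry one fewer short distance over the session. Probe types are
#' balanced across aligned and misaligned trials within each run.
#'
#' @param seed integer seed; the session is a pure function of it.
#' @param iti inter-trial interval in seconds appended after the probe.
#' @param retry_budget maximum restarts of the sequence/start-position
#'   solvers before giving up with an error.
#' @return `session_design`: list with `task = 1`, `trials` (one row per
#'   trial), `tr`, `n_scans`, `run_duration`, `trial_duration` and `iti`.
#' @export
generate_task1_session <- function(seed = NULL, iti = 2, retry_budget = 10000) {
  with_local_seed(seed, {
    bins <- direction_bins()
    disp <- lapply(bins$nominal, admissible_displacements)
    sched <- distance_schedule(bins)

    # per-run alignment-class sequences with rotated transition deficits
    deficit <- c(sample(c("AA", "AM", "MA", "MM")), sample(c("AA", "AM", "MA", "MM"), 2L))
    run_cls <- vector("list", 6L)
    run_bins <- vector("list", 6L)
    for (r in 1:6) {
      ok <- FALSE
      for (try in seq_len(retry_budget)) {
        quota <- c(AA = 6L, AM = 6L, MA = 6L, MM = 6L)
        quota[deficit[r]] <- 5L
        cls <- class_sequence(quota)
        if (is.null(cls)) { deficit[r] <- sample(c("AA", "AM", "MA", "MM"), 1L); next }
        pb <- place_bins(cls, bins)
        if (is.null(pb)) next
        run_cls[[r]] <- cls
        run_bins[[r]] <- pb
        ok <- TRUE
        break
      }
      if (!ok) stop("trial-sequence solver exhausted its retry budget", call. = FALSE)
    }

    # distance class per (bin, run, half): schedule order randomised already
    # half of first occurrence within run is by slot order
    trials <- data.frame(run = rep(1:6, each = 24L),
                         trial = rep(1:24, times = 6L))
    trials$bin <- unlist(run_bins)
    trials$dist_class <- NA_character_
    for (r in 1:6) {
      for (b in 0:11) {
        idx <- which(trials$run == r & trials$bin == b)
        pair <- sched[[b + 1L]][[r]]
        trials$dist_class[idx] <- pair  # idx ordered by half
      }
    }

    # displacement geometry
    dmatch <- match(trials$dist_class, c("longA", "longB", "short"))
    dt <- do.call(rbind, lapply(seq_len(nrow(trials)), function(k) {
      disp[[trials$bin[k] + 1L]][dmatch[k], c("dx", "dy", "length", "angle")]
    }))
    trials <- cbind(trials, dt)
    trials$nominal <- bins$nominal[trials$bin + 1L]
    trials$aligned <- bins$aligned[trials$bin + 1L]

    # start positions: per bin, 12 distinct starts over the session
    trials$start_i <- NA_integer_
    trials$start_j <- NA_integer_
    for (b in 0:11) {
      idx <- which(trials$bin == b)
      rows <- dmatch[idx]
      st <- NULL
      for (try in seq_len(retry_budget)) {
        st <- assign_starts(rows, disp[[b + 1L]])
        if (!is.null(st)) break
      }
      if (is.null(st)) stop("start-position solver exhausted its retry budget", call. = FALSE)
      trials$start_i[idx] <- st[, 1L]
      trials$start_j[idx] <- st[, 2L]
    }
    trials$end_i <- trials$start_i + trials$dx
    trials$end_j <- trials$start_j + trials$dy

    # probes: 4 balance groups x 6 per run, 3 per alignment class
    trials$probe <- NA_character_
    for (r in 1:6) {
      for (al in c(TRUE, FALSE)) {
        idx <- which(trials$run == r & trials$aligned == al)
        grp <- sample(rep(probe_groups(), each = 3L))
        grp[grp == "statement-true"] <- "statement-bothTrue"
        grp[grp == "statement-false"] <-
          sample(c("statement-oneFalse", "statement-bothFalse"),
                 sum(grp == "statement-false"), replace = TRUE)
        trials$probe[idx] <- grp
      }
    }

    tm <- TASK1_TIMING
    trial_dur <- 2 * tm$stim + 2 * tm$gap + tm$reflection + tm$probe + iti
    trials$onset <- (trials$trial - 1L) * trial_dur
    trials$stim1_onset <- trials$onset
    trials$stim2_onset <- trials$onset + tm$stim + tm$gap
    trials$reflection_onset <- trials$onset + 2 * (tm$stim + tm$gap)
    trials$probe_onset <- trials$reflection_onset + tm$reflection

    structure(list(task = 1L, trials = trials, tr = TR,
                   trial_duration = trial_dur,
                   run_duration = 24L * trial_dur,
                   n_scans = as.integer(ceiling(24L * trial_dur / TR)),
                   iti = iti, timing = tm),
              class = "session_design")
  })
}

#' Per-bin realised direction statistics for a generated session
#'
#' Frequency-weighted mean realised angle and mean distance per direction
#' bin, plus the distance-class counts (diagnostic for the cardinal-bin
#' imbalance).
#'
#' @param design a `session_design` from [generate_task1_session()].
#' @return data.frame with one row per bin: `bin`, `nominal`, `mean_angle`
#'   (degrees in `[0, 360)`, 2 dp), `mean_distance`, and counts `n_longA`,
#'   `n_longB`, `n_short`.
#' @export
direction_statistics <- function(design) {
  stopifnot(inherits(design, "session_design"), design$task == 1L)
  tr <- design$trials
  agg <- lapply(split(tr, tr$bin), function(d) {
    data.frame(bin = d$bin[1L], nominal = d$nominal[1L],
               mean_angle = round(mean(d$angle), 2L),
               mean_distance = mean(d$length),
               n_longA = sum(d$dist_class == "longA"),
               n_longB = sum(d$dist_class == "longB"),
               n_short = sum(d$dist_class == "short"))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
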