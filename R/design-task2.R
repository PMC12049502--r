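# Trial sequences for the second comparison task (coloured landmark balls)
# and for the two similarity-rating tasks.

# Arrange the 30 ordered colour pairs of one run by randomised backtracking:
# every unordered pair appears twice (once in each order), its two
# occurrences are never adjacent, and the first ball of a trial never
# repeats the second ball of the previous trial.
arrange_pairs_run <- function(items) {
  up <- utils::combn(items, 2L)
  pool <- rbind(t(up), t(up)[, 2:1])  # both orders of every pair
  pool_key <- apply(apply(pool, 2L, as.character), 1L,
                    function(z) paste(sort(z), collapse = "|"))
  n <- nrow(pool)
  ordv <- integer(n)
  used <- rep(FALSE, n)

  rec <- function(t) {
    if (t > n) return(TRUE)
    cand <- which(!used)
    if (t > 1L) {
      prev <- ordv[t - 1L]
      cand <- cand[pool[cand, 1L] != pool[prev, 2L] &
                     pool_key[cand] != pool_key[prev]]
    }
    for (k in cand[sample.int(length(cand))]) {
      ordv[t] <<- k
      used[k] <<- TRUE
      if (rec(t + 1L)) return(TRUE)
      used[k] <<- FALSE
    }
    FALSE
  }
  if (!rec(1L)) return(NULL)
  pool[ordv, , drop = FALSE]
}

#' Generate one session of the second comparison task
#'
#' 5 runs of 30 trials. In every run all 15 unordered pairs of the six
#' coloured landmark balls appear twice, once in each presentation order;
#' the second occurrence of a pair is separated from the first by at least
#' one trial, and the first ball of a trial never matches the second ball of
#' the preceding trial. The first 28 trials of each run carry balanced probe
#' types; the final two are drawn at random.
#'
#' @param seed integer seed.
#' @param assignment an [sample_assignment()]; supplies the colour-to-
#'   landmark map used to attach grid positions and distances to the trials.
#' @param iti inter-trial interval in seconds.
#' @param retry_budget maximum solver restarts.
#' @return `session_design` with `task = 2` and one trial per row
#'   (`color1`, `color2`, positions, `length`, probe, event onsets).
#' @export
generate_task2_session <- function(seed = NULL, assignment = sample_assignment(seed),
                                   iti = 2, retry_budget = 10000) {
  with_local_seed(seed, {
    cols <- ball_colors()
    grid <- assignment$grid
    lpos <- grid$landmarks[assignment$landmark_colors[cols], , drop = FALSE]
    rownames(lpos) <- cols

    runs <- vector("list", 5L)
    for (r in 1:5) {
      seqm <- NULL
      for (try in seq_len(retry_budget)) {
        seqm <- arrange_pairs_run(cols)
        if (!is.null(seqm)) break
      }
      if (is.null(seqm)) stop("pair-sequence solver exhausted its retry budget", call. = FALSE)
      runs[[r]] <- seqm
    }

    trials <- data.frame(run = rep(1:5, each = 30L),
                         trial = rep(1:30, times = 5L),
                         color1 = unlist(lapply(runs, function(m) m[, 1L])),
                         color2 = unlist(lapply(runs, function(m) m[, 2L])))
    trials$start_i <- lpos[trials$color1, 1L]
    trials$start_j <- lpos[trials$color1, 2L]
    trials$end_i <- lpos[trials$color2, 1L]
    trials$end_j <- lpos[trials$color2, 2L]
    trials$length <- sqrt((trials$end_i - trials$start_i)^2 +
                            (trials$end_j - trials$start_j)^2)

    trials$probe <- NA_character_
    for (r in 1:5) {
      idx <- which(trials$run == r)
      grp <- c(sample(rep(probe_groups(), each = 7L)),
               sample(probe_groups(), 2L, replace = TRUE))
      grp[grp == "statement-true"] <- "statement-bothTrue"
      grp[grp == "statement-false"] <-
        sample(c("statement-oneFalse", "statement-bothFalse"),
               sum(grp == "statement-false"), replace = TRUE)
      trials$probe[idx] <- grp
    }

    tm <- TASK2_TIMING
    trial_dur <- 2 * tm$stim + 2 * tm$gap + tm$reflection + tm$probe + iti
    trials$onset <- (trials$trial - 1L) * trial_dur
    trials$stim1_onset <- trials$onset
    trials$stim2_onset <- trials$onset + tm$stim + tm$gap
    trials$reflection_onset <- trials$onset + 2 * (tm$stim + tm$gap)
    trials$probe_onset <- trials$reflection_onset + tm$reflection

    structure(list(task = 2L, trials = trials, tr = TR,
                   trial_duration = trial_dur,
                   run_duration = 30L * trial_dur,
                   n_scans = as.integer(ceiling(30L * trial_dur / TR)),
                   iti = iti, timing = tm, landmark_positions = lpos),
              class = "session_design")
  })
}

#' Generate the pair sequence for a similarity-rating task
#'
#' All unordered pairs of `items` stimuli are presented twice, once with
#' each left/right order, and every pair appears once before any pair is
#' repeated (two randomised blocks).
#'
#' @param items number of stimuli: 8 (action combinations) or 6 (balls).
#' @param seed integer seed.
#' @return data.frame with columns `trial`, `item_a`, `item_b` (the
#'   left/right stimuli), `repeat_idx` (1 or 2).
#' @export
generate_rating_set <- function(items, seed = NULL) {
  if (!items %in% c(6L, 8L)) {
    stop("`items` must be 6 or 8", call. = FALSE)
  }
  with_local_seed(seed, {
    pairs <- t(utils::combn(seq_len(items), 2L))
    np <- nrow(pairs)
    flip1 <- sample(c(TRUE, FALSE), np, replace = TRUE)
    b1 <- pairs
    b1[flip1, ] <- b1[flip1, 2:1]
    b2 <- b1[, 2:1]
    b1 <- b1[sample(np), , drop = FALSE]
    b2 <- b2[sample(np), , drop = FALSE]
    out <- rbind(b1, b2)
    data.frame(trial = seq_len(2L * np),
               item_a = out[, 1L], item_b = out[, 2L],
               repeat_idx = rep(1:2, each = np))
  })
}
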