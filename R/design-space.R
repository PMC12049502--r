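#' The two-dimensional action-outcome space
#'
#' The space is a 5 x 5 grid of outcome ranks. Each rank on dimension 1 maps
#' to one of five probabilities of catching a launched ball, each rank on
#' dimension 2 to one of five probabilities that the ball stays visible
#' throughout its flight. Adjacent ranks are one distance unit apart, so the
#' shortest possible distance between two grid positions is 1.
#'
#' @param landmarks integer matrix (6 x 2) of landmark positions in rank
#'   coordinates (0-based). The reference protocol fixes six landmark
#'   positions shared by all participants but leaves their coordinates open;
#'   the default here is a reconstruction covering all quadrants and the
#'   centre.
#' @return An object of class `outcome_grid`: list with `prob_catch`,
#'   `prob_vis` (the five probability levels per dimension), `positions`
#'   (25 x 2 integer matrix of all grid positions) and `landmarks`.
#' @export
outcome_grid <- function(landmarks = default_landmarks()) {
  landmarks <- as.matrix(landmarks)
  stopifnot(ncol(landmarks) == 2L, nrow(landmarks) == 6L,
            all(landmarks >= 0), all(landmarks <= 4))
  pos <- as.matrix(expand.grid(i = 0:4, j = 0:4))
  structure(
    list(prob_catch = c(0.1, 0.3, 0.5, 0.7, 0.9),
         prob_vis   = c(0.1, 0.3, 0.5, 0.7, 0.9),
         positions  = pos,
         landmarks  = landmarks,
         unit       = 1),
    class = "outcome_grid")
}

#' @rdname outcome_grid
#' @export
default_landmarks <- function() {
  cbind(i = c(0L, 1L, 2L, 3L, 4L, 1L),
        j = c(1L, 4L, 2L, 0L, 3L, 0L))
}

#' Default positions probed in the action-combination rating task
#'
#' Eight positions spread over the space so that every quadrant and the
#' centre are covered; the exact positions are not part of the protocol
#' specification, so these are a documented reconstruction (four corners,
#' centre, and three interior points breaking the symmetry).
#' @return 8 x 2 integer matrix of rank coordinates.
#' @export
default_rating_positions <- function() {
  cbind(i = c(0L, 0L, 4L, 4L, 2L, 1L, 3L, 1L),
        j = c(0L, 4L, 0L, 4L, 2L, 1L, 3L, 3L))
}

#' Joystick action labels
#' @export
action_labels <- function() c("left", "backward", "up", "right", "forward")

#' Landmark (coloured-ball) labels
#' @export
ball_colors <- function() c("blue", "green", "purple", "turquoise", "red", "yellow")

#' Sample a participant-specific action-to-outcome assignment
#'
#' Each of the five joystick actions is assigned to an outcome rank on each
#' dimension (two independent permutations), under the constraint that no
#' action maps to the same rank on both dimensions -- similar actions are
#' never associated with similar outcome values on both dimensions. The six
#' ball colours are mapped to the six fixed landmark positions by a uniform
#' permutation.
#'
#' @param seed integer seed; the assignment is a pure function of it.
#' @param grid an [outcome_grid()].
#' @param constraint function of two integer vectors (ranks per action on
#'   each dimension) returning TRUE if the pair is admissible. The default
#'   enforces `sigma1(a) != sigma2(a)` for every action.
#' @return `action_assignment`: list with `sigma1`, `sigma2` (named rank
#'   vectors, 0-based), `landmark_colors` (named landmark index per colour)
#'   and the grid.
#' @export
sample_assignment <- function(seed = NULL, grid = outcome_grid(),
                              constraint = function(s1, s2) all(s1 != s2)) {
  with_local_seed(seed, {
    acts <- action_labels()
    repeat {
      s1 <- sample(0:4)
      s2 <- sample(0:4)
      if (constraint(s1, s2)) break
    }
    names(s1) <- acts
    names(s2) <- acts
    cols <- ball_colors()
    lmap <- sample(seq_len(6L))
    names(lmap) <- cols
    structure(list(sigma1 = s1, sigma2 = s2,
                   landmark_colors = lmap, grid = grid),
              class = "action_assignment")
  })
}

#' Translate a grid position to the action combination producing it
#'
#' @param pos length-2 integer vector (or n x 2 matrix) of rank coordinates.
#' @param assignment an [sample_assignment()] result.
#' @return character matrix with columns `action1`, `action2`.
#' @export
position_to_combo <- function(pos, assignment) {
  pos <- matrix(as.integer(pos), ncol = 2L)
  inv1 <- names(assignment$sigma1)[order(assignment$sigma1)]
  inv2 <- names(assignment$sigma2)[order(assignment$sigma2)]
  cbind(action1 = inv1[pos[, 1L] + 1L], action2 = inv2[pos[, 2L] + 1L])
}

#' Count shared actions between two action combinations
#'
#' Classifies a pair of action combinations by motor overlap: 0 if no action
#' label is shared, 1 if exactly one label is shared (by the same or the
#' other joystick), and 2 if both labels are shared with the joysticks
#' exchanged (the first joystick's action of one combination equals the
#' second joystick's action of the other and vice versa -- "very similar").
#'
#' @param combo1,combo2 length-2 character vectors `(action1, action2)`.
#' @return integer in `{0, 1, 2}`.
#' @export
overlap_count <- function(combo1, combo2) {
  stopifnot(length(combo1) == 2L, length(combo2) == 2L)
  same <- (combo1[1L] == combo2[1L]) + (combo1[2L] == combo2[2L])
  cross <- (combo1[1L] == combo2[2L]) + (combo1[2L] == combo2[1L])
  if (same == 2L) {
    stop("the two combinations are identical; pairs always differ by construction",
         call. = FALSE)
  }
  if (cross == 2L) return(2L)
  if (same + cross >= 1L) return(1L)
  0L
}

#' Trial-wise overlap counts for a generated session
#'
#' Maps every trial's start and end positions to action combinations through
#' a participant assignment and returns the shared-action count per trial.
#'
#' @param design a `session_design` from [generate_task1_session()].
#' @param assignment an [sample_assignment()] result.
#' @return integer vector, one value per trial.
#' @export
trial_overlaps <- function(design, assignment) {
  tr <- design$trials
  c1 <- position_to_combo(cbind(tr$start_i, tr$start_j), assignment)
  c2 <- position_to_combo(cbind(tr$end_i, tr$end_j), assignment)
  vapply(seq_len(nrow(tr)),
         function(k) overlap_count(c1[k, ], c2[k, ]),
         integer(1L))
}
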