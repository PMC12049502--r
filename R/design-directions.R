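#' The 12 sampled directions
#'
#' Directions through the action-outcome space are sampled in 12 bins with
#' nominal angles at multiples of 30 degrees (counterclockwise from the +x
#' axis, start-to-end vector). A bin is "aligned" when its nominal angle is
#' a multiple of 60 degrees (aligned with the axes of a putative hexagonal
#' grid code), otherwise "misaligned".
#'
#' @return data.frame with columns `bin` (0-11), `nominal` (degrees),
#'   `aligned` (logical) and `cardinal` (logical).
#' @export
direction_bins <- function() {
  nominal <- seq(0, 330, by = 30)
  data.frame(bin = 0:11,
             nominal = nominal,
             aligned = nominal %% 60 == 0,
             cardinal = nominal %% 90 == 0)
}

#' Admissible displacement vectors for a direction bin
#'
#' Each direction is sampled at three distances. Cardinal bins (0, 90, 180,
#' 270 degrees) use axis-aligned vectors of 4, 3 and 2 units. Non-cardinal
#' bins use the integer grid vectors of length sqrt(20), sqrt(13) and
#' sqrt(5) (~4.5, 3.6 and 2.2 units) whose angle lies within +-4 degrees of
#' the nominal angle, so realised angles deviate from the nominal one by
#' 3.43 or 3.69 degrees.
#'
#' @param nominal nominal bin angle in degrees (multiple of 30).
#' @return data.frame with columns `dx`, `dy`, `length`, `angle` (realised,
#'   degrees in `[0, 360)`) and `dist_class` in `{"longA", "longB", "short"}`,
#'   sorted by decreasing length.
#' @export
admissible_displacements <- function(nominal) {
  stopifnot(length(nominal) == 1L, nominal %% 30 == 0)
  nominal <- nominal %% 360
  cardinal <- nominal %% 90 == 0
  cand <- expand.grid(dx = -4:4, dy = -4:4)
  cand <- cand[!(cand$dx == 0 & cand$dy == 0), ]
  len2 <- cand$dx^2 + cand$dy^2
  ang <- atan2_deg(cand$dy, cand$dx)
  if (cardinal) {
    keep <- len2 %in% c(16L, 9L, 4L) & abs(angle_diff(ang, nominal)) < 1e-9
  } else {
    keep <- len2 %in% c(20L, 13L, 5L) & abs(angle_diff(ang, nominal)) <= 4
  }
  out <- cand[keep, , drop = FALSE]
  out$length <- sqrt(out$dx^2 + out$dy^2)
  out$angle <- atan2_deg(out$dy, out$dx)
  out <- out[order(-out$length), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(nrow(out) == 3L)
  out$dist_class <- c("longA", "longB", "short")
  out
}

# Feasible start positions (0-based rank coordinates) for a displacement.
feasible_starts <- function(dx, dy) {
  is <- max(0L, -dx):(min(4L, 4L - dx))
  js <- max(0L, -dy):(min(4L, 4L - dy))
  as.matrix(expand.grid(i = is, j = js))
}
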