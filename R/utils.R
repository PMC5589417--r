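#' Wrap angles to the principal interval
#'
#' Maps arbitrary angles to `[-pi, pi)`, the convention used for preferred
#' stimulus values, recalled angles and signed angular errors throughout the
#' package.
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length in `[-pi, pi)`.
#' @export
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Preferred angles of a ring of neurons
#'
#' Equally spaced preferred stimulus values on `[-pi, pi)` with periodic
#' boundary conditions.
#'
#' @param n number of neurons (at least 3).
#' @return numeric vector of length `n`.
#' @export
preferred_angles <- function(n) {
  if (n < 3) stop("need at least 3 neurons")
  seq(-pi, pi, length.out = n + 1)[seq_len(n)]
}

#' Angular grid of the response positions
#'
#' The task uses `n_positions` equally spaced locations on a circle; position
#' `p` (1-based) maps to angle `wrap_angle(2*pi*(p-1)/n_positions)`.
#'
#' @param n_positions number of locations (default 20).
#' @return numeric vector of angles in `[-pi, pi)`.
#' @export
position_angles <- function(n_positions = 20) {
  wrap_angle(2 * pi * (seq_len(n_positions) - 1) / n_positions)
}

#' Signed position offset between two angles
#'
#' Converts a wrapped angular difference to the nearest signed offset on the
#' discrete position grid, with offsets in `{-n/2, ..., n/2 - 1}`.
#'
#' @param delta angular difference in radians (any range).
#' @param n_positions number of positions on the circle.
#' @return integer vector of signed offsets.
#' @export
angle_to_offset <- function(delta, n_positions = 20) {
  spacing <- 2 * pi / n_positions
  k <- round(wrap_angle(delta) / spacing)
  # round() can land on +n/2 for deltas just below pi; wrap to -n/2
  k[k >= n_positions / 2] <- k[k >= n_positions / 2] - n_positions
  as.integer(k)
}

# Deterministic child seed for a named pipeline stage (recorded in outputs).
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}
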