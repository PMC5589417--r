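#' Container for sensor-level epochs
#'
#' Trials x channels x time array with per-trial labels, the time axis in
#' seconds, and a baseline window, mirroring the layout of preprocessed
#' evoked-response epochs.
#'
#' @param data numeric array `trials x channels x time`.
#' @param times strictly increasing time axis in seconds, length `dim(data)[3]`.
#' @param angles optional per-trial circular labels in radians.
#' @param categories optional per-trial categorical labels (factor or
#'   character).
#' @param baseline_window two times in seconds (default `c(-0.2, -0.05)`).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, angles = NULL, categories = NULL,
                      baseline_window = c(-0.2, -0.05)) {
  d <- dim(data)
  if (length(d) != 3) stop("data must be a trials x channels x time array")
  if (length(times) != d[3]) stop("times length must match dim(data)[3]")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(angles) && length(angles) != d[1]) {
    stop("angles length must match the trial count")
  }
  if (!is.null(categories) && length(categories) != d[1]) {
    stop("categories length must match the trial count")
  }
  x <- list(data = data, times = times,
            angles = if (is.null(angles)) NULL else wrap_angle(angles),
            categories = if (is.null(categories)) NULL else factor(categories),
            baseline_window = baseline_window)
  class(x) <- "epoch_set"
  x
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch set: %d trials x %d channels x %d time samples (%.3f to %.3f s)\n",
              d[1], d[2], d[3], min(x$times), max(x$times)))
  if (!is.null(x$angles)) cat("  circular labels: angles present\n")
  if (!is.null(x$categories)) {
    cat("  categories:", paste(levels(x$categories), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Circular-linear correlation coefficient
#'
#' Correlation between a linear variable and a circular one, obtained by
#' combining the two linear correlations of the signal with the sine and the
#' cosine of the angle:
#' `rho^2 = (r_xs^2 + r_xc^2 - 2 r_xs r_xc r_sc) / (1 - r_sc^2)`, the multiple
#' correlation of `x` regressed on `(sin(theta), cos(theta))`. Lies in
#' `[0, 1]`; invariant to affine transforms of `x` and to global rotations of
#' the angles.
#'
#' @param x numeric vector (e.g. a sensor signal across trials).
#' @param theta angles in radians, same length.
#' @return `rho` in `[0, 1]`, or `NA` when `x` has zero variance or the
#'   angle set is degenerate.
#' @export
#' @examples
#' th <- runif(50, -pi, pi)
#' circ_linear_r(sin(th), th)  # 1
circ_linear_r <- function(x, theta) {
  if (length(x) != length(theta)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 trials")
  s <- sin(theta); cth <- cos(theta)
  if (stats::sd(x) == 0 || stats::sd(s) == 0 || stats::sd(cth) == 0) {
    return(NA_real_)
  }
  rxs <- stats::cor(x, s)
  rxc <- stats::cor(x, cth)
  rsc <- stats::cor(s, cth)
  if (abs(rsc) >= 1) return(NA_real_)
  rho2 <- (rxs^2 + rxc^2 - 2 * rxs * rxc * rsc) / (1 - rsc^2)
  sqrt(min(max(rho2, 0), 1))
}

# Standardize columns of a matrix; zero-variance columns -> NA columns.
.std_cols <- function(M) {
  mu <- colMeans(M)
  Mc <- sweep(M, 2, mu)
  sdv <- sqrt(colSums(Mc^2) / (nrow(M) - 1))
  sdv[sdv == 0] <- NA_real_
  sweep(Mc, 2, sdv, "/")
}

# rho for all channel/time cells at once given standardized data (K x CT)
# and raw angles; returns a CT-length vector.
.rho_cells <- function(Xs, theta) {
  K <- nrow(Xs)
  s <- sin(theta); cth <- cos(theta)
  ss <- (s - mean(s)) / stats::sd(s)
  cs <- (cth - mean(cth)) / stats::sd(cth)
  rsc <- stats::cor(s, cth)
  rxs <- crossprod(Xs, ss) / (K - 1)
  rxc <- crossprod(Xs, cs) / (K - 1)
  rho2 <- (rxs^2 + rxc^2 - 2 * rxs * rxc * rsc) / (1 - rsc^2)
  sqrt(pmin(pmax(rho2, 0), 1))
}

#' Circular-linear correlation map with a permutation null
#'
#' Computes the circular-linear correlation between each channel/time cell
#' and the per-trial angle, together with an empirical baseline: the mean
#' correlation map over label-shuffled recomputations. The same trial
#' permutations are applied to every channel and time sample so the null
#' preserves the spatial covariance of the data.
#'
#' @param epochs an [epoch_set()] with `angles`.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param perms optional explicit permutation matrix (`n_perm x trials`),
#'   overriding the random draws (used mainly for diagnostics).
#' @return an object of class `circ_map` with `rho`, `null_mean` and
#'   `delta_rho` (all `channels x time`), `times`, `n_perm`.
#' @export
circ_map <- function(epochs, n_perm = 1000L, seed = 1L, perms = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(epochs$angles)) stop("epochs must carry angle labels")
  d <- dim(epochs$data)
  K <- d[1]; C <- d[2]; TT <- d[3]
  X <- matrix(epochs$data, K, C * TT)
  Xs <- .std_cols(X)
  rho <- matrix(.rho_cells(Xs, epochs$angles), C, TT)
  null_mean <- permutation_null(epochs, n_perm = n_perm, seed = seed,
                                perms = perms, .Xs = Xs)
  out <- list(rho = rho, null_mean = null_mean, delta_rho = rho - null_mean,
              times = epochs$times, n_perm = n_perm)
  class(out) <- "circ_map"
  out
}

#' Permutation null of the circular-linear correlation map
#'
#' Mean channels x time correlation map over `n_perm` recomputations with
#' shuffled angle labels.
#'
#' @inheritParams circ_map
#' @param .Xs internal: precomputed standardized data matrix.
#' @return `channels x time` matrix of null means.
#' @export
permutation_null <- function(epochs, n_perm = 1000L, seed = 1L, perms = NULL,
                             .Xs = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(epochs$angles)) stop("epochs must carry angle labels")
  d <- dim(epochs$data)
  K <- d[1]; C <- d[2]; TT <- d[3]
  if (is.null(.Xs)) .Xs <- .std_cols(matrix(epochs$data, K, C * TT))
  if (is.null(perms)) {
    if (n_perm < 1) stop("n_perm must be >= 1")
    set.seed(seed)
    perms <- t(replicate(n_perm, sample.int(K)))
    if (n_perm == 1L) perms <- matrix(perms, 1L, K)
  }
  acc <- numeric(C * TT)
  for (i in seq_len(nrow(perms))) {
    acc <- acc + .rho_cells(.Xs, epochs$angles[perms[i, ]])
  }
  matrix(acc / nrow(perms), C, TT)
}

#' @export
print.circ_map <- function(x, ...) {
  cat(sprintf("Circular-linear correlation map: %d channels x %d time samples\n",
              nrow(x$rho), ncol(x$rho)))
  cat(sprintf("  max delta_rho %.3f (null from %d permutations)\n",
              max(x$delta_rho, na.rm = TRUE), x$n_perm))
  invisible(x)
}

#' @export
plot.circ_map <- function(x, ...) {
  graphics::image(x$times, seq_len(nrow(x$rho)), t(x$delta_rho),
                  xlab = "time (s)", ylab = "channel",
                  main = expression(Delta * rho), useRaster = TRUE, ...)
  invisible(x)
}

#' A-priori analysis windows
#'
#' The four stimulus-locked windows used for temporal averages: an early
#' perceptual period, the P3b window, and the first and second half of the
#' delay period.
#'
#' @return named list of `c(start, end)` pairs in seconds.
#' @export
default_windows <- function() {
  list(early = c(0.100, 0.300), p3b = c(0.300, 0.600),
       delay1 = c(0.600, 1.550), delay2 = c(1.550, 2.530))
}

#' Average a channels x time map over named time windows
#'
#' @param map a `circ_map` (its `delta_rho` is averaged) or a plain
#'   `channels x time` matrix.
#' @param windows named list of `c(start, end)` windows in seconds (default
#'   [default_windows()]). Samples with `start <= t <= end` are included.
#' @param times time axis (taken from `map` when it is a `circ_map`).
#' @param channels optional channel subset (indices).
#' @return matrix `channels x windows` of means, with a `"grand"` attribute
#'   holding the channel-averaged window means.
#' @export
window_average <- function(map, windows = default_windows(), times = NULL,
                           channels = NULL) {
  if (inherits(map, "circ_map")) {
    times <- map$times
    map <- map$delta_rho
  }
  if (is.null(times)) stop("times required for a plain matrix")
  if (is.null(channels)) channels <- seq_len(nrow(map))
  out <- sapply(windows, function(w) {
    sel <- times >= w[1] & times <= w[2]
    if (!any(sel)) stop("empty window [", w[1], ", ", w[2], "]")
    rowMeans(map[channels, sel, drop = FALSE])
  })
  out <- matrix(out, nrow = length(channels),
                dimnames = list(NULL, names(windows)))
  attr(out, "grand") <- colMeans(out)
  out
}
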