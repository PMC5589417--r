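#' Discretized truncated-Gaussian offset distribution
#'
#' The within-tolerance response-error distribution used by the behavioral
#' generator: probabilities proportional to a zero-mean Gaussian density at
#' the integer offsets `-a ... a`, renormalized. `sd = 0` degenerates to a
#' point mass at 0. Note the realized SD of the discretized, truncated
#' distribution is smaller than the nominal `sd` once `sd` approaches `a`.
#'
#' @param sd nominal Gaussian SD in position units (>= 0).
#' @param a truncation half-width in positions (default 2).
#' @return named probability vector over offsets `-a ... a`.
#' @export
#' @examples
#' offset_distribution(1)
offset_distribution <- function(sd, a = 2L) {
  if (sd < 0) stop("sd must be >= 0")
  n <- seq(-a, a)
  w <- if (sd == 0) as.numeric(n == 0) else stats::dnorm(n, 0, sd)
  stats::setNames(w / sum(w), n)
}

#' Generate behavioral trials from the guessing/precision mixture
#'
#' Draws delayed-response trials from the same model family the mixture
#' estimator assumes: each response is, with probability `p_guess`, a uniform
#' draw over all positions, and otherwise the target plus an offset from a
#' discretized truncated Gaussian confined to +/-2 positions. Visibility
#' ratings are drawn independently; `p_guess` and `sd_positions` may vary by
#' visibility level.
#'
#' @param n_trials number of trials.
#' @param p_guess guessing probability: scalar or one value per visibility
#'   level.
#' @param sd_positions nominal SD of the true-memory offset distribution:
#'   scalar or per visibility level.
#' @param visibility_probs probabilities of the visibility ratings 1-4
#'   (default uniform).
#' @param n_positions positions on the circle (default 20).
#' @param tolerance_a truncation half-width of the true-memory distribution
#'   (default 2).
#' @param condition optional named list of condition flags recycled across
#'   trials (e.g. `list(distractor = c(TRUE, FALSE))`).
#' @param seed integer seed.
#' @return data frame with columns `trial`, `target_pos`, `response_pos`,
#'   `visibility`, `guess` (ground truth) and any condition columns.
#' @export
#' @examples
#' head(gen_behavior(10, p_guess = 0.5, sd_positions = 1, seed = 1))
gen_behavior <- function(n_trials, p_guess = 0.5, sd_positions = 1,
                         visibility_probs = rep(0.25, 4), n_positions = 20L,
                         tolerance_a = 2L, condition = NULL, seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (abs(sum(visibility_probs) - 1) > 1e-8 || any(visibility_probs < 0)) {
    stop("visibility_probs must be nonnegative and sum to 1")
  }
  n_vis <- length(visibility_probs)
  p_guess <- rep_len(p_guess, n_vis)
  sd_positions <- rep_len(sd_positions, n_vis)
  if (any(p_guess < 0 | p_guess > 1)) stop("p_guess must be in [0, 1]")
  if (any(sd_positions < 0)) stop("sd_positions must be >= 0")
  set.seed(seed)
  vis <- sample.int(n_vis, n_trials, replace = TRUE, prob = visibility_probs)
  target <- sample.int(n_positions, n_trials, replace = TRUE)
  guess <- stats::runif(n_trials) < p_guess[vis]
  response <- integer(n_trials)
  response[guess] <- sample.int(n_positions, sum(guess), replace = TRUE)
  if (any(!guess)) {
    for (v in unique(vis[!guess])) {
      sel <- !guess & vis == v
      dd <- offset_distribution(sd_positions[v], tolerance_a)
      off <- sample(as.integer(names(dd)), sum(sel), replace = TRUE, prob = dd)
      response[sel] <- as.integer(((target[sel] - 1 + off) %% n_positions) + 1)
    }
  }
  out <- data.frame(trial = seq_len(n_trials), target_pos = target,
                    response_pos = response, visibility = vis, guess = guess)
  if (!is.null(condition)) {
    for (nm in names(condition)) out[[nm]] <- rep_len(condition[[nm]], n_trials)
  }
  out
}

#' Generate sensor-level epochs with planted angle and category codes
#'
#' Builds a `trials x channels x time` epoch array containing Gaussian sensor
#' noise plus (a) a categorical effect: a fixed topography added to trials of
#' the second category within a time window, and (b) a linear angle code:
#' fixed sine and cosine topographies scaled by `sin(theta)` and `cos(theta)`
#' of each trial's angle, switched on within a per-category time window
#' (e.g. a sustained code for seen trials, a transient one for unseen). The
#' planted windows and topographies are recorded in the `ground_truth`
#' attribute for test assertions.
#'
#' @param n_trials total trials.
#' @param n_channels sensors (default 30).
#' @param times time axis in seconds (default -0.2 to 2.5 s at 250 Hz).
#' @param categories category level names (default seen/unseen).
#' @param category_probs per-level probabilities.
#' @param category_amp amplitude of the categorical effect (0 disables).
#' @param category_window `c(start, end)` s of the categorical effect.
#' @param category_channels channel indices carrying the categorical effect.
#' @param angle_amp amplitude of the angle code (0 disables).
#' @param angle_windows list of `c(start, end)` per category level (or a
#'   single window used for all levels).
#' @param angle_channels channel indices carrying the angle code.
#' @param noise_sd sensor noise SD (> 0).
#' @param amp_jitter trial-to-trial multiplicative amplitude jitter SD
#'   (default 0).
#' @param n_positions discrete angles are drawn from this grid (default 20).
#' @param seed integer seed.
#' @return an [epoch_set()] with `angles`, `categories` and attribute
#'   `ground_truth`.
#' @export
gen_epochs <- function(n_trials = 200L, n_channels = 30L,
                       times = seq(-0.2, 2.5, by = 0.004),
                       categories = c("seen", "unseen"),
                       category_probs = c(0.5, 0.5),
                       category_amp = 1,
                       category_window = c(0.3, max(times)),
                       category_channels = seq_len(min(8L, n_channels)),
                       angle_amp = 1,
                       angle_windows = list(seen = c(0.1, max(times)),
                                            unseen = c(0.18, min(0.5, max(times)))),
                       angle_channels = NULL,
                       noise_sd = 1, amp_jitter = 0,
                       n_positions = 20L, seed = 1L) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (!is.list(angle_windows)) angle_windows <- list(angle_windows)
  if (length(angle_windows) == 1L) {
    angle_windows <- stats::setNames(rep(angle_windows, length(categories)),
                                     categories)
  }
  all_w <- c(list(category_window), unname(angle_windows))
  for (w in all_w) {
    if (w[1] < min(times) || w[2] > max(times) + 1e-9) {
      stop("a planted window lies outside the time axis")
    }
  }
  if (is.null(angle_channels)) {
    angle_channels <- seq(min(9L, n_channels), min(16L, n_channels))
  }
  set.seed(seed)
  K <- as.integer(n_trials); C <- as.integer(n_channels); TT <- length(times)
  cat_lab <- factor(sample(categories, K, replace = TRUE, prob = category_probs),
                    levels = categories)
  grid <- position_angles(n_positions)
  angles <- grid[sample.int(n_positions, K, replace = TRUE)]

  topo_cat <- numeric(C)
  topo_cat[category_channels] <- stats::rnorm(length(category_channels))
  topo_sin <- numeric(C); topo_cos <- numeric(C)
  topo_sin[angle_channels] <- stats::rnorm(length(angle_channels))
  topo_cos[angle_channels] <- stats::rnorm(length(angle_channels))

  amp_k <- 1 + amp_jitter * stats::rnorm(K)
  data <- array(stats::rnorm(K * C * TT, sd = noise_sd), c(K, C, TT))
  env_cat <- times >= category_window[1] & times <= category_window[2]
  is_second <- cat_lab == categories[2]
  for (t in which(env_cat)) {
    data[is_second, , t] <- data[is_second, , t] +
      (category_amp * amp_k[is_second]) %o% topo_cat
  }
  for (lev in categories) {
    w <- angle_windows[[lev]]
    if (is.null(w)) next
    env <- times >= w[1] & times <= w[2]
    sel <- cat_lab == lev
    if (!any(sel) || !any(env)) next
    contrib <- (angle_amp * amp_k[sel] * sin(angles[sel])) %o% topo_sin +
      (angle_amp * amp_k[sel] * cos(angles[sel])) %o% topo_cos
    for (t in which(env)) data[sel, , t] <- data[sel, , t] + contrib
  }
  ep <- epoch_set(data, times, angles = angles, categories = cat_lab)
  attr(ep, "ground_truth") <- list(
    category_window = category_window, category_topography = topo_cat,
    angle_windows = angle_windows, sin_topography = topo_sin,
    cos_topography = topo_cos, category_amp = category_amp,
    angle_amp = angle_amp, noise_sd = noise_sd, seed = seed
  )
  ep
}
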