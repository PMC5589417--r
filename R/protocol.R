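#' Default reactivation threshold for regime classification
#'
#' Scale-free midpoint between the baseline firing rate `gain(I_b)` and the
#' peak rate evoked during target presentation on a noiseless reference trial
#' with the same parameters and schedule. Delay-period activity exceeding this
#' threshold counts as a spontaneous reactivation.
#'
#' @param params a [cann_params()] object.
#' @param schedule a [build_schedule()] object.
#' @return threshold in Hz.
#' @export
reactivation_threshold <- function(params, schedule) {
  ref <- cann_engine(params, schedule, schedule$target_angle,
                     noise_mode = "none",
                     collect_windows = list(
                       delay = c(schedule$mask_off + 0.05, schedule$recall_on),
                       readout = c(schedule$recall_on, schedule$recall_off)))
  base <- gain(params$I_b, params$alpha)
  base + 0.5 * (ref$target_max[1L] - base)
}

# Delay window used for regime classification: from 50 ms after mask offset
# (excluding the mask-offset transient) to recall onset.
default_delay_window <- function(schedule) {
  c(schedule$mask_off + 0.05, schedule$recall_on)
}

#' Classify a trial as spontaneously reactivating or activity-silent
#'
#' A trial is `"reactivating"` when the maximum firing rate over the delay
#' window exceeds the threshold at least once, and `"silent"` otherwise.
#'
#' @param trace a [run_network()] trace.
#' @param threshold_hz reactivation threshold in Hz; by default computed with
#'   [reactivation_threshold()].
#' @param delay_window two times (s) bounding the delay period to scan;
#'   default: 50 ms after mask offset to recall onset.
#' @return `"reactivating"` or `"silent"`.
#' @export
classify_regime <- function(trace, threshold_hz = NULL, delay_window = NULL) {
  sch <- trace$schedule
  if (is.null(delay_window)) delay_window <- default_delay_window(sch)
  if (is.null(threshold_hz)) threshold_hz <- reactivation_threshold(trace$params, sch)
  sel <- trace$times >= delay_window[1] & trace$times < delay_window[2]
  if (!any(sel)) stop("empty delay window")
  peak <- max(trace$rates[sel, , drop = FALSE])
  if (peak > threshold_hz) "reactivating" else "silent"
}

#' Population-vector readout of the remembered angle
#'
#' The angle of the firing-rate-weighted sum of unit vectors at the neurons'
#' preferred angles, time-averaged over a window (by default the recall-signal
#' period). When activity carries no coherent bump the resultant length is
#' near zero and the readout is flagged invalid.
#'
#' @param trace a [run_network()] trace, or a vector of mean rates per neuron
#'   (then `theta` must be given).
#' @param window two times (s); default: recall onset to recall offset.
#' @param theta preferred angles (needed when `trace` is a plain vector).
#' @param tol minimum normalized resultant length for a valid readout
#'   (default 0.05).
#' @return list with `angle` (radians in `[-pi, pi)`), `valid` (logical) and
#'   `resultant` (normalized resultant length in `[0, 1]`).
#' @export
population_vector_readout <- function(trace, window = NULL, theta = NULL,
                                      tol = 0.05) {
  if (inherits(trace, "cann_trace")) {
    sch <- trace$schedule
    if (is.null(window)) window <- c(sch$recall_on, sch$recall_off)
    sel <- trace$times >= window[1] & trace$times < window[2]
    if (!any(sel)) stop("empty readout window")
    rbar <- colMeans(trace$rates[sel, , drop = FALSE])
    theta <- trace$params$theta
  } else {
    rbar <- as.numeric(trace)
    if (is.null(theta)) stop("theta required for a plain rate vector")
  }
  z <- sum(rbar * exp(1i * theta))
  denom <- sum(abs(rbar))
  if (denom <= 0) {
    return(list(angle = NA_real_, valid = FALSE, resultant = 0))
  }
  res <- Mod(z) / denom
  list(angle = wrap_angle(Arg(z)), valid = res >= tol, resultant = res)
}

#' Regime as a function of mask amplitude
#'
#' Runs noiseless trials over a grid of mask amplitudes and classifies each;
#' used to verify that the reactivating-to-silent transition happens exactly
#' once (the bracketing assumption of [find_critical_mask()]).
#'
#' @param params a [cann_params()] object.
#' @param schedule base schedule; its `A_mask` is overridden.
#' @param amplitudes mask amplitudes (Hz) to probe.
#' @param threshold_hz reactivation threshold (default from
#'   [reactivation_threshold()]).
#' @return character vector of regimes, named by amplitude.
#' @export
regime_profile <- function(params, schedule, amplitudes, threshold_hz = NULL) {
  if (is.null(threshold_hz)) threshold_hz <- reactivation_threshold(params, schedule)
  out <- vapply(amplitudes, function(a) {
    sch <- modify_schedule(schedule, A_mask = a)
    noiseless_regime(params, sch, threshold_hz)
  }, character(1))
  names(out) <- amplitudes
  out
}

# Rebuild a schedule with some fields overridden.
modify_schedule <- function(schedule, ...) {
  ov <- list(...)
  args <- list(
    target_angle = schedule$target_angle,
    A_target = schedule$A_target,
    target_duration = schedule$target_off - schedule$target_on,
    gap = schedule$mask_on - schedule$target_off,
    A_mask = schedule$A_mask,
    mask_duration = schedule$mask_off - schedule$mask_on,
    delay = schedule$recall_on - schedule$mask_off,
    A_recall = schedule$A_recall,
    recall_duration = schedule$recall_off - schedule$recall_on,
    target_profile_width = schedule$target_profile_width,
    t_pre = -schedule$t_start,
    t_post = schedule$t_end - schedule$recall_off
  )
  bad <- setdiff(names(ov), names(args))
  if (length(bad)) stop("unknown schedule fields: ", paste(bad, collapse = ", "))
  args[names(ov)] <- ov
  do.call(build_schedule, args)
}

# Noiseless single-trial regime classification without storing a raster.
noiseless_regime <- function(params, schedule, threshold_hz) {
  eng <- cann_engine(params, schedule, schedule$target_angle,
                     noise_mode = "none",
                     collect_windows = list(
                       delay = default_delay_window(schedule),
                       readout = c(schedule$recall_on, schedule$recall_off)))
  if (eng$delay_max[1L] > threshold_hz) "reactivating" else "silent"
}

#' Locate the critical mask amplitude by bisection
#'
#' In the noiseless model the network switches, as the mask amplitude grows,
#' from a regime with spontaneous delay-period reactivations of the target
#' bump to an entirely activity-silent delay. This locates the switching
#' amplitude by bisection.
#'
#' @param params a [cann_params()] object.
#' @param schedule base schedule (its `A_mask` is overridden during the
#'   search).
#' @param lo_hz,hi_hz bracket in Hz; the low end must classify as
#'   reactivating and the high end as silent, otherwise an error is raised.
#' @param tol_hz bracket width at which to stop (default 1 Hz).
#' @param threshold_hz reactivation threshold (default from
#'   [reactivation_threshold()]).
#' @return list with `A_critical` (midpoint of the final bracket, Hz),
#'   `bracket`, `n_evals`.
#' @export
#' @examples
#' \donttest{
#' find_critical_mask(cann_params(), build_schedule(), 50, 65)$A_critical
#' }
find_critical_mask <- function(params, schedule = build_schedule(),
                               lo_hz = 50, hi_hz = 65, tol_hz = 1,
                               threshold_hz = NULL) {
  if (is.null(threshold_hz)) threshold_hz <- reactivation_threshold(params, schedule)
  r_lo <- noiseless_regime(params, modify_schedule(schedule, A_mask = lo_hz), threshold_hz)
  r_hi <- noiseless_regime(params, modify_schedule(schedule, A_mask = hi_hz), threshold_hz)
  n_evals <- 2L
  if (r_lo == r_hi) {
    stop("no bracket: both endpoints classify as '", r_lo, "'")
  }
  if (r_lo != "reactivating") stop("low endpoint must be reactivating")
  while (hi_hz - lo_hz > tol_hz) {
    mid <- (lo_hz + hi_hz) / 2
    r <- noiseless_regime(params, modify_schedule(schedule, A_mask = mid), threshold_hz)
    n_evals <- n_evals + 1L
    if (r == "reactivating") lo_hz <- mid else hi_hz <- mid
  }
  list(A_critical = (lo_hz + hi_hz) / 2, bracket = c(lo_hz, hi_hz),
       n_evals = n_evals, threshold_hz = threshold_hz)
}

#' Run a batch of simulated delayed-response trials
#'
#' Simulates `n_trials` trials with target locations drawn uniformly from the
#' discrete position grid, classifies each trial's delay period as
#' spontaneously reactivating or activity-silent, reads out the recalled
#' location from the population vector during the recall signal, and bins the
#' signed response errors into the 20 position offsets for direct comparison
#' with behavioral response histograms.
#'
#' @param n_trials number of trials (>= 1).
#' @param params a [cann_params()] object.
#' @param schedule a [build_schedule()] object; per-trial target angles
#'   override its `target_angle`.
#' @param noise_mode `"continuous"` (default), `"input_only"` or `"none"`.
#' @param seed integer seed (trial locations and noise).
#' @param n_positions number of grid positions (default 20).
#' @param threshold_hz reactivation threshold (default from
#'   [reactivation_threshold()]).
#' @param batch_size trials simulated per internal batch (memory control).
#' @return an object of class `wm_experiment`: per-trial table `trials`
#'   (target angle, recalled angle, regime, signed error, offset bin, peak
#'   delay rate, readout validity), `regime_fraction`, per-regime offset
#'   histograms `histograms`, `threshold_hz`, and the STP bounds seen across
#'   all trials.
#' @export
run_experiment <- function(n_trials, params = cann_params(),
                           schedule = build_schedule(),
                           noise_mode = c("continuous", "input_only", "none"),
                           seed = 1L, n_positions = 20L, threshold_hz = NULL,
                           batch_size = 1000L) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(n_trials >= 1)
  if (is.null(threshold_hz)) threshold_hz <- reactivation_threshold(params, schedule)
  set.seed(seed)
  grid <- position_angles(n_positions)
  targets <- grid[sample.int(n_positions, n_trials, replace = TRUE)]
  cw <- list(delay = default_delay_window(schedule),
             readout = c(schedule$recall_on, schedule$recall_off))
  spacing <- 2 * pi / n_positions

  idx_split <- split(seq_len(n_trials), ceiling(seq_len(n_trials) / batch_size))
  delay_max <- numeric(n_trials)
  recalled <- numeric(n_trials)
  valid <- logical(n_trials)
  stp_u <- c(Inf, -Inf); stp_x <- c(Inf, -Inf)
  for (ix in idx_split) {
    eng <- cann_engine(params, schedule, targets[ix], noise_mode = noise_mode,
                       seed = NULL, collect_windows = cw)
    delay_max[ix] <- eng$delay_max
    ro <- apply(eng$readout_mean, 2, function(r) {
      pv <- population_vector_readout(r, theta = params$theta)
      c(pv$angle, pv$valid)
    })
    recalled[ix] <- ro[1L, ]
    valid[ix] <- as.logical(ro[2L, ])
    stp_u <- c(min(stp_u[1], eng$stp_range$u[1]), max(stp_u[2], eng$stp_range$u[2]))
    stp_x <- c(min(stp_x[1], eng$stp_range$x[1]), max(stp_x[2], eng$stp_range$x[2]))
  }
  regime <- ifelse(delay_max > threshold_hz, "reactivating", "silent")
  err <- wrap_angle(recalled - targets)
  offset <- angle_to_offset(err, n_positions)
  trials <- data.frame(
    trial = seq_len(n_trials),
    target_angle = targets,
    recalled_angle = recalled,
    regime = regime,
    error = err,
    offset = offset,
    peak_delay_rate = delay_max,
    readout_valid = valid
  )
  hist_levels <- seq(-n_positions / 2, n_positions / 2 - 1)
  histos <- lapply(split(offset, regime), function(o) {
    table(factor(o, levels = hist_levels))
  })
  out <- list(
    trials = trials,
    regime_fraction = mean(regime == "reactivating"),
    histograms = histos,
    threshold_hz = threshold_hz,
    stp_range = list(u = stp_u, x = stp_x),
    schedule = schedule, params = params,
    noise_mode = noise_mode, seed = seed, n_positions = n_positions
  )
  class(out) <- "wm_experiment"
  out
}

#' @export
print.wm_experiment <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf("Simulated working-memory experiment: %d trials (noise '%s')\n",
              n, x$noise_mode))
  cat(sprintf("  reactivating: %.1f%%  silent: %.1f%%  (threshold %.1f Hz)\n",
              100 * x$regime_fraction, 100 * (1 - x$regime_fraction),
              x$threshold_hz))
  for (r in names(x$histograms)) {
    h <- x$histograms[[r]]
    cat(sprintf("  %s: modal offset %s, %.1f%% within +/-2 positions\n",
                r, names(h)[which.max(h)],
                100 * sum(h[abs(as.integer(names(h))) <= 2]) / max(sum(h), 1)))
  }
  invisible(x)
}
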