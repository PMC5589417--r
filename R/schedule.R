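#' Build the target/mask/recall stimulus schedule
#'
#' Timed external-input events of one simulated delayed-response trial:
#' a localized target bump, followed after a short gap by a spatially uniform
#' mask, a long unstimulated delay, and a brief spatially uniform recall
#' signal. With the defaults the mask comes on at 0.067 s and the recall
#' signal at 3.267 s after target onset.
#'
#' @param target_angle target location in radians (wrapped to `[-pi, pi)`).
#' @param A_target target amplitude in Hz (default 390).
#' @param target_duration target duration in s (default 0.050).
#' @param gap gap between target offset and mask onset in s (default 0.017).
#' @param A_mask mask amplitude in Hz, applied uniformly to all neurons
#'   (default 62).
#' @param mask_duration mask duration in s (default 0.200).
#' @param delay delay between mask offset and recall onset in s (default 3.0).
#' @param A_recall amplitude of the non-specific recall signal in Hz
#'   (default 10).
#' @param recall_duration recall-signal duration in s (default 0.050).
#' @param target_profile_width SD (radians) of the Gaussian spatial profile of
#'   the target input (default 0.3).
#' @param t_pre simulated time before target onset in s (default 0.2).
#' @param t_post simulated time after recall offset in s (default 0.05).
#' @return an object of class `stim_schedule`: amplitudes, event onset/offset
#'   times (s, relative to target onset) and the total simulated interval
#'   `[-t_pre, recall_off + t_post]`.
#' @export
#' @examples
#' sch <- build_schedule(target_angle = 0)
#' sch$mask_on    # 0.067
#' sch$recall_on  # 3.267
build_schedule <- function(target_angle = 0, A_target = 390, target_duration = 0.050,
                           gap = 0.017, A_mask = 62, mask_duration = 0.200,
                           delay = 3.0, A_recall = 10, recall_duration = 0.050,
                           target_profile_width = 0.3, t_pre = 0.2, t_post = 0.05) {
  durs <- c(target_duration = target_duration, gap = gap,
            mask_duration = mask_duration, delay = delay,
            recall_duration = recall_duration, t_pre = t_pre, t_post = t_post,
            target_profile_width = target_profile_width)
  # delay = 0 (recall immediately after mask) and gap = 0 are legal degenerate
  # schedules; strictly negative values are not.
  if (any(durs < 0) || target_duration <= 0 || mask_duration <= 0 ||
      recall_duration <= 0 || target_profile_width <= 0) {
    stop("durations and profile width must be positive, gaps nonnegative")
  }
  if (any(c(A_target, A_mask, A_recall) < 0)) stop("amplitudes must be >= 0")
  s <- list(
    target_angle = wrap_angle(target_angle),
    A_target = A_target, A_mask = A_mask, A_recall = A_recall,
    target_profile_width = target_profile_width,
    target_on = 0, target_off = target_duration,
    mask_on = target_duration + gap,
    mask_off = target_duration + gap + mask_duration,
    recall_on = target_duration + gap + mask_duration + delay,
    recall_off = target_duration + gap + mask_duration + delay + recall_duration,
    t_start = -t_pre,
    t_end = target_duration + gap + mask_duration + delay + recall_duration + t_post
  )
  class(s) <- "stim_schedule"
  s
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat("Stimulus schedule (times relative to target onset)\n")
  cat(sprintf("  target: %g Hz at %.3f rad, %.3f-%.3f s (Gaussian width %g rad)\n",
              x$A_target, x$target_angle, x$target_on, x$target_off,
              x$target_profile_width))
  cat(sprintf("  mask:   %g Hz (uniform), %.3f-%.3f s\n", x$A_mask, x$mask_on, x$mask_off))
  cat(sprintf("  recall: %g Hz (uniform), %.3f-%.3f s\n", x$A_recall, x$recall_on, x$recall_off))
  cat(sprintf("  simulated interval: %.3f to %.3f s\n", x$t_start, x$t_end))
  invisible(x)
}

# Spatial profile of the target input over the ring (Hz at amplitude 1).
target_profile <- function(theta, target_angle, width) {
  exp(-0.5 * (wrap_angle(theta - target_angle) / width)^2)
}

# Stimulus phase per integration step: 0 none, 1 target, 2 mask, 3 recall.
# Times are the left edge of each Euler step.
schedule_phases <- function(schedule, dt) {
  tt <- seq(schedule$t_start, schedule$t_end - dt / 2, by = dt)
  phase <- integer(length(tt))
  phase[tt >= schedule$target_on & tt < schedule$target_off] <- 1L
  phase[tt >= schedule$mask_on & tt < schedule$mask_off] <- 2L
  phase[tt >= schedule$recall_on & tt < schedule$recall_off] <- 3L
  list(times = tt, phase = phase)
}
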