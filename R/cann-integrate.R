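#' Initial network state
#'
#' Resting state used at the start of every trial: synaptic currents at the
#' background level `I_b`, release probability at its baseline `U`, full
#' neurotransmitter availability `x = 1`, silent inhibitory pool.
#'
#' @param params a [cann_params()] object.
#' @param n_trials number of trials simulated side by side (state vectors
#'   become `n_neurons x n_trials` matrices).
#' @param t0 simulation time attached to the state (s).
#' @return an object of class `cann_state` with elements `h_E`, `u`, `x`
#'   (matrices `n_neurons x n_trials`), `h_I` (length `n_trials`) and `t`.
#' @export
cann_state <- function(params, n_trials = 1L, t0 = -0.2) {
  N <- params$n_neurons
  st <- list(
    h_E = matrix(params$I_b, N, n_trials),
    u = matrix(params$U, N, n_trials),
    x = matrix(1, N, n_trials),
    h_I = numeric(n_trials),
    t = t0
  )
  class(st) <- "cann_state"
  st
}

#' Advance the network by one Euler-Maruyama step
#'
#' One integration step of the coupled firing-rate / short-term-plasticity
#' dynamics. The excitatory current relaxes toward the recurrent drive (the
#' ring integral of kernel times effective efficacy `u * x * R_E`, discretized
#' as `rho * sum_j J[i,j] u_j x_j R_j * dtheta`), minus pooled inhibition,
#' plus background current, external input, and noise. The facilitation
#' variable `u` is pushed toward 1 by firing and decays to `U`; the resource
#' `x` is depleted in proportion to `u * x * R_E` and recovers to 1. The
#' inhibitory pool integrates total excitatory firing. The noise terms
#' `delta1 * xi1` and `delta2 * xi2` enter the current equation alongside the
#' other drive terms (per-step contribution `(delta / tau) * dt * xi` with
#' `xi` standard normal per neuron and step); `delta1` (background) applies on
#' every step in `continuous` mode, `delta2` (stimulus) only while an
#' external stimulus is on.
#'
#' @param state a [cann_state()] object.
#' @param external_input external stimulus current in Hz: matrix
#'   `n_neurons x n_trials` (or vector for a single trial).
#' @param params a [cann_params()] object.
#' @param noise_draws optional list with standard-normal matrices `xi1`, `xi2`
#'   matching `h_E`; `NULL` entries mean no such noise this step.
#' @param stimulus_on logical: is an external stimulus currently on? Gates the
#'   `delta2` noise term.
#' @param J precomputed kernel matrix (recomputed from `params` if missing).
#' @param freeze_stp if `TRUE`, hold `u = U` and `x = 1` fixed (diagnostic
#'   mode: removes the synaptic memory trace).
#' @return the advanced `cann_state`.
#' @export
cann_step <- function(state, external_input, params, noise_draws = NULL,
                      stimulus_on = FALSE, J = NULL, freeze_stp = FALSE) {
  if (is.null(J)) J <- connectivity_matrix(params)
  h_E <- state$h_E
  if (is.null(dim(h_E))) h_E <- matrix(h_E, ncol = 1L)
  K <- ncol(h_E)
  N <- nrow(h_E)
  ext <- external_input
  if (is.null(dim(ext))) ext <- matrix(ext, N, K)
  dt <- params$dt
  rt <- dt / params$tau

  R_E <- gain(h_E, params$alpha)
  R_I <- gain(state$h_I, params$alpha)
  eff <- if (freeze_stp) params$U * R_E else state$u * state$x * R_E
  rec <- (params$rho * params$dtheta) * (J %*% eff)
  drift_E <- -h_E + rec + ext +
    matrix(params$I_b - params$J_EI * R_I, N, K, byrow = TRUE)
  h_E_new <- h_E + rt * drift_E
  if (!is.null(noise_draws$xi1)) {
    h_E_new <- h_E_new + (params$delta1 / params$tau) * dt * noise_draws$xi1
  }
  if (stimulus_on && !is.null(noise_draws$xi2)) {
    h_E_new <- h_E_new + (params$delta2 / params$tau) * dt * noise_draws$xi2
  }
  if (freeze_stp) {
    u_new <- state$u
    x_new <- state$x
  } else {
    u_new <- state$u + dt * ((params$U - state$u) / params$tau_f +
                               params$U * (1 - state$u) * R_E)
    x_new <- state$x + dt * ((1 - state$x) / params$tau_d -
                               state$u * state$x * R_E)
  }
  h_I_new <- state$h_I + rt * (-state$h_I + params$J_IE * colSums(R_E) * params$dtheta)

  for (nm in c("h_E", "u", "x", "h_I")) {
    v <- switch(nm, h_E = h_E_new, u = u_new, x = x_new, h_I = h_I_new)
    if (anyNA(v) || any(!is.finite(v))) {
      stop("network state diverged in component '", nm,
           "' (non-finite values): dt is likely too large")
    }
  }
  st <- list(h_E = h_E_new, u = u_new, x = x_new, h_I = h_I_new, t = state$t + dt)
  class(st) <- "cann_state"
  st
}

# Internal batched engine. Simulates K trials side by side through a common
# schedule (target angles may differ per trial). Divergence is checked every
# check_every steps rather than every step; a diverging trajectory reaches
# non-finite values within a few steps, so this only delays the error message.
cann_engine <- function(params, schedule, target_angles,
                        noise_mode = c("continuous", "input_only", "none"),
                        seed = NULL, record_every = 0L, freeze_stp = FALSE,
                        collect_windows = NULL, check_every = 25L) {
  noise_mode <- match.arg(noise_mode)
  if (!is.null(seed)) set.seed(seed)
  N <- params$n_neurons
  K <- length(target_angles)
  dt <- params$dt
  J <- connectivity_matrix(params)
  Jeff <- (params$rho * params$dtheta) * J
  ph <- schedule_phases(schedule, dt)
  n_steps <- length(ph$phase)
  # per-trial target input profile (N x K), scaled by A_target
  tgt_in <- schedule$A_target *
    vapply(target_angles, function(a) {
      target_profile(params$theta, a, schedule$target_profile_width)
    }, numeric(N))
  tgt_in <- matrix(tgt_in, N, K)

  h_E <- matrix(params$I_b, N, K)
  u <- matrix(params$U, N, K)
  x <- matrix(1, N, K)
  h_I <- numeric(K)

  sig1 <- (params$delta1 / params$tau) * dt
  sig2 <- (params$delta2 / params$tau) * dt
  use_bg_noise <- noise_mode == "continuous" && params$delta1 > 0
  use_stim_noise <- noise_mode %in% c("continuous", "input_only") && params$delta2 > 0

  record <- record_every > 0L
  if (record) {
    keep <- seq(1L, n_steps, by = record_every)
    rates <- array(NA_real_, c(length(keep), N, K))
    u_rec <- array(NA_real_, c(length(keep), N, K))
    x_rec <- array(NA_real_, c(length(keep), N, K))
    keep_idx <- integer(n_steps)
    keep_idx[keep] <- seq_along(keep)
  }
  cw <- collect_windows
  if (!is.null(cw)) {
    in_delay <- ph$times >= cw$delay[1] & ph$times < cw$delay[2]
    in_readout <- ph$times >= cw$readout[1] & ph$times < cw$readout[2]
    in_target <- ph$phase == 1L
    delay_max <- rep(-Inf, K)
    target_max <- rep(-Inf, K)
    readout_sum <- matrix(0, N, K)
    readout_n <- 0L
    u_min <- Inf; u_max <- -Inf
    x_min <- Inf; x_max <- -Inf
  }
  col_max <- function(M) {
    tM <- t(M)
    tM[cbind(seq_len(nrow(tM)), max.col(tM, ties.method = "first"))]
  }

  rt <- dt / params$tau
  for (i in seq_len(n_steps)) {
    phase <- ph$phase[i]
    R_E <- gain(h_E, params$alpha)
    R_I <- gain(h_I, params$alpha)
    eff <- if (freeze_stp) params$U * R_E else u * x * R_E
    ext <- switch(phase + 1L, 0, tgt_in, schedule$A_mask, schedule$A_recall)
    drift <- -h_E + Jeff %*% eff + ext +
      rep(params$I_b - params$J_EI * R_I, each = N)
    h_E <- h_E + rt * drift
    if (use_bg_noise) h_E <- h_E + sig1 * matrix(stats::rnorm(N * K), N, K)
    if (use_stim_noise && phase > 0L) {
      h_E <- h_E + sig2 * matrix(stats::rnorm(N * K), N, K)
    }
    if (!freeze_stp) {
      u_new <- u + dt * ((params$U - u) / params$tau_f + params$U * (1 - u) * R_E)
      x_new <- x + dt * ((1 - x) / params$tau_d - u * x * R_E)
      u <- u_new
      x <- x_new
    }
    h_I <- h_I + rt * (-h_I + params$J_IE * colSums(R_E) * params$dtheta)

    if (i %% check_every == 0L && !all(is.finite(h_E))) {
      stop("network state diverged in component 'h_E' (non-finite values): ",
           "dt is likely too large")
    }
    if (record && keep_idx[i] > 0L) {
      k <- keep_idx[i]
      rates[k, , ] <- gain(h_E, params$alpha)
      u_rec[k, , ] <- u
      x_rec[k, , ] <- x
    }
    if (!is.null(cw)) {
      if (in_delay[i]) delay_max <- pmax(delay_max, col_max(R_E))
      if (in_target[i]) target_max <- pmax(target_max, col_max(R_E))
      if (in_readout[i]) {
        readout_sum <- readout_sum + R_E
        readout_n <- readout_n + 1L
      }
      u_min <- min(u_min, u); u_max <- max(u_max, u)
      x_min <- min(x_min, x); x_max <- max(x_max, x)
    }
  }
  out <- list(times = ph$times, phase = ph$phase,
              final = list(h_E = h_E, u = u, x = x, h_I = h_I))
  if (record) {
    out$rec_times <- ph$times[keep]
    out$rates <- rates
    out$u <- u_rec
    out$x <- x_rec
  }
  if (!is.null(cw)) {
    out$delay_max <- delay_max
    out$target_max <- target_max
    out$readout_mean <- readout_sum / max(readout_n, 1L)
    out$stp_range <- list(u = c(u_min, u_max), x = c(x_min, x_max))
  }
  out
}

#' Simulate one trial of the network
#'
#' Integrates the full network through a stimulus schedule and returns a
#' time-resolved trace: the firing-rate raster and snapshots of the synaptic
#' variables `u` and `x`, decimated by `record_every` integration steps.
#'
#' @param schedule a [build_schedule()] object (its `target_angle` sets the
#'   stimulus location).
#' @param params a [cann_params()] object.
#' @param seed integer seed for the noise stream (ignored when
#'   `noise_mode = "none"`).
#' @param noise_mode `"continuous"` (background noise always on, stimulus
#'   noise during stimuli), `"input_only"` (stimulus noise only) or `"none"`.
#' @param record_every record every this-many integration steps (default 5,
#'   i.e. 5 ms at the default `dt`).
#' @param freeze_stp hold `u` and `x` at baseline (see [cann_step()]).
#' @return an object of class `cann_trace`: `times`, `rates`
#'   (time x neurons, Hz), `u`, `x` (same layout), `events`, `schedule`,
#'   `params`.
#' @export
#' @examples
#' p <- cann_params()
#' tr <- run_network(build_schedule(target_angle = 0, delay = 0.3),
#'                   p, noise_mode = "none")
#' max(tr$rates)
run_network <- function(schedule, params = cann_params(), seed = NULL,
                        noise_mode = c("continuous", "input_only", "none"),
                        record_every = 5L, freeze_stp = FALSE) {
  noise_mode <- match.arg(noise_mode)
  if (schedule$t_end <= schedule$recall_on) {
    stop("schedule must cover the recall signal")
  }
  eng <- cann_engine(params, schedule, schedule$target_angle,
                     noise_mode = noise_mode, seed = seed,
                     record_every = as.integer(record_every),
                     freeze_stp = freeze_stp)
  tr <- list(
    times = eng$rec_times,
    rates = eng$rates[, , 1L],
    u = eng$u[, , 1L],
    x = eng$x[, , 1L],
    events = data.frame(
      event = c("target", "mask", "recall"),
      onset = c(schedule$target_on, schedule$mask_on, schedule$recall_on),
      offset = c(schedule$target_off, schedule$mask_off, schedule$recall_off)
    ),
    schedule = schedule,
    params = params,
    noise_mode = noise_mode,
    seed = seed
  )
  class(tr) <- "cann_trace"
  tr
}

#' @export
print.cann_trace <- function(x, ...) {
  cat(sprintf("Network trial trace: %d time samples x %d neurons (%.3f to %.3f s)\n",
              nrow(x$rates), ncol(x$rates), min(x$times), max(x$times)))
  cat(sprintf("  peak rate %.1f Hz; noise mode '%s'\n", max(x$rates), x$noise_mode))
  invisible(x)
}

#' @export
plot.cann_trace <- function(x, ...) {
  graphics::image(x$times, x$params$theta, x$rates,
                  xlab = "time (s)", ylab = "preferred angle (rad)",
                  main = "firing rate (Hz)", useRaster = TRUE, ...)
  graphics::abline(v = c(x$events$onset, x$events$offset), lty = 3)
  invisible(x)
}
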