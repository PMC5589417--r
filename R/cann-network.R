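#' Parameters of the continuous attractor network
#'
#' Bundles and validates all constants of the one-dimensional ring attractor
#' with short-term synaptic facilitation and depression. Defaults follow the
#' published parameter set of the model: a ring of `N = 100` rate neurons with
#' translation-invariant cosine connectivity, an inhibitory pool, and
#' Tsodyks-Markram style short-term plasticity on the recurrent synapses.
#'
#' The neuronal density `rho` is only identifiable jointly with the scale of
#' the connectivity kernel, and the published parameter list does not fix it.
#' It was therefore calibrated against the model's critical mask amplitude:
#' with the default `rho = 0.07275 * n_neurons / (2 * pi)` (i.e.
#' `rho * dtheta = 0.07275`) and the default target-profile width, the
#' noiseless reactivating-to-silent transition lies at a mask amplitude of
#' about 62 Hz (see [find_critical_mask()]). In this regime the delay period
#' is activity-silent except for discrete population-spike reactivations,
#' and memory is carried by the facilitation variable `u`.
#'
#' @param n_neurons number of excitatory neurons on the ring (N, default 100).
#' @param tau firing-rate time constant in seconds (default 0.008).
#' @param rho neuronal density per radian; default
#'   `0.07275 * n_neurons / (2 * pi)`, calibrated so the critical mask
#'   amplitude falls near 62 Hz.
#' @param J1 amplitude of the excitatory kernel (default 12).
#' @param J0 uniform inhibitory offset inside the kernel (default 1).
#' @param B width factor of the cosine kernel (default 2.2).
#' @param J_EI inhibitory-to-excitatory coupling (default 1.9).
#' @param J_IE excitatory-to-inhibitory coupling (default 1.8).
#' @param I_b constant background current to all excitatory neurons
#'   (default -0.1).
#' @param delta1 background-noise amplitude (default 0.3).
#' @param delta2 stimulus-noise amplitude, applied only while an external
#'   stimulus is on (default 9).
#' @param U baseline release probability / facilitation increment (default
#'   0.3; not part of the published list, standard in the short-term
#'   plasticity literature).
#' @param tau_f facilitation time constant in seconds (default 4).
#' @param tau_d depression time constant in seconds (default 0.3).
#' @param alpha gain-smoothing constant of the threshold-linear transfer
#'   function (default 1.5).
#' @param dt Euler-Maruyama integration step in seconds (default 0.001).
#' @return an object of class `cann_params` (a validated list).
#' @seealso [gain()], [connectivity_kernel()], [run_network()]
#' @export
#' @examples
#' p <- cann_params()
#' p$J1
cann_params <- function(n_neurons = 100L, tau = 0.008,
                        rho = 0.07275 * n_neurons / (2 * pi),
                        J1 = 12, J0 = 1, B = 2.2, J_EI = 1.9, J_IE = 1.8,
                        I_b = -0.1, delta1 = 0.3, delta2 = 9,
                        U = 0.3, tau_f = 4, tau_d = 0.3,
                        alpha = 1.5, dt = 0.001) {
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 3L) stop("n_neurons must be >= 3")
  for (nm in c("tau", "tau_f", "tau_d")) {
    if (get(nm) <= 0) stop(nm, " must be > 0")
  }
  if (dt <= 0 || dt >= tau) stop("dt must satisfy 0 < dt < tau for stability")
  if (U <= 0 || U > 1) stop("U must be in (0, 1]")
  if (alpha <= 0) stop("alpha must be > 0")
  if (J0 < 0 || J1 <= J0) stop("need J1 > J0 >= 0")
  if (rho <= 0) stop("rho must be > 0")
  p <- list(
    n_neurons = n_neurons, tau = tau, rho = rho, J1 = J1, J0 = J0, B = B,
    J_EI = J_EI, J_IE = J_IE, I_b = I_b, delta1 = delta1, delta2 = delta2,
    U = U, tau_f = tau_f, tau_d = tau_d, alpha = alpha, dt = dt,
    dtheta = 2 * pi / n_neurons,
    theta = preferred_angles(n_neurons)
  )
  class(p) <- "cann_params"
  p
}

#' @export
print.cann_params <- function(x, ...) {
  cat("Continuous attractor network parameters\n")
  cat(sprintf("  N = %d neurons, tau = %g s, dt = %g s\n", x$n_neurons, x$tau, x$dt))
  cat(sprintf("  kernel: J1 = %g, J0 = %g, B = %g (rho = %.4g)\n", x$J1, x$J0, x$B, x$rho))
  cat(sprintf("  inhibition: J_EI = %g, J_IE = %g; background I_b = %g\n",
              x$J_EI, x$J_IE, x$I_b))
  cat(sprintf("  STP: U = %g, tau_f = %g s, tau_d = %g s\n", x$U, x$tau_f, x$tau_d))
  cat(sprintf("  noise: delta1 = %g (background), delta2 = %g (stimulus)\n",
              x$delta1, x$delta2))
  invisible(x)
}

#' Smoothed threshold-linear neural gain
#'
#' The firing-rate transfer function `R(h) = alpha * log(1 + exp(h / alpha))`,
#' a softplus: approximately linear for large positive currents and smoothly
#' zero for negative ones. Evaluated in a numerically stable form for large
#' `|h|`.
#'
#' @param h synaptic current (numeric vector, matrix or scalar; must be
#'   finite).
#' @param alpha smoothing constant, > 0.
#' @return firing rate(s) in Hz, same shape as `h`; always nonnegative.
#' @export
#' @examples
#' gain(0, 1.5)          # 1.5 * log(2)
#' gain(1e4, 1.5) - 1e4  # ~ 0: linear limit
gain <- function(h, alpha = 1.5) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (anyNA(h) || any(!is.finite(h))) stop("non-finite synaptic current")
  z <- h / alpha
  out <- z
  big <- z > 30
  # log1p(exp(z)) = z + log1p(exp(-z)) for large z; plain log1p(exp(z)) below
  out[big] <- z[big] + log1p(exp(-z[big]))
  out[!big] <- log1p(exp(z[!big]))
  alpha * out
}

#' Translation-invariant connectivity kernel
#'
#' Interaction strength between neurons with preferred angles `theta_i` and
#' `theta_j`: a truncated cosine `J1 * cos(B * d) - J0` while `B * d` lies
#' within `[-acos(-J0/J1), acos(-J0/J1)]` (with `d` the wrapped angular
#' difference), and a uniform `-J0` outside. Symmetric and a function of the
#' difference only.
#'
#' @param theta_i,theta_j angles in radians (vectors are recycled).
#' @param params a [cann_params()] object.
#' @return numeric vector of connection weights.
#' @export
#' @examples
#' p <- cann_params()
#' connectivity_kernel(0, 0, p)   # J1 - J0 = 11
#' connectivity_kernel(0, pi, p)  # -J0 = -1
connectivity_kernel <- function(theta_i, theta_j, params = cann_params()) {
  if (params$J0 / params$J1 > 1) stop("J0/J1 > 1: kernel cutoff undefined")
  d <- wrap_angle(theta_i - theta_j)
  cutoff <- acos(-params$J0 / params$J1)
  ifelse(abs(params$B * d) <= cutoff,
         params$J1 * cos(params$B * d) - params$J0,
         -params$J0)
}

# Full N x N kernel matrix J[i, j] = J(theta_i, theta_j).
connectivity_matrix <- function(params) {
  th <- params$theta
  outer(th, th, function(a, b) connectivity_kernel(a, b, params))
}
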