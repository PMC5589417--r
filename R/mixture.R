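#' Response-error histogram over signed position offsets
#'
#' Builds the 20-bin histogram of signed positional errors used by the
#' guess/precision mixture model. Offsets are
#' `((response - target + 10) mod 20) - 10`, i.e. bins `-10 ... +9`; the
#' asymmetric extreme bin (-10) lies outside the correct-response region so it
#' never affects the true-memory distribution.
#'
#' @param x a vector of per-trial signed integer offsets (any length); omit
#'   when giving `counts` directly.
#' @param counts alternatively, a vector of `n_positions` bin counts (or
#'   probability weights), ordered by offset `-10 ... +9` or named by offset.
#' @param n_positions number of positions on the circle (default 20).
#' @param tolerance_a half-width of the correct-response region in positions
#'   (default 2).
#' @return an object of class `response_histogram` with `counts`, `offsets`,
#'   `n_trials`, `n_positions`, `tolerance_a`.
#' @export
#' @examples
#' h <- response_histogram(c(0, 0, 1, -1, 7))
#' h$counts
response_histogram <- function(x = NULL, counts = NULL, n_positions = 20L,
                               tolerance_a = 2L) {
  offs <- seq(-n_positions / 2, n_positions / 2 - 1)
  if (is.null(counts) == is.null(x)) {
    stop("give exactly one of per-trial offsets `x` or bin `counts`")
  }
  if (!is.null(counts)) {
    if (length(counts) != n_positions) {
      stop("counts must have length n_positions = ", n_positions)
    }
    if (!is.null(names(counts))) {
      if (!setequal(names(counts), as.character(offs))) {
        stop("count names must be the offsets ", offs[1], "...", offs[n_positions])
      }
      counts <- counts[as.character(offs)]
    }
    counts <- as.numeric(counts)
  } else {
    x <- as.integer(x)
    if (any(x < -n_positions / 2 | x > n_positions / 2 - 1)) {
      stop("offsets must lie in ", -n_positions / 2, "...", n_positions / 2 - 1)
    }
    counts <- as.numeric(table(factor(x, levels = offs)))
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  h <- list(counts = stats::setNames(counts, offs), offsets = offs,
            n_trials = sum(counts), n_positions = as.integer(n_positions),
            tolerance_a = as.integer(tolerance_a))
  class(h) <- "response_histogram"
  h
}

#' Histogram of positional errors from a trial table
#'
#' @param target,response integer positions in `1 ... n_positions`.
#' @inheritParams response_histogram
#' @return a [response_histogram()].
#' @export
position_offsets <- function(target, response, n_positions = 20L) {
  if (length(target) != length(response)) stop("length mismatch")
  ((response - target + n_positions / 2) %% n_positions) - n_positions / 2
}

#' Guess-rate estimate from the tail of the error distribution
#'
#' Under the mixture model `D(n) = p/N + (1 - p) d(n)` with the true-memory
#' distribution `d` vanishing outside `[-a, a]`, the bins outside the
#' correct-response region contain pure guessing, so
#' `p_hat = sum of D(n) outside [-a, a] / (N - 2a - 1) * N`. The estimate is
#' 1 for a uniform histogram and 0 when all mass lies within the region;
#' finite-sample noise can push it outside `[0, 1]`, in which case it is
#' clamped (with a warning).
#'
#' @param hist a [response_histogram()].
#' @return `p_hat` in `[0, 1]`.
#' @export
#' @examples
#' estimate_guess_rate(response_histogram(counts = rep(1, 20)))  # uniform -> 1
estimate_guess_rate <- function(hist) {
  stopifnot(inherits(hist, "response_histogram"))
  if (hist$n_trials <= 0) stop("empty histogram")
  D <- hist$counts / hist$n_trials
  a <- hist$tolerance_a
  N <- hist$n_positions
  outside <- abs(hist$offsets) > a
  p <- sum(D[outside]) / (N - 2 * a - 1) * N
  if (p > 1 || p < 0) {
    warning("guess-rate estimate ", signif(p, 4), " clamped to [0, 1]")
    p <- min(max(p, 0), 1)
  }
  p
}

#' Estimate of the true working-memory distribution
#'
#' Removes the uniform guessing floor, `delta(n) = (D(n) - p_hat/N) /
#' (1 - p_hat)`, restricts to the correct-response region `[-a, a]`, zeroes
#' residual negative mass and renormalizes to 1.
#'
#' @param hist a [response_histogram()].
#' @param p_hat guess rate (default: [estimate_guess_rate()] of `hist`).
#' @param eps guard against division by zero for pure guessing.
#' @return named probabilities over offsets `-a ... a`.
#' @export
estimate_true_distribution <- function(hist, p_hat = estimate_guess_rate(hist),
                                       eps = 1e-8) {
  stopifnot(inherits(hist, "response_histogram"))
  if (p_hat >= 1 - eps) {
    stop("pure guessing (p_hat >= 1): true-memory distribution undefined")
  }
  D <- hist$counts / hist$n_trials
  N <- hist$n_positions
  a <- hist$tolerance_a
  delta <- (D - p_hat / N) / (1 - p_hat)
  inside <- abs(hist$offsets) <= a
  d <- pmax(delta[inside], 0)
  tot <- sum(d)
  if (tot <= 0) stop("no mass inside the correct-response region")
  d / tot
}

#' Precision of the true-memory distribution
#'
#' Standard deviation (about its mean) of the estimated true-memory offset
#' distribution, in position units; one position equals 18 degrees on the
#' 20-location circle.
#'
#' @param d_hat named probabilities over offsets, as returned by
#'   [estimate_true_distribution()].
#' @param degrees if `TRUE`, return degrees (positions x 18).
#' @return nonnegative standard deviation.
#' @export
mixture_precision <- function(d_hat, degrees = FALSE) {
  n <- as.numeric(names(d_hat))
  if (any(is.na(n))) stop("d_hat must be named by offsets")
  m <- sum(n * d_hat)
  sd <- sqrt(sum(d_hat * (n - m)^2))
  if (degrees) sd * 360 / 20 else sd
}

#' Rate of correct responding
#'
#' Proportion of trials within `a` positions (+/-36 degrees at `a = 2`) of
#' the target; chance under uniform guessing is `(2a + 1)/N = 25%`.
#'
#' @param hist a [response_histogram()].
#' @return proportion in `[0, 1]`.
#' @export
rate_correct <- function(hist) {
  stopifnot(inherits(hist, "response_histogram"))
  if (hist$n_trials <= 0) stop("empty histogram")
  sum(hist$counts[abs(hist$offsets) <= hist$tolerance_a]) / hist$n_trials
}

#' Chi-squared eligibility test against chance performance
#'
#' Pearson chi-squared goodness-of-fit of the observed correct/incorrect
#' split against chance (25% correct), one degree of freedom. A subject is
#' eligible for the precision analysis only when performance exceeds chance
#' significantly *and* in the right direction.
#'
#' @param n_correct number of responses within the correct-response region.
#' @param n_trials total responses.
#' @param chance chance rate of correct responding (default 0.25).
#' @param alpha significance level (default 0.05).
#' @return list with `eligible` (logical), `p_value`, `statistic`,
#'   `rate` (observed rate of correct responding).
#' @export
#' @examples
#' eligibility_chi2(50, 100)$eligible  # TRUE
#' eligibility_chi2(25, 100)$eligible  # FALSE (exactly at chance)
eligibility_chi2 <- function(n_correct, n_trials, chance = 0.25, alpha = 0.05) {
  if (n_trials <= 0) stop("n_trials must be > 0")
  if (n_correct < 0 || n_correct > n_trials) stop("invalid n_correct")
  expected <- n_trials * c(chance, 1 - chance)
  if (any(expected < 1)) warning("expected count below 1; test unreliable")
  tst <- suppressWarnings(
    stats::chisq.test(c(n_correct, n_trials - n_correct), p = c(chance, 1 - chance))
  )
  rate <- n_correct / n_trials
  list(eligible = unname(tst$p.value < alpha && rate > chance),
       p_value = unname(tst$p.value),
       statistic = unname(tst$statistic),
       rate = rate)
}

#' Fit the guessing/precision mixture model to an error histogram
#'
#' Decomposes a 20-bin response-error histogram into a uniform guessing
#' component and a concentrated true-memory distribution supported within
#' +/-2 positions of the target, and summarizes it by the guess rate, the
#' precision (SD of the true-memory distribution) and the rate of correct
#' responding.
#'
#' @param x a [response_histogram()], a vector of signed offsets, or a data
#'   frame with columns `target_pos` and `response_pos`.
#' @param min_trials minimum trial count required to fit (default 5).
#' @param ... passed to [response_histogram()] when `x` is not already one.
#' @return an object of class `wm_mixture` with components `p_hat`, `d_hat`,
#'   `precision_sd`, `precision_deg`, `rate_correct`, `eligibility`, `hist`.
#'   Supports `print()`, `summary()`, `coef()`, `fitted()`, `residuals()` and
#'   `simulate()`.
#' @export
#' @examples
#' trials <- gen_behavior(n_trials = 500, p_guess = 0.3, sd_positions = 1, seed = 1)
#' fit <- wm_mixture(trials)
#' coef(fit)
wm_mixture <- function(x, min_trials = 5L, ...) {
  if (is.data.frame(x)) {
    if (!all(c("target_pos", "response_pos") %in% names(x))) {
      stop("data frame must have columns target_pos and response_pos")
    }
    x <- position_offsets(x$target_pos, x$response_pos, ...)
  }
  h <- if (inherits(x, "response_histogram")) x else response_histogram(x, ...)
  if (h$n_trials < min_trials) {
    stop("fewer than ", min_trials, " trials; refusing to fit")
  }
  p_hat <- suppressWarnings(estimate_guess_rate(h))
  pure_guess <- p_hat >= 1 - 1e-8
  d_hat <- if (pure_guess) NULL else estimate_true_distribution(h, p_hat)
  rc <- rate_correct(h)
  n_corr <- sum(h$counts[abs(h$offsets) <= h$tolerance_a])
  fit <- list(
    p_hat = p_hat,
    d_hat = d_hat,
    precision_sd = if (pure_guess) NA_real_ else mixture_precision(d_hat),
    precision_deg = if (pure_guess) NA_real_ else mixture_precision(d_hat, degrees = TRUE),
    rate_correct = rc,
    eligibility = eligibility_chi2(n_corr, h$n_trials),
    hist = h
  )
  class(fit) <- "wm_mixture"
  fit
}

#' @export
print.wm_mixture <- function(x, ...) {
  cat("Guessing/precision mixture fit\n")
  cat(sprintf("  trials: %d   guess rate p_hat: %.3f\n", x$hist$n_trials, x$p_hat))
  if (is.null(x$d_hat)) {
    cat("  pure guessing: precision undefined\n")
  } else {
    cat(sprintf("  precision (SD): %.3f positions (%.1f deg)\n",
                x$precision_sd, x$precision_deg))
  }
  cat(sprintf("  rate correct (+/-2 positions): %.3f (chance 0.25); eligible: %s\n",
              x$rate_correct, x$eligibility$eligible))
  invisible(x)
}

#' @export
summary.wm_mixture <- function(object, ...) {
  print(object)
  if (!is.null(object$d_hat)) {
    cat("  true-memory distribution d_hat:\n")
    print(round(object$d_hat, 4))
  }
  cat(sprintf("  eligibility chi^2 = %.2f, p = %.3g\n",
              object$eligibility$statistic, object$eligibility$p_value))
  invisible(object)
}

#' @export
coef.wm_mixture <- function(object, ...) {
  c(guess_rate = object$p_hat, precision_sd = object$precision_sd,
    rate_correct = object$rate_correct)
}

#' @export
fitted.wm_mixture <- function(object, ...) {
  h <- object$hist
  D <- rep(object$p_hat / h$n_positions, h$n_positions)
  names(D) <- h$offsets
  if (!is.null(object$d_hat)) {
    D[names(object$d_hat)] <- D[names(object$d_hat)] +
      (1 - object$p_hat) * object$d_hat
  }
  D
}

#' @export
residuals.wm_mixture <- function(object, ...) {
  object$hist$counts / object$hist$n_trials - fitted(object)
}

#' @export
simulate.wm_mixture <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  D <- fitted(object)
  offs <- as.integer(names(D))
  replicate(nsim, {
    response_histogram(sample(offs, object$hist$n_trials, replace = TRUE, prob = D),
                       n_positions = object$hist$n_positions,
                       tolerance_a = object$hist$tolerance_a)
  }, simplify = FALSE)
}
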