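test_that("guess-rate estimator hits its analytic limits", {
  uniform <- response_histogram(counts = rep(5, 20))
  expect_equal(estimate_guess_rate(uniform), 1)
  inside <- response_histogram(c(rep(0, 40), rep(1, 5), rep(-2, 5)))
  expect_equal(estimate_guess_rate(inside), 0)
  # half uniform guessing, half exact responses
  mix <- model_family_hist(0.5, c(0, 0, 1, 0, 0))
  expect_equal(estimate_guess_rate(mix), 0.5)
  expect_error(estimate_guess_rate(response_histogram(counts = rep(0, 20))),
               "empty")
})

test_that("finite-sample estimates above 1 are clamped with a warning", {
  # all mass far outside the correct-response region
  h <- response_histogram(rep(c(-9, 8, 9), each = 10))
  expect_warning(p <- estimate_guess_rate(h), "clamped")
  expect_equal(p, 1)
})

test_that("true-distribution estimate removes the guessing floor", {
  # identity case: point mass, no guessing
  h0 <- response_histogram(rep(0, 50))
  d0 <- estimate_true_distribution(h0, p_hat = 0)
  expect_equal(unname(d0[as.character(0)]), 1)
  # worked mixture: inside bins collapse to the point mass
  mix <- model_family_hist(0.5, c(0, 0, 1, 0, 0))
  d <- estimate_true_distribution(mix, p_hat = 0.5)
  expect_equal(unname(d), c(0, 0, 1, 0, 0))
  # contract: simplex over -a..a for arbitrary valid input
  set.seed(2)
  for (i in 1:20) {
    h <- response_histogram(sample(-10:9, 200, replace = TRUE,
                                   prob = runif(20) + 0.2))
    ph <- suppressWarnings(estimate_guess_rate(h))
    if (ph >= 1 - 1e-8) next
    dh <- estimate_true_distribution(h, ph)
    expect_equal(sum(dh), 1)
    expect_true(all(dh >= 0))
    expect_identical(names(dh), as.character(-2:2))
  }
  expect_error(estimate_true_distribution(h0, p_hat = 1), "pure guessing")
})

test_that("mixture recovery is exact on noiseless model-family histograms", {
  set.seed(3)
  for (p in c(0, 0.2, 0.5, 0.8, 0.99)) {
    d <- runif(5); d <- d / sum(d)
    h <- model_family_hist(p, d)
    expect_equal(estimate_guess_rate(h), p, tolerance = 1e-12)
    expect_equal(unname(estimate_true_distribution(h, p)), d, tolerance = 1e-10)
    # analytic identity for the rate of correct responding
    expect_equal(rate_correct(h), p * 0.25 + (1 - p), tolerance = 1e-12)
  }
})

test_that("precision is the SD of the true-memory distribution", {
  expect_equal(mixture_precision(c(`0` = 1)), 0)
  d <- c(`-1` = 0.25, `0` = 0.5, `1` = 0.25)
  expect_equal(mixture_precision(d), sqrt(0.5))
  expect_equal(mixture_precision(d, degrees = TRUE), sqrt(0.5) * 18)
  # asymmetric distribution: SD about the mean, not about zero
  d2 <- c(`-2` = 0, `-1` = 0, `0` = 0.5, `1` = 0.5, `2` = 0)
  expect_equal(mixture_precision(d2), 0.5)
})

test_that("rate of correct responding matches its chance and degenerate values", {
  expect_equal(rate_correct(response_histogram(counts = rep(1, 20))), 0.25)
  expect_equal(rate_correct(response_histogram(rep(0, 10))), 1)
  expect_equal(rate_correct(model_family_hist(0.5, c(0, 0, 1, 0, 0))), 0.625)
})

test_that("chi-squared eligibility requires above-chance performance", {
  at_chance <- eligibility_chi2(25, 100)
  expect_false(at_chance$eligible)
  expect_equal(at_chance$statistic, 0)
  good <- eligibility_chi2(50, 100)
  expect_true(good$eligible)
  expect_equal(good$statistic, 25^2 / 25 + 25^2 / 75, tolerance = 1e-9)
  expect_lt(good$p_value, 0.001)
  # significantly below chance must not count as eligible
  below <- eligibility_chi2(10, 100)
  expect_false(below$eligible)
  expect_lt(below$p_value, 0.05)
  expect_warning(eligibility_chi2(1, 3), "unreliable")
})

test_that("wm_mixture fits, its methods are coherent, and small cells are refused", {
  trials <- gen_behavior(2000, p_guess = 0.4, sd_positions = 1, seed = 9)
  fit <- wm_mixture(trials)
  expect_s3_class(fit, "wm_mixture")
  expect_equal(unname(coef(fit)["guess_rate"]), 0.4, tolerance = 0.07)
  expect_equal(sum(fitted(fit)), 1, tolerance = 1e-12)
  expect_equal(sum(residuals(fit)), 0, tolerance = 1e-12)
  expect_output(print(fit), "guess rate")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(sims[[1]]$n_trials, fit$hist$n_trials)
  expect_error(wm_mixture(c(0, 1, 0)), "fewer than 5")
})

test_that("parameter recovery holds across the guess-rate and precision grid", {
  # mean absolute error of p_hat below 0.03 at n = 2000 over the design grid
  set.seed(11)
  for (p in c(0.2, 0.5, 0.8)) {
    for (s in c(0.5, 1.0)) {
      err <- replicate(25, {
        tr <- gen_behavior(2000, p_guess = p, sd_positions = s,
                           seed = sample.int(1e6, 1))
        abs(wm_mixture(tr)$p_hat - p)
      })
      expect_lt(mean(err), 0.03)
      # precision estimate tracks the SD of the generating distribution
      dd <- offset_distribution(s)
      true_sd <- mixture_precision(dd)
      tr <- gen_behavior(5000, p_guess = p, sd_positions = s, seed = 101)
      expect_lt(abs(wm_mixture(tr)$precision_sd - true_sd), 0.1)
    }
  }
})
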