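test_that("epoch container validates shapes and wraps labels", {
  dat <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  ep <- epoch_set(dat, times = c(0.1, 0.2, 0.3, 0.4), angles = c(0, 7, -7, 1, 2))
  expect_true(all(ep$angles >= -pi & ep$angles < pi))
  expect_error(epoch_set(dat, times = 1:3), "times")
  expect_error(epoch_set(dat, times = c(1, 1, 2, 3)), "increasing")
  expect_error(epoch_set(dat, times = 1:4, angles = 1:3), "angles")
  expect_error(epoch_set(matrix(0, 2, 2), times = 1:2), "array")
})

test_that("a pure sine signal has circular-linear correlation 1", {
  set.seed(4)
  th <- runif(60, -pi, pi)
  expect_equal(circ_linear_r(sin(th), th), 1, tolerance = 1e-9)
  expect_equal(circ_linear_r(3 * cos(th) - 2, th), 1, tolerance = 1e-9)
})

test_that("the statistic equals the two-regressor multiple-correlation oracle", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(8:20, 1)
    th <- runif(n, -pi, pi)
    x <- rnorm(n) + rnorm(1) * sin(th) + rnorm(1) * cos(th)
    oracle <- sqrt(summary(stats::lm(x ~ sin(th) + cos(th)))$r.squared)
    expect_equal(circ_linear_r(x, th), oracle, tolerance = 1e-10)
  }
})

test_that("the statistic is invariant to affine signal transforms and angle rotations", {
  set.seed(6)
  th <- runif(40, -pi, pi)
  x <- rnorm(40) + sin(th)
  r0 <- circ_linear_r(x, th)
  expect_equal(circ_linear_r(5 * x - 7, th), r0, tolerance = 1e-12)
  expect_equal(circ_linear_r(x, wrap_angle(th + 1.1)), r0, tolerance = 1e-9)
  # degenerate inputs are flagged as undefined
  expect_true(is.na(circ_linear_r(rep(1, 40), th)))
  expect_error(circ_linear_r(x[1:2], th[1:2]), "3 trials")
})

test_that("forcing the identity permutation makes the null equal the map", {
  set.seed(7)
  ep <- gen_epochs(n_trials = 40, n_channels = 6,
                   times = seq(-0.1, 0.3, by = 0.05), seed = 7)
  nm <- permutation_null(ep, perms = matrix(1:40, 1, 40))
  cm <- circ_map(ep, n_perm = 3, seed = 1)
  expect_equal(nm, cm$rho, tolerance = 1e-12)
})

test_that("delta_rho localizes a planted angle code and is centered on noise", {
  ep <- gen_epochs(n_trials = 150, n_channels = 12,
                   times = seq(-0.2, 0.9, by = 0.02),
                   category_amp = 0, angle_amp = 1.2,
                   angle_windows = list(c(0.12, 0.5)),
                   angle_channels = 1:4, seed = 8)
  cm <- circ_map(ep, n_perm = 200, seed = 9)
  on <- ep$times >= 0.14 & ep$times <= 0.48
  planted <- cm$delta_rho[1:4, on]
  null_cells <- cm$delta_rho[5:12, !on]
  q95 <- quantile(cm$delta_rho[, ep$times < 0.1], 0.95)
  expect_gt(mean(planted > q95), 0.9)
  expect_lt(abs(mean(null_cells)), 0.05)
  # rho itself is a valid correlation everywhere
  expect_true(all(cm$rho >= 0 & cm$rho <= 1))
})

test_that("window averages reproduce constants and respect window bounds", {
  times <- seq(-0.2, 2.6, by = 0.01)
  map <- matrix(0.3, 4, length(times))
  wa <- window_average(map, times = times)
  expect_equal(dim(wa), c(4L, 4L))
  expect_identical(colnames(wa), c("early", "p3b", "delay1", "delay2"))
  expect_true(all(abs(wa - 0.3) < 1e-12))
  expect_equal(unname(attr(wa, "grand")), rep(0.3, 4))
  # a window covering exactly one sample returns that sample
  map[, which(times == 1)] <- 9
  one <- window_average(map, windows = list(w = c(1, 1)), times = times)
  expect_true(all(one[, "w"] == 9))
  expect_error(window_average(map, windows = list(w = c(90, 91)), times = times),
               "empty window")
})

test_that("the default analysis windows carry the a-priori bounds", {
  w <- default_windows()
  expect_equal(w$early, c(0.1, 0.3))
  expect_equal(w$p3b, c(0.3, 0.6))
  expect_equal(w$delay1, c(0.6, 1.55))
  expect_equal(w$delay2, c(1.55, 2.53))
})
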