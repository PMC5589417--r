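test_that("gain is the smoothed threshold-linear function with stable limits", {
  expect_equal(gain(0, 1.5), 1.5 * log(2), tolerance = 1e-12)
  expect_equal(gain(1e6, 1.5), 1e6, tolerance = 1e-9)
  expect_equal(gain(-1e6, 1.5), 0)
  h <- seq(-10, 10, by = 0.1)
  r <- gain(h)
  expect_true(all(r >= 0))
  expect_true(all(diff(r) >= 0))
  expect_error(gain(NaN), "non-finite")
  expect_error(gain(Inf), "non-finite")
  expect_error(gain(0, alpha = 0), "alpha")
})

test_that("connectivity kernel matches the truncated cosine with uniform tail", {
  p <- cann_params()
  expect_equal(connectivity_kernel(0, 0, p), 11)          # J1 - J0
  expect_equal(connectivity_kernel(0, pi / 2.2, p), -1)   # beyond cutoff -> -J0
  # cutoff angle: B * d = acos(-J0/J1)
  d_cut <- acos(-1 / 12) / 2.2
  expect_equal(connectivity_kernel(0, d_cut - 1e-9, p),
               12 * cos(2.2 * (d_cut - 1e-9)) - 1, tolerance = 1e-9)
  expect_equal(connectivity_kernel(0, d_cut + 1e-6, p), -1)
  # symmetry and translation invariance on random pairs
  set.seed(1)
  a <- runif(20, -pi, pi); b <- runif(20, -pi, pi); s <- runif(20, -pi, pi)
  expect_equal(connectivity_kernel(a, b, p), connectivity_kernel(b, a, p))
  expect_equal(connectivity_kernel(wrap_angle(a + s), wrap_angle(b + s), p),
               connectivity_kernel(a, b, p), tolerance = 1e-12)
  bad <- cann_params()
  bad$J0 <- 20
  expect_error(connectivity_kernel(0, 0, bad), "J0/J1")
})

test_that("parameter validation rejects unstable or inconsistent settings", {
  expect_error(cann_params(n_neurons = 2), "n_neurons")
  expect_error(cann_params(dt = 0.01), "dt")
  expect_error(cann_params(U = 0), "U")
  expect_error(cann_params(J0 = 13), "J1 > J0")
  expect_error(cann_params(tau_f = -1), "tau_f")
})

test_that("baseline state is a fixed point of the STP dynamics", {
  # with u = U, x = 1 and silent firing, du = dx = 0
  p <- cann_params(I_b = -50)  # deeply subthreshold: gain(I_b) ~ 0
  st <- cann_state(p)
  st$h_E[] <- p$I_b
  st$h_I[] <- p$I_b  # inhibitory pool subthreshold as well
  J <- connectivity_matrix(p)
  st2 <- cann_step(st, numeric(p$n_neurons), p, J = J)
  expect_equal(st2$u, st$u, tolerance = 1e-12)
  expect_equal(st2$x, st$x, tolerance = 1e-12)
  # h_E stationary at I_b when the recurrent drive is negligible
  expect_lt(max(abs(st2$h_E - p$I_b)), 1e-10)
})

test_that("the integrator reports the diverging component", {
  p <- cann_params()
  st <- cann_state(p)
  st$h_E[] <- 1e308
  expect_error(cann_step(st, rep(1e308, p$n_neurons), p), "h_E")
})

test_that("run_network is deterministic given a seed and rejects short schedules", {
  p <- cann_params()
  sch <- short_schedule(target_angle = 0.5)
  t1 <- run_network(sch, p, seed = 11, noise_mode = "continuous")
  t2 <- run_network(sch, p, seed = 11, noise_mode = "continuous")
  expect_identical(t1$rates, t2$rates)
  t3 <- run_network(sch, p, seed = 12, noise_mode = "continuous")
  expect_false(identical(t1$rates, t3$rates))
  bad <- sch
  bad$t_end <- bad$recall_on
  expect_error(run_network(bad, p), "recall")
})

test_that("a zero-amplitude schedule stays at the resting rate", {
  p <- cann_params()
  sch <- build_schedule(A_target = 0, A_mask = 1e-9, A_recall = 0, delay = 0.3)
  tr <- run_network(sch, p, noise_mode = "none")
  # resting activity is below the no-drive baseline gain(I_b) (inhibition
  # pulls it slightly lower)
  expect_lt(max(tr$rates), gain(p$I_b, p$alpha) + 0.1)
})

test_that("a target-only schedule leaves a persistent reactivating memory", {
  p <- cann_params()
  th0 <- position_angles(20)[4]
  sch <- build_schedule(target_angle = th0, A_mask = 1e-9, delay = 1.2)
  tr <- cached("target_only_trace", run_network(sch, p, noise_mode = "none"))
  pv <- population_vector_readout(tr, window = c(sch$recall_on, sch$recall_off))
  expect_true(pv$valid)
  expect_lt(abs(wrap_angle(pv$angle - th0)), p$dtheta)
})

test_that("the raster is translation-equivariant under grid shifts of the target", {
  p <- cann_params()
  k <- 10L  # shift by 10 neuron spacings
  sch1 <- short_schedule(target_angle = p$theta[20], A_mask = 30)
  sch2 <- short_schedule(target_angle = p$theta[20 + k], A_mask = 30)
  tr1 <- run_network(sch1, p, noise_mode = "none")
  tr2 <- run_network(sch2, p, noise_mode = "none")
  shifted <- tr1$rates[, c((p$n_neurons - k + 1):p$n_neurons, 1:(p$n_neurons - k))]
  expect_equal(tr2$rates, shifted, tolerance = 1e-8)
})

test_that("STP variables stay within their theoretical bounds on noisy trials", {
  p <- cann_params()
  sch <- short_schedule(A_mask = 62)
  ex <- run_experiment(6, p, sch, seed = 3)
  eps <- 1e-6
  expect_gte(ex$stp_range$u[1], p$U - eps)
  expect_lte(ex$stp_range$u[2], 1 + eps)
  expect_gte(ex$stp_range$x[1], -eps)
  expect_lte(ex$stp_range$x[2], 1 + eps)
})

test_that("with frozen STP the post-mask delay is stationary: no reactivation", {
  p <- cann_params()
  sch <- build_schedule(A_mask = 50, delay = 1.5)  # reactivating with STP on
  tr_stp <- run_network(sch, p, noise_mode = "none")
  tr_frz <- run_network(sch, p, noise_mode = "none", freeze_stp = TRUE)
  thr <- reactivation_threshold(p, sch)
  expect_identical(classify_regime(tr_stp, thr), "reactivating")
  expect_identical(classify_regime(tr_frz, thr), "silent")
  # and the frozen delay trace is flat: memory was carried only by u, x
  sel <- tr_frz$times >= sch$mask_off + 0.1 & tr_frz$times < sch$recall_on
  delay_rates <- tr_frz$rates[sel, ]
  expect_lt(max(delay_rates) - min(delay_rates), 0.5)
})
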