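test_that("stratified folds partition trials and preserve class balance", {
  y <- rep(c("a", "b"), c(60, 40))
  folds <- make_folds(y, 5, seed = 1)
  idx <- sort(unname(unlist(folds)))
  expect_identical(idx, 1:100)
  for (f in folds) {
    expect_equal(sum(y[f] == "a"), 12)
    expect_equal(sum(y[f] == "b"), 8)
  }
  expect_error(make_folds(rep(c("a", "b"), c(98, 2)), 5,
                          require_all_classes = TRUE), "misses a class")
  expect_error(make_folds(y, 1), "k must be")
})

test_that("ANOVA selection keeps planted informative features and drops constants", {
  expect_error(anova_select(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5), 0),
               "fraction")
  set.seed(12)
  X <- matrix(rnorm(200 * 10), 200, 10)
  y <- rep(c("a", "b"), each = 100)
  hits <- replicate(50, {
    Xi <- matrix(rnorm(200 * 10), 200, 10)
    Xi[y == "b", 1:5] <- Xi[y == "b", 1:5] + 1
    all(which(anova_select(Xi, y, 0.5))[1:5] == 1:5)
  })
  expect_gte(mean(hits), 0.95)
  # fraction = 1 keeps everything
  expect_true(all(anova_select(X, y, 1)))
  # a constant feature ranks last
  X[, 3] <- 7
  mask <- anova_select(X, y, 0.9)
  expect_false(mask[3])
})

test_that("AUC matches brute-force pair counting and is monotone-invariant", {
  expect_equal(score_auc(c(-2, -1, 1, 2), c("n", "n", "p", "p"), "p"), 1)
  set.seed(13)
  for (i in 1:25) {
    n <- sample(6:14, 1)
    y <- factor(c("n", "p", sample(c("n", "p"), n - 2, replace = TRUE)))
    s <- sample(seq(-2, 2, by = 0.5), n, replace = TRUE)  # forces ties
    expect_equal(score_auc(s, y, "p"), pairwise_auc(s, y, "p"))
    expect_equal(score_auc(exp(s), y, "p"), score_auc(s, y, "p"))
  }
  expect_error(score_auc(1:3, c("p", "p", "p"), "p"), "both classes")
})

test_that("the linear classifier separates separable classes and weights imbalance", {
  set.seed(14)
  X <- matrix(rnorm(80), 40, 2)
  y <- factor(rep(c("a", "b"), each = 20))
  X[y == "b", 1] <- X[y == "b", 1] + 10
  dec <- fit_categorical(X, y)
  sgn <- if (dec$positive == "b") 1 else -1
  dv <- sgn * (drop(X %*% dec$w) + dec$b)
  expect_equal(score_auc(dv, y, "b"), 1)
  expect_error(fit_categorical(X, factor(rep("a", 40))), "2 classes")
})

test_that("the angle decoder inverts a noiseless sin/cos code and fails gracefully", {
  th <- position_angles(20)[sample(1:20, 80, replace = TRUE)]
  F <- cbind(sin(th), cos(th))
  fa <- fit_angle(F, th)
  expect_lt(max(abs(wrap_angle(fa$predict_angle(F) - th))), 1e-6)
  expect_error(fit_angle(F, rep(1, 80)), "distinct angles")
})

test_that("angular accuracy has the stated range, chance level and invariances", {
  th <- runif(500, -pi, pi)
  expect_equal(angular_accuracy(th, th), pi / 2)
  expect_equal(angular_accuracy(th + pi, th), -pi / 2, tolerance = 1e-9)
  set.seed(15)
  pred <- runif(5000, -pi, pi)
  true <- runif(5000, -pi, pi)
  expect_lt(abs(angular_accuracy(pred, true)), 0.05)
  rot <- 0.7
  expect_equal(angular_accuracy(pred + rot, true + rot),
               angular_accuracy(pred, true), tolerance = 1e-9)
  expect_error(angular_accuracy(1:3, 1:4), "length")
})

test_that("temporal generalization: diagonal consistency and sustained-code blocks", {
  ep <- gen_epochs(n_trials = 100, n_channels = 16,
                   times = seq(-0.1, 0.5, by = 0.05),
                   category_amp = 1.5, category_window = c(0.1, 0.5),
                   angle_amp = 0, seed = 16)
  tg <- temporal_generalization(ep, metric = "auc", seed = 17)
  tg_d <- temporal_generalization(ep, metric = "auc", seed = 17, diag_only = TRUE)
  expect_equal(tg_d$diagonal, diag(tg$scores), tolerance = 1e-12)
  on <- ep$times >= 0.15
  expect_gt(mean(tg$scores[on, on]), 0.85)        # square block over the window
  expect_lt(mean(tg$scores[!on, !on]), 0.65)      # chance-ish before onset
})

test_that("a sequential code generalizes only near the diagonal", {
  # plant a code whose topography flips halfway through the window
  set.seed(18)
  times <- seq(0, 0.7, by = 0.1)
  K <- 120; C <- 10
  dat <- array(rnorm(K * C * length(times)), c(K, C, length(times)))
  y <- factor(rep(c("a", "b"), each = K / 2))
  topo1 <- c(rep(2, 5), rep(0, 5))
  topo2 <- -topo1  # the code reverses halfway through
  for (t in seq_along(times)) {
    topo <- if (times[t] < 0.35) topo1 else topo2
    dat[y == "b", , t] <- sweep(dat[y == "b", , t], 2, -topo)
  }
  ep <- epoch_set(dat, times, categories = y)
  tg <- temporal_generalization(ep, metric = "auc", seed = 19)
  first <- times < 0.35
  within1 <- mean(tg$scores[first, first])
  within2 <- mean(tg$scores[!first, !first])
  across <- mean(c(tg$scores[first, !first], tg$scores[!first, first]))
  expect_gt(within1, 0.9)
  expect_gt(within2, 0.9)
  expect_lt(across, 0.25)  # anti-generalization: the code reversed
})

test_that("cross-condition generalization transfers a shared code and stays at chance otherwise", {
  times <- seq(0, 0.4, by = 0.1)
  ep_a <- gen_epochs(n_trials = 90, n_channels = 12, times = times,
                     category_amp = 2, category_window = c(0.1, 0.4),
                     angle_amp = 0, seed = 101)
  # second condition: fresh noise and trials, but the same planted topography
  gt <- attr(ep_a, "ground_truth")
  set.seed(21)
  K <- 90
  dat_b <- array(rnorm(K * 12 * length(times)), c(K, 12, length(times)))
  y_b <- factor(sample(c("seen", "unseen"), K, replace = TRUE),
                levels = c("seen", "unseen"))
  for (t in which(times >= 0.1)) {
    dat_b[y_b == "unseen", , t] <- sweep(dat_b[y_b == "unseen", , t], 2,
                                         -gt$category_amp * gt$category_topography)
  }
  ep_b <- epoch_set(dat_b, times, categories = y_b)
  cg <- cross_generalize(ep_a, ep_a$categories, ep_b, ep_b$categories,
                         metric = "auc", seed = 22)
  on <- times >= 0.15
  expect_gt(mean(cg$scores[on, on]), 0.9)
  # shuffled test labels: chance
  cg0 <- cross_generalize(ep_a, ep_a$categories, ep_b,
                          sample(ep_b$categories), metric = "auc", seed = 23)
  expect_lt(abs(mean(cg0$scores) - 0.5), 0.06)
})

test_that("angular temporal generalization recovers a planted circular code", {
  ep <- gen_epochs(n_trials = 120, n_channels = 12,
                   times = seq(0, 0.4, by = 0.1),
                   category_amp = 0, angle_amp = 1.5,
                   angle_windows = list(c(0.1, 0.4)),
                   angle_channels = 1:6, seed = 24)
  tg <- temporal_generalization(ep, metric = "angular", seed = 25)
  expect_equal(tg$k, 2L)
  on <- ep$times >= 0.15
  expect_gt(mean(tg$scores[on, on]), 0.8)
  expect_lt(abs(mean(tg$scores[!on, !on])), 0.3)
})
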