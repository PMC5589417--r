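#' Stratified cross-validation fold plan
#'
#' Assigns each trial to exactly one test fold, preserving class proportions
#' per fold. Circular labels are stratified over their discrete values (the
#' 20 task positions).
#'
#' @param labels per-trial labels (factor, character, or discrete angles).
#' @param k number of folds (5 for categorical and 2 for circular labels in
#'   the standard pipeline).
#' @param seed integer seed for the shuffle.
#' @param require_all_classes error if some fold misses a class (used for
#'   categorical decoding).
#' @return list of `k` integer vectors of test-trial indices, with attribute
#'   `"fold_of"` (fold id per trial).
#' @export
make_folds <- function(labels, k, seed = 1L, require_all_classes = FALSE) {
  g <- factor(labels)
  n <- length(g)
  if (k < 2 || k > n) stop("k must be between 2 and the trial count")
  set.seed(seed)
  fold_of <- integer(n)
  for (lev in levels(g)) {
    idx <- sample(which(g == lev))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds <- split(seq_len(n), fold_of)
  if (require_all_classes) {
    for (f in folds) {
      if (nlevels(droplevels(g[-f])) < nlevels(g) ||
          nlevels(droplevels(g[f])) < nlevels(g)) {
        stop("a fold misses a class: too few trials per class for k = ", k)
      }
    }
  }
  attr(folds, "fold_of") <- fold_of
  folds
}

# Vectorized one-way ANOVA F statistic per column of X. Constant or otherwise
# degenerate features get -Inf so they rank last.
feature_f_stat <- function(X, labels) {
  g <- factor(labels)
  n <- nrow(X)
  kk <- nlevels(g)
  if (kk < 2) stop("need at least 2 label groups")
  ng <- as.vector(table(g))
  gm <- colMeans(X)
  G <- rowsum(X, g) / ng
  ssb <- colSums(ng * sweep(G, 2, gm)^2)
  sst <- colSums(sweep(X, 2, gm)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (kk - 1)) / (ssw / (n - kk))
  f[ssw == 0 & ssb == 0] <- -Inf
  f
}

#' Univariate ANOVA feature selection
#'
#' Keeps the top fraction of features (channels) ranked by their one-way
#' ANOVA F statistic against the labels, computed on training data only.
#' Ties are broken by feature index (stable); features with undefined F
#' (e.g. constant channels) rank last.
#'
#' @param train_features `trials x features` training matrix.
#' @param labels training labels (categorical, or discrete angles).
#' @param fraction fraction of features to keep, in `(0, 1]` (default 0.5).
#' @return logical mask over features.
#' @export
anova_select <- function(train_features, labels, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  f <- feature_f_stat(train_features, labels)
  p <- length(f)
  n_keep <- max(1L, floor(fraction * p + 1e-9))
  ord <- order(f, seq_len(p), decreasing = c(TRUE, FALSE), method = "radix")
  mask <- logical(p)
  mask[ord[seq_len(n_keep)]] <- TRUE
  mask
}

# Per-feature z-scoring parameters from training data; zero SDs become 1.
zscore_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

zscore_apply <- function(X, z) {
  sweep(sweep(X, 2, z$mu), 2, z$sd, "/")
}

#' Linear max-margin classifier with class weighting
#'
#' Fits a linear support vector machine (via \pkg{e1071}) with inverse-
#' class-frequency weights and returns the separating hyperplane in primal
#' form, so that decision values for new data are a single matrix product.
#' Larger decision values favor the `positive` class.
#'
#' @param train `trials x features` matrix (already z-scored).
#' @param labels two-class factor.
#' @param cost margin cost parameter (default 1, fixed for determinism).
#' @return list with `w`, `b`, `positive` (the class assigned to large
#'   decision values) and the fitted \pkg{e1071} model.
#' @export
fit_categorical <- function(train, labels, cost = 1) {
  y <- factor(labels)
  y <- droplevels(y)
  if (nlevels(y) != 2) stop("need exactly 2 classes in the training fold")
  tab <- table(y)
  cw <- as.numeric(sum(tab) / (2 * tab))
  names(cw) <- names(tab)
  m <- e1071::svm(train, y, kernel = "linear", cost = cost, scale = FALSE,
                  class.weights = cw)
  w <- drop(crossprod(m$coefs, m$SV))
  b <- -m$rho
  # e1071 names its decision-value column "pos/neg": values > 0 vote "pos"
  dv <- attr(stats::predict(m, train[1:2, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  lv <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  lin <- drop(train[1:2, , drop = FALSE] %*% w) + b
  if (max(abs(lin - dv[, 1])) > 1e-6 * max(1, max(abs(dv)))) {
    w <- -w; b <- -b
    lin <- -lin
    if (max(abs(lin - dv[, 1])) > 1e-4 * max(1, max(abs(dv)))) {
      stop("internal error: primal form disagrees with the fitted classifier")
    }
  }
  list(w = w, b = b, positive = lv[1], model = m)
}

#' Area under the ROC curve of decision values
#'
#' Rank-based AUC (equivalent to the Wilcoxon statistic) with midrank tie
#' handling; invariant to monotone transforms of the scores.
#'
#' @param scores continuous decision values (larger favors `positive`).
#' @param labels two-class labels.
#' @param positive the class treated as positive (default: second factor
#'   level).
#' @return AUC in `[0, 1]`; 0.5 is chance.
#' @export
#' @examples
#' score_auc(c(0.1, 0.9, 0.4, 0.8), c("a", "b", "a", "b"), positive = "b")
score_auc <- function(scores, labels, positive = NULL) {
  y <- factor(labels)
  if (length(scores) != length(y)) stop("length mismatch")
  if (is.null(positive)) positive <- levels(y)[2]
  if (!positive %in% levels(y)) stop("unknown positive class")
  pos <- y == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("need both classes to score an AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Linear angle decoder via paired sine/cosine regressions
#'
#' Two linear support-vector regressions (via \pkg{e1071}) predict the sine
#' and cosine of the angle labels; a predicted angle is reconstructed as
#' `atan2(sin_hat, cos_hat)`.
#'
#' @param train `trials x features` matrix (already z-scored).
#' @param theta_labels training angles in radians.
#' @param cost margin cost parameter (default 1).
#' @param epsilon epsilon of the insensitive loss (default 0.1).
#' @return list with primal weights `w_sin`, `b_sin`, `w_cos`, `b_cos` and a
#'   `predict_angle(newdata)` function.
#' @export
fit_angle <- function(train, theta_labels, cost = 1, epsilon = 0.1) {
  th <- wrap_angle(theta_labels)
  if (length(unique(round(th, 10))) < 2) stop("need at least 2 distinct angles")
  fit1 <- function(yv) {
    m <- e1071::svm(train, yv, type = "eps-regression", kernel = "linear",
                    cost = cost, epsilon = epsilon, scale = FALSE)
    w <- drop(crossprod(m$coefs, m$SV))
    # verify the primal form against the model's own predictions
    b <- -m$rho
    pr <- stats::predict(m, train[1:2, , drop = FALSE])
    lin <- drop(train[1:2, , drop = FALSE] %*% w) + b
    if (max(abs(lin - pr)) > 1e-6 * max(1, max(abs(pr)))) {
      stop("internal error: primal form disagrees with the fitted regression")
    }
    list(w = w, b = b)
  }
  fs <- fit1(sin(th))
  fc <- fit1(cos(th))
  out <- list(w_sin = fs$w, b_sin = fs$b, w_cos = fc$w, b_cos = fc$b)
  out$predict_angle <- function(newdata) {
    atan2(drop(newdata %*% out$w_sin) + out$b_sin,
          drop(newdata %*% out$w_cos) + out$b_cos)
  }
  out
}

#' Angular accuracy score
#'
#' Mean absolute wrapped difference between predicted and true angles
#' (range 0 to pi, chance pi/2), transformed to an accuracy score
#' `pi/2 - mean|error|` (range -pi/2 to pi/2, chance 0). Invariant to a
#' global rotation of both angle sets.
#'
#' @param pred_angles,true_angles angles in radians, equal length.
#' @return score in `[-pi/2, pi/2]`.
#' @export
angular_accuracy <- function(pred_angles, true_angles) {
  if (length(pred_angles) != length(true_angles)) stop("length mismatch")
  pi / 2 - mean(abs(wrap_angle(pred_angles - true_angles)))
}

# Decision values (categorical) or angle predictions (circular) of one fitted
# decoder applied to test trials at every test-time sample in one matrix
# product. test_data: trials x channels x time array already subset to trials.
.apply_decoder <- function(dec, test_data, mask, zs, metric) {
  dte <- dim(test_data)
  A <- matrix(aperm(test_data[, mask, , drop = FALSE], c(1, 3, 2)),
              dte[1] * dte[3], sum(mask))
  A <- zscore_apply(A, zs)
  if (metric == "auc") {
    matrix(drop(A %*% dec$w) + dec$b, dte[1], dte[3])
  } else {
    s <- drop(A %*% dec$w_sin) + dec$b_sin
    cc <- drop(A %*% dec$w_cos) + dec$b_cos
    matrix(atan2(s, cc), dte[1], dte[3])
  }
}

#' Temporal-generalization decoding
#'
#' Trains one decoder per time sample within a stratified cross-validation
#' loop and tests every decoder at every time sample. At each training time,
#' feature selection (top 50% of channels by ANOVA F), z-scoring and class
#' weighting are fitted strictly on the training fold. Categorical labels use
#' a linear max-margin classifier scored by AUC (per fold, then averaged);
#' circular labels use paired sine/cosine regressions whose predictions are
#' pooled across folds and scored by [angular_accuracy()].
#'
#' @param epochs an [epoch_set()].
#' @param labels per-trial labels; defaults to `epochs$categories` for
#'   `metric = "auc"` and `epochs$angles` for `metric = "angular"`.
#' @param metric `"auc"` or `"angular"`.
#' @param k folds (default 5 categorical, 2 circular).
#' @param fraction feature fraction kept by ANOVA selection (default 0.5).
#' @param cost decoder cost parameter (default 1, fixed).
#' @param seed integer seed for the fold split.
#' @param diag_only compute only the matrix diagonal (train time = test
#'   time).
#' @param baseline_correct subtract, per training time, the mean score over
#'   test times in the epoch baseline window (used for circular scores).
#' @return an object of class `tg_matrix` with `scores`
#'   (train time x test time; a 1-column matrix when `diag_only`),
#'   `diagonal`, `times`, `metric`, `k`.
#' @export
temporal_generalization <- function(epochs, labels = NULL,
                                    metric = c("auc", "angular"),
                                    k = NULL, fraction = 0.5, cost = 1,
                                    seed = 1L, diag_only = FALSE,
                                    baseline_correct = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(labels)) {
    labels <- if (metric == "auc") epochs$categories else epochs$angles
  }
  if (is.null(labels)) stop("no labels available for metric '", metric, "'")
  if (is.null(k)) k <- if (metric == "auc") 5L else 2L
  X <- epochs$data
  K <- dim(X)[1]; TT <- dim(X)[3]
  strata <- if (metric == "angular") factor(round(wrap_angle(labels), 10)) else labels
  folds <- make_folds(strata, k, seed = seed,
                      require_all_classes = metric == "auc")

  if (metric == "auc") {
    y <- factor(labels)
    positive <- levels(y)[2]
    fold_scores <- array(NA_real_, c(k, TT, if (diag_only) 1L else TT))
  } else {
    th <- wrap_angle(labels)
    preds <- array(NA_real_, c(K, TT, if (diag_only) 1L else TT))
  }
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(K), te)
    for (t in seq_len(TT)) {
      Xtr <- X[tr, , t, drop = TRUE]
      mask <- anova_select(Xtr, strata[tr], fraction)
      zs <- zscore_fit(Xtr[, mask, drop = FALSE])
      Ztr <- zscore_apply(Xtr[, mask, drop = FALSE], zs)
      test_slice <- if (diag_only) {
        X[te, , t, drop = FALSE]
      } else {
        X[te, , , drop = FALSE]
      }
      if (metric == "auc") {
        dec <- fit_categorical(Ztr, y[tr], cost = cost)
        dv <- .apply_decoder(dec, test_slice, mask, zs, metric)
        sgn <- if (dec$positive == positive) 1 else -1
        fold_scores[f, t, ] <- apply(sgn * dv, 2, score_auc,
                                     labels = y[te], positive = positive)
      } else {
        dec <- fit_angle(Ztr, th[tr], cost = cost)
        preds[te, t, ] <- .apply_decoder(dec, test_slice, mask, zs, metric)
      }
    }
  }
  if (metric == "auc") {
    scores <- apply(fold_scores, c(2, 3), mean)
  } else {
    scores <- apply(preds, c(2, 3), function(p) angular_accuracy(p, th))
  }
  scores <- matrix(scores, TT, if (diag_only) 1L else TT)
  if (baseline_correct && !diag_only) {
    bsel <- epochs$times >= epochs$baseline_window[1] &
      epochs$times <= epochs$baseline_window[2]
    if (!any(bsel)) stop("baseline window contains no samples")
    scores <- scores - rowMeans(scores[, bsel, drop = FALSE])
  }
  out <- list(scores = scores,
              diagonal = if (diag_only) scores[, 1] else diag(scores),
              times = epochs$times, metric = metric, k = k,
              diag_only = diag_only)
  class(out) <- "tg_matrix"
  out
}

#' Cross-condition generalization
#'
#' Trains decoders on one epoch set (within the usual stratified fold loop)
#' and applies every fold's decoder directly to the entire second epoch set,
#' averaging the predictions across folds before scoring. Supports training
#' and testing on different label semantics (e.g. training on visibility and
#' testing on accuracy) as long as both are two-class factors sharing level
#' order, or both circular.
#'
#' @param train_epochs,test_epochs [epoch_set()] objects with equal channel
#'   counts.
#' @param train_labels,test_labels per-trial labels for each set.
#' @inheritParams temporal_generalization
#' @return a `tg_matrix` with `scores` of size
#'   `train times x test times`.
#' @export
cross_generalize <- function(train_epochs, train_labels, test_epochs,
                             test_labels, metric = c("auc", "angular"),
                             k = NULL, fraction = 0.5, cost = 1, seed = 1L) {
  metric <- match.arg(metric)
  if (dim(train_epochs$data)[2] != dim(test_epochs$data)[2]) {
    stop("feature (channel) dimension mismatch between epoch sets")
  }
  if (is.null(k)) k <- if (metric == "auc") 5L else 2L
  X <- train_epochs$data
  K <- dim(X)[1]; TT <- dim(X)[3]
  Tte <- dim(test_epochs$data)[3]
  Kte <- dim(test_epochs$data)[1]
  strata <- if (metric == "angular") {
    factor(round(wrap_angle(train_labels), 10))
  } else train_labels
  folds <- make_folds(strata, k, seed = seed,
                      require_all_classes = metric == "auc")
  if (metric == "auc") {
    y_tr <- factor(train_labels)
    y_te <- factor(test_labels)
    positive <- levels(y_te)[2]
    acc <- array(0, c(Kte, TT, Tte))
  } else {
    th_tr <- wrap_angle(train_labels)
    th_te <- wrap_angle(test_labels)
    acc_s <- array(0, c(Kte, TT, Tte))
    acc_c <- array(0, c(Kte, TT, Tte))
  }
  for (f in seq_along(folds)) {
    tr <- setdiff(seq_len(K), folds[[f]])
    for (t in seq_len(TT)) {
      Xtr <- X[tr, , t, drop = TRUE]
      mask <- anova_select(Xtr, strata[tr], fraction)
      zs <- zscore_fit(Xtr[, mask, drop = FALSE])
      Ztr <- zscore_apply(Xtr[, mask, drop = FALSE], zs)
      if (metric == "auc") {
        dec <- fit_categorical(Ztr, y_tr[tr], cost = cost)
        dv <- .apply_decoder(dec, test_epochs$data, mask, zs, metric)
        sgn <- if (dec$positive == levels(y_tr)[2]) 1 else -1
        acc[, t, ] <- acc[, t, ] + sgn * dv
      } else {
        dec <- fit_angle(Ztr, th_tr[tr], cost = cost)
        A <- matrix(aperm(test_epochs$data[, mask, , drop = FALSE], c(1, 3, 2)),
                    Kte * Tte, sum(mask))
        A <- zscore_apply(A, zs)
        acc_s[, t, ] <- acc_s[, t, ] +
          matrix(drop(A %*% dec$w_sin) + dec$b_sin, Kte, Tte)
        acc_c[, t, ] <- acc_c[, t, ] +
          matrix(drop(A %*% dec$w_cos) + dec$b_cos, Kte, Tte)
      }
    }
  }
  if (metric == "auc") {
    scores <- apply(acc / length(folds), c(2, 3), score_auc,
                    labels = y_te, positive = positive)
  } else {
    pred <- atan2(acc_s, acc_c)
    scores <- apply(pred, c(2, 3), angular_accuracy, true_angles = th_te)
  }
  out <- list(scores = matrix(scores, TT, Tte), diagonal = NULL,
              times = train_epochs$times, times_test = test_epochs$times,
              metric = metric, k = k, diag_only = FALSE)
  if (TT == Tte) out$diagonal <- diag(out$scores)
  class(out) <- "tg_matrix"
  out
}

#' @export
print.tg_matrix <- function(x, ...) {
  chance <- if (x$metric == "auc") 0.5 else 0
  cat(sprintf("Temporal generalization matrix (%s): %d train x %d test times\n",
              x$metric, nrow(x$scores), ncol(x$scores)))
  cat(sprintf("  mean score %.3f (chance %.3g); max %.3f\n",
              mean(x$scores), chance, max(x$scores)))
  invisible(x)
}

#' @export
plot.tg_matrix <- function(x, ...) {
  tt <- x$times
  tte <- if (is.null(x$times_test)) x$times else x$times_test
  graphics::image(tte, tt, t(x$scores), xlab = "test time (s)",
                  ylab = "train time (s)",
                  main = sprintf("temporal generalization (%s)", x$metric),
                  useRaster = TRUE, ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
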