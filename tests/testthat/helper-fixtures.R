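# Shared fixtures. Network runs are expensive, so short-delay schedules are
# used wherever the property under test does not depend on the full 3 s delay,
# and results needed by several tests are cached per session.

short_schedule <- function(...) build_schedule(delay = 0.6, ...)

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Model-family histogram D = p/N + (1 - p) d for exact-recovery checks.
model_family_hist <- function(p, d_inside, n_positions = 20) {
  offs <- seq(-n_positions / 2, n_positions / 2 - 1)
  D <- rep(p / n_positions, n_positions)
  names(D) <- offs
  D[as.character(seq(-2, 2))] <- D[as.character(seq(-2, 2))] + (1 - p) * d_inside
  response_histogram(counts = D * 1000, n_positions = n_positions)
}

# Brute-force AUC by counting concordant pairs (ties count 1/2).
pairwise_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}
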