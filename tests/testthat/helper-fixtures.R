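# shared fixtures and independent oracles used across test files

# 4-sample, 2-feature Relief toy: feature 1 separates the classes perfectly,
# feature 2 alternates identically within both classes
relief_toy <- function() {
  list(x = matrix(c(0, 0.1, 0.9, 1.0,
                    0.2, 0.8, 0.2, 0.8), ncol = 2,
                  dimnames = list(NULL, c("f1", "f2"))),
       y = factor(c("a", "a", "b", "b")))
}

# independent brute-force Relief oracle: plain loops, no shared code with
# relief_weights() beyond the algorithm definition
relief_brute <- function(x, y) {
  n <- nrow(x); p <- ncol(x)
  xs <- apply(x, 2, function(col) {
    r <- range(col)
    if (r[1] == r[2]) rep(0, length(col)) else (col - r[1]) / (r[2] - r[1])
  })
  w <- numeric(p)
  for (i in seq_len(n)) {
    best_hit <- NULL; best_hit_d <- Inf
    best_miss <- NULL; best_miss_d <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sum((xs[i, ] - xs[j, ])^2)
      if (y[j] == y[i] && d < best_hit_d) { best_hit_d <- d; best_hit <- j }
      if (y[j] != y[i] && d < best_miss_d) { best_miss_d <- d; best_miss <- j }
    }
    for (f in seq_len(p))
      w[f] <- w[f] + abs(xs[i, f] - xs[best_miss, f]) -
        abs(xs[i, f] - xs[best_hit, f])
  }
  w / n
}

# linearly separable two-class feature matrix
separable_xy <- function(n_per_class = 20, p = 4, gap = 3, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, gap), n_per_class),
             matrix(rnorm(n_per_class * p, -gap), n_per_class))
  list(x = x, y = factor(rep(c("task", "rest"), each = n_per_class),
                         levels = c("task", "rest")))
}

# preprocessed segments for one simulated subject (memoised per session count)
local_subject_segments <- local({
  cache <- list()
  function(window_s = 10, n_sessions = 3, seed = 11) {
    key <- paste(n_sessions, seed)
    if (is.null(cache[[key]])) {
      cfg <- sim_config(n_subjects = 1, n_sessions = n_sessions)
      recs <- simulate_dataset(cfg, seed = seed)
      cache[[key]] <<- lapply(recs, preprocess_session)
    }
    unlist(lapply(cache[[key]], segment_session, window_s = window_s),
           recursive = FALSE)
  }
})
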