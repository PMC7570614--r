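# internal helpers shared across modules

# Deterministic 32-bit sub-seed for a pipeline stage. Every stochastic stage
# draws from a seed derived from (master seed, stage tag) so the whole run is
# a pure function of the master seed.
derive_seed <- function(master, tag) {
  stopifnot(length(master) == 1L, is.finite(master))
  h <- 0
  for (c in utf8ToInt(as.character(tag))) h <- (h * 31 + c) %% 1000000007
  as.integer(((abs(as.numeric(master)) %% 1000003) * 2029 + h) %% 2147483647)
}

# round-half-up (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin so every fold gets near-equal class proportions.
make_folds <- function(y, k, seed, stratify = TRUE) {
  n <- length(y)
  stopifnot(k >= 2, n >= k)
  set.seed(seed)
  fold <- integer(n)
  if (stratify) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold <- rep_len(seq_len(k), n)[sample.int(n)]
  }
  fold
}

# z-score using training statistics; zero-variance columns pass through
# centred only (scale 1) so constant features cannot produce NaN.
standardizer <- function(x_train) {
  mu <- colMeans(x_train)
  sig <- apply(x_train, 2, sd)
  sig[!is.finite(sig) | sig == 0] <- 1
  function(x) sweep(sweep(x, 2, mu, "-"), 2, sig, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
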