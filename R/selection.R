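#' Relief feature weights
#'
#' Classic two-class Relief: features are min-max scaled to [0, 1]; for each
#' instance the nearest same-class neighbour (hit) and nearest other-class
#' neighbour (miss) are found by Euclidean distance (excluding the instance
#' itself, ties to the lowest index), and each feature's weight accumulates
#' `(|x_f - miss_f| - |x_f - hit_f|) / n_iterations`. By default every
#' instance is visited once (exhaustive), which removes sampling randomness
#' and makes the weights independent of sample order; `n_iterations` smaller
#' than the sample count draws a seeded random subset of instances.
#'
#' @param x numeric feature matrix (samples x features)
#' @param y two-level factor or vector of class labels
#' @param n_iterations instances to visit; `NULL` (default) visits all
#' @param seed seed for the sampled variant
#' @return numeric weight vector, one per feature (named from `x`'s columns)
#' @export
relief_weights <- function(x, y, n_iterations = NULL, seed = 1) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2)
    stop("Relief requires exactly two classes with >= 1 sample each")
  n <- nrow(x); p <- ncol(x)
  # min-max scale; constant features map to 0 and thus get weight 0
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  xs <- sweep(sweep(x, 2, rng[1, ], "-"), 2, span, "/")
  xs[, rng[2, ] == rng[1, ]] <- 0

  d2 <- as.matrix(stats::dist(xs))^2
  diag(d2) <- Inf
  visit <- if (is.null(n_iterations)) seq_len(n) else {
    set.seed(seed)
    sample.int(n, min(n_iterations, n), replace = n_iterations > n)
  }
  w <- numeric(p)
  for (i in visit) {
    same <- which(y == y[i]); same <- same[same != i]
    diff <- which(y != y[i])
    if (!length(same) || !length(diff))
      stop("Relief needs a hit and a miss for every instance")
    hit <- same[which.min(d2[i, same])]
    miss <- diff[which.min(d2[i, diff])]
    w <- w + (abs(xs[i, ] - xs[miss, ]) - abs(xs[i, ] - xs[hit, ]))
  }
  stats::setNames(w / length(visit), colnames(x))
}

#' Features with strictly positive Relief weight
#'
#' Indices (original order) of positive-weight features. If no weight is
#' positive, the single best-weighted feature is returned with a warning so
#' the downstream classifier always has an input.
#'
#' @param weights vector from [relief_weights()]
#' @export
positive_subset <- function(weights) {
  idx <- which(weights > 0)
  if (!length(idx)) {
    warning("no positive Relief weights; falling back to the top-ranked feature")
    idx <- which.max(weights)
  }
  idx
}

#' Cross-validated linear-SVM accuracy of a feature subset
#'
#' The default criterion for the sequential forward search: stratified
#' k-fold cross-validation on the supplied data, each fold standardized by
#' its training statistics, linear SVM with unit box constraint.
#'
#' @param x feature matrix (already restricted to the candidate subset)
#' @param y labels
#' @param k folds (capped at the size of the smaller class)
#' @param seed fold-partition seed
#' @param spec a [classifier_spec()]
#' @return mean held-out accuracy in [0, 1]
#' @export
svm_cv_accuracy <- function(x, y, k = 10, seed = 1, spec = classifier_spec()) {
  x <- as.matrix(x)
  y <- as.factor(y)
  k <- max(2L, min(k, min(table(y))))
  fold <- make_folds(y, k, seed)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    std <- standardizer(x[tr, , drop = FALSE])
    fit <- svm_fit(std(x[tr, , drop = FALSE]), y[tr], spec)
    pred <- predict(fit, std(x[!tr, , drop = FALSE]))
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Sequential forward selection driven by a wrapper criterion
#'
#' Greedy forward search: starting from the empty set, repeatedly add the
#' feature that maximizes the criterion (by default the cross-validated
#' linear-SVM accuracy, see [svm_cv_accuracy()]); ties go to the lowest
#' feature index; the search stops when no addition strictly improves the
#' criterion. Deterministic given the seed, which fixes the evaluator's fold
#' partitions.
#'
#' @param x feature matrix
#' @param y labels
#' @param evaluator `function(x_subset, y, seed)` returning a scalar
#'   criterion; `NULL` uses the default SVM evaluator
#' @param seed evaluator seed
#' @param spec a [classifier_spec()] for the default evaluator
#' @return list with `selected` (ordered indices) and `trace`
#'   (criterion after each accepted feature)
#' @export
sfs_select <- function(x, y, evaluator = NULL, seed = 1,
                       spec = classifier_spec()) {
  x <- as.matrix(x)
  if (is.null(evaluator))
    evaluator <- function(xs, y, seed) svm_cv_accuracy(xs, y, seed = seed,
                                                       spec = spec)
  p <- ncol(x)
  selected <- integer(0)
  trace <- numeric(0)
  best <- -Inf
  repeat {
    remaining <- setdiff(seq_len(p), selected)
    if (!length(remaining)) break
    scores <- vapply(remaining, function(j)
      evaluator(x[, c(selected, j), drop = FALSE], y, seed), numeric(1))
    j_best <- remaining[which.max(scores)]  # which.max: first max, lowest index
    if (max(scores) > best) {
      best <- max(scores)
      selected <- c(selected, j_best)
      trace <- c(trace, best)
    } else break
  }
  if (!length(selected)) {  # criterion never beat -Inf start is impossible,
    selected <- 1L          # but guard an all-NA evaluator anyway
    trace <- NA_real_
  }
  list(selected = selected, trace = trace)
}
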