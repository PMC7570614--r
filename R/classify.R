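#' Linear SVM specification
#'
#' Linear-kernel support vector machine with unit box constraint. "Kernel
#' scaling" is realized by z-score standardization of the features on each
#' training fold, which for a linear kernel is the equivalent operation.
#'
#' @param cost box constraint C (> 0)
#' @param tolerance solver termination tolerance
#' @export
classifier_spec <- function(cost = 1, tolerance = 0.001) {
  stopifnot(cost > 0, tolerance > 0)
  structure(list(cost = cost, tolerance = tolerance),
            class = "fnirs_classifier_spec")
}

svm_fit <- function(x, y, spec = classifier_spec()) {
  e1071::svm(x, y, kernel = "linear", cost = spec$cost,
             tolerance = spec$tolerance, scale = FALSE)
}

#' Classification metrics from pooled confusion counts
#'
#' Task is the positive class. `precision = TP/(TP+FP)`,
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`, F1 the harmonic
#' mean of precision and sensitivity. Undefined 0/0 ratios are reported as 0
#' with a warning (an empty denominator never silently scores well).
#'
#' @param tp,fp,fn,tn confusion counts
#' @return named list: `precision`, `sensitivity`, `specificity`, `f1`
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0); reported as 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  sensitivity <- safe_div(tp, tp + fn, "sensitivity")
  specificity <- safe_div(tn, tn + fp, "specificity")
  f1 <- if (precision + sensitivity == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)
  list(precision = precision, sensitivity = sensitivity,
       specificity = specificity, f1 = f1)
}

#' Nested cross-validated linear-SVM classification
#'
#' Outer stratified 10-fold partition (seeded). In every outer fold the
#' features are standardized using training-fold statistics, the selector is
#' fitted on the training fold only (the leakage-safe default), the linear
#' SVM is trained on the selected features and scored on the held-out fold.
#' The reported accuracy is the arithmetic mean of the ten held-out
#' accuracies (in %); F1, sensitivity, specificity and precision come from
#' the confusion counts pooled over folds.
#'
#' `paper_mode = TRUE` instead runs the selector once on the full dataset
#' before the outer partition — the apparent procedure of the original
#' analysis; its selected set leaks into the test folds, which typically
#' inflates accuracy.
#'
#' @param x feature matrix (samples x features)
#' @param y labels (task/rest factor or coercible)
#' @param selector `"relief"` (positive-weight subset), `"sfs"` (forward
#'   search with the inner-CV SVM criterion) or `"none"` (all features)
#' @param spec a [classifier_spec()]
#' @param seed seed controlling outer folds and the selector's inner folds
#' @param k outer folds (capped at the smaller class size)
#' @param paper_mode run selection once on the full dataset before CV?
#' @param stratify stratified outer folds? With `FALSE`, partitions are
#'   redrawn (up to 100 times) until every training fold has both classes
#' @param inner_k inner folds for the SFS criterion
#' @return an object of class `fnirs_cv`
#' @export
nested_cv <- function(x, y, selector = c("relief", "sfs", "none"),
                      spec = classifier_spec(), seed = 1, k = 10,
                      paper_mode = FALSE, stratify = TRUE, inner_k = 10) {
  selector <- match.arg(selector)
  x <- as.matrix(x)
  y <- factor(y, levels = if (all(y %in% c("task", "rest")))
    c("task", "rest") else sort(unique(as.character(y))))
  if (nlevels(y) != 2) stop("nested_cv requires two classes")
  if (length(y) < k) k <- max(2L, min(table(y)))
  k <- min(k, min(table(y)))

  select_on <- function(xs, ys, sd) {
    switch(selector,
      none = seq_len(ncol(xs)),
      relief = positive_subset(relief_weights(xs, ys)),
      sfs = sfs_select(xs, ys, seed = sd, spec = spec)$selected)
  }

  global_sel <- NULL
  if (paper_mode) {
    std_all <- standardizer(x)
    global_sel <- select_on(std_all(x), y, derive_seed(seed, "select_full"))
  }

  # draw an outer partition whose training folds all contain both classes
  fold <- NULL
  for (attempt in seq_len(100)) {
    cand <- make_folds(y, k, derive_seed(seed, paste0("outer", attempt)),
                       stratify = stratify)
    ok <- all(vapply(seq_len(k), function(f)
      nlevels(droplevels(y[cand != f])) == 2, logical(1)))
    if (ok) { fold <- cand; break }
  }
  if (is.null(fold))
    stop("could not draw an outer partition with both classes in every training fold")

  fold_acc <- numeric(k)
  conf <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  n_feat <- integer(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    std <- standardizer(x[tr, , drop = FALSE])
    xtr <- std(x[tr, , drop = FALSE])
    sel <- if (paper_mode) global_sel else
      select_on(xtr, y[tr], derive_seed(seed, paste0("select_fold", f)))
    n_feat[f] <- length(sel)
    fit <- svm_fit(xtr[, sel, drop = FALSE], y[tr], spec)
    xte <- std(x[!tr, , drop = FALSE])[, sel, drop = FALSE]
    pred <- predict(fit, xte)
    truth <- y[!tr]
    fold_acc[f] <- 100 * mean(pred == truth)
    conf["tp"] <- conf["tp"] + sum(pred == "task" & truth == "task")
    conf["fp"] <- conf["fp"] + sum(pred == "task" & truth == "rest")
    conf["fn"] <- conf["fn"] + sum(pred == "rest" & truth == "task")
    conf["tn"] <- conf["tn"] + sum(pred == "rest" & truth == "rest")
  }
  met <- confusion_metrics(conf[["tp"]], conf[["fp"]], conf[["fn"]],
                           conf[["tn"]])
  structure(list(fold_accuracies = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 f1 = met$f1, sensitivity = met$sensitivity,
                 specificity = met$specificity, precision = met$precision,
                 confusion = conf, method_used = selector,
                 n_features_used = if (paper_mode) length(global_sel)
                                   else as.integer(round(mean(n_feat))),
                 paper_mode = paper_mode, k = k, seed = seed),
            class = "fnirs_cv")
}

#' @export
print.fnirs_cv <- function(x, ...) {
  cat(sprintf("Nested %d-fold CV, linear SVM, selector '%s'%s\n", x$k,
              x$method_used, if (x$paper_mode) " (paper mode)" else ""))
  cat(sprintf("  mean accuracy %.1f%% (folds %s)\n", x$mean_accuracy,
              paste(sprintf("%.0f", x$fold_accuracies), collapse = " ")))
  cat(sprintf("  F1 %.3f | sens %.3f | spec %.3f | prec %.3f | ~%d features\n",
              x$f1, x$sensitivity, x$specificity, x$precision,
              x$n_features_used))
  invisible(x)
}

#' @export
summary.fnirs_cv <- function(object, ...) {
  out <- data.frame(mean_accuracy = object$mean_accuracy,
                    sd_accuracy = sd(object$fold_accuracies),
                    f1 = object$f1, sensitivity = object$sensitivity,
                    specificity = object$specificity,
                    precision = object$precision,
                    method = object$method_used,
                    n_features = object$n_features_used)
  class(out) <- c("summary.fnirs_cv", "data.frame")
  out
}

#' Keep the better of the two selector outcomes
#'
#' Returns whichever outcome has the higher mean accuracy; ties go first to
#' the outcome that used fewer features, then to Relief.
#'
#' @param outcome_sfs,outcome_relief `fnirs_cv` objects fitted on the same
#'   dataset and seed
#' @export
best_of_two <- function(outcome_sfs, outcome_relief) {
  if (outcome_sfs$mean_accuracy > outcome_relief$mean_accuracy) return(outcome_sfs)
  if (outcome_relief$mean_accuracy > outcome_sfs$mean_accuracy) return(outcome_relief)
  if (outcome_sfs$n_features_used < outcome_relief$n_features_used)
    return(outcome_sfs)
  outcome_relief
}

#' Enumerate the (subject, location, window) analysis grid
#'
#' @param subjects subject identifiers
#' @param locations location names
#' @param windows window lengths (s)
#' @return data.frame with one row per dataset the grid run will classify
#' @export
dataset_grid <- function(subjects, locations = location_channels(),
                         windows = segmentation_policy()$window_s) {
  expand.grid(subject = subjects, location = locations, window_s = windows,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Classify every (subject, location, window) dataset
#'
#' For each subject, preprocesses the retained sessions, segments them at
#' every requested window length, builds the location-restricted feature
#' matrices and runs [nested_cv()] with each selection method, keeping the
#' best-of-two outcome per dataset. The default grid — 8 subjects, 6
#' locations, 5 window lengths — yields 240 outcomes.
#'
#' @param recordings list of `fnirs_recording` (screened or not; screening is
#'   applied here with the default thresholds unless `screen = FALSE`)
#' @param locations location names to analyse
#' @param windows window lengths (s)
#' @param methods selection methods to compare (subset of `"relief"`,
#'   `"sfs"`); one method skips the best-of-two comparison
#' @param seed master seed
#' @param optics,fspec,policy,spec pipeline settings
#' @param paper_mode see [nested_cv()]
#' @param screen apply [screen_sessions()] first?
#' @param quiet suppress progress messages
#' @return an accuracy table of class `fnirs_accuracy`: one row per dataset
#'   with the best outcome's accuracy, method and feature count
#' @export
run_grid <- function(recordings, locations = location_channels(),
                     windows = segmentation_policy()$window_s,
                     methods = c("relief", "sfs"), seed = 1,
                     optics = optics_params(), fspec = filter_spec(),
                     policy = segmentation_policy(),
                     spec = classifier_spec(), paper_mode = FALSE,
                     screen = TRUE, quiet = TRUE) {
  methods <- match.arg(methods, c("relief", "sfs"), several.ok = TRUE)
  if (screen) recordings <- screen_sessions(recordings, quiet = quiet)
  if (!length(recordings)) stop("no recordings to analyse after screening")
  subjects <- unique(vapply(recordings, function(r) r$meta$subject,
                            character(1)))
  rows <- list()
  for (sub in subjects) {
    recs <- Filter(function(r) identical(r$meta$subject, sub), recordings)
    hemos <- lapply(recs, preprocess_session, optics = optics, spec = fspec)
    for (w in windows) {
      segs <- unlist(lapply(hemos, segment_session, window_s = w,
                            policy = policy), recursive = FALSE)
      for (loc in locations) {
        fm <- feature_matrix(segs, loc)
        ds_seed <- derive_seed(seed, paste(sub, loc, w, sep = "_"))
        outs <- lapply(methods, function(m)
          nested_cv(fm$x, fm$y, selector = m, spec = spec, seed = ds_seed,
                    paper_mode = paper_mode))
        best <- if (length(outs) == 2) {
          names(outs) <- methods
          best_of_two(outs[["sfs"]], outs[["relief"]])
        } else outs[[1]]
        if (!quiet)
          message(sprintf("%s %s %gs: %.1f%% (%s)", sub, loc, w,
                          best$mean_accuracy, best$method_used))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sub, location = loc, window_s = w,
          accuracy_pct = best$mean_accuracy, method = best$method_used,
          n_features = best$n_features_used, f1 = best$f1,
          sensitivity = best$sensitivity, specificity = best$specificity,
          precision = best$precision)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "source") <- "pipeline"
  class(out) <- c("fnirs_accuracy", "data.frame")
  out
}
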