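#' Published per-subject accuracy table
#'
#' The 8-subject x 6-location x 5-window classification accuracies of the
#' original study, packaged as a fixture so the summary statistics and the
#' location-vs-Whole significance pattern can be recomputed exactly. The file
#' is checksum-pinned: an accidental edit raises an error.
#'
#' @return an accuracy table of class `fnirs_accuracy` (long format:
#'   `subject`, `location`, `window_s`, `accuracy_pct`) with
#'   `attr(, "source") = "table1_fixture"`
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_accuracies.csv",
                      package = "fnirsloc", mustWork = TRUE)
  sum <- tools::md5sum(path)[[1]]
  if (!identical(sum, "782ebd47591a402589a3b838ee88cf2c"))
    stop("table1_accuracies.csv has been modified (md5 ", sum, ")")
  tab <- read.csv(path, check.names = FALSE)
  stopifnot(nrow(tab) == 240,
            all(tab$accuracy_pct >= 0 & tab$accuracy_pct <= 100))
  attr(tab, "source") <- "table1_fixture"
  class(tab) <- c("fnirs_accuracy", "data.frame")
  tab
}

#' Mean, SD and standard error per location and window
#'
#' Arithmetic mean, sample standard deviation (n-1) and standard error
#' `SE = SD / sqrt(n_subjects)` of the per-subject accuracies for every
#' location x window cell. Values are kept at full precision; the print
#' method rounds to one decimal.
#'
#' @param table an accuracy table (from [run_grid()] or [table1_fixture()])
#' @return data.frame of class `fnirs_summary` with columns `location`,
#'   `window_s`, `n`, `mean`, `sd`, `se`
#' @export
accuracy_summary <- function(table) {
  agg <- aggregate(accuracy_pct ~ location + window_s, data = table,
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       sd = sd(v)))
  out <- data.frame(location = agg$location, window_s = agg$window_s,
                    n = agg$accuracy_pct[, "n"],
                    mean = agg$accuracy_pct[, "mean"],
                    sd = agg$accuracy_pct[, "sd"])
  if (any(out$n < 2)) stop("need at least two subjects per cell")
  out$se <- out$sd / sqrt(out$n)
  out <- out[order(out$window_s, match(out$location, location_channels())), ]
  rownames(out) <- NULL
  class(out) <- c("fnirs_summary", "data.frame")
  out
}

#' @export
print.fnirs_summary <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  y$mean <- round(y$mean, digits)
  y$sd <- round(y$sd, digits)
  y$se <- round(y$se, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Two-sample t-tests of every partial location against whole-forehead sensing
#'
#' For each window length and each location other than the reference, a
#' two-sided pooled-variance (Student) two-sample t-test compares the
#' per-subject accuracies of that location against the reference location's.
#' With 8 subjects per group the tests have 14 degrees of freedom. No
#' multiplicity correction is applied. Identical groups give t = 0; a zero
#' pooled variance with unequal means is reported significant with a warning.
#'
#' @param table an accuracy table
#' @param alpha significance level
#' @param reference reference location (default `"Whole"`)
#' @param var_equal pooled (TRUE, default) or Welch (FALSE) test
#' @return data.frame of class `fnirs_comparisons`: `location`, `window_s`,
#'   `mean`, `sd`, `se`, `t`, `df`, `p`, `significant`
#' @export
ttest_vs_whole <- function(table, alpha = 0.05, reference = "Whole",
                           var_equal = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  if (!reference %in% table$location)
    stop("reference location '", reference, "' absent from table")
  locs <- setdiff(unique(table$location), reference)
  wins <- sort(unique(table$window_s))
  rows <- list()
  for (w in wins) {
    ref <- table$accuracy_pct[table$location == reference &
                                table$window_s == w]
    for (loc in locs) {
      v <- table$accuracy_pct[table$location == loc & table$window_s == w]
      if (length(v) < 2 || length(ref) < 2)
        stop("need >= 2 subjects per group for the t-test")
      if (sd(v) == 0 && sd(ref) == 0) {
        if (mean(v) == mean(ref)) {
          tt <- list(statistic = 0, parameter = length(v) + length(ref) - 2,
                     p.value = 1)
        } else {
          warning("zero pooled variance with unequal means (", loc, ", ", w,
                  " s); reported significant", call. = FALSE)
          tt <- list(statistic = sign(mean(v) - mean(ref)) * Inf,
                     parameter = length(v) + length(ref) - 2, p.value = 0)
        }
      } else {
        tt <- t.test(v, ref, var.equal = var_equal)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        location = loc, window_s = w, mean = mean(v), sd = sd(v),
        se = sd(v) / sqrt(length(v)), t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value,
        significant = tt$p.value < alpha)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$window_s, match(out$location, location_channels())), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "reference") <- reference
  class(out) <- c("fnirs_comparisons", "data.frame")
  out
}

#' Number of significant location-vs-reference comparisons
#' @param comparisons output of [ttest_vs_whole()]
#' @export
count_significant <- function(comparisons) {
  if (!nrow(comparisons)) return(0L)
  sum(comparisons$significant)
}

#' @export
print.fnirs_comparisons <- function(x, ...) {
  y <- as.data.frame(x)
  y$mean <- round(y$mean, 1); y$sd <- round(y$sd, 1); y$se <- round(y$se, 1)
  y$t <- round(y$t, 2); y$p <- signif(y$p, 3)
  cat(sprintf("Two-sample t-tests vs %s (alpha = %g): %d of %d significant\n",
              attr(x, "reference"), attr(x, "alpha"), count_significant(x),
              nrow(x)))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Grouped bar chart of mean accuracies with standard-error bars
#'
#' One group of bars per window length, one bar per location; error bars show
#' the standard error of the mean, and locations significantly different from
#' the reference (when `comparisons` is supplied) are starred.
#'
#' @param x an `fnirs_summary`
#' @param comparisons optional [ttest_vs_whole()] output for the stars
#' @param ylim y-axis range
#' @param ... passed to [graphics::barplot()]
#' @export
plot.fnirs_summary <- function(x, comparisons = NULL, ylim = c(0, 110), ...) {
  locs <- intersect(location_channels(), unique(x$location))
  wins <- sort(unique(x$window_s))
  m <- matrix(NA_real_, length(locs), length(wins),
              dimnames = list(locs, paste0(wins, " s")))
  e <- m
  for (i in seq_along(locs)) for (j in seq_along(wins)) {
    row <- x[x$location == locs[i] & x$window_s == wins[j], ]
    if (nrow(row)) { m[i, j] <- row$mean; e[i, j] <- row$se }
  }
  bp <- barplot(m, beside = TRUE, ylim = ylim,
                ylab = "Mean classification accuracy (%)",
                xlab = "Segmentation window", legend.text = locs,
                args.legend = list(x = "topright", bty = "n", cex = 0.7,
                                   ncol = 2), ...)
  arrows(bp, m - e, bp, m + e, angle = 90, code = 3, length = 0.02)
  if (!is.null(comparisons)) {
    for (i in seq_along(locs)) for (j in seq_along(wins)) {
      hit <- comparisons$significant[comparisons$location == locs[i] &
                                       comparisons$window_s == wins[j]]
      if (length(hit) && isTRUE(hit[1]))
        text(bp[i, j], m[i, j] + e[i, j] + 3, "*", cex = 1.2)
    }
  }
  invisible(bp)
}

#' Write the location-comparison report
#'
#' Writes the per-subject accuracies, the summary table (wide, one column
#' per location, as in the published layout), the t-test comparisons, the
#' grouped bar chart (PDF) and a short run log.
#'
#' @param table accuracy table
#' @param out_dir output directory
#' @param alpha significance level for the comparisons
#' @return invisibly, named vector of the files written
#' @export
location_report <- function(table, out_dir, alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- accuracy_summary(table)
  comp <- ttest_vs_whole(table, alpha = alpha)

  files <- c(
    accuracies = file.path(out_dir, "accuracies.csv"),
    summary = file.path(out_dir, "summary_wide.csv"),
    comparisons = file.path(out_dir, "comparisons.csv"),
    figure = file.path(out_dir, "mean_accuracy_by_location.pdf"),
    log = file.path(out_dir, "report_log.txt"))

  write.csv(as.data.frame(table), files["accuracies"], row.names = FALSE)
  locs <- intersect(location_channels(), unique(summ$location))
  wide <- do.call(rbind, lapply(sort(unique(summ$window_s)), function(w) {
    row <- data.frame(window_s = w)
    for (loc in locs) {
      cell <- summ[summ$location == loc & summ$window_s == w, ]
      row[[loc]] <- sprintf("%.1f +/- %.1f", cell$mean, cell$sd)
    }
    row
  }))
  write.csv(wide, files["summary"], row.names = FALSE)
  write.csv(as.data.frame(comp), files["comparisons"], row.names = FALSE)

  pdf(files["figure"], width = 8, height = 5)
  plot(summ, comparisons = comp)
  dev.off()

  writeLines(c(
    paste("source:", attr(table, "source") %||% "unknown"),
    paste("datasets:", nrow(table)),
    paste("alpha:", alpha),
    paste("significant comparisons:", count_significant(comp), "of",
          nrow(comp))), files["log"])
  invisible(files)
}
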