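#' Per-session segment-count policy
#'
#' Number of task- and rest-labelled windows cut from each session at every
#' supported window length. The defaults pin the published per-session
#' tuples: 18/11 at 5 s, 9/5 at 10 s, 4/2 at 20 s, 2/1 at 25 s and 1/1 for
#' the whole-period windows, which give per-subject totals of 290, 140, 60,
#' 30 and 20 samples over ten sessions. Starts are spaced evenly across each
#' period, which lands the overlap near 50 % at every length.
#'
#' @return data.frame with columns `window_s`, `n_task`, `n_rest`
#' @export
segmentation_policy <- function() {
  data.frame(window_s = c(5, 10, 20, 25, 48),
             n_task = c(18L, 9L, 4L, 2L, 1L),
             n_rest = c(11L, 5L, 2L, 1L, 1L))
}

#' Evenly spaced window start times within a period
#'
#' `n_windows` starts spanning `[0, period_s - window_s]`:
#' `start_i = i * (period_s - window_s) / (n_windows - 1)` for
#' `i = 0, ..., n_windows - 1`, or `0` for a single window. Every window lies
#' inside the period.
#'
#' @param period_s period length (s)
#' @param window_s window length (s), at most `period_s`
#' @param n_windows number of windows (>= 1)
#' @return numeric vector of start offsets (s)
#' @export
window_starts <- function(period_s, window_s, n_windows) {
  stopifnot(n_windows >= 1)
  if (window_s > period_s)
    stop("window_s (", window_s, ") exceeds period_s (", period_s, ")")
  if (n_windows == 1) return(0)
  (seq_len(n_windows) - 1) * (period_s - window_s) / (n_windows - 1)
}

#' Cut one session into labelled task/rest windows
#'
#' Windows are placed by [window_starts()] within the task and rest periods
#' (the baseline is never segmented); fractional start times are converted to
#' sample indices by half-up rounding. A nominal window length exceeding a
#' period (the whole-period 48 s setting against the 25 s rest block) takes
#' the entire period as its single window.
#'
#' @param hemo an `fnirs_hemo` with markers
#' @param window_s one of the policy's window lengths
#' @param policy a [segmentation_policy()]-shaped data.frame
#' @param subject,session provenance carried onto each segment (defaults
#'   from `hemo$meta` when present)
#' @return list of `fnirs_segment` objects, ordered task windows then rest
#'   windows, each by start time
#' @export
segment_session <- function(hemo, window_s, policy = segmentation_policy(),
                            subject = NULL, session = NULL) {
  row <- policy[policy$window_s == window_s, ]
  if (nrow(row) != 1) stop("window_s ", window_s, " not in policy")
  subject <- subject %||% hemo$meta$subject %||% "sub01"
  session <- session %||% hemo$meta$session %||% 1L
  fs <- hemo$fs_hz
  spans <- list(
    task = range(which(hemo$markers == "task")),
    rest = range(which(hemo$markers == "rest")))
  counts <- c(task = row$n_task, rest = row$n_rest)
  segs <- list()
  for (lab in c("task", "rest")) {
    period_i <- spans[[lab]]
    period_s <- (period_i[2] - period_i[1] + 1) / fs
    w_eff <- min(window_s, period_s)     # whole-period fallback
    offs <- window_starts(period_s, w_eff, counts[[lab]])
    w_n <- as.integer(round(w_eff * fs))
    for (o in offs) {
      i0 <- period_i[1] + as.integer(round_half_up(o * fs))
      idx <- i0:(i0 + w_n - 1L)
      if (idx[length(idx)] > period_i[2])
        idx <- idx - (idx[length(idx)] - period_i[2])
      segs[[length(segs) + 1L]] <- structure(
        list(subject = subject, session = session, label = lab,
             window_s = window_s,
             start_s = hemo$time_s[idx[1]],
             time_s = hemo$time_s[idx],
             dhbo = hemo$dhbo[idx, , drop = FALSE],
             dhbr = hemo$dhbr[idx, , drop = FALSE],
             markers = hemo$markers[idx], fs_hz = fs),
        class = "fnirs_segment")
    }
  }
  segs
}

#' Labelled samples per subject for a window length
#'
#' `n_sessions * (n_task + n_rest)` — the total number of classifier samples
#' one subject contributes at the given window length.
#'
#' @param n_sessions sessions retained for the subject
#' @param window_s window length (s)
#' @param policy a [segmentation_policy()]-shaped data.frame
#' @export
dataset_counts <- function(n_sessions, window_s,
                           policy = segmentation_policy()) {
  row <- policy[policy$window_s == window_s, ]
  if (nrow(row) != 1) stop("window_s ", window_s, " not in policy")
  as.integer(n_sessions) * (row$n_task + row$n_rest)
}

#' @export
print.fnirs_segment <- function(x, ...) {
  cat(sprintf("fNIRS segment: %s session %s, %s, %g s window at t=%g s (%d samples)\n",
              x$subject, x$session, x$label, x$window_s, x$start_s,
              nrow(x$dhbo)))
  invisible(x)
}
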