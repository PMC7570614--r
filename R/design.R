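#' Block-design session layout
#'
#' Defines the timing of one recording session: a pre-task baseline, a task
#' block made of equal-length 2-back events, and a rest block, sampled at a
#' fixed rate. The defaults encode a 10 s baseline, a 48 s task period of 24
#' two-second events, and 25 s of rest at 25 Hz.
#'
#' @param baseline_s baseline duration before the task (s)
#' @param task_s task-block duration (s); must equal `n_events * event_s`
#' @param rest_s rest-block duration (s)
#' @param n_events number of task events
#' @param event_s duration of one event (s)
#' @param fs_hz sampling rate (Hz)
#' @return an object of class `fnirs_design`
#' @examples
#' d <- fnirs_design()
#' design_n_samples(d)  # 2075
#' @export
fnirs_design <- function(baseline_s = 10, task_s = 48, rest_s = 25,
                         n_events = 24, event_s = 2, fs_hz = 25) {
  if (!isTRUE(all.equal(task_s, n_events * event_s)))
    stop("inconsistent design: task_s (", task_s, ") != n_events * event_s (",
         n_events * event_s, ")")
  stopifnot(baseline_s >= 0, rest_s >= 0, fs_hz > 0)
  total <- (baseline_s + task_s + rest_s) * fs_hz
  if (!isTRUE(all.equal(total, round(total))))
    stop("total duration times sampling rate must be an integer number of samples")
  structure(list(baseline_s = baseline_s, task_s = task_s, rest_s = rest_s,
                 n_events = n_events, event_s = event_s, fs_hz = fs_hz),
            class = "fnirs_design")
}

#' @export
print.fnirs_design <- function(x, ...) {
  cat("fNIRS block design: ", x$baseline_s, "s baseline + ", x$task_s,
      "s task (", x$n_events, " x ", x$event_s, " s events) + ", x$rest_s,
      "s rest @ ", x$fs_hz, " Hz (", design_n_samples(x), " samples)\n", sep = "")
  invisible(x)
}

#' Total number of samples in a session
#' @param design an [fnirs_design()]
#' @export
design_n_samples <- function(design) {
  as.integer(round((design$baseline_s + design$task_s + design$rest_s) * design$fs_hz))
}

#' Per-sample condition markers
#'
#' Contiguous, non-overlapping `baseline`, `task`, `rest` labels covering the
#' whole session.
#'
#' @param design an [fnirs_design()]
#' @return character vector of length `design_n_samples(design)`
#' @export
design_markers <- function(design) {
  fs <- design$fs_hz
  rep(c("baseline", "task", "rest"),
      times = round(c(design$baseline_s, design$task_s, design$rest_s) * fs))
}

#' Sample time grid of a session, starting at 0 s
#' @param design an [fnirs_design()]
#' @export
design_time <- function(design) {
  (seq_len(design_n_samples(design)) - 1) / design$fs_hz
}
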