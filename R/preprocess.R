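#' Screen sessions on behavioural accuracy and motion
#'
#' Drops sessions whose 2-back behavioural accuracy is below the threshold
#' (assumed low task engagement) and, optionally, sessions flagged for
#' movement. Each rejection is reported with its reason.
#'
#' @param recordings list of `fnirs_recording`
#' @param min_behavioral_pct minimum behavioural accuracy (%) to keep
#' @param drop_motion drop sessions with `motion_flag = TRUE`?
#' @param quiet suppress per-rejection messages
#' @return the retained recordings (possibly empty, with a warning)
#' @export
screen_sessions <- function(recordings, min_behavioral_pct = 90,
                            drop_motion = TRUE, quiet = FALSE) {
  keep <- vapply(recordings, function(r) {
    m <- r$meta
    id <- sprintf("%s session %s", m$subject %||% "?", m$session %||% "?")
    if (!is.null(m$behavioral_accuracy_pct) &&
        m$behavioral_accuracy_pct < min_behavioral_pct) {
      if (!quiet) message("rejected ", id, ": behavioral accuracy ",
                          sprintf("%.1f", m$behavioral_accuracy_pct),
                          "% < ", min_behavioral_pct, "%")
      return(FALSE)
    }
    if (drop_motion && isTRUE(m$motion_flag)) {
      if (!quiet) message("rejected ", id, ": motion flagged")
      return(FALSE)
    }
    TRUE
  }, logical(1))
  if (!any(keep)) warning("all sessions rejected by screening")
  recordings[keep]
}

#' Filter specification for the temporal preprocessing
#'
#' Third-order Butterworth band-pass (0.01-0.5 Hz corners) followed by a 2 s
#' moving average, the band chosen to pass the slow task-locked hemodynamic
#' response while rejecting drift below 0.01 Hz and Mayer-wave/respiratory/
#' cardiac interference above 0.5 Hz. `zero_phase = TRUE` applies the
#' Butterworth forward and backward (no phase shift; effective order doubles).
#'
#' @param order Butterworth order
#' @param band_hz length-2 pass band (Hz)
#' @param ma_window_s moving-average window (s)
#' @param zero_phase forward-backward application?
#' @export
filter_spec <- function(order = 3, band_hz = c(0.01, 0.5), ma_window_s = 2,
                        zero_phase = TRUE) {
  stopifnot(order >= 1, length(band_hz) == 2, band_hz[1] > 0,
            band_hz[2] > band_hz[1], ma_window_s >= 0)
  structure(list(order = order, band_hz = band_hz,
                 ma_window_s = ma_window_s, zero_phase = zero_phase),
            class = "fnirs_filter_spec")
}

#' Butterworth band-pass filter
#'
#' Filters each column independently. The column mean is removed before
#' filtering and restored afterwards: a band-pass rejects DC in any case, and
#' restoring the mean keeps raw intensities positive for the downstream
#' log-ratio conversion.
#'
#' @param x numeric vector or matrix (columns = series)
#' @param fs sampling rate (Hz)
#' @param spec a [filter_spec()]
#' @export
bandpass_filter <- function(x, fs, spec = filter_spec()) {
  if (any(spec$band_hz >= fs / 2))
    stop("pass band must lie inside (0, fs/2)")
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (nrow(x) <= 3 * spec$order)
    stop("signal too short for filter order ", spec$order)
  bf <- signal::butter(spec$order, spec$band_hz / (fs / 2), type = "pass")
  out <- apply(x, 2, function(col) {
    mu <- mean(col)
    y <- if (spec$zero_phase) signal::filtfilt(bf, col - mu)
         else signal::filter(bf, col - mu)
    y + mu
  })
  out <- matrix(out, nrow = nrow(x), dimnames = dimnames(x))
  if (vec) drop(out) else out
}

#' Centred moving average with shrinking edge windows
#'
#' Window of `window_s * fs` samples (rounded), centred on each sample; at
#' the edges the window shrinks to the available samples rather than
#' truncating the series, so the 10 s baseline keeps its full length.
#' Constant signals pass through unchanged.
#'
#' @param x numeric vector or matrix (columns = series)
#' @param fs sampling rate (Hz)
#' @param window_s window length (s)
#' @export
moving_average <- function(x, fs, window_s = 2) {
  w <- max(1L, as.integer(round(window_s * fs)))
  if (w == 1L) return(x)
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  k1 <- (w - 1L) %/% 2L      # samples before
  k2 <- w - 1L - k1          # samples after
  lo <- pmax(seq_len(n) - k1, 1L)
  hi <- pmin(seq_len(n) + k2, n)
  out <- apply(x, 2, function(col) {
    cs <- c(0, cumsum(col))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  out <- matrix(out, nrow = n, dimnames = dimnames(x))
  if (vec) drop(out) else out
}

#' Apply the temporal filters to a raw recording
#'
#' Band-pass then moving average, applied to every channel x wavelength
#' intensity series independently. Markers and metadata pass through
#' untouched.
#'
#' @param rec an `fnirs_recording`
#' @param spec a [filter_spec()]
#' @export
filter_recording <- function(rec, spec = filter_spec()) {
  for (w in seq_len(dim(rec$intensity)[3])) {
    y <- bandpass_filter(rec$intensity[, , w], rec$fs_hz, spec)
    if (spec$ma_window_s > 0)
      y <- moving_average(y, rec$fs_hz, spec$ma_window_s)
    rec$intensity[, , w] <- y
  }
  rec
}

#' Optical-density change relative to the baseline window
#'
#' Per channel and wavelength, the baseline intensity `I0` is the mean over
#' the baseline period (by default every sample marked `baseline`, i.e. the
#' first 10 s) and `dOD = -log10(I / I0)`.
#'
#' @param rec an `fnirs_recording` with positive intensities
#' @param baseline_s use the first `baseline_s` seconds instead of the
#'   baseline markers (optional)
#' @return an object of class `fnirs_od`
#' @export
to_optical_density <- function(rec, baseline_s = NULL) {
  if (any(rec$intensity <= 0, na.rm = TRUE))
    stop("non-positive intensities; cannot form optical density")
  idx <- if (is.null(baseline_s)) which(rec$markers == "baseline")
         else which(rec$time_s < baseline_s)
  if (!length(idx)) stop("empty baseline window")
  od <- rec$intensity
  nch <- dim(od)[2]
  for (w in seq_len(dim(od)[3])) {
    iw <- matrix(rec$intensity[, , w], ncol = nch)
    i0 <- colMeans(iw[idx, , drop = FALSE])
    od[, , w] <- -log10(sweep(iw, 2, i0, "/"))
  }
  structure(list(time_s = rec$time_s, od = od, markers = rec$markers,
                 fs_hz = rec$fs_hz, meta = rec$meta),
            class = "fnirs_od")
}

#' Modified Beer-Lambert conversion to hemoglobin concentration changes
#'
#' Solves, per sample and channel, the 2x2 linear system
#' `dOD(w) / (d * DPF(w)) = eps_hbo2(w) dHbO2 + eps_hbr(w) dHbR`
#' for the oxy- and deoxyhemoglobin concentration changes (micromolar).
#'
#' @param od an `fnirs_od`
#' @param optics an [optics_params()] whose extinction matrix is invertible
#' @return an `fnirs_hemo`
#' @export
mbll <- function(od, optics = optics_params()) {
  eps <- optics$eps
  if (abs(det(eps)) < .Machine$double.eps) stop("singular extinction matrix")
  path <- optics$sds_cm * optics$dpf
  n <- dim(od$od)[1]; nch <- dim(od$od)[2]
  # scaled OD, stacked as (2 x n*nch) for one solve
  rhs <- rbind(as.vector(od$od[, , 1]) / path[1],
               as.vector(od$od[, , 2]) / path[2])
  conc <- solve(eps, rhs)  # rows: hbo2, hbr
  dhbo <- matrix(conc[1, ], n, nch)
  dhbr <- matrix(conc[2, ], n, nch)
  colnames(dhbo) <- colnames(dhbr) <- dimnames(od$od)[[2]]
  h <- new_hemo(od$time_s, dhbo, dhbr, od$markers, od$fs_hz)
  h$meta <- od$meta
  h
}

#' Full preprocessing of one raw session
#'
#' Temporal filtering (optional), optical density, then the modified
#' Beer-Lambert conversion — the fixed pipeline order; filters act on raw
#' intensities before conversion.
#'
#' @param rec an `fnirs_recording`
#' @param optics an [optics_params()]
#' @param spec a [filter_spec()]
#' @param filter apply the temporal filters? (disable for round-trip checks)
#' @return an `fnirs_hemo`
#' @export
preprocess_session <- function(rec, optics = optics_params(),
                               spec = filter_spec(), filter = TRUE) {
  if (filter) rec <- filter_recording(rec, spec)
  mbll(to_optical_density(rec), optics)
}
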