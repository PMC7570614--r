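#' Canonical double-gamma hemodynamic response function
#'
#' The standard block-design impulse response: a gamma-density peak minus a
#' scaled, later gamma-density undershoot, normalised to unit peak so channel
#' amplitudes are interpretable as peak concentration changes.
#'
#' @param t time since stimulus onset (s); values < 0 return 0
#' @param peak_s time-to-peak of the positive lobe (s)
#' @param undershoot_s time-to-peak of the undershoot (s)
#' @param undershoot_ratio relative undershoot amplitude
#' @return numeric vector, unit peak amplitude
#' @export
hrf_double_gamma <- function(t, peak_s = 6, undershoot_s = 16,
                             undershoot_ratio = 1 / 6) {
  # unit-rate gamma densities; shape = mode + 1 puts the lobe maxima at
  # peak_s and undershoot_s
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
  h[t < 0] <- 0
  m <- max(h)
  if (m > 0) h <- h / m
  h
}

#' Task-locked activation profile for the 12 forehead channels
#'
#' Describes where and how strongly the 2-back task drives the simulated
#' hemodynamic response. The default amplitude vector concentrates activation
#' in the mid-forehead channels (5-8), with weaker responses toward the
#' temples, emulating frontopolar-dominated working-memory activation.
#' Deoxyhemoglobin is modelled as an anticorrelated, lagged copy of the
#' oxyhemoglobin response.
#'
#' @param amplitude peak task-locked change in oxygenated hemoglobin per
#'   channel (micromolar), length 12
#' @param hbr_ratio relative amplitude of the deoxyhemoglobin response
#'   (must be negative)
#' @param hbr_lag_s lag of the deoxyhemoglobin response (s)
#' @param hrf_peak_s,hrf_undershoot_s,hrf_undershoot_ratio shape of the
#'   double-gamma response, see [hrf_double_gamma()]
#' @export
effect_profile <- function(amplitude = c(0.3, 0.3, 0.6, 0.6, 1, 1, 1, 1,
                                         0.6, 0.6, 0.3, 0.3),
                           hbr_ratio = -1 / 3, hbr_lag_s = 1,
                           hrf_peak_s = 6, hrf_undershoot_s = 16,
                           hrf_undershoot_ratio = 1 / 6) {
  if (length(amplitude) != 12)
    stop("amplitude must have one entry per channel (12)")
  if (hbr_ratio >= 0) stop("hbr_ratio must be negative (anticorrelated HbR)")
  structure(list(amplitude = amplitude, hbr_ratio = hbr_ratio,
                 hbr_lag_s = hbr_lag_s, hrf_peak_s = hrf_peak_s,
                 hrf_undershoot_s = hrf_undershoot_s,
                 hrf_undershoot_ratio = hrf_undershoot_ratio),
            class = "fnirs_effect")
}

#' Physiological and instrumental noise parameters
#'
#' Sinusoidal interference at the Mayer-wave, respiratory and cardiac bands
#' (random phase per channel), slow linear drift, and white measurement
#' noise. Amplitudes are expressed in micromolar equivalents so the noise can
#' be injected directly into the concentration-change signals before the
#' forward optics.
#'
#' @param mayer_hz,mayer_amp Mayer-wave frequency (Hz) and amplitude (uM)
#' @param resp_hz,resp_amp respiration frequency (Hz) and amplitude (uM)
#' @param cardiac_hz,cardiac_amp cardiac frequency (Hz) and amplitude (uM)
#' @param drift_amp maximum linear drift magnitude (uM per minute)
#' @param white_sd white-noise standard deviation (uM)
#' @export
noise_params <- function(mayer_hz = 0.1, mayer_amp = 0.3,
                         resp_hz = 0.25, resp_amp = 0.2,
                         cardiac_hz = 1.1, cardiac_amp = 0.2,
                         drift_amp = 0.2, white_sd = 0.05) {
  stopifnot(mayer_hz > 0, resp_hz > 0, cardiac_hz > 0,
            mayer_amp >= 0, resp_amp >= 0, cardiac_amp >= 0,
            drift_amp >= 0, white_sd >= 0)
  structure(list(mayer_hz = mayer_hz, mayer_amp = mayer_amp,
                 resp_hz = resp_hz, resp_amp = resp_amp,
                 cardiac_hz = cardiac_hz, cardiac_amp = cardiac_amp,
                 drift_amp = drift_amp, white_sd = white_sd),
            class = "fnirs_noise")
}

new_hemo <- function(time_s, dhbo, dhbr, markers, fs_hz) {
  stopifnot(identical(dim(dhbo), dim(dhbr)), nrow(dhbo) == length(time_s),
            length(markers) == length(time_s))
  structure(list(time_s = time_s, dhbo = dhbo, dhbr = dhbr,
                 markers = markers, fs_hz = fs_hz),
            class = "fnirs_hemo")
}

#' @export
print.fnirs_hemo <- function(x, ...) {
  cat("fNIRS concentration-change series: ", nrow(x$dhbo), " samples x ",
      ncol(x$dhbo), " channels @ ", x$fs_hz, " Hz\n", sep = "")
  cat("  markers:", paste(sprintf("%s=%d", names(table(x$markers)),
                                  as.integer(table(x$markers))), collapse = " "), "\n")
  invisible(x)
}

#' Simulate noise-free task-locked hemodynamics
#'
#' Convolves the session's task boxcar (1 during the task block, 0 elsewhere)
#' with the double-gamma response and scales by each channel's amplitude.
#' Deoxyhemoglobin is the lagged, negatively scaled copy defined by the
#' profile. Baseline and rest decay toward zero through the kernel itself.
#'
#' @param design an [fnirs_design()]
#' @param profile an [effect_profile()]
#' @return an object of class `fnirs_hemo` with micromolar units
#' @export
simulate_hemodynamics <- function(design, profile = effect_profile()) {
  fs <- design$fs_hz
  markers <- design_markers(design)
  n <- length(markers)
  boxcar <- as.numeric(markers == "task")
  kern_t <- seq(0, 32, by = 1 / fs)
  kern <- hrf_double_gamma(kern_t, profile$hrf_peak_s, profile$hrf_undershoot_s,
                           profile$hrf_undershoot_ratio)
  # discrete convolution, truncated to the session, normalised so a
  # sustained block reaches the nominal amplitude at steady state
  resp <- convolve(boxcar, rev(kern), type = "open")[seq_len(n)] / sum(kern)
  lag_n <- as.integer(round(profile$hbr_lag_s * fs))
  resp_lag <- c(rep(0, lag_n), resp)[seq_len(n)]
  dhbo <- outer(resp, profile$amplitude)
  dhbr <- outer(resp_lag, profile$amplitude * profile$hbr_ratio)
  colnames(dhbo) <- colnames(dhbr) <- sprintf("ch%02d", 1:12)
  new_hemo(design_time(design), dhbo, dhbr, markers, fs)
}

#' Inject physiological noise into a concentration-change series
#'
#' Adds, per channel and independently for the oxy- and deoxyhemoglobin
#' series: sinusoids at the Mayer, respiratory and cardiac frequencies with
#' random phases, a random-slope linear drift, and Gaussian white noise.
#' Deterministic given the seed; zero amplitudes return the input unchanged.
#'
#' @param hemo an `fnirs_hemo`
#' @param noise a [noise_params()]
#' @param seed integer seed
#' @export
add_noise <- function(hemo, noise = noise_params(), seed = 1) {
  amps <- c(noise$mayer_amp, noise$resp_amp, noise$cardiac_amp,
            noise$drift_amp, noise$white_sd)
  if (all(amps == 0)) return(hemo)
  set.seed(seed)
  t <- hemo$time_s
  nch <- ncol(hemo$dhbo)
  mk <- function() {
    out <- matrix(0, length(t), nch)
    for (j in seq_len(nch)) {
      s <- noise$mayer_amp * sin(2 * pi * noise$mayer_hz * t + runif(1, 0, 2 * pi)) +
        noise$resp_amp   * sin(2 * pi * noise$resp_hz   * t + runif(1, 0, 2 * pi)) +
        noise$cardiac_amp * sin(2 * pi * noise$cardiac_hz * t + runif(1, 0, 2 * pi)) +
        noise$drift_amp * runif(1, -1, 1) * t / 60
      out[, j] <- s + rnorm(length(t), sd = noise$white_sd)
    }
    out
  }
  hemo$dhbo <- hemo$dhbo + mk()
  hemo$dhbr <- hemo$dhbr + mk()
  hemo
}
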