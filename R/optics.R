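#' Hemoglobin extinction coefficients
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the two
#' operating wavelengths, loaded from the packaged constants table
#' (`extdata/extinction_coefficients.csv`, values from the standard
#' Prahl/Cope compilation used throughout near-infrared spectroscopy, in
#' cm^-1 mM^-1). Returned in cm^-1 uM^-1 to match the package's micromolar
#' concentration convention.
#'
#' @param wavelengths_nm wavelengths to look up (must be present in the table)
#' @return 2x2 matrix, rows = wavelengths, columns = `c("hbo2", "hbr")`,
#'   units cm^-1 uM^-1
#' @export
extinction_coefficients <- function(wavelengths_nm = c(770, 850)) {
  path <- system.file("extdata", "extinction_coefficients.csv",
                      package = "fnirsloc", mustWork = TRUE)
  tab <- read.csv(path)
  idx <- match(wavelengths_nm, tab$wavelength_nm)
  if (anyNA(idx))
    stop("no extinction coefficients tabulated for wavelength(s) ",
         paste(wavelengths_nm[is.na(idx)], collapse = ", "), " nm")
  eps <- cbind(hbo2 = tab$eps_hbo2_cm1_mM1[idx],
               hbr = tab$eps_hbr_cm1_mM1[idx]) / 1000  # cm^-1 mM^-1 -> cm^-1 uM^-1
  rownames(eps) <- paste0(wavelengths_nm, "nm")
  eps
}

#' Optical forward-model parameters
#'
#' Geometry and optics of one source-detector channel: operating wavelengths,
#' source-detector separation, per-wavelength differential pathlength factor
#' (dimensionless multiplier on the geometric separation), extinction
#' coefficient matrix, baseline detector intensity and relative shot noise.
#'
#' @param wavelengths_nm two wavelengths (nm)
#' @param sds_cm source-detector separation (cm)
#' @param dpf differential pathlength factor per wavelength; the default
#'   (6.2, 5.1) pairs with 770 and 850 nm
#' @param eps 2x2 extinction matrix in cm^-1 uM^-1 (rows wavelengths,
#'   columns HbO2, HbR); defaults to the packaged table
#' @param i0 baseline intensity per channel (arbitrary detector units, > 0);
#'   scalar or length-12
#' @param shot_noise_rel relative (multiplicative) intensity noise SD
#' @export
optics_params <- function(wavelengths_nm = c(770, 850), sds_cm = 3,
                          dpf = c(6.2, 5.1),
                          eps = extinction_coefficients(wavelengths_nm),
                          i0 = 1, shot_noise_rel = 0) {
  stopifnot(length(wavelengths_nm) == 2, sds_cm > 0, length(dpf) == 2,
            all(dpf > 0), all(i0 > 0), shot_noise_rel >= 0)
  eps <- as.matrix(eps)
  if (!all(dim(eps) == c(2, 2)) || abs(det(eps)) < .Machine$double.eps)
    stop("eps must be an invertible 2x2 matrix (wavelengths x chromophores)")
  structure(list(wavelengths_nm = wavelengths_nm, sds_cm = sds_cm, dpf = dpf,
                 eps = eps, i0 = rep_len(i0, 12),
                 shot_noise_rel = shot_noise_rel),
            class = "fnirs_optics")
}

new_recording <- function(time_s, intensity, markers, fs_hz, meta) {
  structure(list(time_s = time_s, intensity = intensity, markers = markers,
                 fs_hz = fs_hz, meta = meta),
            class = "fnirs_recording")
}

#' @export
print.fnirs_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat("fNIRS raw recording: ", d[1], " samples x ", d[2], " channels x ",
      d[3], " wavelengths @ ", x$fs_hz, " Hz\n", sep = "")
  m <- x$meta
  if (!is.null(m$subject))
    cat(sprintf("  subject %s session %s | behavioral %.1f%% | motion %s\n",
                m$subject, m$session, m$behavioral_accuracy_pct,
                m$motion_flag))
  invisible(x)
}

#' Forward Beer-Lambert optics: concentrations to detector intensities
#'
#' Maps concentration changes to dual-wavelength raw intensities through the
#' modified Beer-Lambert law:
#' `I(t, w) = i0 * 10^(-(eps_hbo2(w) dHbO2 + eps_hbr(w) dHbR) * d * DPF(w))`,
#' optionally followed by multiplicative Gaussian shot noise. This is the
#' exact inverse of the analysis pipeline's optical-density + MBLL stage, so
#' with shot noise off the round trip recovers the input concentrations to
#' numerical precision.
#'
#' @param hemo an `fnirs_hemo` in micromolar
#' @param optics an [optics_params()]
#' @param seed seed for the shot noise (unused when `shot_noise_rel = 0`)
#' @param meta list of session metadata carried into the recording
#' @return an object of class `fnirs_recording` with an
#'   `samples x 12 x 2` intensity array
#' @export
forward_optics <- function(hemo, optics = optics_params(), seed = 1,
                           meta = list()) {
  nch <- ncol(hemo$dhbo)
  n <- nrow(hemo$dhbo)
  inten <- array(NA_real_, c(n, nch, 2),
                 dimnames = list(NULL, colnames(hemo$dhbo),
                                 paste0("w", optics$wavelengths_nm)))
  path <- optics$sds_cm * optics$dpf  # effective pathlength per wavelength
  for (w in 1:2) {
    od <- (hemo$dhbo * optics$eps[w, "hbo2"] +
             hemo$dhbr * optics$eps[w, "hbr"]) * path[w]
    inten[, , w] <- sweep(10^(-od), 2, optics$i0[seq_len(nch)], "*")
  }
  if (optics$shot_noise_rel > 0) {
    set.seed(seed)
    inten <- inten * (1 + rnorm(length(inten), sd = optics$shot_noise_rel))
    inten[inten <= 0] <- .Machine$double.eps
  }
  new_recording(hemo$time_s, inten, hemo$markers, hemo$fs_hz, meta)
}
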