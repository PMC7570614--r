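#' Forehead sensing locations and their channels
#'
#' The 12 forehead channels group into three four-channel locations (Left =
#' channels 1-4, Mid = 5-8, Right = 9-12), two ten-channel unions (Left-Mid =
#' 1-10, Right-Mid = 3-12) and the full array (Whole = 1-12).
#'
#' @param name location name; omit to list all names
#' @return integer channel indices, or the location names when `name` is
#'   missing
#' @examples
#' location_channels("Mid")
#' @export
location_channels <- function(name) {
  map <- list("Left" = 1:4, "Mid" = 5:8, "Right" = 9:12,
              "Left-Mid" = 1:10, "Right-Mid" = 3:12, "Whole" = 1:12)
  if (missing(name)) return(names(map))
  if (!name %in% names(map))
    stop("unknown location '", name, "'; one of: ",
         paste(names(map), collapse = ", "))
  map[[name]]
}

# biased (moment) skewness and non-excess kurtosis; both 0 for degenerate
# (zero-variance) input by convention so feature matrices stay complete
moment_skew <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}
moment_kurt <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^4) / m2^2
}

# least-squares slope of x against time in seconds
ls_slope <- function(t, x) {
  vt <- var(t)
  if (vt == 0) return(0)
  cov(t, x) / vt
}

#' The 11 statistical features of one channel within a segment
#'
#' Mean, variance (n-1 divisor), degree-1 least-squares slope per second,
#' moment skewness and non-excess kurtosis (a Gaussian scores 3) of the oxy-
#' and deoxyhemoglobin series — ten values — plus the Pearson correlation
#' between the two series. Zero-variance series get skewness, kurtosis and
#' correlation 0 (with a warning) so downstream matrices never contain
#' missing values.
#'
#' @param segment an `fnirs_segment`
#' @param channel channel index
#' @return named numeric vector of length 11
#' @export
channel_features <- function(segment, channel) {
  hbo <- segment$dhbo[, channel]
  hbr <- segment$dhbr[, channel]
  if (length(hbo) < 3) stop("segment too short for feature extraction")
  t <- segment$time_s
  degen <- var(hbo) == 0 || var(hbr) == 0
  if (degen)
    warning("zero-variance series in channel ", channel,
            "; skewness/kurtosis/correlation set to 0", call. = FALSE)
  corr <- if (var(hbo) == 0 || var(hbr) == 0) 0 else cor(hbo, hbr)
  vals <- c(mean(hbo), var(hbo), ls_slope(t, hbo), moment_skew(hbo),
            moment_kurt(hbo),
            mean(hbr), var(hbr), ls_slope(t, hbr), moment_skew(hbr),
            moment_kurt(hbr),
            corr)
  names(vals) <- c(
    sprintf("ch%02d_hbo_%s", channel, c("mean", "var", "slope", "skew", "kurt")),
    sprintf("ch%02d_hbr_%s", channel, c("mean", "var", "slope", "skew", "kurt")),
    sprintf("ch%02d_corr", channel))
  vals
}

#' Assemble the feature matrix for a sensing location
#'
#' One row per segment (ordered by session then start time), 11 features per
#' channel of the location — 44 columns for Left/Mid/Right, 110 for
#' Left-Mid/Right-Mid, 132 for Whole.
#'
#' @param segments list of `fnirs_segment` sharing one window length
#' @param location location name, see [location_channels()]
#' @return an object of class `fnirs_features`: list with `x` (numeric
#'   matrix), `y` (factor task/rest) and `info` (provenance data.frame)
#' @export
feature_matrix <- function(segments, location = "Whole") {
  channels <- location_channels(location)
  ws <- unique(vapply(segments, `[[`, numeric(1), "window_s"))
  if (length(ws) != 1) stop("segments mix window lengths: ",
                            paste(ws, collapse = ", "))
  ord <- order(vapply(segments, function(s) as.numeric(s$session), numeric(1)),
               vapply(segments, function(s) s$start_s, numeric(1)))
  segments <- segments[ord]
  x <- t(vapply(segments, function(s)
    unlist(lapply(channels, function(ch) channel_features(s, ch))),
    numeric(11 * length(channels))))
  if (any(!is.finite(x))) stop("non-finite feature values")
  y <- factor(vapply(segments, `[[`, character(1), "label"),
              levels = c("task", "rest"))
  info <- data.frame(
    subject = vapply(segments, `[[`, character(1), "subject"),
    session = vapply(segments, function(s) as.integer(s$session), integer(1)),
    window_s = ws,
    start_s = vapply(segments, function(s) s$start_s, numeric(1)),
    label = as.character(y))
  structure(list(x = x, y = y, info = info, location = location,
                 window_s = ws),
            class = "fnirs_features")
}

#' @export
print.fnirs_features <- function(x, ...) {
  cat(sprintf("fNIRS feature matrix: %d samples x %d features (%s, %g s window; %d task / %d rest)\n",
              nrow(x$x), ncol(x$x), x$location, x$window_s,
              sum(x$y == "task"), sum(x$y == "rest")))
  invisible(x)
}
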