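#' Write a recording as CSV plus JSON sidecar
#'
#' The CSV holds the sample grid, the 24 intensity columns
#' (`ch01_770, ch01_850, ..., ch12_850`) and the per-sample marker; the
#' sidecar holds the session metadata. Numbers are written with `%.10g`
#' precision so a write/read cycle is lossless at that precision.
#'
#' @param rec an `fnirs_recording` with subject/session metadata
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written (`csv`, `json`)
#' @export
write_session <- function(rec, dir) {
  stopifnot(inherits(rec, "fnirs_recording"))
  m <- rec$meta
  if (is.null(m$subject) || is.null(m$session))
    stop("recording metadata must include subject and session")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sprintf("%s_sess%02d", m$subject, m$session)
  csv <- file.path(dir, paste0(stem, ".csv"))
  json <- file.path(dir, paste0(stem, ".json"))

  wl <- m$wavelengths_nm %||% c(770, 850)
  cols <- list(time_s = sprintf("%.10g", rec$time_s))
  for (ch in 1:12) for (w in 1:2)
    cols[[sprintf("ch%02d_%d", ch, wl[w])]] <-
      sprintf("%.10g", rec$intensity[, ch, w])
  cols$marker <- rec$markers
  con <- file(csv, open = "wb")  # binary mode forces LF endings
  writeLines(c(paste(names(cols), collapse = ","),
               do.call(paste, c(unname(cols), sep = ","))), con)
  close(con)
  jsonlite::write_json(m[c("subject", "session", "fs_hz", "wavelengths_nm",
                           "sds_cm", "dpf", "behavioral_accuracy_pct",
                           "motion_flag", "seed")],
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(csv = csv, json = json))
}

#' Read a session CSV and its JSON sidecar back into a recording
#'
#' @param csv_path path to the session CSV; the sidecar is expected next to
#'   it with extension `.json`
#' @export
read_session <- function(csv_path) {
  json_path <- sub("\\.csv$", ".json", csv_path)
  if (!file.exists(json_path))
    stop("missing JSON sidecar: expected ", json_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  dat <- read.csv(csv_path, check.names = FALSE)
  wl <- meta$wavelengths_nm
  inten <- array(NA_real_, c(nrow(dat), 12, 2),
                 dimnames = list(NULL, sprintf("ch%02d", 1:12),
                                 paste0("w", wl)))
  for (ch in 1:12) for (w in 1:2) {
    col <- sprintf("ch%02d_%d", ch, wl[w])
    if (!col %in% names(dat)) stop("session CSV lacks column ", col)
    inten[, ch, w] <- dat[[col]]
  }
  bad <- which(apply(inten <= 0 | !is.finite(inten), 1, any))
  if (length(bad))
    stop("non-positive intensity in ", basename(csv_path),
         " at data row ", bad[1])
  new_recording(dat$time_s, inten, dat$marker, meta$fs_hz, meta)
}

#' Write a concentration-change series as CSV
#'
#' Columns `time_s, ch01_hbo, ch01_hbr, ..., ch12_hbr, marker`, micromolar.
#' @param hemo an `fnirs_hemo`
#' @param path output CSV path
#' @export
write_hemo <- function(hemo, path) {
  cols <- list(time_s = sprintf("%.10g", hemo$time_s))
  for (ch in seq_len(ncol(hemo$dhbo))) {
    cols[[sprintf("ch%02d_hbo", ch)]] <- sprintf("%.10g", hemo$dhbo[, ch])
    cols[[sprintf("ch%02d_hbr", ch)]] <- sprintf("%.10g", hemo$dhbr[, ch])
  }
  cols$marker <- hemo$markers
  con <- file(path, open = "wb")
  writeLines(c(paste(names(cols), collapse = ","),
               do.call(paste, c(unname(cols), sep = ","))), con)
  close(con)
  invisible(path)
}

#' Read a concentration-change CSV written by [write_hemo()]
#' @param path CSV path
#' @param fs_hz sampling rate; inferred from the time grid when `NULL`
#' @export
read_hemo <- function(path, fs_hz = NULL) {
  dat <- read.csv(path, check.names = FALSE)
  hbo_cols <- grep("_hbo$", names(dat), value = TRUE)
  nch <- length(hbo_cols)
  dhbo <- as.matrix(dat[hbo_cols])
  dhbr <- as.matrix(dat[sub("_hbo$", "_hbr", hbo_cols)])
  colnames(dhbo) <- colnames(dhbr) <- sprintf("ch%02d", seq_len(nch))
  if (is.null(fs_hz)) fs_hz <- 1 / stats::median(diff(dat$time_s))
  new_hemo(dat$time_s, dhbo, dhbr, dat$marker, fs_hz)
}

#' Read a simulation/pipeline configuration file (JSON or YAML)
#'
#' Field names mirror the constructor arguments of [sim_config()] and the
#' pipeline settings of [run_config()]. A config read, written and re-read
#' round-trips identically.
#'
#' @param path `.json`, `.yaml` or `.yml` file
#' @return a named list
#' @export
read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write a configuration list as JSON
#' @param config named list
#' @param path output path
#' @export
write_config_file <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
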