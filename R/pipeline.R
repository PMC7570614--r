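#' Full-run configuration
#'
#' Bundles the simulation settings with the pipeline settings used by
#' [run_all()]. Every stochastic stage derives its seed deterministically
#' from the master seed, so a configuration plus a seed fully determines
#' every output file.
#'
#' @param simulation a [sim_config()]
#' @param locations,windows analysis grid
#' @param methods selection methods (see [run_grid()])
#' @param min_behavioral_pct,drop_motion screening rule
#' @param fspec a [filter_spec()]
#' @param policy a [segmentation_policy()]-shaped data.frame
#' @param spec a [classifier_spec()]
#' @param paper_mode selection before (TRUE) or inside (FALSE) the outer CV
#' @param alpha significance level for the location comparisons
#' @param seed master seed
#' @export
run_config <- function(simulation = sim_config(),
                       locations = location_channels(),
                       windows = segmentation_policy()$window_s,
                       methods = c("relief", "sfs"),
                       min_behavioral_pct = 90, drop_motion = TRUE,
                       fspec = filter_spec(), policy = segmentation_policy(),
                       spec = classifier_spec(), paper_mode = FALSE,
                       alpha = 0.05, seed = 1) {
  structure(list(simulation = simulation, locations = locations,
                 windows = windows, methods = methods,
                 min_behavioral_pct = min_behavioral_pct,
                 drop_motion = drop_motion, fspec = fspec, policy = policy,
                 spec = spec, paper_mode = paper_mode, alpha = alpha,
                 seed = as.integer(seed)),
            class = "fnirs_run_config")
}

#' Run the whole pipeline end to end
#'
#' Simulate -> write session files -> screen -> preprocess -> segment ->
#' extract features -> nested-CV classification per (subject, location,
#' window) -> summary statistics and location-vs-Whole t-tests -> report.
#' Writes everything under `out_dir` plus `manifest.csv` with an md5 checksum
#' of every artifact; a rerun with the same configuration and seed
#' reproduces identical session, accuracy and comparison files.
#'
#' @param config a [run_config()]
#' @param out_dir output directory
#' @param quiet suppress progress messages
#' @return invisibly, a list with `accuracies`, `summary`, `comparisons`,
#'   `files`
#' @export
run_all <- function(config = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "fnirs_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  say("stage simulate: ", config$simulation$n_subjects, " subjects x ",
      config$simulation$n_sessions, " sessions (seed ", config$seed, ")")
  recs <- simulate_dataset(config$simulation, seed = config$seed)
  sess_dir <- file.path(out_dir, "sessions")
  for (r in recs) write_session(r, sess_dir)

  kept <- screen_sessions(recs, config$min_behavioral_pct,
                          config$drop_motion, quiet = quiet)
  say("stage screen: kept ", length(kept), " of ", length(recs), " sessions")
  if (!length(kept)) stop("stage screen: no sessions left to analyse")

  say("stage classify: ", length(unique(vapply(kept, function(r)
    r$meta$subject, character(1)))), " subjects x ",
    length(config$locations), " locations x ", length(config$windows),
    " windows")
  acc <- run_grid(kept, locations = config$locations,
                  windows = config$windows, methods = config$methods,
                  seed = derive_seed(config$seed, "classify"),
                  fspec = config$fspec, policy = config$policy,
                  spec = config$spec, paper_mode = config$paper_mode,
                  optics = config$simulation$optics,
                  screen = FALSE, quiet = quiet)
  say("stage classify: ", nrow(acc), " dataset outcomes")

  files <- location_report(acc, out_dir, alpha = config$alpha)
  cfg_path <- file.path(out_dir, "run_config.json")
  write_config_file(list(seed = config$seed,
                         n_subjects = config$simulation$n_subjects,
                         n_sessions = config$simulation$n_sessions,
                         locations = config$locations,
                         windows = config$windows,
                         methods = config$methods,
                         min_behavioral_pct = config$min_behavioral_pct,
                         drop_motion = config$drop_motion,
                         paper_mode = config$paper_mode,
                         alpha = config$alpha), cfg_path)

  arts <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                  file.path(out_dir, "manifest.csv"))
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", arts),
                         md5 = unname(tools::md5sum(arts)))
  manifest <- manifest[order(manifest$file), ]
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  say("wrote ", nrow(manifest), " artifacts to ", out_dir)

  invisible(list(accuracies = acc, summary = accuracy_summary(acc),
                 comparisons = ttest_vs_whole(acc, alpha = config$alpha),
                 files = c(files, config = cfg_path,
                           manifest = file.path(out_dir, "manifest.csv"))))
}
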