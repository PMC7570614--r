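#' Simulation configuration for a multi-subject study
#'
#' Bundles the session design, activation profile, noise model, optics and
#' behavioural parameters for [simulate_dataset()]. Defaults reproduce the
#' study conditions the pipeline targets: 8 subjects with 10 sessions each,
#' behavioural 2-back accuracy drawn from a Gaussian (mean 96, SD 4) clipped
#' to [0, 100] so the 90 % screening rule occasionally fires, and a 5 %
#' chance of a motion-contaminated session.
#'
#' @param n_subjects,n_sessions study size
#' @param design an [fnirs_design()]
#' @param profile an [effect_profile()]
#' @param noise a [noise_params()]
#' @param optics an [optics_params()]
#' @param behav_mean,behav_sd behavioural accuracy distribution (%)
#' @param motion_prob probability a session is flagged for motion
#' @export
sim_config <- function(n_subjects = 8, n_sessions = 10,
                       design = fnirs_design(), profile = effect_profile(),
                       noise = noise_params(), optics = optics_params(),
                       behav_mean = 96, behav_sd = 4, motion_prob = 0.05) {
  stopifnot(n_subjects >= 1, n_sessions >= 1,
            motion_prob >= 0, motion_prob <= 1, behav_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 design = design, profile = profile, noise = noise,
                 optics = optics, behav_mean = behav_mean,
                 behav_sd = behav_sd, motion_prob = motion_prob),
            class = "fnirs_sim_config")
}

#' Simulate one recording session
#'
#' Ground-truth hemodynamics, physiological noise, forward optics and
#' behavioural metadata for a single (subject, session) pair. All randomness
#' derives from `seed`.
#'
#' @param config a [sim_config()]
#' @param subject,session 1-based indices
#' @param seed integer seed for this session
#' @return an `fnirs_recording`
#' @export
simulate_session <- function(config, subject, session, seed) {
  hemo <- simulate_hemodynamics(config$design, config$profile)
  hemo <- add_noise(hemo, config$noise, seed = derive_seed(seed, "noise"))
  set.seed(derive_seed(seed, "behavior"))
  behav <- min(100, max(0, rnorm(1, config$behav_mean, config$behav_sd)))
  motion <- runif(1) < config$motion_prob
  meta <- list(subject = sprintf("sub%02d", subject),
               session = as.integer(session),
               fs_hz = config$design$fs_hz,
               wavelengths_nm = config$optics$wavelengths_nm,
               sds_cm = config$optics$sds_cm, dpf = config$optics$dpf,
               behavioral_accuracy_pct = behav, motion_flag = motion,
               seed = as.integer(seed))
  forward_optics(hemo, config$optics, seed = derive_seed(seed, "shot"),
                 meta = meta)
}

#' Simulate a full multi-subject dataset
#'
#' Produces `n_subjects * n_sessions` recordings, each fully reproducible
#' from `(config, seed)`: every session uses a sub-seed derived from the
#' master seed and its (subject, session) index.
#'
#' @param config a [sim_config()]
#' @param seed master seed
#' @return list of `fnirs_recording`, ordered by subject then session
#' @examples
#' recs <- simulate_dataset(sim_config(n_subjects = 1, n_sessions = 2), seed = 7)
#' length(recs)
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  recs <- vector("list", config$n_subjects * config$n_sessions)
  k <- 0
  for (s in seq_len(config$n_subjects)) {
    for (j in seq_len(config$n_sessions)) {
      k <- k + 1
      recs[[k]] <- simulate_session(
        config, s, j, derive_seed(seed, sprintf("session_%02d_%02d", s, j)))
    }
  }
  recs
}
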