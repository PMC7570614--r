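make_rec <- function(behav, motion, subject = "sub01", session = 1L) {
  h <- simulate_hemodynamics(fnirs_design(),
                             effect_profile(amplitude = rep(0, 12)))
  forward_optics(h, optics_params(),
                 meta = list(subject = subject, session = session,
                             behavioral_accuracy_pct = behav,
                             motion_flag = motion))
}

test_that("screening drops low behavioural accuracy and motion sessions", {
  recs <- list(make_rec(89, FALSE), make_rec(95, TRUE, session = 2L),
               make_rec(90, FALSE, session = 3L),
               make_rec(99, FALSE, session = 4L))
  kept <- suppressMessages(screen_sessions(recs))
  expect_length(kept, 2)
  expect_equal(vapply(kept, function(r) r$meta$session, integer(1)), 3:4)
  # all passing -> identity
  ok <- recs[3:4]
  expect_identical(suppressMessages(screen_sessions(ok)), ok)
  # threshold is >=: exactly 90 survives, 89 does not
  expect_warning(
    expect_length(suppressMessages(screen_sessions(recs[1])), 0),
    "all sessions")
})

test_that("band-pass passes 0.1 Hz, rejects 1.1 Hz, keeps zero at zero", {
  fs <- 25
  t <- seq(0, 82.96, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  core <- 200:1800  # away from filter edge transients
  expect_true(all(bandpass_filter(rep(0, length(t)), fs) == 0))
  stopb <- bandpass_filter(sin(2 * pi * 1.1 * t), fs)
  expect_lt(rms(stopb[core]), 0.1 * rms(sin(2 * pi * 1.1 * t)[core]))
  passb <- bandpass_filter(sin(2 * pi * 0.1 * t), fs)
  ratio <- rms(passb[core]) / rms(sin(2 * pi * 0.1 * t)[core])
  expect_gt(ratio, 0.5); expect_lt(ratio, 2)
  expect_error(bandpass_filter(t, fs, filter_spec(band_hz = c(0.01, 13))),
               "fs/2")
})

test_that("moving average: constant invariant, 1-sample identity, variance ~ 1/w", {
  expect_equal(moving_average(rep(3.3, 100), 25, 2), rep(3.3, 100))
  x <- rnorm(100)
  expect_equal(moving_average(x, 25, 1 / 25), x)
  set.seed(7)
  w <- rnorm(20000)
  sm <- moving_average(w, 25, 2)  # 50-sample window
  interior <- sm[100:19900]
  expect_equal(var(interior) * 50, 1, tolerance = 0.2)
})

test_that("optical density follows the log10 baseline-ratio definition", {
  d <- fnirs_design()
  h0 <- simulate_hemodynamics(d, effect_profile(amplitude = rep(0, 12)))
  rec <- forward_optics(h0, optics_params(i0 = 4))
  od <- to_optical_density(rec)
  expect_true(all(od$od == 0))  # I == I0 everywhere

  # drop one sample to I0/10 -> dOD exactly 1 there
  rec2 <- rec
  rec2$intensity[500, 3, 1] <- 0.4
  od2 <- to_optical_density(rec2)
  i0_hat <- mean(rec2$intensity[rec2$markers == "baseline", 3, 1])
  expect_equal(od2$od[500, 3, 1], -log10(0.4 / i0_hat))
  rec_bad <- rec
  rec_bad$intensity[1, 1, 1] <- -1
  expect_error(to_optical_density(rec_bad), "non-positive")
})

test_that("baseline intensity is the arithmetic mean of the first 10 s", {
  d <- fnirs_design()
  h <- simulate_hemodynamics(d)
  rec <- forward_optics(add_noise(h, noise_params(), seed = 3),
                        optics_params())
  idx <- which(rec$markers == "baseline")
  expect_length(idx, 250)
  od <- to_optical_density(rec)
  i0 <- mean(rec$intensity[idx, 7, 2])
  expect_equal(od$od[, 7, 2], -log10(rec$intensity[, 7, 2] / i0))
})

test_that("Beer-Lambert inversion matches the closed-form 2x2 solution", {
  eps <- matrix(c(6.5e-4, 1.0580e-3, 1.3622e-3, 6.913e-4), 2, 2,
                dimnames = list(c("770nm", "850nm"), c("hbo2", "hbr")))
  opt <- optics_params(eps = eps)
  d <- opt$sds_cm; dpf <- opt$dpf
  od_pair <- c(0.012, 0.009)
  od <- structure(list(
    time_s = 0:2 / 25,
    od = array(rep(od_pair, each = 3), c(3, 1, 2)),
    markers = rep("task", 3), fs_hz = 25, meta = NULL),
    class = "fnirs_od")
  h <- mbll(od, opt)
  # hand inversion: [a b; c d]^-1 = 1/det [d -b; -c a]
  y <- od_pair / (d * dpf)
  det <- eps[1, 1] * eps[2, 2] - eps[1, 2] * eps[2, 1]
  hbo <- (eps[2, 2] * y[1] - eps[1, 2] * y[2]) / det
  hbr <- (-eps[2, 1] * y[1] + eps[1, 1] * y[2]) / det
  expect_equal(unname(h$dhbo[1, 1]), hbo)
  expect_equal(unname(h$dhbr[1, 1]), hbr)
  # zero OD -> zero concentrations; doubling OD doubles both
  od0 <- od; od0$od[] <- 0
  expect_true(all(mbll(od0, opt)$dhbo == 0))
  od2 <- od; od2$od <- 2 * od$od
  expect_equal(mbll(od2, opt)$dhbo, 2 * h$dhbo)
  expect_error(optics_params(eps = matrix(1, 2, 2)), "invertible")
})

test_that("temporal filtering preserves markers and signal shape", {
  cfg <- sim_config(n_subjects = 1, n_sessions = 1)
  rec <- simulate_dataset(cfg, seed = 3)[[1]]
  f <- filter_recording(rec)
  expect_identical(f$markers, rec$markers)
  expect_identical(dim(f$intensity), dim(rec$intensity))
  h <- preprocess_session(rec)
  expect_identical(h$markers, rec$markers)
})
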