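test_that("zero activation gives identically zero hemodynamics", {
  h <- simulate_hemodynamics(fnirs_design(),
                             effect_profile(amplitude = rep(0, 12)))
  expect_true(all(h$dhbo == 0))
  expect_true(all(h$dhbr == 0))
})

test_that("task-locked response raises task-epoch oxyhemoglobin above rest", {
  h <- simulate_hemodynamics(fnirs_design())
  for (ch in c(1, 6, 12)) {
    expect_gt(mean(h$dhbo[h$markers == "task", ch]),
              mean(h$dhbo[h$markers == "rest", ch]))
    # HbR anticorrelated with HbO by construction
    expect_lt(mean(h$dhbr[h$markers == "task", ch]), 0)
  }
  # baseline is causally silent: boxcar has not started (FFT roundoff only)
  expect_lt(max(abs(h$dhbo[h$markers == "baseline", ])), 1e-9)
})

test_that("response peak matches a brute-force convolution of kernel and boxcar", {
  d <- fnirs_design()
  prof <- effect_profile(amplitude = c(1, rep(0, 11)))
  h <- simulate_hemodynamics(d, prof)
  fs <- d$fs_hz
  boxcar <- as.numeric(design_markers(d) == "task")
  kern <- hrf_double_gamma(seq(0, 32, by = 1 / fs))
  n <- length(boxcar)
  direct <- numeric(n)
  for (i in seq_len(n)) {
    jmax <- min(i, length(kern))
    direct[i] <- sum(boxcar[i - seq_len(jmax) + 1] * kern[seq_len(jmax)])
  }
  direct <- direct / sum(kern)
  expect_equal(which.max(h$dhbo[, 1]), which.max(direct))
  expect_equal(h$dhbo[, 1], direct, tolerance = 1e-10)
})

test_that("noise injection is seed-deterministic and silent at zero amplitude", {
  h <- simulate_hemodynamics(fnirs_design())
  zero <- noise_params(mayer_amp = 0, resp_amp = 0, cardiac_amp = 0,
                       drift_amp = 0, white_sd = 0)
  expect_identical(add_noise(h, zero, seed = 1), h)
  n1 <- add_noise(h, noise_params(), seed = 9)
  n2 <- add_noise(h, noise_params(), seed = 9)
  n3 <- add_noise(h, noise_params(), seed = 10)
  expect_identical(n1, n2)
  expect_false(identical(n1$dhbo, n3$dhbo))
})

test_that("each injected sinusoid peaks at its configured frequency", {
  h <- simulate_hemodynamics(fnirs_design())
  for (band in list(c("cardiac", 1.1), c("mayer", 0.1), c("resp", 0.25))) {
    np <- noise_params(mayer_amp = 0, resp_amp = 0, cardiac_amp = 0,
                       drift_amp = 0, white_sd = 0)
    np[[paste0(band[1], "_amp")]] <- 0.2
    noisy <- add_noise(h, np, seed = 4)
    delta <- noisy$dhbo[, 3] - h$dhbo[, 3]
    sp <- stats::spec.pgram(stats::ts(delta, frequency = 25), plot = FALSE,
                            taper = 0)
    f_peak <- sp$freq[which.max(sp$spec)]
    expect_lt(abs(f_peak - as.numeric(band[2])), 2 * diff(sp$freq[1:2]))
  }
})

test_that("forward optics is the exact inverse of OD + Beer-Lambert", {
  # noise off: the baseline is exactly zero, so the estimated baseline
  # intensity equals the true i0 and the inversion is exact
  h <- simulate_hemodynamics(fnirs_design())
  opt <- optics_params(shot_noise_rel = 0)
  rec <- forward_optics(h, opt)
  expect_true(all(rec$intensity > 0))
  back <- mbll(to_optical_density(rec), opt)
  denom <- pmax(abs(h$dhbo), 1e-3)
  expect_lt(max(abs(back$dhbo - h$dhbo) / denom), 1e-6)
  expect_lt(max(abs(back$dhbr - h$dhbr) / pmax(abs(h$dhbr), 1e-3)), 1e-6)
})

test_that("zero concentrations give constant intensity; exponent is linear", {
  d <- fnirs_design()
  h0 <- simulate_hemodynamics(d, effect_profile(amplitude = rep(0, 12)))
  opt <- optics_params(i0 = 2.5)
  rec0 <- forward_optics(h0, opt)
  expect_true(all(rec0$intensity == 2.5))

  h1 <- simulate_hemodynamics(d)
  h2 <- h1; h2$dhbo <- 2 * h1$dhbo; h2$dhbr <- 2 * h1$dhbr
  r1 <- forward_optics(h1, opt); r2 <- forward_optics(h2, opt)
  expect_equal(-log10(r2$intensity / 2.5), 2 * -log10(r1$intensity / 2.5),
               tolerance = 1e-10)
})

test_that("dataset simulation is reproducible and sized n_subjects x n_sessions", {
  cfg <- sim_config(n_subjects = 2, n_sessions = 3)
  a <- simulate_dataset(cfg, seed = 5)
  b <- simulate_dataset(cfg, seed = 5)
  expect_length(a, 6)
  expect_identical(a, b)
  expect_length(simulate_dataset(sim_config(n_subjects = 1, n_sessions = 1),
                                 seed = 1), 1)
  subj <- vapply(a, function(r) r$meta$subject, character(1))
  expect_equal(unique(subj), c("sub01", "sub02"))
})
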