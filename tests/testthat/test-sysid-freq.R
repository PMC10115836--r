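test_that("coherence is 1 for a noise-free linear pair and scale-invariant", {
  stim <- generate_triangular_stimulus(triangular_schedule(), 4, fs = 120)
  y <- dplyr::mutate(stim, value = 2 * value)
  sp <- estimate_spectra(stim, y)
  expect_true(all(sp$coherence >= 0 & sp$coherence <= 1))
  expect_true(all(abs(sp$coherence - 1) < 1e-6))

  sp_scaled <- estimate_spectra(dplyr::mutate(stim, value = 10 * value),
                                dplyr::mutate(y, value = 0.1 * value))
  expect_equal(sp$coherence, sp_scaled$coherence, tolerance = 1e-10)
  expect_error(estimate_spectra(stim, y[-1, ]), "equal length")
})

test_that("independent noise stays below the coherence bias floor", {
  set.seed(42)
  n <- 4096; fs <- 100
  x <- tibble::tibble(t = (0:(n - 1)) / fs, value = rnorm(n))
  y <- tibble::tibble(t = (0:(n - 1)) / fs, value = rnorm(n))
  sp <- estimate_spectra(x, y)
  k_seg <- length(seq(1, n - 1024 + 1, by = 512))
  expect_lt(mean(sp$coherence), 2 / k_seg)
})

test_that("coherence follows the analytic SNR relation in band", {
  set.seed(7)
  n <- 8192; fs <- 100
  x <- tibble::tibble(t = (0:(n - 1)) / fs, value = rnorm(n))
  for (r in c(1, 3)) {
    y <- tibble::tibble(t = x$t, value = x$value + rnorm(n) / r)
    sp <- estimate_spectra(x, y)
    # Welch coherence carries a positive finite-average bias of order 1/K
    expect_equal(mean(sp$coherence), r^2 / (1 + r^2), tolerance = 0.1)
  }
})

test_that("CZT agrees with the FFT on coincident grids and zooms finer", {
  set.seed(3)
  n <- 256; fs <- 64
  sig <- tibble::tibble(t = (0:(n - 1)) / fs, value = rnorm(n))
  ff <- fft(sig$value)
  # CZT over bins 8..32 of the FFT grid
  k1 <- 8; k2 <- 32
  cz <- czt_spectrum(sig, k1 * fs / n, k2 * fs / n, n_points = k2 - k1 + 1)
  expect_equal(cz$spectrum, ff[(k1 + 1):(k2 + 1)], tolerance = 1e-10)

  # pure sinusoid peaks at the nearest grid point to its frequency
  f0 <- 5.13
  sine <- tibble::tibble(t = sig$t, value = sin(2 * pi * f0 * sig$t))
  zoom <- czt_spectrum(sine, 4, 6, n_points = 201)
  expect_equal(zoom$freq[which.max(Mod(zoom$spectrum))], f0, tolerance = 0.011)

  # zoom band on a short record: >= 10x finer than the raw FFT grid
  rec <- tibble::tibble(t = (0:479) / 120, value = rnorm(480))
  zoom2 <- czt_spectrum(rec, 0.05, 1.15, n_points = 64)
  expect_lt(diff(zoom2$freq[1:2]), (120 / 480) / 10)
  expect_error(czt_spectrum(rec, 0.05, 80), "Nyquist")
})

test_that("empirical FRF reproduces trivial and analytic responses", {
  trial <- example_trial_noisefree()
  sig <- trial_signals(trial)

  # resp == stim -> H == 1
  frf_id <- empirical_frf(sig$stim, sig$stim, band = c(0.25, 5))
  expect_true(all(Mod(frf_id$response - 1) < 1e-9))

  # worked-example model: magnitude within 2%, phase within 2 degrees
  # over the strongly excited part of the band
  frf <- empirical_frf(sig$stim, sig$resp, band = c(0.25, 2))
  truth <- tf_eval(eq_example_model("freq"), frf$freq)
  expect_true(all(Mod(frf$response) / Mod(truth) < 1.02 &
                  Mod(frf$response) / Mod(truth) > 0.98))
  dphase <- Arg(frf$response / truth)
  expect_true(all(abs(dphase) < 2 * pi / 180))

  # pure delay: unwrapped phase is -omega tau. The stimulus record is one
  # whole cycle, so the steady-state delayed response is its circular shift.
  nrec <- nrow(sig$stim)
  shift <- 6                                   # 50 ms at 120 Hz
  delayed <- tibble::tibble(
    t = sig$stim$t,
    value = sig$stim$value[((seq_len(nrec) - 1 - shift) %% nrec) + 1]
  )
  frf_d <- empirical_frf(sig$stim, delayed, band = c(0.25, 5))
  expect_equal(Arg(frf_d$response * exp(2i * pi * frf_d$freq * 0.05)),
               rep(0, nrow(frf_d)), tolerance = 1e-6)
})

test_that("score_model anchors at 100 for a perfect model and errors on p >= K", {
  trial <- example_trial_noisefree()
  sig <- trial_signals(trial)
  frf <- empirical_frf(sig$stim, sig$resp, band = c(0.25, 5))
  sc <- score_model(frf, eq_example_model("freq"))
  expect_gt(sc$fit_percent, 99.9)
  expect_lt(sc$mse, 1e-8 * max(frf$weight)^2)

  big <- tf_model(rep(1, 10), c(1, rep(0.1, 9)))
  expect_error(score_model(frf, big), "p >= K")
})

test_that("structure selection reproduces the worked-example ranking", {
  # light measurement noise, as in a realistic record: the 3-pole/3-zero
  # structure wins over both the underparameterized and the inflated one
  trial <- make_tracking_trial(eq_example_model("freq"), duration = 4,
                               snr = 50, seed = 5)
  res <- identify_visuomotor(trial)
  fit <- res$fit[[1]]
  crit <- fit$criteria[fit$criteria$delay_kind == "pure", ]
  expect_equal(crit$n_poles[1], 3)
  expect_equal(crit$n_zeros[1], 3)
  expect_gt(crit$fit_percent[1], 90)
  # (2,1) is far worse, matching the reported ordering
  f21 <- crit$fit_percent[crit$n_poles == 2 & crit$n_zeros == 1]
  expect_lt(f21, crit$fit_percent[1] - 5)
  # the winning delay is the generating 15 ms (1 ms grid)
  expect_lt(abs(res$delay_s - 0.015), 0.0015)
})

test_that("pure delay structure beats its linear approximation on pure-delay data", {
  trial <- example_trial_noisefree()
  sig <- trial_signals(trial)
  frf <- empirical_frf(sig$stim, sig$resp, band = c(0.25, 5))
  fit <- fit_tf_with_delay(frf, orders = list(c(3, 3)),
                           delay_grid = seq(0, 0.05, by = 0.001))
  kinds <- fit$criteria$delay_kind
  fits <- fit$criteria$fit_percent
  expect_gt(fits[kinds == "pure"], fits[kinds == "linear_approx"])
  expect_equal(fit$model$delay_kind, "pure")
})

test_that("noise-free delay recovery is exact on the 1 ms grid", {
  for (tau in c(0.005, 0.015, 0.040, 0.100)) {
    m <- eq_example_model("freq")
    m_tau <- tf_model(m$num, m$den, tau = tau)
    trial <- make_tracking_trial(m_tau, duration = 4)
    sig <- trial_signals(trial)
    frf <- empirical_frf(sig$stim, sig$resp, band = c(0.25, 8))
    fit <- fit_tf_with_delay(frf, orders = list(c(3, 3)), kinds = "pure")
    expect_equal(fit$model$tau, tau, tolerance = 1e-9)
    expect_gt(fit$criteria$fit_percent[1], 99.9)
  }
})

test_that("self-consistency: an exactly representable FRF scores FIT ~ 100", {
  trial <- example_trial_noisefree()
  sig <- trial_signals(trial)
  frf <- empirical_frf(sig$stim, sig$resp, band = c(0.25, 5))
  fit <- fit_tf_with_delay(frf, orders = list(c(3, 3)),
                           delay_grid = c(0.010, 0.015, 0.020), kinds = "pure")
  expect_gt(fit$criteria$fit_percent[1], 99.9)
  expect_equal(fit$status, "ok")
})
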