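#' Generate one identification trial at periodic steady state
#'
#' Emulates one recorded tracking bout: the triangular stimulus runs
#' continuously and the analysed record is an excised window of steady
#' tracking. The responder is simulated at an internally oversampled rate
#' (the delay is applied to the piecewise-linear stimulus, where fractional
#' interpolation is exact), started from the exact periodic steady state
#' (solving x0 = Phi_cycle x0 + g), and both channels are then decimated to
#' the camera rate through one shared zero-phase anti-alias FIR - a common
#' filter cancels exactly in the frequency-response ratio. The record is
#' trimmed to whole stimulus cycles so the analysis grid is leakage-free;
#' measurement noise is added at the camera rate.
#'
#' @param model A [tf_model()] (pure delay kind for the transport-delay
#'   path).
#' @param schedule A [triangular_schedule()].
#' @param duration Requested record length in seconds; trimmed down to a
#'   whole number of stimulus cycles (at least one).
#' @param fs Camera sampling rate in Hz.
#' @param snr Amplitude signal-to-noise ratio for the response, or NULL.
#' @param seed Seed for the noise draw.
#' @param oversample Internal simulation rate multiplier (default 10).
#' @return A tibble with columns `t`, `stimulus`, `response`.
#' @export
#' @examples
#' trial <- make_tracking_trial(eq_example_model("freq"), duration = 4)
#' nrow(trial) / 120 # 3.75 s: one whole stimulus cycle
make_tracking_trial <- function(model, schedule = triangular_schedule(),
                                duration = 4, fs = 120, snr = NULL,
                                seed = NULL, oversample = 10) {
  stopifnot(inherits(model, "tf_model"))
  period <- schedule_period(schedule)
  n_cycles <- max(1L, floor(duration / period + 1e-9))
  fsi <- fs * oversample

  cyc <- generate_triangular_stimulus(schedule, period, fs = fsi)$value
  np <- length(cyc)
  if (np %% oversample != 0) {
    abort("schedule period must be a whole number of camera-rate samples")
  }
  u_del <- if (model$delay_kind == "pure" && model$tau > 0) {
    shift_fractional(rep(cyc, 2), model$tau, fsi)[(np + 1):(2 * np)]
  } else cyc

  dss <- discretize_foh(tf_to_ss(model), fsi)
  x0 <- steady_state_x0(dss, u_del)

  # one guard cycle each side of the analysis cycles for the FIR edges
  total_cycles <- n_cycles + 2L
  u_fine <- rep(cyc, total_cycles)
  y_fine <- run_foh(dss, rep(u_del, total_cycles), x0)$y

  fir <- aa_fir(oversample)
  u_cam <- decimate_shared(u_fine, fir, oversample)
  y_cam <- decimate_shared(y_fine, fir, oversample)
  np_cam <- np / oversample
  keep <- (np_cam + 1):(np_cam * (n_cycles + 1))
  u_cam <- u_cam[keep]; y_cam <- y_cam[keep]

  if (!is.null(snr)) {
    if (is.null(seed)) abort("`seed` is required when `snr` is given")
    y_cam <- y_cam + scaled_noise(y_cam, snr, seed)
  }
  tibble(
    t = (seq_along(u_cam) - 1) / fs,
    stimulus = u_cam,
    response = y_cam
  )
}

# internal: exact periodic steady-state initial condition for a
# FOH-discretized system driven by one periodic input cycle
steady_state_x0 <- function(dss, u_cycle) {
  n <- dss$order
  if (n == 0L) return(numeric(0))
  np <- length(u_cycle)
  uw <- c(u_cycle, u_cycle[1])
  x <- rep(0, n)
  for (k in seq_len(np)) {
    x <- dss$phi %*% x + dss$g0 * uw[k] + dss$g1 * (uw[k + 1] - uw[k]) / dss$ts
  }
  phin <- diag(n)
  pp <- dss$phi
  e <- np
  while (e > 0) {
    if (e %% 2) phin <- pp %*% phin
    pp <- pp %*% pp
    e <- e %/% 2
  }
  as.numeric(solve(diag(n) - phin, x))
}

# internal: zero-phase Blackman windowed-sinc lowpass for decimation by q
aa_fir <- function(q, taps_per_q = 100) {
  l <- taps_per_q * q + 1L
  m <- (-(l - 1) / 2):((l - 1) / 2)
  fc <- 0.45 / q
  h <- ifelse(m == 0, 2 * fc, sin(2 * pi * fc * m) / (pi * m))
  idx <- 0:(l - 1)
  w <- 0.42 - 0.5 * cos(2 * pi * idx / (l - 1)) + 0.08 * cos(4 * pi * idx / (l - 1))
  h <- h * w
  h / sum(h)
}

decimate_shared <- function(v, fir, q) {
  filt <- stats::filter(v, fir, sides = 2)
  as.numeric(filt[seq(1, length(v), by = q)])
}

#' Worked-example responder models
#'
#' The two printed identified models used as ground truth throughout:
#' `"freq"` is the 3-pole/3-zero model with a 15 ms transport delay from the
#' frequency-domain worked example; `"time"` is the 2-pole/1-zero model with
#' a 40 ms delay from the time-domain worked example.
#'
#' @param which `"freq"` or `"time"`.
#' @return A [tf_model()].
#' @export
eq_example_model <- function(which = c("freq", "time")) {
  which <- match.arg(which)
  switch(which,
    freq = tf_model(
      num = c(0.7377, 0.5992, 1.175, 0.2213),
      den = c(1, 0.544, 1.85, 0.2594),
      tau = 0.015
    ),
    time = tf_model(
      num = c(-5.462, 39.42),
      den = c(1, 4.471, 75.86),
      tau = 0.04
    )
  )
}

#' Identify visuomotor dynamics from a stimulus/response record
#'
#' Routes by record length: records longer than 1.5 s go to the
#' frequency-domain path ([empirical_frf()] + [fit_tf_with_delay()]);
#' records of 1.5 s or less go to the time-domain ARX path
#' ([arx_fit_delay_grid()]). Both report a transport delay and a fit
#' percentage.
#'
#' @param stimulus,response Signal tibbles (`t`, `value`), or a single trial
#'   tibble from [make_tracking_trial()] passed as `stimulus` with
#'   `response = NULL`.
#' @param domain `"auto"` (route by duration), `"frequency"`, or `"time"`.
#' @param kinds Delay structures for the frequency-domain fit (see
#'   [fit_tf_with_delay()]).
#' @param ... Passed to [empirical_frf()] (frequency domain) or
#'   [arx_fit_delay_grid()] (time domain).
#' @return A tibble row: `domain`, `delay_s`, `fit_percent`, `status`, and a
#'   `fit` list column holding the full fitted object.
#' @export
identify_visuomotor <- function(stimulus, response = NULL,
                                domain = c("auto", "frequency", "time"),
                                kinds = c("pure", "linear_approx"), ...) {
  domain <- match.arg(domain)
  if (is.null(response)) {
    stopifnot(all(c("t", "stimulus", "response") %in% names(stimulus)))
    response <- tibble(t = stimulus$t, value = stimulus$response)
    stimulus <- tibble(t = stimulus$t, value = stimulus$stimulus)
  }
  t_rec <- nrow(stimulus) / signal_rate(stimulus)
  if (domain == "auto") domain <- if (t_rec > 1.5) "frequency" else "time"

  if (domain == "frequency") {
    frf <- empirical_frf(stimulus, response, ...)
    fit <- fit_tf_with_delay(frf, kinds = kinds)
    tibble(domain = "frequency", delay_s = fit$model$tau,
           fit_percent = fit$criteria$fit_percent[1], status = fit$status,
           fit = list(fit))
  } else {
    fit <- arx_fit_delay_grid(stimulus, response, ...)
    tibble(domain = "time", delay_s = fit$delay_s,
           fit_percent = fit$fit_percent, status = "ok", fit = list(fit))
  }
}

#' Swarm simulation presets
#'
#' The published simulation operating point: alpha = 7, beta = 6,
#' B_r = 0.5, D_r = 1. The reported agent count differs between the
#' simulation description (100) and its illustration (30); both variants
#' are provided.
#'
#' @param which `"n30"` (N = 30) or `"n100"` (N = 100).
#' @return A [swarm_params()].
#' @export
preset_swarm <- function(which = c("n30", "n100")) {
  which <- match.arg(which)
  n <- switch(which, n30 = 30L, n100 = 100L)
  swarm_params(alpha = 7, beta = 6, b_r = 0.5, d_r = 1, n_agents = n)
}

# internal: counter-based per-trial seeds below 2^31
trial_seeds <- function(master, n) {
  (as.integer(master) * 100003L + 7919L * seq_len(n)) %% 2147483545L + 1L
}

#' Run the end-to-end synthetic replica
#'
#' Executes the full chain on synthetic data: draw a population of
#' responder delays, simulate each tracking trial, identify each delay
#' (frequency- or time-domain by record length), fit a shifted-gamma
#' distribution to the identified delays, and (optionally) map mean-field
#' stability and simulate the swarm under the fitted delays.
#'
#' @param n_trials Trials per condition.
#' @param delay_population Distribution the true per-trial delays are drawn
#'   from, in SECONDS (default: uniform draws on the 1 ms grid between 5 and
#'   120 ms, the range spanned by the reported delay histograms; pass a
#'   [shifted_gamma()] to draw from a fitted population instead).
#' @param base_model A [tf_model()] whose rational part every responder
#'   shares (default the worked-example model).
#' @param snr Amplitude SNR of the simulated measurements (NULL =
#'   noise-free).
#' @param duration,fs Record length request and camera rate.
#' @param seed Master seed; per-trial seeds are derived by a counter scheme.
#' @param stability Also compute the solo/group [region_map()]? (slow-ish;
#'   default FALSE)
#' @return A list of class `replica_report`: `trials` (per-trial tibble:
#'   true and identified delay, fit, domain, status), `dist_fit`
#'   (shifted-gamma fit to identified delays), optional `stability_map`.
#' @export
run_replica <- function(n_trials = 20, delay_population = NULL,
                        base_model = eq_example_model("freq"),
                        snr = 20, duration = 4, fs = 120, seed = 1,
                        stability = FALSE) {
  seeds <- trial_seeds(seed, n_trials)
  set.seed(seed)
  true_delays <- if (is.null(delay_population)) {
    sample(seq(0.005, 0.120, by = 0.001), n_trials, replace = TRUE)
  } else {
    pmin(sample_delay_population(delay_population, n_trials), 0.2)
  }

  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    model_i <- tf_model(base_model$num, base_model$den, tau = true_delays[i])
    row <- tryCatch({
      trial <- make_tracking_trial(model_i, duration = duration, fs = fs,
                                   snr = snr, seed = seeds[i])
      # population delays come from the pure-delay structure (the linear
      # approximation's tau is a pole position, not a transport delay, and
      # the pure structure is the one used for subsequent analysis)
      res <- identify_visuomotor(trial, kinds = "pure")
      tibble(trial = i, true_delay_s = true_delays[i],
             delay_s = res$delay_s, fit_percent = res$fit_percent,
             domain = res$domain, status = res$status)
    }, error = function(e) {
      tibble(trial = i, true_delay_s = true_delays[i],
             delay_s = NA_real_, fit_percent = NA_real_,
             domain = NA_character_, status = paste("error:", conditionMessage(e)))
    })
    rows[[i]] <- row
  }
  trials <- bind_rows(rows)

  ok <- trials[trials$status == "ok" & !is.na(trials$delay_s), ]
  dist_fit <- if (nrow(ok) >= 10L) fit_shifted_gamma(ok$delay_s) else NULL

  out <- list(trials = trials, dist_fit = dist_fit, seed = seed)
  if (stability) out$stability_map <- region_map()
  structure(out, class = "replica_report")
}

#' @export
print.replica_report <- function(x, ...) {
  ok <- x$trials[x$trials$status == "ok", ]
  cat(sprintf("<replica_report> %d trials (%d ok); delay MAE %.2f ms; median fit %.1f%%\n",
              nrow(x$trials), nrow(ok),
              1000 * mean(abs(ok$delay_s - ok$true_delay_s)),
              median(ok$fit_percent)))
  invisible(x)
}

#' Export / ingest trial records as CSV
#'
#' `write_trial_csv()` writes a trial's `t`, `stimulus`, `response` columns;
#' `ingest_real()` reads trajectory CSVs back into trial tibbles under a
#' declared column mapping (the deposited recordings' schema is not
#' standardized, so the mapping must name which columns hold time, stimulus
#' and response positions).
#'
#' @param trial Trial tibble (`t`, `stimulus`, `response`).
#' @param path Output file path.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(all(c("t", "stimulus", "response") %in% names(trial)))
  utils::write.csv(trial[, c("t", "stimulus", "response")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @param paths CSV files to ingest.
#' @param mapping Named character vector mapping standard names to file
#'   columns, e.g. `c(t = "time", stimulus = "stim_x", response = "bee_x")`.
#' @return A list of trial tibbles.
#' @export
ingest_real <- function(paths,
                        mapping = c(t = "t", stimulus = "stimulus",
                                    response = "response")) {
  needed <- c("t", "stimulus", "response")
  if (!all(needed %in% names(mapping))) {
    abort("`mapping` must name columns for t, stimulus and response")
  }
  lapply(paths, function(p) {
    df <- utils::read.csv(p, check.names = FALSE)
    missing <- setdiff(unname(mapping[needed]), names(df))
    if (length(missing)) {
      abort(sprintf("schema error in %s: missing column(s) %s",
                    basename(p), paste(missing, collapse = ", ")))
    }
    tibble(
      t = as.numeric(df[[mapping[["t"]]]]),
      stimulus = as.numeric(df[[mapping[["stimulus"]]]]),
      response = as.numeric(df[[mapping[["response"]]]])
    )
  })
}
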