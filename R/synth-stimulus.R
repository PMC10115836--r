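#' Triangular stimulus schedule
#'
#' A schedule describes the moving hive-entrance stimulus as a sequence of
#' peak-to-peak ramps. Each row is one ramp: the entrance sweeps from one
#' amplitude extreme to the other in `half_period` seconds, so a constant
#' schedule of half-period h produces a classic triangle wave of period 2h.
#' Successive rows with shrinking half-periods give the accelerating zigzag
#' used to pack frequency content into short tracking records.
#'
#' The default spans roughly 0.25-2 Hz, the band where tethered-target
#' tracking by flying insects is coherent.
#'
#' @param half_period Ramp durations in seconds (one per segment).
#' @param amplitude Peak amplitudes in metres (recycled to match).
#' @return A tibble with columns `half_period` and `amplitude`.
#' @export
#' @examples
#' triangular_schedule()
#' triangular_schedule(half_period = 1, amplitude = 0.05)
triangular_schedule <- function(half_period = c(2, 1, 0.5, 0.25),
                                amplitude = 0.1) {
  if (length(half_period) < 1L) abort("schedule needs at least one segment")
  if (any(half_period <= 0)) abort("all half-periods must be > 0")
  if (any(amplitude < 0)) abort("amplitudes must be >= 0")
  tibble(
    half_period = as.numeric(half_period),
    amplitude = rep_len(as.numeric(amplitude), length(half_period))
  )
}

#' Generate a triangular-wave stimulus signal
#'
#' Builds the piecewise-linear entrance trajectory from a
#' [triangular_schedule()]: alternating linear ramps between the positive and
#' negative amplitude extremes, cycling through the schedule for as long as
#' `duration` requires. A triangular wave contains only odd harmonics, and
#' every segment contributes a slope reversal, which is where the usable
#' frequency diversity of the stimulus lives.
#'
#' The waveform starts at the positive extreme of the first segment, so a
#' schedule with an even number of segments tiles periodically with period
#' `sum(half_period)`.
#'
#' @param schedule A tibble from [triangular_schedule()].
#' @param duration Record length in seconds; must cover at least the first
#'   segment.
#' @param fs Sampling rate in Hz.
#' @param t0 Start time in seconds.
#' @return A signal tibble with columns `t` (s) and `value` (m).
#' @export
#' @examples
#' stim <- generate_triangular_stimulus(triangular_schedule(), duration = 4)
#' range(stim$value)
generate_triangular_stimulus <- function(schedule, duration, fs = 120, t0 = 0) {
  if (!is.data.frame(schedule) || nrow(schedule) == 0L) {
    abort("`schedule` must be a non-empty schedule tibble")
  }
  if (!all(c("half_period", "amplitude") %in% names(schedule))) {
    abort("`schedule` must have columns `half_period` and `amplitude`")
  }
  if (any(schedule$half_period <= 0)) abort("all half-periods must be > 0")
  if (fs <= 0) abort("`fs` must be > 0")
  if (duration < schedule$half_period[1]) {
    abort("`duration` must cover at least the first schedule segment")
  }

  n <- floor(duration * fs)
  t_rel <- (seq_len(n) - 1) / fs
  value <- numeric(n)

  seg_start <- 0
  k <- 0L
  level <- schedule$amplitude[1]
  while (seg_start < duration) {
    row <- (k %% nrow(schedule)) + 1L
    hp <- schedule$half_period[row]
    amp <- schedule$amplitude[row]
    target <- if (k %% 2L == 0L) -amp else amp
    idx <- which(t_rel >= seg_start & t_rel < seg_start + hp)
    if (length(idx)) {
      frac <- (t_rel[idx] - seg_start) / hp
      value[idx] <- level + (target - level) * frac
    }
    level <- target
    seg_start <- seg_start + hp
    k <- k + 1L
  }

  tibble(t = t0 + t_rel, value = value)
}

# internal: duration of one full period of the tiled schedule
schedule_period <- function(schedule) {
  s <- sum(schedule$half_period)
  if (nrow(schedule) %% 2L == 0L) s else 2 * s
}
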