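#' Continuous-time transfer-function model with a transport delay
#'
#' Represents the closed-loop tracking dynamics of one insect as a rational
#' transfer function G(s) = num(s)/den(s) composed with a visuomotor delay.
#' The delay enters either as a pure transport delay exp(-s tau) or as its
#' first-order rational approximation 1/(1 + tau s).
#'
#' @param num Numerator coefficients, descending powers of s.
#' @param den Denominator coefficients, descending powers of s; the leading
#'   coefficient must be nonzero. The model must be proper
#'   (numerator degree <= denominator degree).
#' @param tau Transport delay in seconds (>= 0).
#' @param delay_kind `"pure"` for exp(-s tau), `"linear_approx"` for
#'   1/(1 + tau s).
#' @return An object of class `tf_model`.
#' @export
#' @examples
#' # the worked-example insect model: three poles, three zeros, 15 ms delay
#' m <- tf_model(
#'   num = c(0.7377, 0.5992, 1.175, 0.2213),
#'   den = c(1, 0.544, 1.85, 0.2594),
#'   tau = 0.015
#' )
#' m
tf_model <- function(num, den, tau = 0, delay_kind = c("pure", "linear_approx")) {
  delay_kind <- match.arg(delay_kind)
  num <- as.numeric(num)
  den <- as.numeric(den)
  if (length(den) < 1L || den[1] == 0) abort("denominator leading coefficient must be nonzero")
  if (length(num) < 1L) abort("numerator must be non-empty")
  if (length(num) > length(den)) abort("model must be proper (deg num <= deg den)")
  if (!is.finite(tau) || tau < 0) abort("`tau` must be >= 0")
  structure(
    list(num = num / den[1], den = den / den[1], tau = tau, delay_kind = delay_kind),
    class = "tf_model"
  )
}

#' @export
print.tf_model <- function(x, ...) {
  cat("<tf_model> ", length(x$den) - 1L, " poles, ", length(x$num) - 1L,
      " zeros, delay ", format(x$tau * 1000), " ms (", x$delay_kind, ")\n", sep = "")
  cat("  num:", signif(x$num, 5), "\n  den:", signif(x$den, 5), "\n")
  invisible(x)
}

# internal: evaluate a polynomial (descending coefficients) at complex s
polyval_c <- function(p, s) {
  r <- rep(0 + 0i, length(s))
  for (c in p) r <- r * s + c
  r
}

#' Evaluate a model's frequency response
#'
#' @param model A [tf_model()].
#' @param f Frequencies in Hz.
#' @param delay Include the delay factor? (default TRUE)
#' @return Complex response values.
#' @export
tf_eval <- function(model, f, delay = TRUE) {
  s <- 2i * pi * f
  g <- polyval_c(model$num, s) / polyval_c(model$den, s)
  if (delay && model$tau > 0) {
    g <- g * switch(model$delay_kind,
      pure = exp(-s * model$tau),
      linear_approx = 1 / (1 + model$tau * s)
    )
  }
  g
}

#' Poles of the rational part
#' @param model A [tf_model()].
#' @return Complex pole locations.
#' @export
tf_poles <- function(model) {
  if (length(model$den) < 2L) return(complex(0))
  polyroot(rev(model$den))
}

# internal: controllable-canonical state space of the rational part,
# optionally cascaded with 1/(1 + tau s) for the linear_approx delay kind
tf_to_ss <- function(model, include_linear_delay = TRUE) {
  num <- model$num
  den <- model$den
  if (include_linear_delay && model$delay_kind == "linear_approx" && model$tau > 0) {
    # multiply denominator by (tau s + 1)
    den <- c(model$tau * den, 0) + c(0, den)
    num <- c(0, num)
  }
  n <- length(den) - 1L
  if (n == 0L) {
    return(list(A = matrix(0, 0, 0), B = matrix(0, 0, 1), C = matrix(0, 1, 0),
                D = num[1] / den[1], order = 0L))
  }
  den <- den / den[1]
  num <- c(rep(0, n + 1L - length(num)), num)
  b0 <- num[1]
  cvec <- num[-1] - den[-1] * b0
  A <- rbind(-den[-1], cbind(diag(1, n - 1L), rep(0, n - 1L)))
  list(A = A, B = matrix(c(1, rep(0, n - 1L))), C = matrix(cvec, 1), D = b0, order = n)
}

# internal: hold-equivalent discretization via the augmented matrix
# exponential. "foh" (first-order hold, linear interpolation between
# samples) is exact at the samples for piecewise-linear inputs; "zoh"
# (zero-order hold) matches a staircase input and yields a discrete system
# with no feedthrough for strictly proper models (the ARX-compatible form).
discretize_hold <- function(ss, fs, hold = c("foh", "zoh")) {
  hold <- match.arg(hold)
  n <- ss$order
  ts <- 1 / fs
  if (n == 0L) {
    return(list(phi = matrix(0, 0, 0), g0 = numeric(0), g1 = numeric(0),
                C = ss$C, D = ss$D, ts = ts, order = 0L, hold = hold))
  }
  m <- rbind(
    cbind(ss$A, ss$B, matrix(0, n, 1)),
    cbind(matrix(0, 1, n), 0, 1),
    matrix(0, 1, n + 2)
  )
  e <- pracma::expm(m * ts)
  g1 <- if (hold == "foh") e[seq_len(n), n + 2L] else rep(0, n)
  list(
    phi = e[seq_len(n), seq_len(n), drop = FALSE],
    g0 = e[seq_len(n), n + 1L],
    g1 = g1,
    C = ss$C, D = ss$D, ts = ts, order = n, hold = hold
  )
}

discretize_foh <- function(ss, fs) discretize_hold(ss, fs, "foh")

# internal: run the FOH-discretized system over input u from state x0;
# returns list(y, x_final)
run_foh <- function(dss, u, x0 = NULL) {
  n <- dss$order
  nu <- length(u)
  if (n == 0L) return(list(y = dss$D * u, x = numeric(0)))
  x <- if (is.null(x0)) rep(0, n) else x0
  y <- numeric(nu)
  phi <- dss$phi; g0 <- dss$g0; g1 <- dss$g1
  cvec <- as.numeric(dss$C); d <- dss$D; ts <- dss$ts
  for (k in seq_len(nu)) {
    y[k] <- sum(cvec * x) + d * u[k]
    if (k < nu) {
      x <- phi %*% x + g0 * u[k] + g1 * (u[k + 1] - u[k]) / ts
    }
  }
  list(y = y, x = as.numeric(x))
}

# internal: shift a sampled signal by tau seconds (fractional-sample linear
# interpolation, constant pre-history). Exact when the underlying continuous
# signal is piecewise linear with knots on the sample grid.
shift_fractional <- function(v, tau, fs) {
  if (tau == 0) return(v)
  dsamp <- tau * fs
  i0 <- floor(dsamp)
  fr <- dsamp - i0
  nv <- length(v)
  pad <- i0 + 2L
  vp <- c(rep(v[1], pad), v)
  idx <- seq_len(nv) - i0 + pad
  (1 - fr) * vp[idx] + fr * vp[idx - 1L]
}

#' Simulate a delayed linear responder
#'
#' Drives a [tf_model()] with a stimulus signal and returns the simulated
#' insect position. The rational part is integrated by first-order-hold
#' discretization at the stimulus sampling rate (exact at the samples for
#' piecewise-linear stimuli such as the triangular wave); a pure transport
#' delay is applied to the input by fractional-sample linear interpolation,
#' while the `linear_approx` kind augments the dynamics with 1/(1 + tau s).
#'
#' If `snr` is given, white Gaussian measurement noise w is added to the
#' output y so that RMS(y)/RMS(w) equals `snr` (the amplitude signal-to-noise
#' ratio |Y|/|w|); the stimulus is commanded and stays noise-free.
#'
#' @param stimulus Signal tibble (`t`, `value`).
#' @param model A [tf_model()].
#' @param snr Amplitude signal-to-noise ratio (> 0), or NULL for noise-free.
#' @param seed Integer seed for the noise draw (required when `snr` is set).
#' @param hold `"foh"` (linear-interpolation hold, exact for
#'   piecewise-linear stimuli) or `"zoh"` (staircase hold, whose discrete
#'   equivalent is exactly an ARX structure for strictly proper models).
#' @return A signal tibble (`t`, `value`) aligned with the stimulus.
#' @export
#' @examples
#' stim <- generate_triangular_stimulus(triangular_schedule(), duration = 4)
#' resp <- simulate_responder(stim, tf_model(1, c(0.2, 1), tau = 0.05))
simulate_responder <- function(stimulus, model, snr = NULL, seed = NULL,
                               hold = c("foh", "zoh")) {
  hold <- match.arg(hold)
  check_signal(stimulus, "stimulus")
  if (!inherits(model, "tf_model")) abort("`model` must be a tf_model")
  if (!is.null(snr) && (!is.finite(snr) || snr <= 0)) abort("`snr` must be > 0")
  fs <- signal_rate(stimulus)

  if (any(Re(tf_poles(model)) > 1e-12)) {
    warn("model is unstable; simulating anyway")
  }

  u <- stimulus$value
  if (model$delay_kind == "pure") u <- shift_fractional(u, model$tau, fs)
  dss <- discretize_hold(tf_to_ss(model), fs, hold)
  y <- run_foh(dss, u)$y

  if (!is.null(snr)) {
    if (is.null(seed)) abort("`seed` is required when `snr` is given")
    y <- y + scaled_noise(y, snr, seed)
  }
  tibble(t = stimulus$t, value = y)
}

# internal: white Gaussian noise scaled so RMS(signal)/RMS(noise) = snr
scaled_noise <- function(y, snr, seed) {
  set.seed(seed)
  w <- rnorm(length(y))
  w * sqrt(mean(y^2)) / sqrt(mean(w^2)) / snr
}
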