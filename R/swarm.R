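#' Swarm model parameters
#'
#' Parameters of the delayed attraction-repulsion swarm: each of N agents
#' integrates dx_i/dt = -(1/N) sum_j (alpha x_i(t) - beta x_j(t - tau_ij))
#' plus the gradient of an exponential repulsive potential with amplitude
#' `b_r` and length scale `d_r`, where alpha weights the agent's own
#' (egocentric) position and beta the visually observed, delay-stale
#' neighbor positions.
#'
#' @param alpha Egocentric influence weight.
#' @param beta Neighbor influence weight.
#' @param b_r Repulsion amplitude (>= 0).
#' @param d_r Repulsion length scale (> 0).
#' @param n_agents Number of agents N (>= 2).
#' @return An object of class `swarm_params`.
#' @export
swarm_params <- function(alpha, beta, b_r = 0.5, d_r = 1, n_agents = 30) {
  if (n_agents < 2) abort("`n_agents` must be >= 2")
  if (d_r <= 0) abort("`d_r` must be > 0")
  if (b_r < 0) abort("`b_r` must be >= 0")
  structure(list(alpha = alpha, beta = beta, b_r = b_r, d_r = d_r,
                 n_agents = as.integer(n_agents)),
            class = "swarm_params")
}

#' @export
print.swarm_params <- function(x, ...) {
  cat(sprintf("<swarm_params> N = %d, alpha = %g, beta = %g, B_r = %g, D_r = %g\n",
              x$n_agents, x$alpha, x$beta, x$b_r, x$d_r))
  invisible(x)
}

#' Sample a pairwise delay matrix
#'
#' Draws the visual delays tau_ij (delay with which agent i sees agent j).
#' `per_pair` draws every ordered pair independently (the approximation the
#' mean-field double sum uses); `per_agent_observer` gives each observer i a
#' single delay applied to all its neighbors, the biologically motivated
#' alternative.
#'
#' @param dist A [shifted_gamma()] delay distribution.
#' @param n_agents Number of agents.
#' @param mode `"per_pair"` or `"per_agent_observer"`.
#' @param seed Integer seed.
#' @return An `n_agents` x `n_agents` matrix of delays (diagonal unused,
#'   set to 0) with attribute `mode`.
#' @export
sample_delay_matrix <- function(dist, n_agents,
                                mode = c("per_pair", "per_agent_observer"),
                                seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_agents)
  tau <- switch(mode,
    per_pair = matrix(dist$tau_m + rgamma(n * n, shape = dist$m, rate = dist$a), n, n),
    per_agent_observer = {
      ti <- dist$tau_m + rgamma(n, shape = dist$m, rate = dist$a)
      matrix(ti, n, n)
    }
  )
  diag(tau) <- 0
  attr(tau, "mode") <- mode
  tau
}

#' Interaction drift of the delayed swarm
#'
#' Computes each agent's velocity from current positions and delay-stale
#' neighbor positions: the attraction term
#' -(1/N) sum_{j != i} (alpha x_i - beta x_j^delayed) plus the repulsion
#' gradient sum_{j != i} (alpha B_r / D_r) exp(-r_ij / D_r) d_ij / r_ij with
#' d_ij = alpha x_i - beta x_j^delayed and r_ij = ||d_ij|| (pairs closer
#' than 1e-9 are skipped).
#'
#' @param x_now N x 2 matrix of current positions.
#' @param x_delayed N x N x 2 array; `x_delayed[i, j, ]` is x_j(t - tau_ij)
#'   as seen by observer i.
#' @param params A [swarm_params()].
#' @return N x 2 matrix of velocities.
#' @export
interaction_drift <- function(x_now, x_delayed, params) {
  n <- params$n_agents
  stopifnot(nrow(x_now) == n, dim(x_delayed)[1] == n, dim(x_delayed)[2] == n)
  al <- params$alpha; be <- params$beta
  # d[i, j, ] = alpha x_i - beta x_j(t - tau_ij), j != i
  dx <- al * x_now[, 1] - be * x_delayed[, , 1]
  dy <- al * x_now[, 2] - be * x_delayed[, , 2]
  diag(dx) <- 0; diag(dy) <- 0
  drift_x <- -rowSums(dx) / n
  drift_y <- -rowSums(dy) / n
  if (params$b_r > 0) {
    r <- sqrt(dx^2 + dy^2)
    coef <- (al * params$b_r / params$d_r) * exp(-r / params$d_r) / r
    coef[r < 1e-9] <- 0
    diag(coef) <- 0
    drift_x <- drift_x + rowSums(coef * dx)
    drift_y <- drift_y + rowSums(coef * dy)
  }
  cbind(drift_x, drift_y, deparse.level = 0)
}

#' Simulate the delayed swarm
#'
#' Fixed-step explicit Euler integration of the delayed attraction-repulsion
#' model in the plane. Delays are quantized to the step grid (at least one
#' step); the pre-history is constant, x_i(t < 0) = x_i(0). Euler with
#' quantized delays makes runs exactly reproducible. Divergence
#' (any |coordinate| > 1e6, or non-finite values) truncates the run with a
#' flag instead of crashing.
#'
#' @param params A [swarm_params()].
#' @param delays N x N delay matrix (seconds of simulation time), e.g. from
#'   [sample_delay_matrix()].
#' @param init N x 2 initial positions, or NULL to draw uniformly from
#'   `init_range` using `seed`.
#' @param t_end Simulation horizon.
#' @param dt Step size; default min(tau_min/10, 1e-3 t_end) with tau_min the
#'   smallest positive delay.
#' @param seed Seed for random initial positions.
#' @param init_range Half-width of the uniform initial square (default 2).
#' @return An object of class `swarm_trajectory`: list with `time` (length
#'   nt), `positions` (N x 2 x nt array), `params`, `delays`, `dt`,
#'   `diverged`, `truncated_at`.
#' @export
simulate_swarm <- function(params, delays, init = NULL, t_end = 200,
                           dt = NULL, seed = NULL, init_range = 2) {
  n <- params$n_agents
  stopifnot(is.matrix(delays), nrow(delays) == n, ncol(delays) == n)
  if (any(delays < 0)) abort("delays must be >= 0")
  pos_delays <- delays[delays > 0]
  if (is.null(dt)) {
    dt <- if (length(pos_delays)) min(min(pos_delays) / 10, 1e-3 * t_end)
          else 1e-3 * t_end
  }
  if (length(pos_delays) && dt > min(pos_delays) + 1e-12) {
    abort("`dt` must not exceed the smallest positive delay")
  }
  if (is.null(init)) {
    if (!is.null(seed)) set.seed(seed)
    init <- matrix(runif(n * 2, -init_range, init_range), n, 2)
  }
  stopifnot(nrow(init) == n, ncol(init) == 2)

  lag <- matrix(pmax(1L, as.integer(round(delays / dt))), n, n)
  diag(lag) <- 0L
  max_lag <- max(lag)
  nt <- ceiling(t_end / dt)
  # history buffers: columns are time slots 1..(max_lag + nt + 1)
  total <- max_lag + nt + 1L
  hx <- matrix(init[, 1], n, total)
  hy <- matrix(init[, 2], n, total)

  res <- swarm_euler_loop(hx, hy, lag, params, max_lag, nt, dt)
  hx <- res$hx; hy <- res$hy
  diverged <- res$diverged
  truncated_at <- res$truncated_at

  keep <- (max_lag + 1L):(max_lag + res$n_done)
  positions <- array(0, c(n, 2, length(keep)))
  positions[, 1, ] <- hx[, keep]
  positions[, 2, ] <- hy[, keep]
  structure(
    list(time = (seq_along(keep) - 1L) * dt, positions = positions,
         params = params, delays = delays, dt = dt,
         diverged = diverged, truncated_at = truncated_at),
    class = "swarm_trajectory"
  )
}

# internal: Euler loop with per-pair delayed gathers
swarm_euler_loop <- function(hx, hy, lag, params, max_lag, nt, dt) {
  n <- params$n_agents
  al <- params$alpha; be <- params$beta
  br <- params$b_r; dr <- params$d_r
  jmat <- matrix(rep(seq_len(n), each = n), n, n)  # [i, j] = j
  diverged <- FALSE
  truncated_at <- NA_real_
  n_done <- nt
  for (step in seq_len(nt)) {
    k <- max_lag + step
    src <- cbind(as.vector(jmat), as.vector(k - lag))
    xd <- matrix(hx[src], n, n)   # [i, j] = x_j(k - lag[i, j])
    yd <- matrix(hy[src], n, n)
    xi <- hx[, k]; yi <- hy[, k]
    dxm <- al * xi - be * xd
    dym <- al * yi - be * yd
    diag(dxm) <- 0; diag(dym) <- 0
    vx <- -rowSums(dxm) / n
    vy <- -rowSums(dym) / n
    if (br > 0) {
      r <- sqrt(dxm^2 + dym^2)
      coef <- (al * br / dr) * exp(-r / dr) / r
      coef[!is.finite(coef) | r < 1e-9] <- 0
      diag(coef) <- 0
      vx <- vx + rowSums(coef * dxm)
      vy <- vy + rowSums(coef * dym)
    }
    nx <- xi + dt * vx
    ny <- yi + dt * vy
    if (any(!is.finite(nx)) || any(!is.finite(ny)) ||
        max(abs(nx), abs(ny)) > 1e6) {
      diverged <- TRUE
      truncated_at <- step * dt
      n_done <- step
      hx[, k + 1L] <- xi; hy[, k + 1L] <- yi
      break
    }
    hx[, k + 1L] <- nx
    hy[, k + 1L] <- ny
  }
  list(hx = hx, hy = hy, diverged = diverged,
       truncated_at = truncated_at, n_done = n_done)
}

#' Swarm center time series
#'
#' The barycenter C(t) = (1/N) sum_i x_i(t) and its norm
#' ||C(t)|| = sqrt(Cx^2 + Cy^2). The settling verdict checks whether the
#' trailing 20% of the run drifts by less than `tol` relative to its level
#' (||C|| -> constant), the swarm-center stability notion used throughout.
#'
#' @param traj A [simulate_swarm()] trajectory.
#' @param tol Relative drift tolerance for the settling verdict
#'   (default 1e-3).
#' @return A tibble with columns `t`, `cx`, `cy`, `norm`, carrying
#'   attributes `settled` (logical) and `trailing_drift`.
#' @export
swarm_center <- function(traj, tol = 1e-3) {
  stopifnot(inherits(traj, "swarm_trajectory"))
  cx <- colMeans(traj$positions[, 1, , drop = FALSE][, 1, ])
  cy <- colMeans(traj$positions[, 2, , drop = FALSE][, 1, ])
  nrm <- sqrt(cx^2 + cy^2)
  nt <- length(nrm)
  tail_idx <- max(1L, ceiling(0.8 * nt)):nt
  tail_vals <- nrm[tail_idx]
  drift <- diff(range(tail_vals)) / max(mean(tail_vals), 1e-12)
  settled <- !traj$diverged && drift < tol
  out <- tibble(t = traj$time, cx = cx, cy = cy, norm = nrm)
  attr(out, "settled") <- settled
  attr(out, "trailing_drift") <- drift
  out
}

#' @export
glance.swarm_trajectory <- function(x, ...) {
  ctr <- swarm_center(x)
  tibble(
    n_agents = x$params$n_agents, t_end = max(x$time), dt = x$dt,
    diverged = x$diverged, settled = attr(ctr, "settled"),
    trailing_drift = attr(ctr, "trailing_drift"),
    final_center_norm = ctr$norm[nrow(ctr)]
  )
}

#' @export
tidy.swarm_trajectory <- function(x, ...) {
  n <- x$params$n_agents
  nt <- length(x$time)
  tibble(
    t = rep(x$time, each = n),
    agent = rep(seq_len(n), nt),
    x = as.vector(x$positions[, 1, ]),
    y = as.vector(x$positions[, 2, ])
  )
}

#' Simulate the mean-field swarm-center equation
#'
#' Scalar distributed-delay equation
#' dC/dt = -alpha C(t) + beta integral C(t - tau) g(tau) dtau obtained by
#' averaging the swarm over agents and delays. The gamma delay kernel is
#' discretized into `n_atoms` equal-probability atoms (quantile midpoints),
#' and the equation integrated by explicit Euler with constant pre-history
#' C(t < 0) = c0. Planar components decouple, so C is scalar here.
#'
#' @param alpha,beta Egocentric and neighbor weights.
#' @param dist A [shifted_gamma()] delay distribution.
#' @param c0 Initial center value (default 1).
#' @param t_end Horizon.
#' @param dt Step; default tau_m/10 (or mean delay/50 when tau_m = 0),
#'   capped at t_end/1000.
#' @param n_atoms Number of quadrature atoms (default 50).
#' @return A tibble with columns `t` and `c`.
#' @export
simulate_meanfield <- function(alpha, beta, dist, c0 = 1, t_end = 100,
                               dt = NULL, n_atoms = 50) {
  stopifnot(inherits(dist, "shifted_gamma"))
  taus <- dist$tau_m +
    qgamma((seq_len(n_atoms) - 0.5) / n_atoms, shape = dist$m, rate = dist$a)
  if (is.null(dt)) {
    base <- if (dist$tau_m > 0) dist$tau_m / 10 else delay_mean(dist) / 50
    # explicit Euler needs dt well inside 2/(alpha + beta); guard stiffness
    dt <- min(base, t_end / 1000, 0.2 / (abs(alpha) + abs(beta) + 1e-9))
  }
  lags <- pmax(1L, as.integer(round(taus / dt)))
  max_lag <- max(lags)
  nt <- ceiling(t_end / dt)
  cv <- numeric(max_lag + nt + 1L)
  cv[seq_len(max_lag + 1L)] <- c0
  wq <- 1 / n_atoms
  for (step in seq_len(nt)) {
    k <- max_lag + step
    cbar <- sum(cv[k - lags]) * wq
    nxt <- cv[k] + dt * (-alpha * cv[k] + beta * cbar)
    if (!is.finite(nxt)) nxt <- sign(cv[k]) * 1e12
    cv[k + 1L] <- nxt
  }
  idx <- (max_lag + 1L):(max_lag + nt)
  tibble(t = (seq_along(idx) - 1L) * dt, c = cv[idx])
}
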