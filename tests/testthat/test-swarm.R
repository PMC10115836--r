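test_that("interaction drift matches closed forms", {
  # symmetric pair, alpha = beta = 1, no delay, no repulsion:
  # drifts point along -(x1 - x2)/2 and its opposite
  p <- swarm_params(1, 1, b_r = 0, n_agents = 2)
  x <- rbind(c(1, 0.5), c(-1, -0.5))
  xd <- array(0, c(2, 2, 2))
  for (i in 1:2) for (j in 1:2) xd[i, j, ] <- x[j, ]
  v <- interaction_drift(x, xd, p)
  expect_equal(v[1, ], -(x[1, ] - x[2, ]) / 2, ignore_attr = TRUE)
  expect_equal(v[2, ], (x[1, ] - x[2, ]) / 2, ignore_attr = TRUE)

  # alpha = beta, arbitrary delays, B_r = 0: instantaneous center drift
  # equals (beta/N^2) sum_ij [x_j(t - tau_ij) - x_j(t)]
  set.seed(31)
  n <- 5
  p2 <- swarm_params(1.3, 1.3, b_r = 0, n_agents = n)
  xn <- matrix(rnorm(n * 2), n, 2)
  xdel <- array(rnorm(n * n * 2), c(n, n, 2))
  for (i in 1:n) xdel[i, i, ] <- xn[i, ]
  v2 <- interaction_drift(xn, xdel, p2)
  cdot <- colMeans(v2)
  lhs <- c(0, 0)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    lhs <- lhs + (xdel[i, j, ] - xn[j, ])
  }
  expect_equal(cdot, 1.3 / n^2 * lhs, tolerance = 1e-12, ignore_attr = TRUE)

  # strong repulsion between near-coincident agents pushes at ~ alpha B_r / D_r
  p3 <- swarm_params(1, 1, b_r = 50, d_r = 1, n_agents = 2)
  x3 <- rbind(c(0, 0), c(1e-4, 0))
  xd3 <- array(0, c(2, 2, 2))
  for (i in 1:2) for (j in 1:2) xd3[i, j, ] <- x3[j, ]
  v3 <- interaction_drift(x3, xd3, p3)
  expect_equal(abs(v3[1, 1]), 1 * 50 / 1, tolerance = 0.01)
  expect_equal(v3[1, 1], -v3[2, 1], tolerance = 1e-6)
})

test_that("zero-delay center dynamics follow the scalar reduction", {
  n <- 12
  tau0 <- matrix(0, n, n)
  # alpha = beta: center of mass is exactly conserved
  p_eq <- swarm_params(2, 2, b_r = 0, n_agents = n)
  tr <- simulate_swarm(p_eq, tau0, t_end = 5, dt = 0.005, seed = 41)
  ctr <- swarm_center(tr)
  expect_lt(diff(range(ctr$norm)), 1e-10)

  # alpha > beta: ||C|| decays like exp(-(alpha-beta)(N-1)t/N)
  p_dec <- swarm_params(2, 1, b_r = 0, n_agents = n)
  tr2 <- simulate_swarm(p_dec, tau0, t_end = 3, dt = 0.001, seed = 42)
  ctr2 <- swarm_center(tr2)
  keep <- ctr2$norm > 1e-8
  rate <- -stats::coef(stats::lm(log(norm) ~ t, data = ctr2[keep, ]))[[2]]
  expect_equal(rate, (2 - 1) * (n - 1) / n, tolerance = 0.02)
})

test_that("dynamics are translation-equivariant when alpha equals beta", {
  n <- 8
  d <- preset_distribution("group")
  tau <- sample_delay_matrix(d, n, seed = 51)
  p <- swarm_params(1.5, 1.5, b_r = 0.5, d_r = 1, n_agents = n)
  set.seed(52)
  init <- matrix(runif(n * 2, -1, 1), n, 2)
  shift <- c(3, -2)
  tr_a <- simulate_swarm(p, tau, init = init, t_end = 10, dt = 0.05)
  tr_b <- simulate_swarm(p, tau, init = sweep(init, 2, -shift), t_end = 10, dt = 0.05)
  expect_equal(tr_b$positions[, 1, ] - shift[1], tr_a$positions[, 1, ],
               tolerance = 1e-9)
  expect_equal(tr_b$positions[, 2, ] - shift[2], tr_a$positions[, 2, ],
               tolerance = 1e-9)
})

test_that("halving the step changes a stable center trajectory by < 1%", {
  n <- 10
  d <- preset_distribution("group")
  tau <- sample_delay_matrix(d, n, seed = 61)
  p <- swarm_params(3, 2, b_r = 0.5, d_r = 1, n_agents = n)
  set.seed(62)
  init <- matrix(runif(n * 2, -2, 2), n, 2)
  tr1 <- simulate_swarm(p, tau, init = init, t_end = 30, dt = 0.04)
  tr2 <- simulate_swarm(p, tau, init = init, t_end = 30, dt = 0.02)
  n1 <- swarm_center(tr1)$norm
  n2 <- swarm_center(tr2)$norm[seq(1, length(swarm_center(tr2)$norm), by = 2)]
  len <- min(length(n1), length(n2))
  rel <- sqrt(mean((n1[1:len] - n2[1:len])^2)) / max(mean(n2[1:len]), 1e-9)
  expect_lt(rel, 0.01)
})

test_that("mean-field equation reproduces its delay-free and Hopf limits", {
  # beta = 0: pure exponential decay
  d <- preset_distribution("solo")
  mf <- simulate_meanfield(2, 0, d, t_end = 2.5)
  expect_equal(mf$c[nrow(mf)], exp(-2 * 2.5), tolerance = 0.01)

  # near point-mass delay (variance -> 0): the Hopf boundary of the gamma
  # kernel approaches the classical single-delay boundary. For the scalar
  # DDE C' = -alpha C + beta C(t - tau) with positive beta, the imaginary
  # crossing at alpha = 1, beta = 2 needs omega tau in (pi, 2 pi):
  # omega = sqrt(beta^2 - alpha^2), tau* = (2 pi - acos(alpha/beta))/omega.
  al <- 1; be <- 2
  omega_star <- sqrt(be^2 - al^2)
  tau_star <- (2 * pi - acos(al / be)) / omega_star
  m_big <- 1e4
  d_point <- shifted_gamma(m_big, m_big / tau_star, 0)
  hc <- hopf_contour(d_point, omega = seq(0.8 * omega_star, 1.2 * omega_star,
                                          length.out = 200))
  i <- which.min(abs(hc$alpha - al))
  expect_equal(hc$beta[i], be, tolerance = 0.01)
  expect_equal(hc$omega[i], omega_star, tolerance = 0.01)
  # at beta > alpha a positive real characteristic root dominates any
  # Hopf pair; the simulated growth rate must match that root exactly
  lam_real <- uniroot(function(l) l + al - be * exp(-l * tau_star),
                      c(0, 5))$root
  mf2 <- simulate_meanfield(al, be, d_point, t_end = 20, dt = 5e-4)
  sl <- mf2[mf2$t > 5, ]
  growth <- stats::coef(stats::lm(log(abs(sl$c)) ~ sl$t))[[2]]
  expect_equal(growth, lam_real, tolerance = 0.001)
})

test_that("mean-field verdicts flip across the operative stability boundary", {
  # for any delay kernel |G(i omega)| <= 1, so the Hopf branch lies above
  # the real-root line beta = alpha; the first crossing as beta grows is
  # always lambda = 0 at beta = alpha, and verdicts must flip there
  d <- preset_distribution("group")
  inside <- simulate_meanfield(3, 0.9 * 3, d, t_end = 400)
  outside <- simulate_meanfield(3, 1.1 * 3, d, t_end = 400)
  expect_lt(abs(inside$c[nrow(inside)]), 0.5)
  expect_gt(max(abs(outside$c)), 10)
  # and the Hopf branch indeed sits above beta = alpha in the quadrant
  hc <- hopf_contour(d)
  quad <- hc[hc$alpha > 0 & hc$beta > 0, ]
  expect_true(all(quad$beta >= quad$alpha - 1e-9))
})

test_that("swarm center tracks the mean-field solution for many agents", {
  n <- 100
  d <- preset_distribution("group")
  tau <- sample_delay_matrix(d, n, seed = 71)
  p <- swarm_params(3, 2, b_r = 0, n_agents = n)
  set.seed(72)
  init <- matrix(runif(n * 2, 0, 2), n, 2)   # nonzero initial center
  tr <- simulate_swarm(p, tau, init = init, t_end = 15, dt = 0.05)
  ctr <- swarm_center(tr)

  c0x <- mean(init[, 1]); c0y <- mean(init[, 2])
  mfx <- simulate_meanfield(3, 2, d, c0 = c0x, t_end = 15, dt = 0.05)
  mfy <- simulate_meanfield(3, 2, d, c0 = c0y, t_end = 15, dt = 0.05)
  len <- min(nrow(ctr), nrow(mfx))
  mf_norm <- sqrt(mfx$c[1:len]^2 + mfy$c[1:len]^2)
  rel <- sqrt(mean((ctr$norm[1:len] - mf_norm)^2)) / mean(mf_norm)
  expect_lt(rel, 0.1)
})

test_that("divergence is flagged, not fatal", {
  n <- 4
  p <- swarm_params(-5, 12, b_r = 0, n_agents = n)  # strongly unstable
  tau <- matrix(0.2, n, n); diag(tau) <- 0
  tr <- simulate_swarm(p, tau, t_end = 50, dt = 0.02, seed = 81)
  expect_true(tr$diverged)
  expect_true(is.finite(tr$truncated_at))
})
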