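#' Characteristic-equation residual of the mean-field swarm
#'
#' Literal evaluation of
#' lambda + alpha - beta exp(-lambda tau_m) a^m / (a + lambda)^m,
#' the characteristic function of the linearized mean-field swarm-center
#' equation with a shifted-gamma delay kernel. Roots in the right half plane
#' mean the swarm center is unstable.
#'
#' @param lam Complex (or real) lambda.
#' @param alpha,beta Egocentric and neighbor weights.
#' @param dist A [shifted_gamma()].
#' @return Complex residual values.
#' @export
#' @examples
#' char_residual(-2, alpha = 2, beta = 0, preset_distribution("solo")) # 0
char_residual <- function(lam, alpha, beta, dist) {
  stopifnot(inherits(dist, "shifted_gamma"))
  lam <- as.complex(lam)
  lam + alpha - beta * gamma_laplace(dist, lam, shifted = TRUE)
}

#' Hopf stability boundary for a gamma delay distribution
#'
#' Parametric boundary (alpha(omega), beta(omega)) where the characteristic
#' equation has a purely imaginary root lambda = i omega. Writing
#' E(omega) = exp(-i omega tau_m) a^m/(a + i omega)^m, the real and
#' imaginary parts of the characteristic equation are linear in (alpha,
#' beta) and solve exactly to beta = omega / Im(E), alpha = beta Re(E).
#' Two printed closed forms exist, differing in the sign of the
#' m atan(omega/a) term inside alpha; both are evaluated against the exact
#' solution and the agreeing branch is recorded in the `branch` attribute.
#' Every retained point is validated: |residual| of [char_residual()] at
#' i omega below `tol`.
#'
#' @param dist A [shifted_gamma()].
#' @param omega Frequency grid (rad/time, > 0); default 400 log-spaced
#'   points over 1e-3 to 50.
#' @param tol Residual validation tolerance (default 1e-8).
#' @return An object of class `stability_contour`: tibble with columns
#'   `omega`, `alpha`, `beta`, `residual`; attributes `dist` and `branch`.
#' @export
#' @examples
#' hc <- hopf_contour(preset_distribution("group"))
#' max(hc$residual) < 1e-8
hopf_contour <- function(dist, omega = NULL, tol = 1e-8) {
  stopifnot(inherits(dist, "shifted_gamma"))
  if (is.null(omega)) omega <- exp(seq(log(1e-3), log(50), length.out = 400))
  if (any(omega <= 0)) abort("`omega` must be > 0")

  e <- gamma_laplace(dist, 1i * omega, shifted = TRUE)
  beta <- omega / Im(e)
  alpha <- beta * Re(e)
  res <- Mod(char_residual(1i * omega, alpha, beta, dist))

  # branch arbitration against the two printed closed forms
  theta <- atan(omega / dist$a)
  a_plus <- -omega / tan(omega * dist$tau_m + dist$m * theta)
  a_minus <- -omega / tan(omega * dist$tau_m - dist$m * theta)
  b_plus <- -omega / (cos(theta)^dist$m * sin(omega * dist$tau_m + dist$m * theta))
  dev_plus <- stats::median(abs(a_plus - alpha) / pmax(abs(alpha), 1e-9), na.rm = TRUE)
  dev_minus <- stats::median(abs(a_minus - alpha) / pmax(abs(alpha), 1e-9), na.rm = TRUE)
  branch <- if (dev_plus <= dev_minus) "plus" else "minus"

  keep <- is.finite(alpha) & is.finite(beta) & res < tol
  out <- tibble(omega = omega[keep], alpha = alpha[keep],
                beta = beta[keep], residual = res[keep])
  if (nrow(out) == 0L) abort("empty validated contour")
  structure(out, class = c("stability_contour", class(out)),
            dist = dist, branch = branch,
            beta_form_deviation = stats::median(abs(b_plus - beta), na.rm = TRUE))
}

#' @export
tidy.stability_contour <- function(x, ...) as_tibble(x)

#' Boundary neighbor weight at a given egocentric weight
#'
#' Interpolates the physically relevant branch of a [hopf_contour()] (alpha
#' and beta both positive) to give the Hopf-crossing beta at each requested
#' alpha. The full stability boundary also includes the real-root line
#' beta = alpha (lambda = 0 when alpha = beta); `include_real_root = TRUE`
#' returns min(alpha, beta_hopf).
#'
#' @param contour A [hopf_contour()].
#' @param alpha Egocentric weights to query.
#' @param include_real_root Include the beta = alpha crossing (default TRUE).
#' @return Numeric vector of boundary beta values (Inf where the Hopf branch
#'   never crosses that alpha).
#' @export
boundary_beta <- function(contour, alpha, include_real_root = TRUE) {
  quad <- contour[contour$alpha > 0 & contour$beta > 0, ]
  bh <- rep(Inf, length(alpha))
  if (nrow(quad) >= 2L) {
    # first crossing in beta as alpha(omega) passes each query value
    o <- order(quad$omega)
    qa <- quad$alpha[o]; qb <- quad$beta[o]
    for (i in seq_along(alpha)) {
      cross <- which(diff(sign(qa - alpha[i])) != 0)
      if (length(cross)) {
        vals <- vapply(cross, function(j) {
          w <- (alpha[i] - qa[j]) / (qa[j + 1] - qa[j])
          qb[j] + w * (qb[j + 1] - qb[j])
        }, 0)
        bh[i] <- min(vals)
      }
    }
  }
  if (include_real_root) pmin(bh, alpha) else bh
}

#' Classify mean-field stability at a parameter point
#'
#' Verdict from the mean-field delay-differential oracle rather than from
#' the contour: [simulate_meanfield()] runs from C(0) = 1 for 200
#' characteristic times (the distribution's mean delay, floored by 1/alpha
#' scales); stable if the trailing-window maximum of |C| falls below 0.5,
#' unstable if |C| ever exceeds 10, indeterminate otherwise (near-boundary
#' band).
#'
#' @param alpha,beta Weights.
#' @param dist A [shifted_gamma()].
#' @param horizon_factor Characteristic-time multiplier (default 200).
#' @return `"stable"`, `"unstable"`, or `"indeterminate"`.
#' @export
classify_stability <- function(alpha, beta, dist, horizon_factor = 200) {
  t_char <- max(delay_mean(dist), 1 / max(abs(alpha), abs(beta), 1e-3))
  t_end <- horizon_factor * t_char
  mf <- simulate_meanfield(alpha, beta, dist, c0 = 1, t_end = t_end)
  ac <- abs(mf$c)
  if (max(ac) > 10) return("unstable")
  tail_max <- max(ac[ceiling(0.8 * length(ac)):length(ac)])
  if (tail_max < 0.5) "stable" else "indeterminate"
}

#' Stability region map for the solo and group delay distributions
#'
#' Classifies a grid of (alpha, beta) cells with the mean-field oracle for
#' both distributions and attaches both Hopf contours, reproducing the
#' stability-map comparison between solitary and group delay populations.
#'
#' @param dist_solo,dist_group [shifted_gamma()] distributions.
#' @param alpha_range,beta_range Ranges (positive).
#' @param resolution Grid cells per axis (default 10).
#' @return An object of class `stability_map`: tibble with `alpha`, `beta`,
#'   `verdict_solo`, `verdict_group`, plus attributes `contour_solo` and
#'   `contour_group`.
#' @export
region_map <- function(dist_solo = preset_distribution("solo"),
                       dist_group = preset_distribution("group"),
                       alpha_range = c(0.5, 10), beta_range = c(0.5, 10),
                       resolution = 10) {
  if (any(c(alpha_range, beta_range) <= 0)) abort("ranges must be positive")
  al <- seq(alpha_range[1], alpha_range[2], length.out = resolution)
  be <- seq(beta_range[1], beta_range[2], length.out = resolution)
  grid <- tidyr::expand_grid(alpha = al, beta = be)
  grid$verdict_solo <- purrr::map2_chr(grid$alpha, grid$beta,
                                       ~ classify_stability(.x, .y, dist_solo))
  grid$verdict_group <- purrr::map2_chr(grid$alpha, grid$beta,
                                        ~ classify_stability(.x, .y, dist_group))
  structure(grid, class = c("stability_map", class(grid)),
            contour_solo = hopf_contour(dist_solo),
            contour_group = hopf_contour(dist_group))
}
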