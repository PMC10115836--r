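#' Pinhole camera model
#'
#' A 3 x 4 projection matrix in pixel units plus the sensor size. The left
#' 3 x 3 block must be nonsingular (a proper finite camera).
#'
#' @param p 3 x 4 projection matrix.
#' @param width,height Image size in pixels.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(p, width = 1280, height = 1024) {
  p <- as.matrix(p)
  stopifnot(nrow(p) == 3, ncol(p) == 4)
  if (abs(det(p[, 1:3])) < 1e-12) abort("left 3x3 block must be nonsingular")
  structure(list(p = p, width = width, height = height), class = "camera_model")
}

#' Synthetic multi-camera rig
#'
#' Builds a synthetic stand-in for the recording rig: cameras on a
#' horizontal arc of radius `radius` around the origin, all aimed at the
#' origin, with angular positions giving 50 and 70 degree separations by
#' default (the recordings used separations between 50 and 90 degrees).
#'
#' @param angles_deg Camera azimuths in degrees on the arc.
#' @param radius Arc radius in metres.
#' @param focal_px Focal length in pixels.
#' @param width,height Sensor size in pixels.
#' @param height_m Camera height above the target plane in metres.
#' @return A list of [camera_model()]s.
#' @export
camera_rig <- function(angles_deg = c(0, 50, 120), radius = 1.5,
                       focal_px = 1500, width = 1280, height = 1024,
                       height_m = 0.3) {
  k <- matrix(c(focal_px, 0, width / 2,
                0, focal_px, height / 2,
                0, 0, 1), 3, 3, byrow = TRUE)
  lapply(angles_deg, function(az) {
    a <- az * pi / 180
    centre <- c(radius * cos(a), radius * sin(a), height_m)
    zc <- -centre / sqrt(sum(centre^2))          # optical axis toward origin
    up <- c(0, 0, 1)
    xc <- cross3(zc, up); xc <- xc / sqrt(sum(xc^2))
    yc <- cross3(zc, xc)
    r <- rbind(xc, yc, zc)
    p <- k %*% cbind(r, -r %*% centre)
    camera_model(p, width, height)
  })
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# internal: project world points (matrix n x 3) through one camera;
# returns u, v and the depth (z in camera coordinates)
project_points <- function(cam, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  h <- cam$p %*% rbind(t(xyz), 1)
  list(u = h[1, ] / h[3, ], v = h[2, ] / h[3, ], depth = h[3, ])
}

#' Project 3-D trajectories into synthetic camera detections
#'
#' Homogeneous pinhole projection of each agent's 3-D position into each
#' camera, with Gaussian pixel noise and Bernoulli dropouts. Points behind a
#' camera are marked missing for that camera. Ground-truth identities are
#' retained in the `truth_id` column for testing; the tracker never uses
#' them.
#'
#' @param tracks Tibble with columns `t`, `agent`, `x`, `y`, `z` (all agents
#'   on a shared time base).
#' @param cameras List of [camera_model()]s (>= 2).
#' @param pixel_noise_sd Pixel noise standard deviation.
#' @param dropout_rate Per-detection dropout probability.
#' @param seed Integer seed.
#' @return A detections tibble: `t`, `camera`, `u`, `v`, `truth_id`.
#' @export
project_scene <- function(tracks, cameras, pixel_noise_sd = 0.5,
                          dropout_rate = 0, seed = NULL) {
  if (length(cameras) < 2L) abort("need at least 2 cameras")
  stopifnot(all(c("t", "agent", "x", "y", "z") %in% names(tracks)))
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::imap(cameras, function(cam, ci) {
    pr <- project_points(cam, cbind(tracks$x, tracks$y, tracks$z))
    keep <- pr$depth > 0 &
      pr$u >= 0 & pr$u <= cam$width & pr$v >= 0 & pr$v <= cam$height
    tibble(
      t = tracks$t[keep], camera = ci,
      u = pr$u[keep] + rnorm(sum(keep), 0, pixel_noise_sd),
      v = pr$v[keep] + rnorm(sum(keep), 0, pixel_noise_sd),
      truth_id = tracks$agent[keep]
    )
  })
  det <- bind_rows(out)
  if (dropout_rate > 0) det <- det[runif(nrow(det)) >= dropout_rate, ]
  det
}

#' Triangulate one 3-D point from multi-camera observations
#'
#' Linear least-squares (DLT) triangulation from one 2-D point per camera,
#' plus the mean Euclidean reprojection error in pixels, the quantity the
#' data association thresholds.
#'
#' @param obs Matrix (n_cameras x 2) of pixel coordinates, rows aligned with
#'   `cameras`; rows with NA are skipped.
#' @param cameras List of [camera_model()]s.
#' @return List with `point` (length-3) and `error` (mean pixel distance).
#' @export
triangulate <- function(obs, cameras) {
  obs <- matrix(obs, ncol = 2)
  use <- which(stats::complete.cases(obs))
  if (length(use) < 2L) abort("need observations from at least 2 cameras")
  a <- do.call(rbind, lapply(use, function(i) {
    p <- cameras[[i]]$p
    rbind(obs[i, 1] * p[3, ] - p[1, ],
          obs[i, 2] * p[3, ] - p[2, ])
  }))
  sv <- svd(a)
  if (sv$d[3] / sv$d[1] < 1e-10) abort("degenerate geometry (parallel rays)")
  xh <- sv$v[, 4]
  if (abs(xh[4]) < 1e-14) abort("point at infinity")
  x <- xh[1:3] / xh[4]
  errs <- vapply(use, function(i) {
    pr <- project_points(cameras[[i]], matrix(x, 1))
    sqrt((pr$u - obs[i, 1])^2 + (pr$v - obs[i, 2])^2)
  }, 0)
  list(point = x, error = mean(errs))
}

#' Associate one frame of multi-camera detections
#'
#' For every camera-1 detection, enumerates all m^(Nc-1) combinations of one
#' detection from each other camera, triangulates each combination, and
#' accepts the minimum-reprojection-error combination when its error is
#' below `sigma` pixels. When two camera-1 detections compete for the same
#' partner detections, assignments are resolved greedily by ascending
#' reprojection error, each non-camera-1 detection used at most once.
#'
#' @param frame Detections tibble for one time step (`camera`, `u`, `v`,
#'   optionally `truth_id`).
#' @param cameras List of [camera_model()]s.
#' @param sigma Reprojection-error acceptance threshold in pixels
#'   (default 3).
#' @return A tibble, one row per camera-1 detection: `det1` (its index in
#'   the frame's camera-1 subset), `matched`, `x`, `y`, `z`, `error`, and
#'   `members` (list column with the per-camera row indices used).
#' @export
associate_frame <- function(frame, cameras, sigma = 3) {
  nc <- length(cameras)
  percam <- lapply(seq_len(nc), function(ci) which(frame$camera == ci))
  if (!length(percam[[1]])) abort("no camera-1 detections in frame")

  # enumerate all candidate combinations for every camera-1 detection
  cands <- list()
  for (i1 in seq_along(percam[[1]])) {
    others <- percam[-1]
    if (any(!lengths(others))) next
    combos <- expand.grid(lapply(others, seq_along))
    for (r in seq_len(nrow(combos))) {
      rows <- c(percam[[1]][i1],
                vapply(seq_len(nc - 1L),
                       function(j) others[[j]][combos[r, j]], 0L))
      obs <- matrix(NA_real_, nc, 2)
      obs[1, ] <- c(frame$u[rows[1]], frame$v[rows[1]])
      for (j in 2:nc) obs[j, ] <- c(frame$u[rows[j]], frame$v[rows[j]])
      tri <- tryCatch(triangulate(obs, cameras), error = function(e) NULL)
      if (is.null(tri)) next
      cands[[length(cands) + 1L]] <-
        list(det1 = i1, rows = rows, point = tri$point, error = tri$error)
    }
  }

  n1 <- length(percam[[1]])
  out <- tibble(det1 = seq_len(n1), matched = FALSE,
                x = NA_real_, y = NA_real_, z = NA_real_,
                error = NA_real_, members = vector("list", n1))
  if (!length(cands)) return(out)

  errs <- vapply(cands, function(cc) cc$error, 0)
  used_other <- integer(0)
  done1 <- logical(n1)
  for (ci in order(errs)) {
    cc <- cands[[ci]]
    if (cc$error >= sigma) break
    if (done1[cc$det1]) next
    other_rows <- cc$rows[-1]
    if (any(other_rows %in% used_other)) next
    done1[cc$det1] <- TRUE
    used_other <- c(used_other, other_rows)
    out$matched[cc$det1] <- TRUE
    out$x[cc$det1] <- cc$point[1]
    out$y[cc$det1] <- cc$point[2]
    out$z[cc$det1] <- cc$point[3]
    out$error[cc$det1] <- cc$error
    out$members[[cc$det1]] <- cc$rows
  }
  out
}

#' Reconstruct 3-D tracks from a detection table
#'
#' Runs [associate_frame()] on every time step and links the reconstructed
#' points over time by nearest neighbor to the previous frame's track
#' positions. Intended for the small synthetic scenes used in testing the
#' association stage.
#'
#' @param detections Tibble from [project_scene()].
#' @param cameras List of [camera_model()]s.
#' @param sigma Association threshold in pixels.
#' @return A tibble `t`, `track_id`, `x`, `y`, `z`, `error`, `truth_id`
#'   (majority truth label of the member detections when available).
#' @export
track_scene <- function(detections, cameras, sigma = 3) {
  times <- sort(unique(detections$t))
  has_truth <- "truth_id" %in% names(detections)
  last_pos <- NULL   # matrix track_id rows x 3
  next_id <- 1L
  rows <- list()
  for (tt in times) {
    frame <- detections[detections$t == tt, ]
    if (!any(frame$camera == 1L)) next
    assoc <- associate_frame(frame, cameras, sigma)
    assoc <- assoc[assoc$matched, ]
    if (!nrow(assoc)) next
    pts <- cbind(assoc$x, assoc$y, assoc$z)
    ids <- integer(nrow(assoc))
    if (is.null(last_pos)) {
      ids <- seq_len(nrow(assoc))
      next_id <- nrow(assoc) + 1L
    } else {
      taken <- logical(nrow(last_pos))
      for (i in seq_len(nrow(assoc))) {
        d2 <- rowSums((last_pos[, 1:3, drop = FALSE] -
                         matrix(pts[i, ], nrow(last_pos), 3, byrow = TRUE))^2)
        d2[taken] <- Inf
        j <- which.min(d2)
        if (is.finite(d2[j])) {
          ids[i] <- last_pos[j, 4]
          taken[j] <- TRUE
        } else {
          ids[i] <- next_id
          next_id <- next_id + 1L
        }
      }
    }
    last_pos <- cbind(pts, ids)
    truth <- rep(NA_real_, nrow(assoc))
    if (has_truth) {
      truth <- vapply(assoc$members, function(m) {
        tv <- frame$truth_id[m]
        as.numeric(names(sort(table(tv), decreasing = TRUE))[1])
      }, 0)
    }
    rows[[length(rows) + 1L]] <- tibble(
      t = tt, track_id = ids, x = pts[, 1], y = pts[, 2], z = pts[, 3],
      error = assoc$error, truth_id = truth
    )
  }
  bind_rows(rows)
}

#' Bridge tracking dropouts with a constant-acceleration Kalman filter
#'
#' Per-axis Kalman filter with state (position, velocity, acceleration).
#' Measurement noise is epsilon^2 and process noise epsilon_a^2 on the
#' acceleration, matching the tracker's published parameters epsilon = 0.2,
#' epsilon_a = 0.8 (to which the identification results are insensitive).
#' Gaps are filled by pure prediction and flagged `imputed`; a gap at the
#' start of the track is left unfilled.
#'
#' @param track Tibble with columns `t`, `x`, `y`, `z` and logical `valid`.
#' @param epsilon Position (measurement) noise scale.
#' @param epsilon_a Acceleration (process) noise scale.
#' @return The track with gap samples filled, plus an `imputed` column and
#'   `x_s`, `y_s`, `z_s` smoothed coordinates.
#' @export
bridge_dropouts <- function(track, epsilon = 0.2, epsilon_a = 0.8) {
  stopifnot(all(c("t", "x", "y", "z", "valid") %in% names(track)))
  if (epsilon <= 0 || epsilon_a <= 0) abort("noise scales must be > 0")
  first_valid <- which(track$valid)
  if (length(first_valid) < 2L) abort("need at least 2 valid samples")
  dt <- median(diff(track$t))
  f <- matrix(c(1, dt, dt^2 / 2,
                0, 1, dt,
                0, 0, 1), 3, 3, byrow = TRUE)
  g <- c(dt^2 / 2, dt, 1)
  q <- epsilon_a^2 * tcrossprod(g)
  r <- epsilon^2

  out <- track
  out$imputed <- FALSE
  for (axis in c("x", "y", "z")) {
    z <- track[[axis]]
    xs <- numeric(nrow(track))
    state <- c(z[first_valid[1]], 0, 0)
    p <- diag(c(r, 1, 1))
    started <- FALSE
    for (k in seq_len(nrow(track))) {
      if (k < first_valid[1]) { xs[k] <- NA_real_; next }
      if (started) {
        state <- as.numeric(f %*% state)
        p <- f %*% p %*% t(f) + q
      }
      started <- TRUE
      if (track$valid[k]) {
        s <- p[1, 1] + r
        kg <- p[, 1] / s
        state <- state + kg * (z[k] - state[1])
        p <- p - tcrossprod(kg, p[1, ])
      } else {
        out$imputed[k] <- TRUE
      }
      xs[k] <- state[1]
    }
    out[[paste0(axis, "_s")]] <- xs
    fill <- out$imputed & !is.na(xs)
    out[[axis]][fill] <- xs[fill]
  }
  out$imputed[seq_len(first_valid[1] - 1L)] <- FALSE  # start gap left unfilled
  out
}

#' Label tracks as solo or group by pairwise coherence
#'
#' A track is labelled "group" when the mean magnitude-squared coherence of
#' its stimulus-axis coordinate (x) with any concurrently recorded track
#' exceeds `threshold` over `band_hz` - the criterion used to separate
#' insects flying with conspecifics from solitary ones. Tracks shorter than
#' one coherence window are labelled solo with a warning.
#'
#' @param tracks Tibble with columns `t`, `track_id`, `x`.
#' @param band_hz Frequency band c(f1, f2) in Hz (default c(0, 5)).
#' @param threshold Coherence threshold (default 0.6).
#' @return A tibble `track_id`, `role`, `peak_coherence` (the best pairwise
#'   mean coherence in band).
#' @export
segment_roles <- function(tracks, band_hz = c(0, 5), threshold = 0.6) {
  ids <- unique(tracks$track_id)
  peak <- setNames(rep(NA_real_, length(ids)), ids)
  for (i in seq_along(ids)) {
    ti <- tracks[tracks$track_id == ids[i], ]
    for (j in seq_along(ids)) {
      if (i == j) next
      tj <- tracks[tracks$track_id == ids[j], ]
      common <- intersect(ti$t, tj$t)
      if (length(common) < 32L) next
      si <- ti[match(common, ti$t), ]
      sj <- tj[match(common, tj$t), ]
      sp <- tryCatch(
        estimate_spectra(tibble(t = common, value = si$x),
                         tibble(t = common, value = sj$x)),
        error = function(e) NULL
      )
      if (is.null(sp)) next
      inband <- sp$freq >= band_hz[1] & sp$freq <= band_hz[2] & sp$freq > 0
      if (!any(inband)) next
      mc <- mean(sp$coherence[inband])
      if (is.na(peak[i]) || mc > peak[i]) peak[i] <- mc
    }
    if (is.na(peak[i]) && nrow(ti) < 32L) {
      warn(sprintf("track %s shorter than one coherence window; labelled solo", ids[i]))
    }
  }
  tibble(
    track_id = ids,
    role = unname(ifelse(!is.na(peak) & peak > threshold, "group", "solo")),
    peak_coherence = unname(as.numeric(peak))
  )
}
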