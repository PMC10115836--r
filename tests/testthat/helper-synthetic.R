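# Shared fixtures, built in code. The worked-example trial is cached once
# per test run because several files probe the same record.

example_trial_noisefree <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_tracking_trial(eq_example_model("freq"), duration = 4)
    }
    cache
  }
})

trial_signals <- function(trial) {
  list(
    stim = tibble::tibble(t = trial$t, value = trial$stimulus),
    resp = tibble::tibble(t = trial$t, value = trial$response)
  )
}

# small two-agent crossing scene for the tracking tests
two_agent_tracks <- function(duration = 2, fs = 60) {
  tt <- seq(0, duration, by = 1 / fs)
  dplyr::bind_rows(
    tibble::tibble(t = tt, agent = 1, x = 0.1 * sin(2 * pi * tt),
                   y = 0.05 * cos(2 * pi * tt), z = 0.1),
    tibble::tibble(t = tt, agent = 2, x = 0.1 * sin(2 * pi * tt + 2),
                   y = -0.05 * cos(2 * pi * tt), z = -0.08)
  )
}

# brute-force joint data association: over all ways to give each camera-1
# detection a disjoint combination (or leave it unmatched), maximize the
# number matched under the sigma gate, then minimize total reprojection
# error. Independent of the greedy implementation under test.
brute_force_associate <- function(frame, cameras, sigma) {
  nc <- length(cameras)
  idx1 <- which(frame$camera == 1)
  others <- lapply(2:nc, function(ci) which(frame$camera == ci))
  combos <- expand.grid(lapply(others, seq_along))
  tri_err <- function(rows) {
    obs <- matrix(NA_real_, nc, 2)
    for (j in seq_len(nc)) obs[j, ] <- c(frame$u[rows[j]], frame$v[rows[j]])
    tryCatch(triangulate(obs, cameras)$error, error = function(e) Inf)
  }
  # candidate table: det1 x combo -> error
  errs <- matrix(Inf, length(idx1), nrow(combos))
  members <- vector("list", length(idx1) * nrow(combos))
  for (i in seq_along(idx1)) {
    for (r in seq_len(nrow(combos))) {
      rows <- c(idx1[i], vapply(seq_len(nc - 1),
                                function(j) others[[j]][combos[r, j]], 0L))
      errs[i, r] <- tri_err(rows)
      members[[(i - 1) * nrow(combos) + r]] <- rows
    }
  }
  # enumerate joint assignments (including "unmatched" = 0)
  choices <- lapply(seq_along(idx1), function(i) 0:nrow(combos))
  joint <- expand.grid(choices)
  best <- NULL
  for (r in seq_len(nrow(joint))) {
    sel <- as.integer(joint[r, ])
    used <- list()
    total <- 0
    nmatch <- 0
    ok <- TRUE
    for (i in seq_along(sel)) {
      if (sel[i] == 0) next
      if (errs[i, sel[i]] >= sigma) { ok <- FALSE; break }
      rows <- members[[(i - 1) * nrow(combos) + sel[i]]][-1]
      if (any(rows %in% unlist(used))) { ok <- FALSE; break }
      used[[length(used) + 1]] <- rows
      total <- total + errs[i, sel[i]]
      nmatch <- nmatch + 1
    }
    if (!ok) next
    if (is.null(best) || nmatch > best$nmatch ||
        (nmatch == best$nmatch && total < best$total)) {
      best <- list(sel = sel, nmatch = nmatch, total = total)
    }
  }
  matched <- best$sel > 0
  err <- rep(NA_real_, length(idx1))
  for (i in seq_along(idx1)) if (matched[i]) err[i] <- errs[i, best$sel[i]]
  list(matched = matched, error = err)
}
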