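# mean of Normal(mean, sd) truncated below at `lower`
truncnorm_mean <- function(mean, sd, lower) {
  if (sd == 0) return(mean)
  a <- (lower - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# E[1/T] for T ~ Normal(mean, sd) truncated below at `lower` (quadrature)
truncnorm_mean_inv <- function(mean, sd, lower) {
  if (sd == 0) return(1 / mean)
  a <- (lower - mean) / sd
  z <- 1 - stats::pnorm(a)
  stats::integrate(function(t) stats::dnorm(t, mean, sd) / (z * t),
                   lower = lower, upper = mean + 10 * sd,
                   rel.tol = 1e-10)$value
}

# E[S_l / T_l] over the independent truncated larva-level distributions
expected_net_rate <- function(p) {
  truncnorm_mean(p$stride_length_mean, p$stride_length_sd, 1e-9) *
    truncnorm_mean_inv(p$stride_duration_mean, p$stride_duration_sd,
                       0.5 * p$stride_duration_mean)
}

# per-larva wobble amplitude: solves the time-weighted mean path rate
# sum_j T_j sqrt(d_j^2 + w^2) * fps / sum_j T_j = v on the realised cycles,
# with d_j = S_j / (T_j fps); 0 when the realised net rate already >= v
solve_wobble <- function(S_j, T_j, v, fps) {
  d_j <- S_j / (T_j * fps)
  path_rate <- function(w) sum(T_j * sqrt(d_j^2 + w^2)) * fps / sum(T_j)
  if (path_rate(0) >= v) return(0)
  stats::uniroot(function(w) path_rate(w) - v,
                 lower = 0, upper = v / fps, tol = 1e-12)$root
}

#' Simulate one crawling larva
#'
#' Generates a spine-tracking time series for a single peristaltically
#' crawling larva. The construction inverts the downstream measurement
#' model, so the kinematics pipeline recovers the generating parameters:
#'
#' * the larva's own mean stride length `S_l` and stride duration `T_l`
#'   are drawn once from `Normal(stride_length_mean, stride_length_sd)`
#'   (truncated at 0) and `Normal(stride_duration_mean,
#'   stride_duration_sd)` (truncated at half the mean): the sd parameters
#'   are the between-larva spread of per-larva means, which is what a
#'   cohort's SEM times sqrt(n) estimates. Individual cycles then jitter
#'   around the larva's means with the same sd (truncated identically);
#' * within cycle `j` the spine length follows
#'   `L(t) = L0 - a cos(2 pi phi_j(t))` with the phase `phi_j` rising 0 to
#'   1 over the cycle, so the derivative of the spine length has a
#'   positive-going zero crossing exactly at each cycle boundary;
#' * the centroid advances `S_j` net millimetres over cycle `j`, linearly
#'   in time, along a heading that performs a random walk with per-cycle
#'   steps `Normal(0, heading_sd)`;
#' * the larva's target walking rate scales with its own net rate,
#'   `v_l = walking_rate_mean * (S_l/T_l) / E[S_l/T_l]` (the expectation
#'   taken over the truncated larva-level distributions, computed by
#'   quadrature), so the path-to-net ratio is a shared gait constant, the
#'   cohort mean walking rate equals `walking_rate_mean`, and `v_l` never
#'   falls below the larva's net rate;
#' * a constant-amplitude lateral wobble, alternating side every frame,
#'   raises the per-frame path rate from the net rate to `v_l`. Each
#'   frame's step satisfies `|step|^2 = d_j^2 + w^2` with
#'   `d_j = S_j / (T_j fps)` the cycle's net step, and the per-larva `w`
#'   solves the time-weighted mean path rate equation
#'   `sum_j T_j sqrt(d_j^2 + w^2) fps / sum_j T_j = v_l` on the realised
#'   cycle draws (`w = 0` when the realised net rate already exceeds
#'   `v_l`).
#'
#' Five spine points are laid out collinearly along the instantaneous
#' heading, spaced `L(t)/4` apart, the third point being the centroid.
#'
#' @param params a [kinematic_params()] object.
#' @param seed integer seed; identical `(params, seed)` give bit-identical
#'   tracks.
#' @param larva_id identifier stored on the track.
#' @return an object of class `spine_track`: a list with `larva_id`, `fps`,
#'   `time` (s), `x` and `y` (`n x 5` matrices, mm, columns head to tail),
#'   `gap` (logical per frame) and a `truth` attribute holding the per-cycle
#'   draws.
#' @seealso [simulate_cohort()], [summarize_larva()]
#' @export
simulate_larva <- function(params, seed, larva_id = "larva_1") {
  stopifnot(inherits(params, "kinematic_params"))
  set.seed(as.integer(seed))
  p <- params

  n_frames <- round(p$fps * p$duration)
  if (n_frames < 2) stop("duration too short for the given fps")
  t_frames <- (seq_len(n_frames) - 1) / p$fps

  # larva-level means (between-larva variability), then per-cycle jitter
  S_l <- rnorm_trunc(1, p$stride_length_mean, p$stride_length_sd, lower = 1e-9)
  T_l <- rnorm_trunc(1, p$stride_duration_mean, p$stride_duration_sd,
                     lower = 0.5 * p$stride_duration_mean)
  v_l <- p$walking_rate_mean * (S_l / T_l) / expected_net_rate(p)

  # draw cycles until they cover the recording (plus one spare)
  n_guess <- ceiling(p$duration / (0.5 * p$stride_duration_mean)) + 2L
  draw_T <- function(k) rnorm_trunc(k, T_l, p$stride_duration_sd,
                                    lower = 0.5 * p$stride_duration_mean)
  draw_S <- function(k) rnorm_trunc(k, S_l, p$stride_length_sd, lower = 1e-9)
  T_j <- draw_T(n_guess)
  S_j <- draw_S(n_guess)
  pause_j <- if (p$pause_prob > 0) {
    stats::runif(n_guess) < p$pause_prob
  } else rep(FALSE, n_guess)
  while (sum(T_j + ifelse(pause_j, p$pause_duration, 0)) < p$duration + p$stride_duration_mean) {
    T_j <- c(T_j, draw_T(4L))
    S_j <- c(S_j, draw_S(4L))
    pause_j <- c(pause_j, if (p$pause_prob > 0) stats::runif(4L) < p$pause_prob
                 else rep(FALSE, 4L))
  }
  n_cyc <- length(T_j)

  theta0 <- stats::runif(1, 0, 2 * pi)
  dtheta <- if (p$heading_sd > 0) stats::rnorm(n_cyc, 0, p$heading_sd) else numeric(n_cyc)
  theta_j <- theta0 + cumsum(c(0, dtheta[-n_cyc]))

  # segment table: cycles interleaved with optional pauses at boundaries
  seg_dur   <- numeric(0); seg_cycle <- integer(0); seg_pause <- logical(0)
  for (j in seq_len(n_cyc)) {
    seg_dur <- c(seg_dur, T_j[j]); seg_cycle <- c(seg_cycle, j); seg_pause <- c(seg_pause, FALSE)
    if (pause_j[j]) {
      seg_dur <- c(seg_dur, p$pause_duration); seg_cycle <- c(seg_cycle, j); seg_pause <- c(seg_pause, TRUE)
    }
  }
  seg_start <- cumsum(c(0, seg_dur[-length(seg_dur)]))

  # cumulative centroid position at cycle starts
  dx <- S_j * cos(theta_j); dy <- S_j * sin(theta_j)
  x_at_cycle_start <- cumsum(c(0, dx[-n_cyc]))
  y_at_cycle_start <- cumsum(c(0, dy[-n_cyc]))

  seg_idx <- findInterval(t_frames, seg_start)
  cyc <- seg_cycle[seg_idx]
  is_pause <- seg_pause[seg_idx]
  frac <- ifelse(is_pause, 0,
                 (t_frames - seg_start[seg_idx]) / seg_dur[seg_idx])

  cx <- x_at_cycle_start[cyc] + frac * dx[cyc]
  cy <- y_at_cycle_start[cyc] + frac * dy[cyc]

  # lateral wobble: alternate between two rails perpendicular to the heading;
  # amplitude solves the time-weighted path-rate equation on the realised draws
  w <- solve_wobble(S_j, T_j, v_l, p$fps)
  rail <- (seq_len(n_frames) - 1) %% 2
  # during a pause the whole position (rail included) is frozen below
  cx <- cx + rail * w * (-sin(theta_j[cyc]))
  cy <- cy + rail * w * ( cos(theta_j[cyc]))
  if (any(is_pause)) {
    for (k in which(is_pause)) {
      prev <- max(which(!is_pause[seq_len(k)]), 1L)
      cx[k] <- cx[prev]; cy[k] <- cy[prev]
    }
  }

  # spine length phase: phi = frac within the active cycle, frozen in pauses
  a <- p$contraction_amplitude * p$spine_length_rest
  L <- p$spine_length_rest - a * cos(2 * pi * frac)

  u_x <- cos(theta_j[cyc]); u_y <- sin(theta_j[cyc])
  offs <- (3 - seq_len(5)) / 4                      # head (+L/2) to tail (-L/2)
  x <- outer(L, offs) * u_x + cx
  y <- outer(L, offs) * u_y + cy

  structure(list(
    larva_id = larva_id,
    fps = p$fps,
    time = t_frames,
    x = x, y = y,
    gap = rep(FALSE, n_frames)
  ),
  truth = list(T_j = T_j, S_j = S_j, theta_j = theta_j, wobble = w,
               S_l = S_l, T_l = T_l, v_l = v_l,
               params = p, seed = as.integer(seed)),
  class = "spine_track")
}

#' @export
print.spine_track <- function(x, ...) {
  cat(sprintf("<spine_track> %s: %d frames at %g fps (%.1f s), %d gap frame(s)\n",
              x$larva_id, length(x$time), x$fps,
              length(x$time) / x$fps, sum(x$gap)))
  invisible(x)
}

#' Simulate a cohort of crawling larvae
#'
#' Generates `n` independent larvae with per-larva sub-seeds derived from
#' `seed` by a counter scheme (`seed + i` for larva `i`), so the cohort is
#' reproducible and independent of call order.
#'
#' @param n number of larvae.
#' @param params a [kinematic_params()] object shared by the cohort.
#' @param seed integer base seed.
#' @param genotype label attached to every larva in the metadata table.
#' @return an object of class `track_cohort`: list with `tracks` (list of
#'   `spine_track`) and `metadata` (data.frame larva_id, genotype, seed).
#' @export
simulate_cohort <- function(n, params, seed, genotype = "control") {
  if (n < 1) stop("'n' must be >= 1")
  ids <- sprintf("%s_%03d", genotype, seq_len(n))
  seeds <- vapply(seq_len(n), function(i) derive_subseed(seed, i), integer(1))
  tracks <- lapply(seq_len(n), function(i)
    simulate_larva(params, seed = seeds[i], larva_id = ids[i]))
  names(tracks) <- ids
  structure(list(
    tracks = tracks,
    metadata = data.frame(larva_id = ids, genotype = genotype,
                          seed = seeds, stringsAsFactors = FALSE)
  ), class = "track_cohort")
}

#' @export
print.track_cohort <- function(x, ...) {
  cat(sprintf("<track_cohort> %d larvae (%s)\n", length(x$tracks),
              paste(unique(x$metadata$genotype), collapse = ", ")))
  invisible(x)
}
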