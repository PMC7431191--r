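#' Spine length time series
#'
#' Computes the spine length at every frame as the sum of the Euclidean
#' distances between the four successive pairs of the five tracked spine
#' points. Gap frames propagate as `NA`.
#'
#' @param track a `spine_track`.
#' @return an object of class `spine_length_series`: data.frame with
#'   `time` (s), `L` (mm) and `dLdt` (mm/s, `NA` until
#'   [smooth_derivative()] fills it); the track's `fps` and `larva_id`
#'   are carried as attributes.
#' @export
spine_length <- function(track) {
  stopifnot(inherits(track, "spine_track"))
  dx <- track$x[, -1, drop = FALSE] - track$x[, -5, drop = FALSE]
  dy <- track$y[, -1, drop = FALSE] - track$y[, -5, drop = FALSE]
  L <- rowSums(sqrt(dx^2 + dy^2))
  L[track$gap] <- NA_real_
  structure(
    data.frame(time = track$time, L = L, dLdt = NA_real_),
    fps = track$fps, larva_id = track$larva_id,
    class = c("spine_length_series", "data.frame"))
}

#' Smoothed derivative of the spine length
#'
#' Smooths `L` with a centred moving average of odd `window` length
#' (shrinking one-sidedly at the ends and around gaps), then differentiates
#' by central differences scaled by the frame rate; the two endpoints use
#' one-sided differences. The result is the smoothly-oscillating-around-zero
#' series whose positive-going zero crossings delimit peristalsis cycles.
#'
#' @param series a `spine_length_series`.
#' @param window odd moving-average length in frames; `window = 1` disables
#'   smoothing. Default 3 frames (0.6 s at 5 fps): at ~5.5 frames per cycle
#'   a wider window would flatten the oscillation itself.
#' @return the series with `dLdt` filled (mm/s).
#' @export
smooth_derivative <- function(series, window = 3) {
  stopifnot(inherits(series, "spine_length_series"))
  if (window %% 2 != 1 || window < 1) stop("'window' must be odd and >= 1")
  n <- nrow(series)
  if (n < 3) stop("need at least 3 frames to differentiate")
  if (window > n) stop("'window' larger than the series")
  fps <- attr(series, "fps")
  L <- series$L

  Ls <- L
  if (window > 1) {
    half <- (window - 1) / 2
    Ls <- vapply(seq_len(n), function(i) {
      idx <- max(1, i - half):min(n, i + half)
      mean(L[idx])                       # NA if any gap in the window
    }, numeric(1))
  }

  d <- rep(NA_real_, n)
  d[2:(n - 1)] <- (Ls[3:n] - Ls[1:(n - 2)]) * fps / 2
  d[1] <- (Ls[2] - Ls[1]) * fps
  d[n] <- (Ls[n] - Ls[n - 1]) * fps
  series$dLdt <- d
  series$L_smooth <- Ls
  series
}

#' Segment peristalsis cycles by zero crossings
#'
#' A cycle boundary is a positive-going zero crossing of the smoothed
#' spine-length derivative (the start of elongation); crossing times are
#' linearly interpolated between the bracketing frames so durations are not
#' quantised to the frame interval. Cycles shorter than
#' `min_cycle_duration` are merged into the following cycle; partial cycles
#' at the record edges are discarded; crossings are never formed across gap
#' frames.
#'
#' @param series a `spine_length_series` with `dLdt` filled.
#' @param min_cycle_duration minimum credible cycle length, s. Default
#'   0.4 s, under half a typical larval stride duration, to reject
#'   jitter-induced double crossings.
#' @param zero_tol derivative magnitudes below this (mm/s) are treated as
#'   exactly zero, so numerically flat series yield no crossings.
#' @return an object of class `peristalsis_cycles`: data.frame with
#'   `t_start`, `t_end`, `duration` (one row per complete cycle; may be
#'   empty).
#' @export
segment_cycles <- function(series, min_cycle_duration = 0.4,
                           zero_tol = 1e-9) {
  stopifnot(inherits(series, "spine_length_series"))
  if (all(is.na(series$dLdt))) stop("dLdt not computed; run smooth_derivative()")
  t <- series$time
  d <- series$dLdt
  d[!is.na(d) & abs(d) < zero_tol] <- 0

  ok <- !is.na(d)
  # contiguous runs of valid frames; crossings only inside a run
  run_id <- cumsum(!ok)
  crossings <- numeric(0)
  for (r in unique(run_id[ok])) {
    idx <- which(ok & run_id == r)
    if (length(idx) < 2) next
    di <- d[idx]; ti <- t[idx]
    i <- which(di[-length(di)] < 0 & di[-1] >= 0)
    if (length(i) == 0) next
    tc <- ti[i] + (-di[i]) / (di[i + 1] - di[i]) * (ti[i + 1] - ti[i])
    crossings <- c(crossings, tc)
  }
  crossings <- sort(crossings)
  if (length(crossings) < 2)
    return(structure(data.frame(t_start = numeric(0), t_end = numeric(0),
                                duration = numeric(0)),
                     class = c("peristalsis_cycles", "data.frame")))

  # merge short cycles into the following cycle by dropping their end boundary
  b <- crossings
  repeat {
    dur <- diff(b)
    short <- which(dur < min_cycle_duration)
    if (length(short) == 0) break
    b <- b[-(short[1] + 1)]
    if (length(b) < 2) break
  }
  if (length(b) < 2)
    return(structure(data.frame(t_start = numeric(0), t_end = numeric(0),
                                duration = numeric(0)),
                     class = c("peristalsis_cycles", "data.frame")))
  structure(data.frame(t_start = b[-length(b)], t_end = b[-1],
                       duration = diff(b)),
            class = c("peristalsis_cycles", "data.frame"))
}

# centroid (3rd spine point) position at arbitrary times, linearly
# interpolated; NA when the bracketing frames include a gap
centroid_at <- function(track, times) {
  ok <- !track$gap
  x <- stats::approx(track$time[ok], track$x[ok, 3], xout = times)$y
  y <- stats::approx(track$time[ok], track$y[ok, 3], xout = times)$y
  gap_t <- track$time[track$gap]
  if (length(gap_t) > 0) {
    dt <- 1 / track$fps
    near_gap <- vapply(times, function(tt) any(abs(tt - gap_t) < dt), logical(1))
    x[near_gap] <- NA_real_; y[near_gap] <- NA_real_
  }
  cbind(x = x, y = y)
}

#' Stride length and duration per cycle
#'
#' Fills each segmented cycle with its stride duration
#' `T = t_end - t_start` and stride length `S`, the net (straight-line)
#' displacement of the centroid (3rd spine point) between the interpolated
#' cycle boundaries. Cycles spanning a gap are dropped.
#'
#' @param track the `spine_track` the cycles were segmented from.
#' @param cycles a `peristalsis_cycles` table.
#' @return the cycles table with `S` (mm) and `T` (s) columns.
#' @export
stride_metrics <- function(track, cycles) {
  stopifnot(inherits(track, "spine_track"),
            inherits(cycles, "peristalsis_cycles"))
  if (nrow(cycles) == 0) {
    cycles$S <- numeric(0); cycles$T <- numeric(0)
    return(cycles)
  }
  p0 <- centroid_at(track, cycles$t_start)
  p1 <- centroid_at(track, cycles$t_end)
  cycles$S <- sqrt((p1[, 1] - p0[, 1])^2 + (p1[, 2] - p0[, 2])^2)
  cycles$T <- cycles$duration
  keep <- !is.na(cycles$S)
  if (any(track$gap)) {
    gap_t <- track$time[track$gap]
    spans <- vapply(seq_len(nrow(cycles)), function(i)
      any(gap_t > cycles$t_start[i] & gap_t < cycles$t_end[i]), logical(1))
    keep <- keep & !spans
  }
  cycles[keep, , drop = FALSE]
}

#' Walking rate (crawling speed)
#'
#' The mean over frames of the frame-to-frame displacement of the centroid
#' (3rd spine point) times the frame rate, i.e. the centroid path rate
#' averaged across the whole recording. Steps adjacent to gap frames are
#' skipped.
#'
#' @param track a `spine_track` with at least 2 frames.
#' @return walking rate in mm/s.
#' @export
walking_rate <- function(track) {
  stopifnot(inherits(track, "spine_track"))
  n <- length(track$time)
  if (n < 2) stop("need at least 2 frames")
  ok <- !track$gap
  valid <- ok[-n] & ok[-1]
  if (!any(valid)) stop("no valid frame-to-frame steps (all gapped)")
  dx <- diff(track$x[, 3]); dy <- diff(track$y[, 3])
  mean(sqrt(dx[valid]^2 + dy[valid]^2)) * track$fps
}

#' Per-larva kinematic summary
#'
#' Runs the full measurement chain — spine length, smoothed derivative,
#' cycle segmentation, stride metrics, walking rate — and averages the
#' per-cycle values across the recording, one larva as the statistical
#' unit. Larvae with no complete cycle carry the walking rate only and are
#' flagged.
#'
#' @param track a `spine_track`.
#' @param window smoothing window, frames (see [smooth_derivative()]).
#' @param min_cycle_duration minimum cycle length, s (see
#'   [segment_cycles()]).
#' @return an object of class `larva_kinematics`: one-row data.frame with
#'   `larva_id`, `walking_rate` (mm/s), `stride_length_mean` (mm),
#'   `stride_duration_mean` (s), `n_cycles`, `no_cycles` flag.
#' @export
summarize_larva <- function(track, window = 3, min_cycle_duration = 0.4) {
  series <- smooth_derivative(spine_length(track), window = window)
  cycles <- stride_metrics(track, segment_cycles(series, min_cycle_duration))
  n_cyc <- nrow(cycles)
  structure(data.frame(
    larva_id = track$larva_id,
    walking_rate = walking_rate(track),
    stride_length_mean = if (n_cyc > 0) mean(cycles$S) else NA_real_,
    stride_duration_mean = if (n_cyc > 0) mean(cycles$T) else NA_real_,
    n_cycles = n_cyc,
    no_cycles = n_cyc == 0,
    stringsAsFactors = FALSE
  ), class = c("larva_kinematics", "data.frame"))
}

#' Cohort kinematics table
#'
#' Applies [summarize_larva()] to every track of a cohort and joins the
#' genotype metadata.
#'
#' @param cohort a `track_cohort` (or plain list of `spine_track`).
#' @param metadata optional data.frame with `larva_id` and `genotype`;
#'   taken from the cohort when present.
#' @inheritParams summarize_larva
#' @return data.frame of class `cohort_kinematics`, one row per larva, with
#'   the per-cycle table attached as attribute `"cycles"`.
#' @export
analyze_cohort <- function(cohort, metadata = NULL, window = 3,
                           min_cycle_duration = 0.4) {
  tracks <- if (inherits(cohort, "track_cohort")) cohort$tracks else cohort
  metadata <- metadata %||%
    (if (inherits(cohort, "track_cohort")) cohort$metadata else NULL)
  rows <- lapply(tracks, summarize_larva, window = window,
                 min_cycle_duration = min_cycle_duration)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  cyc <- lapply(tracks, function(tr) {
    s <- smooth_derivative(spine_length(tr), window = window)
    cc <- stride_metrics(tr, segment_cycles(s, min_cycle_duration))
    if (nrow(cc) > 0) cbind(larva_id = tr$larva_id, cc) else NULL
  })
  cyc <- do.call(rbind, c(Filter(Negate(is.null), cyc),
                          list(make.row.names = FALSE)))
  if (!is.null(metadata))
    out <- merge(out, metadata[, c("larva_id", "genotype")],
                 by = "larva_id", sort = FALSE)
  structure(out, cycles = cyc,
            class = c("cohort_kinematics", "data.frame"))
}
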