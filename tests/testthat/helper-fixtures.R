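# shared fixtures and independent oracles

# small, fast kinematic parameter set for property tests
quick_kin <- function(...) {
  kinematic_params(walking_rate_mean = 1.15, stride_length_mean = 1.17,
                   stride_length_sd = 0.1, stride_duration_mean = 1.09,
                   stride_duration_sd = 0.1, heading_sd = 0.1,
                   fps = 5, duration = 20, ...)
}

# hand-built spine track from coordinate matrices
make_track <- function(x, y, fps = 5, gap = NULL, id = "t") {
  n <- nrow(x)
  structure(list(larva_id = id, fps = fps, time = (seq_len(n) - 1) / fps,
                 x = x, y = y, gap = gap %||% rep(FALSE, n)),
            class = "spine_track")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# straight-crawling track: centroid advances at `speed` mm/s along +x,
# 5 collinear points with constant spine length L0
straight_track <- function(speed = 1, fps = 5, duration = 20, L0 = 4) {
  n <- round(fps * duration)
  t <- (seq_len(n) - 1) / fps
  cx <- speed * t
  offs <- (3 - 1:5) / 4 * L0
  make_track(outer(cx, rep(1, 5)) + matrix(offs, n, 5, byrow = TRUE),
             matrix(0, n, 5), fps = fps)
}

# track whose spine length follows L(t) (collinear, stationary centroid)
oscillating_track <- function(Lfun, fps = 5, duration = 20) {
  n <- round(fps * duration)
  t <- (seq_len(n) - 1) / fps
  L <- Lfun(t)
  make_track(outer(L, (3 - 1:5) / 4), matrix(0, n, 5), fps = fps)
}

# independent zero-crossing oracle: positive-going roots of analytic f on
# [t0, t1], located by sign scan on a fine grid + uniroot refinement
oracle_crossings <- function(f, t0, t1, step = 1e-4) {
  g <- seq(t0, t1, by = step)
  v <- f(g)
  i <- which(v[-length(v)] < 0 & v[-1] >= 0)
  vapply(i, function(k)
    stats::uniroot(f, c(g[k], g[k + 1]), tol = 1e-12)$root, numeric(1))
}

# build an in-memory image_stack from an array (c, z, y, x)
as_stack <- function(arr, channels = c("col", "nau")) {
  structure(arr, channels = channels, pixel_size = NA_real_,
            class = "image_stack")
}
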