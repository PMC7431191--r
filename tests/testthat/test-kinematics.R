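test_that("spine length sums the four segment distances", {
  # 5 collinear points spaced 1 mm
  x <- matrix(rep(4:0, each = 3), nrow = 3)
  tr <- make_track(x, matrix(0, 3, 5))
  expect_equal(spine_length(tr)$L, rep(4, 3))
  # folded at a right angle: two 2-mm arms, 1-mm spacing; still L = 4
  xf <- matrix(rep(c(0, 0, 0, 1, 2), each = 3), nrow = 3)
  yf <- matrix(rep(c(2, 1, 0, 0, 0), each = 3), nrow = 3)
  trf <- make_track(xf, yf)
  expect_equal(spine_length(trf)$L, rep(4, 3))
  # generator with zero contraction amplitude: constant L = L0
  p <- kinematic_params(contraction_amplitude = 0, spine_length_rest = 4)
  trg <- simulate_larva(p, 5)
  expect_equal(spine_length(trg)$L, rep(4, length(trg$time)), tolerance = 1e-12)
})

test_that("smoothed derivative matches analytic expectations", {
  # constant L -> dLdt identically 0
  tr <- oscillating_track(function(t) rep(4, length(t)))
  s <- smooth_derivative(spine_length(tr), window = 3)
  expect_equal(s$dLdt, rep(0, nrow(s)))
  # linear L = 2t -> 2 mm/s everywhere (one-sided ends included)
  tr2 <- oscillating_track(function(t) 4 + 2 * t)
  s2 <- smooth_derivative(spine_length(tr2), window = 1)
  expect_equal(s2$dLdt, rep(2, nrow(s2)), tolerance = 1e-10)
  # sine at 5 fps, window 1: central difference attenuates by sinc(2*pi*h)
  tr3 <- oscillating_track(function(t) 4 + 0.5 * sin(2 * pi * t))
  s3 <- smooth_derivative(spine_length(tr3), window = 1)
  h <- 1 / 5
  atten <- sin(2 * pi * h) / (2 * pi * h)
  interior <- 2:(nrow(s3) - 1)
  expected <- 0.5 * 2 * pi * cos(2 * pi * s3$time[interior]) * atten
  expect_equal(s3$dLdt[interior], expected, tolerance = 1e-8)
  expect_error(smooth_derivative(spine_length(tr3), window = 2), "odd")
  expect_error(smooth_derivative(spine_length(tr3), window = 999), "larger")
})

test_that("cycle segmentation matches a brute-force zero-crossing oracle", {
  # analytic dLdt = sin(2 pi t): sample L = -cos(2 pi t)/(2 pi) densely so
  # interpolation error is far below 1e-6 s, and compare crossing times to
  # uniroot-refined fine-grid roots of the analytic derivative
  fps <- 1000
  n <- 10 * fps
  t <- (seq_len(n) - 1) / fps
  # crossings at 0.5, 1.5, ..., 9.5 -> 9 complete interior cycles in 10 s
  tr <- make_track(outer(4 - cos(2 * pi * (t - 0.5)) / (2 * pi), (3 - 1:5) / 4),
                   matrix(0, n, 5), fps = fps)
  s <- smooth_derivative(spine_length(tr), window = 1)
  cyc <- segment_cycles(s, min_cycle_duration = 0.4)
  oracle <- oracle_crossings(function(u) sin(2 * pi * (u - 0.5)), 0, max(t))
  oracle <- oracle[oracle > min(t) & oracle < max(t)]
  expect_equal(nrow(cyc), 9L)
  expect_equal(nrow(cyc), length(oracle) - 1)
  bounds <- c(cyc$t_start, cyc$t_end[nrow(cyc)])
  expect_lt(max(abs(bounds - oracle)), 1e-6)
  expect_equal(cyc$duration, rep(1, nrow(cyc)), tolerance = 1e-6)
})

test_that("degenerate derivative series yield no cycles", {
  tr <- oscillating_track(function(t) rep(4, length(t)))
  s <- smooth_derivative(spine_length(tr))
  expect_equal(nrow(segment_cycles(s)), 0L)
  expect_error(segment_cycles(spine_length(tr)), "dLdt")
})

test_that("noise-free simulated larva recovers its stride duration", {
  p <- kinematic_params(walking_rate_mean = 1.2, stride_length_mean = 1.17,
                        stride_duration_mean = 1.1, fps = 5, duration = 20)
  tr <- simulate_larva(p, 21)
  s <- smooth_derivative(spine_length(tr))
  cyc <- segment_cycles(s)
  expect_gt(nrow(cyc), 10)
  expect_equal(mean(cyc$duration), 1.1, tolerance = 0.02)
})

test_that("stride metrics give net displacement and duration", {
  # stationary larva with oscillating spine: S = 0 each cycle
  tr <- oscillating_track(function(t) 4 - 0.6 * cos(2 * pi * t / 1.0),
                          fps = 20, duration = 10)
  s <- smooth_derivative(spine_length(tr), window = 1)
  cyc <- stride_metrics(tr, segment_cycles(s))
  expect_gt(nrow(cyc), 5)
  expect_equal(cyc$S, rep(0, nrow(cyc)), tolerance = 1e-9)
  # straight motion at 1 mm/s with 1-s cycles: S = 1 mm, T = 1 s
  n <- 200; fps <- 20
  t <- (seq_len(n) - 1) / fps
  L <- 4 - 0.6 * cos(2 * pi * t)
  x <- outer(L, (3 - 1:5) / 4) + t        # centroid at x = t
  tr2 <- make_track(x, matrix(0, n, 5), fps = fps)
  s2 <- smooth_derivative(spine_length(tr2), window = 1)
  cyc2 <- stride_metrics(tr2, segment_cycles(s2))
  expect_equal(cyc2$S, rep(1, nrow(cyc2)), tolerance = 1e-6)
  expect_equal(cyc2$T, rep(1, nrow(cyc2)), tolerance = 1e-6)
})

test_that("walking rate is the mean per-frame centroid displacement rate", {
  expect_equal(walking_rate(straight_track(speed = 1)), 1)
  expect_equal(walking_rate(straight_track(speed = 0)), 0)
  expect_error(walking_rate(make_track(matrix(0, 1, 5), matrix(0, 1, 5))),
               "2 frames")
})

test_that("per-larva summary composes the chain and flags empty larvae", {
  p <- kinematic_params(walking_rate_mean = 1.2, stride_length_mean = 1.17,
                        stride_duration_mean = 1.1, fps = 5, duration = 20)
  lk <- summarize_larva(simulate_larva(p, 31))
  expect_equal(lk$walking_rate, 1.2, tolerance = 0.03)
  expect_equal(lk$stride_length_mean, 1.17, tolerance = 0.03)
  expect_equal(lk$stride_duration_mean, 1.1, tolerance = 0.03)
  expect_false(lk$no_cycles)
  # constant-length crawler: no cycles, flag set, walking rate still present
  lk0 <- summarize_larva(straight_track(speed = 1))
  expect_true(lk0$no_cycles)
  expect_true(is.na(lk0$stride_length_mean))
  expect_equal(lk0$walking_rate, 1)
})

test_that("net displacement never exceeds path length and units scale", {
  p <- quick_kin()
  for (seed in 1:5) {
    tr <- simulate_larva(p, seed)
    s <- smooth_derivative(spine_length(tr))
    cyc <- stride_metrics(tr, segment_cycles(s))
    path <- sum(sqrt(diff(tr$x[, 3])^2 + diff(tr$y[, 3])^2))
    expect_lte(sum(cyc$S), path + 1e-9)
    # scaling coordinates by k scales S and v by k, leaves T unchanged
    k <- 2.5
    trk <- tr; trk$x <- tr$x * k; trk$y <- tr$y * k
    sk <- smooth_derivative(spine_length(trk))
    cyck <- stride_metrics(trk, segment_cycles(sk))
    expect_equal(cyck$S, cyc$S * k, tolerance = 1e-9)
    expect_equal(cyck$T, cyc$T, tolerance = 1e-9)
    expect_equal(walking_rate(trk), walking_rate(tr) * k, tolerance = 1e-9)
  }
})

test_that("time reversal flips crossing polarity: counts differ by <= 1", {
  p <- quick_kin()
  for (seed in 6:9) {
    tr <- simulate_larva(p, seed)
    s <- smooth_derivative(spine_length(tr))
    n_fwd <- nrow(segment_cycles(s, min_cycle_duration = 0))
    trr <- tr
    trr$x <- tr$x[rev(seq_len(nrow(tr$x))), ]
    trr$y <- tr$y[rev(seq_len(nrow(tr$y))), ]
    sr <- smooth_derivative(spine_length(trr))
    n_rev <- nrow(segment_cycles(sr, min_cycle_duration = 0))
    expect_lte(abs(n_fwd - n_rev), 1)
  }
})

test_that("gap frames are respected end to end", {
  tr <- straight_track(speed = 1)
  tr$gap[50] <- TRUE
  tr$x[50, ] <- NA; tr$y[50, ] <- NA
  expect_true(is.na(spine_length(tr)$L[50]))
  expect_equal(walking_rate(tr), 1)      # gap-adjacent steps skipped
})
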