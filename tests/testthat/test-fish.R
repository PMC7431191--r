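test_that("sum projection is the pixelwise z-sum per channel", {
  set.seed(1)
  slice <- matrix(runif(6 * 5), 6, 5)
  # single-slice stack: projection equals the slice
  arr <- array(0, dim = c(2, 1, 6, 5))
  arr[1, 1, , ] <- slice; arr[2, 1, , ] <- 2 * slice
  pr <- sum_projection(as_stack(arr))
  expect_equal(pr$col, slice)
  expect_equal(pr$nau, 2 * slice)
  # k identical slices: projection = k * slice
  k <- 4
  arrk <- array(0, dim = c(2, k, 6, 5))
  for (z in 1:k) { arrk[1, z, , ] <- slice; arrk[2, z, , ] <- slice }
  prk <- sum_projection(as_stack(arrk))
  expect_equal(prk$col, k * slice)
})

test_that("projected focus integral equals the generator amplitude", {
  p <- fish_gen_params(n_nuclei = 3, ratio_mean = 2, ratio_sd = 0,
                       background_level = 0, noise_model = "none",
                       stack_shape = c(12, 96, 96))
  sim <- simulate_fish_stack(p, seed = 2)
  pr <- sum_projection(sim$stack)
  for (i in 1:3) {
    sel <- sim$masks == i
    expect_equal(sum(pr$nau[sel]), p$nau_amplitude_mean, tolerance = 0.01)
    expect_equal(sum(pr$col[sel]), 2 * p$nau_amplitude_mean, tolerance = 0.01)
  }
})

test_that("threshold subtracts background softly", {
  expect_equal(as.vector(apply_threshold(matrix(0, 4, 4))), rep(0, 16))
  # constant background with percentile method: everything removed
  b <- matrix(7, 10, 10)
  expect_equal(as.vector(apply_threshold(b)), rep(0, 100))
  # known background + focus: integrated signal within 5% of amplitude
  p <- fish_gen_params(n_nuclei = 1, ratio_mean = 1, ratio_sd = 0,
                       background_level = 50, noise_model = "none",
                       stack_shape = c(12, 64, 64))
  sim <- simulate_fish_stack(p, seed = 3)
  pr <- sum_projection(sim$stack)
  th <- apply_threshold(pr$nau)
  expect_equal(attr(th, "threshold"), 50 * 12, tolerance = 1e-6)
  expect_equal(sum(th[sim$masks == 1]), p$nau_amplitude_mean,
               tolerance = 0.05)
  expect_error(apply_threshold(pr$nau, method = "nope"))
})

test_that("ROI ratio obeys symmetry and linearity", {
  set.seed(4)
  img <- matrix(rexp(400), 20, 20)
  mask <- matrix(0L, 20, 20); mask[5:10, 5:10] <- 1L
  m <- roi_ratio(img, img, mask, 1)
  expect_equal(m$R, 1)
  m2 <- roi_ratio(2 * img, img, mask, 1)
  expect_equal(m2$R, 2)
  expect_error(roi_ratio(img, img, mask, 9), "not found")
  # zero nau signal flagged invalid
  m0 <- roi_ratio(img, img * 0, mask, 1)
  expect_false(m0$valid)
  expect_true(is.na(m0$R))
})

test_that("noise-free quantification equals generator truth exactly", {
  p <- fish_gen_params(n_nuclei = 6, ratio_mean = 2.2, ratio_sd = 0.4,
                       background_level = 0, noise_model = "none",
                       stack_shape = c(10, 128, 128))
  sim <- simulate_fish_stack(p, seed = 5)
  m <- quantify_stack(sim$stack, sim$masks)
  expect_equal(m$R, sim$truth$R_true, tolerance = 1e-12)
  # ratio_sd = 0: every nucleus measures exactly ratio_mean
  p0 <- fish_gen_params(n_nuclei = 4, ratio_mean = 1.7, ratio_sd = 0,
                        background_level = 0, noise_model = "none",
                        stack_shape = c(10, 96, 96))
  sim0 <- simulate_fish_stack(p0, seed = 6)
  m0 <- quantify_stack(sim0$stack, sim0$masks)
  expect_equal(m0$R, rep(1.7, 4), tolerance = 1e-12)
})

test_that("channels are exchangeable at ratio 1", {
  p <- fish_gen_params(n_nuclei = 4, ratio_mean = 1, ratio_sd = 0,
                       background_level = 0, noise_model = "none",
                       stack_shape = c(10, 96, 96))
  sim <- simulate_fish_stack(p, seed = 7)
  expect_equal(sim$stack[1, , , ], sim$stack[2, , , ], tolerance = 1e-12)
})

test_that("ratios are invariant to global scaling, equivariant per channel", {
  p <- fish_gen_params(n_nuclei = 5, ratio_mean = 2, ratio_sd = 0.3,
                       background_level = 20, noise_model = "none",
                       stack_shape = c(8, 96, 96))
  sim <- simulate_fish_stack(p, seed = 8)
  m <- quantify_stack(sim$stack, sim$masks)
  k <- 3.7
  scaled <- as_stack(unclass(sim$stack) * k)
  mk <- quantify_stack(scaled, sim$masks)
  expect_equal(mk$R, m$R, tolerance = 1e-10)
  col_only <- unclass(sim$stack); col_only[1, , , ] <- col_only[1, , , ] * k
  mc <- quantify_stack(as_stack(col_only), sim$masks)
  expect_equal(mc$R, m$R * k, tolerance = 1e-10)
})

test_that("group comparison matches the pooled-variance t formula", {
  a <- c(2.1, 2.4, 2.0); b <- c(1.1, 1.3, 0.9)
  cmpr <- group_compare(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(cmpr$t, t_hand)
  expect_equal(cmpr$p, 2 * pt(-abs(t_hand), df = 4))
  expect_equal(cmpr$summaryA$mean, mean(a))
  expect_equal(cmpr$summaryA$sem, sd(a) / sqrt(3))
  # identical groups: t = 0, p = 1
  same <- group_compare(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # degenerate zero-variance groups flagged
  deg <- group_compare(c(1, 1, 1), c(1, 1, 1))
  expect_true(deg$degenerate)
  expect_error(group_compare(1, b), "n >= 2")
})

test_that("nucleus placement fails gracefully when the stack is too small", {
  p <- fish_gen_params(n_nuclei = 50, stack_shape = c(8, 32, 32))
  expect_error(simulate_fish_stack(p, seed = 1, max_retries = 50),
               "could not place")
})

test_that("simulation under a fixed seed is reproducible", {
  p <- fish_gen_params(n_nuclei = 3, stack_shape = c(8, 64, 64))
  a <- simulate_fish_stack(p, seed = 9)
  b <- simulate_fish_stack(p, seed = 9)
  expect_identical(unclass(a$stack), unclass(b$stack))
  expect_identical(a$truth, b$truth)
})
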