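#' Simulate a two-channel FISH stack with known per-nucleus ratio
#'
#' Builds a synthetic two-channel 3D stack emulating intronic-probe
#' fluorescence in situ hybridisation of nascent transcripts: nuclei are
#' axis-aligned ellipsoids placed without overlap, and each carries exactly
#' one transcription focus per channel, co-located at its centre and
#' rendered as a 3D Gaussian of integrated intensity `A` (the point-spread
#' blur of a diffraction-limited spot). For nucleus `i` the generative
#' col/nau ratio `R_i ~ Normal(ratio_mean, ratio_sd)` fixes
#' `A_col = R_i * A_nau`, so before noise the background-subtracted
#' integrated intensity ratio within the nuclear mask equals `R_i` exactly.
#' A constant background and, optionally, Poisson shot noise or Gaussian
#' read noise are added.
#'
#' @param params a [fish_gen_params()] object.
#' @param seed integer seed.
#' @param max_retries placement attempts per nucleus before giving up.
#' @return a list of class `fish_sim` with
#'   * `stack`: an `image_stack` (array `c(2, z, y, x)`, channels
#'     `col`, `nau`),
#'   * `masks`: integer-labelled `y x x` matrix (0 = outside any nucleus),
#'   * `truth`: data.frame `nucleus_id`, `R_true`, `A_nau`, `A_col`,
#'     and centre coordinates.
#' @export
simulate_fish_stack <- function(params, seed, max_retries = 2000) {
  stopifnot(inherits(params, "fish_gen_params"))
  set.seed(as.integer(seed))
  p <- params
  nz <- p$stack_shape[1]; ny <- p$stack_shape[2]; nx <- p$stack_shape[3]
  rz <- p$nucleus_radii[1]; ry <- p$nucleus_radii[2]; rx <- p$nucleus_radii[3]

  # place ellipsoid centres with no overlap (distance in radius-scaled space)
  centers <- matrix(NA_real_, nrow = p$n_nuclei, ncol = 3)
  for (i in seq_len(p$n_nuclei)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      cand <- c(stats::runif(1, rz + 1, nz - rz),
                stats::runif(1, ry + 1, ny - ry),
                stats::runif(1, rx + 1, nx - rx))
      if (i == 1) { centers[1, ] <- cand; placed <- TRUE; break }
      prev <- centers[seq_len(i - 1), , drop = FALSE]
      dd <- sqrt(((prev[, 1] - cand[1]) / rz)^2 +
                 ((prev[, 2] - cand[2]) / ry)^2 +
                 ((prev[, 3] - cand[3]) / rx)^2)
      if (all(dd > 2)) { centers[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf("could not place nucleus %d without overlap in a %s stack",
                   i, paste(p$stack_shape, collapse = "x")))
  }

  R_true <- rnorm_trunc(p$n_nuclei, p$ratio_mean, p$ratio_sd, lower = 0.05)
  A_nau <- rep(p$nau_amplitude_mean, p$n_nuclei)
  A_col <- R_true * A_nau

  img <- array(p$background_level, dim = c(2L, nz, ny, nx))
  masks <- matrix(0L, nrow = ny, ncol = nx)
  sg <- p$psf_sigma
  half <- ceiling(4 * sg)

  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (i in seq_len(p$n_nuclei)) {
    cz <- centers[i, 1]; cy <- centers[i, 2]; cx <- centers[i, 3]
    inside <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
    masks[inside] <- i

    zi <- max(1, floor(cz - half)):min(nz, ceiling(cz + half))
    yi <- max(1, floor(cy - half)):min(ny, ceiling(cy + half))
    xi <- max(1, floor(cx - half)):min(nx, ceiling(cx + half))
    gz <- exp(-((zi - cz)^2) / (2 * sg^2))
    gy <- exp(-((yi - cy)^2) / (2 * sg^2))
    gx <- exp(-((xi - cx)^2) / (2 * sg^2))
    kern <- outer(outer(gz, gy), gx)          # (z, y, x) footprint
    kern <- kern / sum(kern)                  # unit mass: integral = A exactly
    img[1, zi, yi, xi] <- img[1, zi, yi, xi] + A_col[i] * kern
    img[2, zi, yi, xi] <- img[2, zi, yi, xi] + A_nau[i] * kern
  }

  if (p$noise_model == "poisson") {
    img[] <- stats::rpois(length(img), lambda = img)
  } else if (p$noise_model == "gaussian") {
    img[] <- pmax(img + stats::rnorm(length(img), 0, p$gaussian_sd), 0)
  }

  stack <- structure(img, channels = c("col", "nau"), pixel_size = NA_real_,
                     class = "image_stack")
  truth <- data.frame(nucleus_id = seq_len(p$n_nuclei), R_true = R_true,
                      A_nau = A_nau, A_col = A_col,
                      z = centers[, 1], y = centers[, 2], x = centers[, 3])
  structure(list(stack = stack, masks = masks, truth = truth),
            class = "fish_sim")
}

#' @export
print.fish_sim <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<fish_sim> %d nuclei in a %d-channel %dx%dx%d (z,y,x) stack\n",
              nrow(x$truth), d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack> channels %s, %d z-slices of %dx%d\n",
              paste(attr(x, "channels"), collapse = "/"), d[2], d[3], d[4]))
  invisible(x)
}
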