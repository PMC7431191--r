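#' Kinematic generator parameters
#'
#' Bundles the ground-truth parameters of the peristaltic crawler model:
#' mean walking rate (path speed of the centroid), per-cycle stride length
#' and stride duration distributions, heading diffusion, frame rate and
#' recording duration.
#'
#' The walking rate must be at least `stride_length_mean / stride_duration_mean`:
#' the path rate (frame-to-frame centroid displacement rate) can never fall
#' below the net progression rate, and the lateral wobble amplitude that
#' reconciles the two is derived from their difference (see
#' [simulate_larva()]).
#'
#' @param walking_rate_mean mean centroid path speed, mm/s.
#' @param stride_length_mean,stride_length_sd per-cycle net centroid
#'   displacement distribution, mm (draws truncated at 0).
#' @param stride_duration_mean,stride_duration_sd per-cycle duration
#'   distribution, s (draws truncated at half the mean).
#' @param heading_sd standard deviation of the per-cycle heading update,
#'   radians.
#' @param fps sampling rate, frames/s.
#' @param duration recording length, s.
#' @param pause_prob probability of a pause at each cycle boundary.
#' @param pause_duration pause length, s.
#' @param spine_length_rest resting spine length L0, mm.
#' @param contraction_amplitude peak spine shortening as a fraction of
#'   `spine_length_rest` (the spine length oscillates between
#'   `L0 (1 - amplitude)` and `L0 (1 + amplitude)` over a cycle... see
#'   details: L(t) = L0 - a cos(2 pi phi) with a = amplitude * L0).
#' @return an object of class `kinematic_params`.
#' @export
kinematic_params <- function(walking_rate_mean = 1.15,
                             stride_length_mean = 1.17,
                             stride_length_sd = 0,
                             stride_duration_mean = 1.09,
                             stride_duration_sd = 0,
                             heading_sd = 0,
                             fps = 5,
                             duration = 20,
                             pause_prob = 0,
                             pause_duration = 0.5,
                             spine_length_rest = 4,
                             contraction_amplitude = 0.15) {
  stop_if_not_scalar_number(walking_rate_mean, "walking_rate_mean", positive = TRUE)
  stop_if_not_scalar_number(stride_length_mean, "stride_length_mean", positive = TRUE)
  stop_if_not_scalar_number(stride_duration_mean, "stride_duration_mean", positive = TRUE)
  stop_if_not_scalar_number(fps, "fps", positive = TRUE)
  stop_if_not_scalar_number(duration, "duration", positive = TRUE)
  if (stride_length_sd < 0 || stride_duration_sd < 0 || heading_sd < 0)
    stop("standard deviations must be >= 0")
  if (pause_prob < 0 || pause_prob > 1)
    stop("'pause_prob' must be in [0, 1]")
  net_rate <- stride_length_mean / stride_duration_mean
  if (walking_rate_mean < net_rate - 1e-12)
    stop(sprintf(paste0(
      "walking_rate_mean (%.4g mm/s) is below the net progression rate ",
      "stride_length_mean/stride_duration_mean (%.4g mm/s); ",
      "the lateral wobble amplitude would be imaginary"),
      walking_rate_mean, net_rate))
  structure(list(
    walking_rate_mean = walking_rate_mean,
    stride_length_mean = stride_length_mean,
    stride_length_sd = stride_length_sd,
    stride_duration_mean = stride_duration_mean,
    stride_duration_sd = stride_duration_sd,
    heading_sd = heading_sd,
    fps = fps,
    duration = duration,
    pause_prob = pause_prob,
    pause_duration = pause_duration,
    spine_length_rest = spine_length_rest,
    contraction_amplitude = contraction_amplitude
  ), class = "kinematic_params")
}

#' @export
print.kinematic_params <- function(x, ...) {
  cat("Kinematic generator parameters\n")
  cat(sprintf("  walking rate    %.3f mm/s\n", x$walking_rate_mean))
  cat(sprintf("  stride length   %.3f mm (sd %.3f)\n",
              x$stride_length_mean, x$stride_length_sd))
  cat(sprintf("  stride duration %.3f s (sd %.3f)\n",
              x$stride_duration_mean, x$stride_duration_sd))
  cat(sprintf("  sampling        %g fps for %g s\n", x$fps, x$duration))
  invisible(x)
}

#' FISH stack generator parameters
#'
#' Parameters for the two-channel synthetic fluorescence in situ
#' hybridisation stack: number of nuclei, the generative distribution of the
#' per-nucleus col/nau intensity ratio, focus brightness, background, point
#' spread, noise model and stack geometry. Each nucleus carries exactly one
#' nascent-transcription focus per channel, co-located at its centre.
#'
#' @param n_nuclei number of nuclei to place.
#' @param ratio_mean,ratio_sd generative distribution of the per-nucleus
#'   col/nau integrated intensity ratio (draws truncated at 0.05).
#' @param nau_amplitude_mean integrated intensity of the nau focus,
#'   photon counts.
#' @param background_level constant background per voxel, counts.
#' @param psf_sigma isotropic Gaussian point-spread sigma, pixels.
#' @param noise_model `"poisson"`, `"gaussian"` or `"none"`.
#' @param gaussian_sd read-noise sd when `noise_model = "gaussian"`.
#' @param stack_shape integer vector `(z, y, x)` in pixels.
#' @param nucleus_radii ellipsoid semi-axes `(z, y, x)` in pixels.
#' @return an object of class `fish_gen_params`.
#' @export
fish_gen_params <- function(n_nuclei = 28,
                            ratio_mean = 2.2,
                            ratio_sd = 0,
                            nau_amplitude_mean = 5e4,
                            background_level = 50,
                            psf_sigma = 1.5,
                            noise_model = c("poisson", "gaussian", "none"),
                            gaussian_sd = 10,
                            stack_shape = c(12, 256, 256),
                            nucleus_radii = c(3, 6, 6)) {
  noise_model <- match.arg(noise_model)
  stop_if_not_scalar_number(ratio_mean, "ratio_mean", positive = TRUE)
  stop_if_not_scalar_number(nau_amplitude_mean, "nau_amplitude_mean", positive = TRUE)
  if (background_level < 0) stop("'background_level' must be >= 0")
  if (ratio_sd < 0) stop("'ratio_sd' must be >= 0")
  if (n_nuclei < 1) stop("'n_nuclei' must be >= 1")
  if (length(stack_shape) != 3L) stop("'stack_shape' must be (z, y, x)")
  if (any(stack_shape < 2 * (nucleus_radii + 1)))
    stop("stack_shape too small for nucleus_radii: each axis needs at least ",
         "2 * (radius + 1) pixels")
  structure(list(
    n_nuclei = as.integer(n_nuclei),
    ratio_mean = ratio_mean,
    ratio_sd = ratio_sd,
    nau_amplitude_mean = nau_amplitude_mean,
    background_level = background_level,
    psf_sigma = psf_sigma,
    noise_model = noise_model,
    gaussian_sd = gaussian_sd,
    stack_shape = as.integer(stack_shape),
    nucleus_radii = nucleus_radii
  ), class = "fish_gen_params")
}

#' @export
print.fish_gen_params <- function(x, ...) {
  cat("FISH stack generator parameters\n")
  cat(sprintf("  nuclei        %d\n", x$n_nuclei))
  cat(sprintf("  col/nau ratio %.3f (sd %.3f)\n", x$ratio_mean, x$ratio_sd))
  cat(sprintf("  stack (z,y,x) %s, noise: %s\n",
              paste(x$stack_shape, collapse = "x"), x$noise_model))
  invisible(x)
}

#' Phenotype category proportions
#'
#' Ground-truth proportions of the four per-segment muscle phenotype
#' categories: normal DA3, branched DA3, DA3-to-DA2 transformed, and absent.
#'
#' @param normal,branched,transformed,absent category probabilities;
#'   must sum to 1.
#' @return an object of class `phenotype_proportions` (named numeric).
#' @export
phenotype_proportions <- function(normal, branched, transformed, absent) {
  p <- c(normal = normal, branched = branched,
         transformed = transformed, absent = absent)
  if (any(p < 0) || any(p > 1))
    stop("all proportions must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    stop(sprintf("proportions must sum to 1 (got %.12f)", sum(p)))
  structure(p, class = "phenotype_proportions")
}

#' Phenotype category levels
#' @keywords internal
phenotype_levels <- function() c("normal", "branched", "transformed", "absent")
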