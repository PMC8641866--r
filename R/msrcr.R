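# Fundus image enhancement: multiscale retinex with colour restoration
# (MSRCR), weighted grayscale conversion and the dataset-level normalisation
# used before patches are fed to the network.
#
# Retinex models an image P as the product of reflectance and illumination.
# The single-scale retinex (SSR) estimates the log-reflectance as
# log(P + eps) - log(G_sigma * P + eps), where G_sigma is a unit-sum Gaussian
# surround; the multiscale version (MSR) averages SSR maps over several
# surround scales, and the colour restoration gain re-weights each channel by
# its share of the local colour so chromatic information survives the
# log-domain processing.

#' MSRCR configuration
#'
#' Bundles the surround scales, scale weights, colour-restoration constants
#' and the output rescaling policy of the enhancement stage.
#'
#' @param sigmas Gaussian surround scales in pixels. The defaults (15, 80,
#'   250) are the canonical small/medium/large surround triple for multiscale
#'   retinex.
#' @param weights Non-negative scale weights; normalised to sum to 1.
#' @param cr_alpha Colour restoration gain applied inside the logarithm.
#' @param cr_beta Colour restoration output gain.
#' @param epsilon Positive floor added before every logarithm, guarding
#'   against log(0) on dark background pixels.
#' @param rescale Policy mapping the enhanced log-domain result to 0-255:
#'   `"meanstd"` (affine map of mean +/- k sd per channel, clipped; robust to
#'   isolated outliers) or `"minmax"` (global per-channel min-max).
#' @param k Width of the `"meanstd"` window in standard deviations.
#' @return An object of class `msrcr_config`.
#' @export
msrcr_config <- function(sigmas = c(15, 80, 250),
                         weights = rep(1, length(sigmas)) / length(sigmas),
                         cr_alpha = 125, cr_beta = 46, epsilon = 1,
                         rescale = c("meanstd", "minmax"), k = 2) {
  rescale <- match.arg(rescale)
  if (length(sigmas) < 1 || any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    abort_param("sigmas must be positive and non-empty")
  }
  if (length(weights) != length(sigmas)) {
    abort_param("weights and sigmas must have the same length")
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    abort_param("weights must be non-negative with positive sum")
  }
  if (!is.finite(epsilon) || epsilon <= 0) abort_param("epsilon must be > 0")
  structure(list(sigmas = as.numeric(sigmas),
                 weights = as.numeric(weights) / sum(weights),
                 cr_alpha = cr_alpha, cr_beta = cr_beta,
                 epsilon = epsilon, rescale = rescale, k = k),
            class = "msrcr_config")
}

gaussian_kernel_1d <- function(sigma) {
  h <- ceiling(3 * sigma)
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Single-scale retinex
#'
#' Log-domain reflectance of one channel: `log(x + epsilon) -
#' log(G_sigma * x + epsilon)` with a truncated separable Gaussian surround
#' (half-width `ceiling(3 sigma)`) and reflective borders.
#'
#' @param channel Non-negative H x W intensity matrix.
#' @param sigma Surround scale in pixels (> 0).
#' @param epsilon Positive floor inside the logarithms.
#' @return H x W reflectance matrix (signed, log domain).
#' @export
single_scale_retinex <- function(channel, sigma, epsilon = 1) {
  validate_gray(channel)
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0) {
    abort_param("sigma must be a single positive number")
  }
  if (!is.finite(epsilon) || epsilon <= 0) abort_param("epsilon must be > 0")
  if (any(channel < 0)) abort_input("channel contains negative intensities")
  surround <- cpp_sepconv_reflect(channel, gaussian_kernel_1d(sigma))
  log(channel + epsilon) - log(surround + epsilon)
}

#' Multiscale retinex
#'
#' Weighted sum of single-scale retinex maps over the configured surround
#' scales.
#'
#' @param channel Non-negative H x W intensity matrix.
#' @param config An [msrcr_config()].
#' @return H x W reflectance matrix.
#' @export
multi_scale_retinex <- function(channel, config = msrcr_config()) {
  if (!inherits(config, "msrcr_config")) abort_param("config must be an msrcr_config")
  out <- 0
  for (m in seq_along(config$sigmas)) {
    if (config$weights[m] == 0) next
    out <- out + config$weights[m] *
      single_scale_retinex(channel, config$sigmas[m], config$epsilon)
  }
  if (identical(out, 0)) out <- matrix(0, nrow(channel), ncol(channel))
  out
}

#' Colour restoration gain
#'
#' Per-channel chromatic gain `beta * (log(alpha * P_i + eps) -
#' log(sum_j P_j + eps))`, restoring the colour balance lost by the
#' channel-wise retinex.
#'
#' @param image H x W x 3 RGB array.
#' @param cr_alpha,cr_beta Restoration gains.
#' @param epsilon Positive floor inside the logarithms.
#' @return H x W x 3 gain array, finite everywhere.
#' @export
color_restoration <- function(image, cr_alpha = 125, cr_beta = 46, epsilon = 1) {
  validate_rgb(image)
  total <- image[, , 1] + image[, , 2] + image[, , 3]
  out <- array(0, dim(image))
  for (c in 1:3) {
    out[, , c] <- cr_beta * (log(cr_alpha * image[, , c] + epsilon) -
                               log(total + epsilon))
  }
  out
}

rescale_channel <- function(x, policy, k) {
  if (policy == "meanstd") {
    mu <- mean(x)
    sd <- stats::sd(as.vector(x))
    lo <- mu - k * sd
    hi <- mu + k * sd
  } else {
    lo <- min(x)
    hi <- max(x)
  }
  if (!is.finite(hi - lo) || hi - lo < 1e-12) {
    return(matrix(127.5, nrow(x), ncol(x)))
  }
  pmin(pmax((x - lo) / (hi - lo) * 255, 0), 255)
}

#' MSRCR enhancement of an RGB fundus image
#'
#' Applies the multiscale retinex to each channel, multiplies by the colour
#' restoration gain, and maps the result back to 0-255 with the configured
#' rescale policy. The operation is fully deterministic.
#'
#' @param image H x W x 3 RGB array on the 0-255 scale.
#' @param config An [msrcr_config()].
#' @return Enhanced H x W x 3 array with values in [0, 255].
#' @export
msrcr_enhance <- function(image, config = msrcr_config()) {
  validate_rgb(image)
  if (!inherits(config, "msrcr_config")) abort_param("config must be an msrcr_config")
  cr <- color_restoration(image, config$cr_alpha, config$cr_beta, config$epsilon)
  out <- array(0, dim(image))
  for (c in 1:3) {
    msr <- multi_scale_retinex(image[, , c], config)
    out[, , c] <- rescale_channel(cr[, , c] * msr, config$rescale, config$k)
  }
  out
}

#' Weighted RGB to grayscale conversion
#'
#' `gray = 0.299 R + 0.587 G + 0.114 B`, the luma weighting under which the
#' red, green and blue channels contribute 29.9%, 58.7% and 11.4% of the
#' grayscale value. The green channel dominates, which suits fundus imagery
#' where vessels have their strongest contrast in green.
#'
#' @param image H x W x 3 RGB array.
#' @return H x W grayscale matrix.
#' @export
rgb_to_gray <- function(image) {
  validate_rgb(image)
  gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  if (!is.matrix(gray)) gray <- matrix(gray, dim(image)[1], dim(image)[2])
  gray
}

#' Z-score normalisation over a set of images
#'
#' Standardises all pixels of a collection of grayscale images to pooled mean
#' 0 and unit variance (population standard deviation). The statistics are
#' returned so they can be frozen on a training split and re-applied to test
#' images.
#'
#' @param images A list of grayscale matrices (a single matrix is accepted).
#' @param stats Optional list with elements `mean` and `sd` to apply instead
#'   of estimating from `images`.
#' @return A list with `images` (normalised) and `stats` (`mean`, `sd`).
#' @export
zscore_normalize <- function(images, stats = NULL) {
  single <- is.matrix(images)
  if (single) images <- list(images)
  lapply(images, validate_gray)
  if (is.null(stats)) {
    all_px <- unlist(lapply(images, as.vector), use.names = FALSE)
    mu <- mean(all_px)
    sd <- sqrt(mean((all_px - mu)^2))
    if (sd <= 0) abort_degenerate("constant input: pooled standard deviation is zero")
    stats <- list(mean = mu, sd = sd)
  } else if (!is.finite(stats$sd) || stats$sd <= 0) {
    abort_degenerate("normalisation stats have non-positive sd")
  }
  out <- lapply(images, function(im) (im - stats$mean) / stats$sd)
  list(images = if (single) out[[1]] else out, stats = stats)
}

#' Min-max rescaling to 0-255
#'
#' Affine map sending the image minimum to exactly 0 and the maximum to
#' exactly 255; strictly order-preserving.
#'
#' @param image Grayscale matrix with `max > min`.
#' @return Rescaled matrix in [0, 255].
#' @export
minmax_rescale <- function(image) {
  validate_gray(image)
  lo <- min(image)
  hi <- max(image)
  if (hi - lo <= 0) abort_degenerate("constant image: min-max rescaling undefined")
  (image - lo) / (hi - lo) * 255
}

#' Full preprocessing pipeline for one fundus image
#'
#' MSRCR enhancement, weighted grayscale conversion, Z-score normalisation
#' (with dataset-level statistics if supplied) and min-max mapping to
#' [0, 255]. Deterministic; shape-preserving.
#'
#' @param image H x W x 3 RGB array.
#' @param config An [msrcr_config()].
#' @param stats Optional frozen normalisation statistics (see
#'   [zscore_normalize()]); when `NULL` the statistics of this image are used.
#' @return H x W grayscale matrix in [0, 255].
#' @export
preprocess_image <- function(image, config = msrcr_config(), stats = NULL) {
  gray <- rgb_to_gray(msrcr_enhance(image, config))
  z <- zscore_normalize(gray, stats = stats)
  minmax_rescale(z$images)
}

#' Preprocess a list of fundus samples with shared statistics
#'
#' Runs the enhancement and grayscale conversion on every sample, estimates
#' pooled Z-score statistics across the collection (or applies frozen ones),
#' and stores the processed image in each sample's `proc` field.
#'
#' @param samples List of [fundus_sample()] objects.
#' @param config An [msrcr_config()].
#' @param stats Optional frozen normalisation statistics from a training
#'   split.
#' @return A list with `samples` (each with a `proc` matrix in [0, 255]) and
#'   `stats`.
#' @export
preprocess_samples <- function(samples, config = msrcr_config(), stats = NULL) {
  grays <- lapply(samples, function(s) rgb_to_gray(msrcr_enhance(s$image, config)))
  z <- zscore_normalize(grays, stats = stats)
  for (i in seq_along(samples)) {
    samples[[i]]$proc <- minmax_rescale(z$images[[i]])
  }
  list(samples = samples, stats = z$stats)
}
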