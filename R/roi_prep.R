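#' Gray-level normalization parameters for a lesion ROI
#'
#' Computes the mean and population standard deviation of the masked
#' intensities and the clipping window `[mu - 3 sigma, mu + 3 sigma]` used to
#' limit the gray-level dynamics before quantization. Restricting the dynamic
#' range to three standard deviations around the ROI mean removes per-scan
#' brightness and contrast differences so that texture features compare across
#' acquisitions.
#'
#' @param image Numeric matrix of pixel intensities (rows = y, columns = x).
#' @param mask Logical (or 0/1) matrix of the same dimensions; `TRUE` marks
#'   ROI pixels.
#' @param n_levels Number of gray levels after quantization (default 64).
#' @return An object of class `norm_params`: a list with `mu`, `sigma`,
#'   `n_levels`, `clip_low`, `clip_high`.
#' @seealso [quantize_roi()]
#' @export
compute_norm_params <- function(image, mask, n_levels = 64L) {
  mask <- check_lesion_pair(image, mask)
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be >= 2")
  v <- as.numeric(image[mask])
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))  # population SD, fixed for reproducibility
  structure(
    list(mu = mu, sigma = sigma, n_levels = n_levels,
         clip_low = mu - 3 * sigma, clip_high = mu + 3 * sigma),
    class = "norm_params"
  )
}

#' @export
print.norm_params <- function(x, ...) {
  cat(sprintf(
    "ROI normalization: mu = %.4g, sigma = %.4g, window [%.4g, %.4g], %d levels\n",
    x$mu, x$sigma, x$clip_low, x$clip_high, x$n_levels))
  invisible(x)
}

#' Quantize a lesion ROI to discrete gray levels
#'
#' Clips the masked intensities to the `mu +/- 3 sigma` window of `params` and
#' bins them linearly into `n_levels` equal-width bins mapped to integer
#' levels `1..n_levels`. Out-of-window pixels are clipped (not excluded) so
#' that texture and geometry operate on the identical pixel support. A
#' zero-variance ROI maps every pixel to the middle level
#' `ceiling(n_levels / 2)`.
#'
#' @inheritParams compute_norm_params
#' @param params A `norm_params` object from [compute_norm_params()]; computed
#'   from `image`/`mask` when omitted.
#' @return An object of class `quantized_roi`: list with `levels` (integer
#'   matrix, `NA` outside the mask), `mask`, and `params`.
#' @examples
#' img <- matrix(rnorm(64, 100, 10), 8, 8)
#' q <- quantize_roi(img, matrix(TRUE, 8, 8))
#' range(q$levels)
#' @export
quantize_roi <- function(image, mask, params = NULL) {
  mask <- check_lesion_pair(image, mask)
  if (is.null(params)) params <- compute_norm_params(image, mask)
  stopifnot(inherits(params, "norm_params"))
  n <- params$n_levels
  lev <- matrix(NA_integer_, nrow(image), ncol(image))
  v <- as.numeric(image[mask])
  if (params$sigma <= 0) {
    lev[mask] <- as.integer(ceiling(n / 2))
  } else {
    v <- pmin(pmax(v, params$clip_low), params$clip_high)
    w <- params$clip_high - params$clip_low
    k <- floor((v - params$clip_low) / w * n) + 1
    lev[mask] <- as.integer(pmin(pmax(k, 1L), n))
  }
  structure(list(levels = lev, mask = mask, params = params),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("Quantized ROI: %d pixels, levels in [%d, %d] of %d\n",
              sum(x$mask), min(x$levels, na.rm = TRUE),
              max(x$levels, na.rm = TRUE), x$params$n_levels))
  invisible(x)
}

# Validate an (image, mask) pair; returns the mask coerced to logical.
check_lesion_pair <- function(image, mask, min_pixels = 1L) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (!all(dim(image) == dim(mask))) {
    stop(sprintf("mask dimensions (%s) do not match image dimensions (%s)",
                 paste(dim(mask), collapse = "x"),
                 paste(dim(image), collapse = "x")))
  }
  mask <- matrix(as.logical(mask) & (as.numeric(mask) > 0), nrow(image), ncol(image))
  mask[is.na(mask)] <- FALSE
  if (sum(mask) < min_pixels) {
    stop(sprintf("mask has %d pixels; at least %d required", sum(mask), min_pixels))
  }
  mask
}

# quantized_roi constructed directly from a level matrix (used by tests and
# the sliding-window feature maps)
quantized_from_levels <- function(levels, mask, n_levels) {
  mask <- matrix(as.logical(mask), nrow(levels), ncol(levels))
  lev <- matrix(NA_integer_, nrow(levels), ncol(levels))
  lev[mask] <- as.integer(levels[mask])
  params <- structure(list(mu = NA_real_, sigma = NA_real_,
                           n_levels = as.integer(n_levels),
                           clip_low = NA_real_, clip_high = NA_real_),
                      class = "norm_params")
  structure(list(levels = lev, mask = mask, params = params),
            class = "quantized_roi")
}
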