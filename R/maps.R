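#' Sliding-window feature map of a single radiomic feature
#'
#' For every masked pixel, the named texture feature is recomputed on the
#' intersection of a centered square window with the ROI, using the gray
#' levels quantized once with the normalization parameters of the full ROI
#' (so map contrast reflects texture, not local renormalization). Windows
#' containing fewer than 16 masked pixels yield a missing value. Geometry
#' (GEO) features are global shape descriptors and cannot be mapped.
#'
#' @param image Numeric intensity matrix.
#' @param mask Binary ROI matrix.
#' @param feature_name A registry name outside the GEO family (e.g.,
#'   `"S(1,1)SumEntrp"`).
#' @param window Odd window side length >= 3 (default 15).
#' @param n_levels Gray levels for the global quantization.
#' @return Object of class `feature_map`: list with `values` (numeric matrix,
#'   `NA` off-mask and where the window support is too small),
#'   `feature_name`, `window`.
#' @export
compute_feature_map <- function(image, mask, feature_name, window = 15L,
                                n_levels = 64L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  reg <- registry_table()
  fam <- reg$family[match(feature_name, reg$name)]
  if (is.na(fam)) stop("unknown feature: ", feature_name)
  if (fam == "GEO") stop(feature_name, " is a global feature; GEO cannot be mapped")
  mask <- check_lesion_pair(image, mask, min_pixels = 16L)
  q <- quantize_roi(image, mask, compute_norm_params(image, mask, n_levels))
  half <- (window - 1L) %/% 2L
  nr <- nrow(mask); nc <- ncol(mask)
  vals <- matrix(NA_real_, nr, nc)
  idx <- which(mask)
  for (s in idx) {
    r <- (s - 1L) %% nr + 1L
    c_ <- (s - 1L) %/% nr + 1L
    rr <- max(1L, r - half):min(nr, r + half)
    cc <- max(1L, c_ - half):min(nc, c_ + half)
    sub_mask <- matrix(FALSE, nr, nc)
    sub_mask[rr, cc] <- mask[rr, cc]
    if (sum(sub_mask) < 16L) next
    sub_q <- quantized_from_levels(q$levels, sub_mask, q$params$n_levels)
    vals[r, c_] <- suppressWarnings(feature_value(sub_q, feature_name, fam))
  }
  structure(list(values = vals, feature_name = feature_name, window = window),
            class = "feature_map")
}

# single named feature of one quantized ROI (map kernel)
feature_value <- function(q, feature_name, family) {
  switch(family,
    HIS = his_features(q)[[feature_name]],
    COM = {
      m <- regmatches(feature_name,
                      regexec("^S\\((-?\\d+),(-?\\d+)\\)(.+)$", feature_name))[[1]]
      off <- c(as.integer(m[2]), as.integer(m[3]))
      com_features(com_matrix(q, off))[[m[4]]]
    },
    RLM = {
      dir <- sub("_.*$", "", feature_name)
      rlm_features(q, dir)[[feature_name]]
    },
    GRA = gra_features(q)[[feature_name]],
    ARM = arm_features(q)[[feature_name]],
    WAV = wav_features(q)[[feature_name]],
    stop("unsupported family: ", family))
}

#' @export
print.feature_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("feature map '%s' (window %d): %d defined pixels, range [%.4g, %.4g]\n",
              x$feature_name, x$window, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Render a feature map as a color overlay PNG
#'
#' Writes the grayscale image with the feature map color-coded (blue = low,
#' red = high, linear min-max scaling over the defined values) alpha-blended
#' over the lesion area. Pixels without a defined map value keep their
#' grayscale intensity. The rendering is fully deterministic.
#'
#' @param map A `feature_map`.
#' @param image The intensity matrix the map was computed from.
#' @param out_path Output PNG path.
#' @param alpha Overlay opacity in `[0, 1]` (default 0.6).
#' @return `out_path`, invisibly.
#' @export
render_overlay <- function(map, image, out_path, alpha = 0.6) {
  stopifnot(inherits(map, "feature_map"))
  v <- map$values
  def <- !is.na(v)
  if (!any(def)) stop("feature map has no defined values")
  g <- image - min(image)
  if (max(g) > 0) g <- g / max(g)
  rng <- range(v[def])
  t <- matrix(0, nrow(v), ncol(v))
  t[def] <- if (diff(rng) > 0) (v[def] - rng[1]) / diff(rng) else 0.5
  rgb <- array(rep(g, 3), c(nrow(g), ncol(g), 3))
  # blue-to-red ramp over the defined map area
  rgb[, , 1][def] <- (1 - alpha) * g[def] + alpha * t[def]
  rgb[, , 2][def] <- (1 - alpha) * g[def] + alpha * 0.2 * (1 - abs(2 * t[def] - 1))
  rgb[, , 3][def] <- (1 - alpha) * g[def] + alpha * (1 - t[def])
  png::writePNG(rgb, out_path)
  invisible(out_path)
}
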