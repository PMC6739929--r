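#' Class recipe for synthetic lesion generation
#'
#' A recipe fixes the generative parameters of one lesion class: the interior
#' texture (a standardized Gaussian-smoothed random field with a controllable
#' correlation length, scaled by a contrast amplitude, plus white noise) and
#' the outline (a base ellipse of given mean radius and elongation whose
#' boundary radius is perturbed by a low-order random-phase sinusoid,
#' emulating spiculation).
#'
#' @param name Class label (e.g., a molecular subtype name).
#' @param correlation_length Gaussian kernel SD of the interior random field,
#'   pixels, > 0. Larger values give smoother, coarser texture.
#' @param contrast_amplitude Intensity amplitude of the texture field, >= 0.
#' @param noise_sd White-noise SD added inside the lesion, >= 0.
#' @param elongation Major/minor axis ratio of the base ellipse, >= 1.
#' @param spiculation_amplitude Boundary perturbation as a fraction of the
#'   mean radius, in `[0, 0.5]`.
#' @param mean_radius Mean lesion radius in pixels, >= 8.
#' @return An object of class `class_recipe`.
#' @export
class_recipe <- function(name,
                         correlation_length = 2,
                         contrast_amplitude = 120,
                         noise_sd = 20,
                         elongation = 1.2,
                         spiculation_amplitude = 0.1,
                         mean_radius = 20) {
  stopifnot(is.character(name), nchar(name) > 0,
            correlation_length > 0,
            contrast_amplitude >= 0,
            noise_sd >= 0,
            elongation >= 1,
            spiculation_amplitude >= 0, spiculation_amplitude <= 0.5,
            mean_radius >= 8)
  structure(list(name = name,
                 correlation_length = correlation_length,
                 contrast_amplitude = contrast_amplitude,
                 noise_sd = noise_sd,
                 elongation = elongation,
                 spiculation_amplitude = spiculation_amplitude,
                 mean_radius = mean_radius),
            class = "class_recipe")
}

#' @export
print.class_recipe <- function(x, ...) {
  cat(sprintf(
    "class_recipe '%s': corr %.2g px, contrast %.3g, noise %.3g, elong %.2f, spic %.2f, radius %.3g px\n",
    x$name, x$correlation_length, x$contrast_amplitude, x$noise_sd,
    x$elongation, x$spiculation_amplitude, x$mean_radius))
  invisible(x)
}

#' Synthetic cohort specification
#'
#' @param recipes List of [class_recipe()] objects with unique names.
#' @param n_per_class Samples per class: a single count or one count per
#'   recipe, each >= 2.
#' @param image_size Square image side, pixels (default 256).
#' @param background_level Background intensity (default 400; lesions enhance
#'   above it, as on post-contrast T1).
#' @param background_noise_sd Background white-noise SD (default 15).
#' @param seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(recipes, n_per_class, image_size = 256L,
                        background_level = 400, background_noise_sd = 15,
                        seed = 1L) {
  if (inherits(recipes, "class_recipe")) recipes <- list(recipes)
  stopifnot(length(recipes) >= 1,
            all(vapply(recipes, inherits, logical(1), "class_recipe")))
  nm <- vapply(recipes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate recipe names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  n_per_class <- as.integer(rep_len(n_per_class, length(recipes)))
  stopifnot(all(n_per_class >= 2), image_size >= 16)
  structure(list(recipes = recipes, n_per_class = n_per_class,
                 image_size = as.integer(image_size),
                 background_level = background_level,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate one synthetic lesion image and mask
#'
#' The mask is a single 4-connected region with boundary radius
#' `r(phi) = mean_radius * (1 + spiculation_amplitude * g(phi))`, where
#' `g` is a unit-bounded sum of sinusoids of angular orders 5-12 with seeded
#' random phases and amplitudes, scaled anisotropically so the major/minor
#' axis ratio equals `elongation` at (approximately) constant area. Interior
#' intensities are `background_level + contrast_amplitude * field + noise`,
#' where `field` is white noise smoothed by an isotropic Gaussian kernel of
#' SD `correlation_length` and standardized to unit variance over the lesion;
#' the background is `background_level` plus white noise of
#' `background_noise_sd`. Intensities are clipped to the 16-bit range and
#' rounded.
#'
#' @param recipe A [class_recipe()].
#' @param image_size Square image side; must be at least `4 * mean_radius`.
#' @param seed Integer seed; the same (recipe, seed) pair is bit-reproducible.
#' @param background_level,background_noise_sd Background intensity model.
#' @return List with `image` (integer matrix) and `mask` (logical matrix).
#' @export
generate_lesion <- function(recipe, image_size, seed,
                            background_level = 400,
                            background_noise_sd = 15) {
  stopifnot(inherits(recipe, "class_recipe"))
  image_size <- as.integer(image_size)
  if (image_size < 4 * recipe$mean_radius) {
    stop(sprintf("image_size %d < 4 * mean_radius (%g)",
                 image_size, recipe$mean_radius))
  }
  r_out <- recipe$mean_radius * (1 + recipe$spiculation_amplitude) *
    sqrt(recipe$elongation)
  if (2 * r_out >= image_size - 2) {
    stop(sprintf("lesion outer radius %.1f px exceeds the %d px frame",
                 r_out, image_size))
  }
  withr::with_seed(as.integer(seed), {
    ctr <- (image_size + 1) / 2
    x <- col(matrix(0, image_size, image_size)) - ctr
    y <- row(matrix(0, image_size, image_size)) - ctr
    # anisotropic coordinates: major axis along x
    u <- x / sqrt(recipe$elongation)
    v <- y * sqrt(recipe$elongation)
    ang <- atan2(v, u)
    orders <- 5:12
    amp <- stats::runif(length(orders))
    phase <- stats::runif(length(orders), 0, 2 * pi)
    if (sum(amp) > 0) amp <- amp / sum(amp)     # |g| <= 1
    g <- matrix(0, image_size, image_size)
    for (k in seq_along(orders)) {
      g <- g + amp[k] * sin(orders[k] * ang + phase[k])
    }
    r_phi <- recipe$mean_radius * (1 + recipe$spiculation_amplitude * g)
    mask <- sqrt(u^2 + v^2) <= r_phi
    mask <- largest_component(mask)

    img <- matrix(background_level, image_size, image_size)
    bg_noise <- matrix(stats::rnorm(image_size^2, 0, background_noise_sd),
                       image_size, image_size)
    img[!mask] <- img[!mask] + bg_noise[!mask]
    field <- gaussian_field(image_size, recipe$correlation_length)
    f <- field[mask]
    s <- sqrt(mean((f - mean(f))^2))
    f <- if (s > 0) (f - mean(f)) / s else f * 0
    img[mask] <- background_level + recipe$contrast_amplitude * f +
      stats::rnorm(sum(mask), 0, recipe$noise_sd)
    img <- matrix(as.integer(round(pmin(pmax(img, 0), 65535))),
                  image_size, image_size)
    list(image = img, mask = mask)
  })
}

# white noise convolved with an isotropic Gaussian kernel (separable)
gaussian_field <- function(size, sigma) {
  z <- matrix(stats::rnorm(size^2), size, size)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), 0, sigma)
  k <- k / sum(k)
  sm <- apply(z, 2, function(col) conv_same(col, k))
  t(apply(sm, 1, function(row) conv_same(row, k)))
}

# 1-D "same" convolution with edge replication
conv_same <- function(v, k) {
  half <- (length(k) - 1L) / 2L
  vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
  as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + length(v))]
}

#' Generate a synthetic cohort on disk
#'
#' Writes one 16-bit grayscale TIFF image and one 8-bit PNG mask
#' (foreground = 255) per sample plus a manifest CSV with header
#' `sample_id,image,mask,er,pr,her2,subtype`. Per-sample seeds are derived
#' deterministically from `spec$seed`, the class index and the sample index,
#' so extending a cohort does not reshuffle earlier samples. Receptor columns
#' are filled by inverting the immunohistochemical subtype mapping (see
#' [map_receptors_to_subtype()]) when the recipe name is one of the four
#' canonical subtypes, and set to `unknown` otherwise.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if absent).
#' @return The cohort manifest (invisibly written to `manifest.csv`).
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ci in seq_along(spec$recipes)) {
    recipe <- spec$recipes[[ci]]
    for (si in seq_len(spec$n_per_class[ci])) {
      seed_i <- derive_seed(spec$seed, ci, si)
      les <- generate_lesion(recipe, spec$image_size, seed_i,
                             spec$background_level, spec$background_noise_sd)
      sid <- sprintf("%s_%03d", recipe$name, si)
      img_path <- file.path(out_dir, paste0(sid, ".tif"))
      msk_path <- file.path(out_dir, paste0(sid, "_mask.png"))
      write_image16(les$image, img_path)
      write_mask(les$mask, msk_path)
      rec <- subtype_to_receptors(recipe$name)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, image = img_path, mask = msk_path,
        er = rec["er"], pr = rec["pr"], her2 = rec["her2"],
        subtype = recipe$name, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  class(manifest) <- c("cohort_manifest", "data.frame")
  manifest
}

#' Default synthetic subtype recipes
#'
#' Four recipes named after the canonical molecular subtypes, with texture
#' and shape parameters chosen so the classes are separable but overlapping:
#' luminal A smooth and regular, luminal B spiculated and elongated, HER2E
#' fine-grained and heterogeneous, TN round and circumscribed with coarse
#' contrast. These are calibration knobs of the phantom, not claims about
#' real tumors.
#'
#' @return Named list of four [class_recipe()] objects.
#' @export
default_recipes <- function() {
  list(
    LuminalA = class_recipe("LuminalA", correlation_length = 3,
                            contrast_amplitude = 90, noise_sd = 20,
                            elongation = 1.2, spiculation_amplitude = 0.08,
                            mean_radius = 20),
    LuminalB = class_recipe("LuminalB", correlation_length = 2,
                            contrast_amplitude = 130, noise_sd = 25,
                            elongation = 1.8, spiculation_amplitude = 0.25,
                            mean_radius = 20),
    HER2E = class_recipe("HER2E", correlation_length = 1,
                         contrast_amplitude = 150, noise_sd = 30,
                         elongation = 1.4, spiculation_amplitude = 0.15,
                         mean_radius = 20),
    TN = class_recipe("TN", correlation_length = 4,
                      contrast_amplitude = 110, noise_sd = 15,
                      elongation = 1.05, spiculation_amplitude = 0.04,
                      mean_radius = 20)
  )
}
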