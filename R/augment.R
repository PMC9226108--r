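#' Augmentation configuration
#'
#' Training-set augmentation combines a random in-plane rotation with a
#' smooth random elastic deformation; with the default `multiplier = 3` each
#' training pair yields itself plus two augmented variants, tripling the set.
#' Horizontal flip and additive Gaussian noise are implemented but default to
#' off: flipping degrades performance on anatomically-sided kidneys, and
#' Gaussian noise is redundant with ultrasound speckle.
#'
#' @param rotation_range maximum absolute rotation in degrees (draws are
#'   uniform in the symmetric range; default 15).
#' @param elastic_spacing control-grid spacing of the elastic field, px.
#' @param elastic_sigma displacement standard deviation at the control
#'   points, px (scaled for a 256 px slab; other sizes scale proportionally).
#' @param multiplier total outputs per input pair (>= 1).
#' @param enable_flip random horizontal flip (default off).
#' @param enable_gaussian_noise additive intensity noise (default off).
#' @param noise_sd intensity noise SD on the 0-255 scale.
#' @param seed RNG seed.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(rotation_range = 15, elastic_spacing = 32,
                           elastic_sigma = 4, multiplier = 3L,
                           enable_flip = FALSE,
                           enable_gaussian_noise = FALSE, noise_sd = 5,
                           seed = 1L) {
  if (multiplier < 1) stopf("multiplier must be at least 1")
  if (rotation_range < 0) stopf("rotation_range must be non-negative")
  structure(list(rotation_range = rotation_range,
                 elastic_spacing = elastic_spacing,
                 elastic_sigma = elastic_sigma,
                 multiplier = as.integer(multiplier),
                 enable_flip = enable_flip,
                 enable_gaussian_noise = enable_gaussian_noise,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "augment_config")
}

# Smooth random displacement field: N(0, sigma) draws on a coarse control
# grid, upsampled to the full frame with separable cubic splines.
elastic_field <- function(n, spacing, sigma) {
  m <- max(3L, as.integer(ceiling(n / spacing)) + 1L)
  coarse <- matrix(stats::rnorm(m * m, 0, sigma), m, m)
  xs <- seq(1, n, length.out = m)
  half <- t(vapply(seq_len(m), function(i)
    stats::spline(xs, coarse[i, ], xout = seq_len(n))$y, numeric(n)))
  vapply(seq_len(n), function(j)
    stats::spline(xs, half[, j], xout = seq_len(n))$y, numeric(n))
}

# One random rotation + elastic warp applied identically to image (bilinear)
# and mask (nearest neighbour).  Consumes RNG state.  `image` may carry
# trailing channels; all channels share the transform.
augment_once <- function(image, mask, cfg) {
  n <- nrow(image)
  theta <- stats::runif(1, -cfg$rotation_range, cfg$rotation_range) * pi / 180
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  # inverse map: source position for each output pixel
  dr <- rows - ctr; dc <- cols - ctr
  mapr <- ctr + cos(theta) * dr - sin(theta) * dc
  mapc <- ctr + sin(theta) * dr + cos(theta) * dc
  if (cfg$elastic_sigma > 0) {
    sig <- cfg$elastic_sigma * n / 256
    sp <- max(4, cfg$elastic_spacing * n / 256)
    mapr <- mapr + elastic_field(n, sp, sig)
    mapc <- mapc + elastic_field(n, sp, sig)
  }
  flip <- cfg$enable_flip && stats::runif(1) < 0.5
  if (flip) mapc <- mapc[, rev(seq_len(n))]
  if (length(dim(image)) == 3L) {
    img_out <- array(0, dim(image))
    for (ch in seq_len(dim(image)[3]))
      img_out[, , ch] <- cpp_warp_bilinear(image[, , ch], mapr, mapc)
  } else {
    img_out <- cpp_warp_bilinear(image, mapr, mapc)
  }
  if (cfg$enable_gaussian_noise)
    img_out <- img_out + array(stats::rnorm(length(img_out), 0, cfg$noise_sd),
                               dim(img_out))
  msk_out <- cpp_warp_nearest(mask, mapr, mapc)
  list(image = img_out, mask = msk_out)
}

#' Augment one image/mask slab pair
#'
#' Returns `multiplier` pairs: the untouched input first, followed by
#' independently drawn rotation + elastic-deformation variants.  The same
#' geometric transform is applied to image (bilinear) and mask (nearest
#' neighbour), so augmented masks stay strictly binary.  Deterministic under
#' a fixed `cfg$seed` and `index`.
#'
#' @param image 2D numeric matrix, or a 3D slab (H x W x channels) whose
#'   channels share one transform.
#' @param mask 2D binary matrix matching the in-plane shape.
#' @param cfg an [augment_config()].
#' @param index stream index distinguishing samples within an epoch.
#' @return list of `multiplier` `list(image, mask)` pairs.
#' @export
augment_pair <- function(image, mask, cfg = augment_config(), index = 1L) {
  if (!identical(dim(image)[1:2], dim(mask)[1:2]))
    stopf("image and mask shapes differ: %s vs %s",
          paste(dim(image), collapse = "x"),
          paste(dim(mask), collapse = "x"))
  assert_binary(mask)
  out <- vector("list", cfg$multiplier)
  out[[1]] <- list(image = image, mask = mask)
  if (cfg$multiplier > 1) {
    extra <- with_seed(child_seed(cfg$seed, index), {
      lapply(seq_len(cfg$multiplier - 1L), function(i)
        augment_once(image, mask, cfg))
    })
    out[-1] <- extra
  }
  out
}
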