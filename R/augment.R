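#' Training-time augmentation policy
#'
#' Bundles the parameters of the augmentation stack applied jointly to each
#' training image and its mask, in this fixed order: display-window (LUT)
#' jitter, horizontal flip, rotation, elastic deformation, cropping, gamma,
#' Gaussian noise. Geometric steps are applied identically to image and
#' mask; intensity steps touch the image only.
#'
#' @param lut_jitter relative window center/width jitter (default 0.05,
#'   i.e. +/-5%).
#' @param flip_prob horizontal flip probability (default 0.5).
#' @param rotation_deg symmetric rotation range in degrees (default 5).
#' @param elastic_alpha displacement-field scale (default 1).
#' @param elastic_sigma Gaussian smoothing width of the displacement field
#'   in pixels (default 100).
#' @param elastic_alpha_affine scale of the random affine corner jitter in
#'   pixels (default 20).
#' @param crop_size square crop side in pixels (default 512).
#' @param crop_max_outside maximum pixels the crop may reach outside the
#'   image on any side (default 64, i.e. 12.5% of 512); must be at most
#'   `crop_size / 2`.
#' @param gamma_range interval for the random gamma exponent (default
#'   `c(0.5, 1.5)`).
#' @param noise_sd_fraction Gaussian noise sd as a fraction of the image
#'   range (default 0.05).
#' @param seed optional integer recorded with the policy (callers seed the
#'   session RNG).
#' @return list of class `"augmentation_policy"`.
#' @export
augmentation_policy <- function(lut_jitter = 0.05, flip_prob = 0.5,
                                rotation_deg = 5, elastic_alpha = 1,
                                elastic_sigma = 100, elastic_alpha_affine = 20,
                                crop_size = 512, crop_max_outside = 64,
                                gamma_range = c(0.5, 1.5),
                                noise_sd_fraction = 0.05, seed = NULL) {
  stopifnot(lut_jitter >= 0, lut_jitter < 1, flip_prob >= 0, flip_prob <= 1,
            rotation_deg >= 0, elastic_alpha >= 0, elastic_sigma >= 0,
            elastic_alpha_affine >= 0, crop_size >= 1,
            length(gamma_range) == 2, gamma_range[1] > 0,
            gamma_range[1] <= gamma_range[2], noise_sd_fraction >= 0)
  if (crop_max_outside > crop_size / 2) {
    stop("crop_max_outside must be at most crop_size/2", call. = FALSE)
  }
  structure(list(lut_jitter = lut_jitter, flip_prob = flip_prob,
                 rotation_deg = rotation_deg, elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma,
                 elastic_alpha_affine = elastic_alpha_affine,
                 crop_size = crop_size, crop_max_outside = crop_max_outside,
                 gamma_range = gamma_range,
                 noise_sd_fraction = noise_sd_fraction, seed = seed),
            class = "augmentation_policy")
}

#' Random horizontal flip of an image/mask pair
#'
#' With probability `prob` both grids are mirrored about the vertical axis.
#' Uses the session RNG.
#' @param img numeric matrix.
#' @param mask integer label matrix of the same shape.
#' @param prob flip probability.
#' @param force `NA` to draw; `TRUE`/`FALSE` to override (used by replays).
#' @return list(img, mask, flipped).
#' @export
random_horizontal_flip <- function(img, mask, prob = 0.5, force = NA) {
  stopifnot_same_shape(img, mask)
  flip <- if (is.na(force)) stats::runif(1) < prob else isTRUE(force)
  if (flip) {
    img <- flip_horizontal(img)
    mask <- flip_horizontal(mask)
  }
  list(img = img, mask = mask, flipped = flip)
}

## coordinate maps for a rotation by `angle_deg` about the grid center;
## returns source coordinates (0-based) for every target pixel
rotation_maps <- function(h, w, angle_deg) {
  th <- angle_deg * pi / 180
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  r <- matrix(seq_len(h) - 1, h, w) - cr
  c <- matrix(seq_len(w) - 1, h, w, byrow = TRUE) - cc
  # backward map: rotate target coords by -angle
  list(map_r = cos(th) * r + sin(th) * c + cr,
       map_c = -sin(th) * r + cos(th) * c + cc)
}

#' Random rotation of an image/mask pair
#'
#' A single angle drawn uniformly from `[-range_deg, +range_deg]` is applied
#' to both grids about their center: bilinear interpolation for the image,
#' nearest-neighbor for the mask (value set preserved), out-of-bounds filled
#' with 0 / background.
#' @inheritParams random_horizontal_flip
#' @param range_deg symmetric angle range in degrees.
#' @param angle `NA` to draw; a fixed angle otherwise.
#' @param fill out-of-bounds image fill value (default 0; the full stack
#'   passes the image's own background level so raw images, whose
#'   background is bright, are not given contradictory dark borders).
#' @return list(img, mask, angle).
#' @export
random_rotation <- function(img, mask, range_deg = 5, angle = NA, fill = 0) {
  stopifnot_same_shape(img, mask)
  if (is.na(angle)) angle <- stats::runif(1, -range_deg, range_deg)
  if (angle == 0) return(list(img = img, mask = mask, angle = 0))
  m <- rotation_maps(nrow(img), ncol(img), angle)
  list(img = .warp_bilinear(img, m$map_r, m$map_c, fill),
       mask = matrix(as.integer(.warp_nearest(mask + 0, m$map_r, m$map_c, 0)),
                     nrow(mask), ncol(mask)),
       angle = angle)
}

#' Elastic deformation of an image/mask pair
#'
#' One random warp per call: per-axis displacement fields drawn uniform in
#' `[-1, 1]`, Gaussian-smoothed with width `sigma` and scaled by `alpha`,
#' composed with a random affine whose three corner-point offsets are drawn
#' uniform in `[-alpha_affine, +alpha_affine]` pixels. The identical warp is
#' applied to the image (bilinear) and the mask (nearest-neighbor);
#' out-of-bounds areas are filled with 0 / background.
#'
#' @inheritParams random_horizontal_flip
#' @param alpha displacement-field scale (>= 0).
#' @param sigma smoothing width in pixels (>= 0).
#' @param alpha_affine affine corner jitter in pixels (>= 0).
#' @param fill out-of-bounds image fill value (default 0; see
#'   [random_rotation()]).
#' @return list(img, mask).
#' @export
elastic_deformation <- function(img, mask, alpha = 1, sigma = 100,
                                alpha_affine = 20, fill = 0) {
  stopifnot_same_shape(img, mask)
  if (alpha < 0 || sigma < 0 || alpha_affine < 0) {
    stop("alpha, sigma and alpha_affine must be non-negative", call. = FALSE)
  }
  h <- nrow(img); w <- ncol(img)
  if (alpha == 0 && alpha_affine == 0) return(list(img = img, mask = mask))
  # affine from three jittered corner points of the centered third-size square
  cr <- (h - 1) / 2; cc <- (w - 1) / 2; s <- min(h, w) / 3
  src <- rbind(c(cr - s, cc - s), c(cr - s, cc + s), c(cr + s, cc - s))
  dst <- src + matrix(stats::runif(6, -alpha_affine, alpha_affine), 3, 2)
  # solve backward affine: source = A %*% target + t (maps dst -> src)
  X <- cbind(dst, 1)
  coef <- solve(X, src)  # 3x2: rows (a_r, a_c, t) for each source coord
  tr <- matrix(seq_len(h) - 1, h, w)
  tc <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  map_r <- coef[1, 1] * tr + coef[2, 1] * tc + coef[3, 1]
  map_c <- coef[1, 2] * tr + coef[2, 2] * tc + coef[3, 2]
  if (alpha > 0) {
    dr <- gaussian_smooth_field(matrix(stats::runif(h * w, -1, 1), h, w), sigma) * alpha
    dc <- gaussian_smooth_field(matrix(stats::runif(h * w, -1, 1), h, w), sigma) * alpha
    map_r <- map_r + dr
    map_c <- map_c + dc
  }
  list(img = .warp_bilinear(img, map_r, map_c, fill),
       mask = matrix(as.integer(.warp_nearest(mask + 0, map_r, map_c, 0)), h, w))
}

#' Random square crop of an image/mask pair
#'
#' Output is exactly `size x size`. The crop origin is uniform over all
#' positions whose window stays within the image dilated by `max_outside`
#' pixels on every side; out-of-image area is zero-padded (image) /
#' background-padded (mask). Inputs smaller than the feasible range are
#' center-cropped with padding.
#'
#' @inheritParams random_horizontal_flip
#' @param size crop side in pixels.
#' @param max_outside maximum overshoot outside the image per side.
#' @param origin `NULL` to draw; `c(row, col)` 0-based origin to override.
#' @param fill out-of-image fill value for the image (default 0; masks are
#'   always background-padded).
#' @return list(img, mask, origin).
#' @export
random_crop <- function(img, mask, size = 512, max_outside = 64, origin = NULL,
                        fill = 0) {
  stopifnot_same_shape(img, mask)
  h <- nrow(img); w <- ncol(img)
  draw_origin <- function(n) {
    lo <- -max_outside; hi <- n - size + max_outside
    if (lo > hi) round((n - size) / 2) else runif_int(lo, hi)
  }
  if (is.null(origin)) origin <- c(draw_origin(h), draw_origin(w))
  r0 <- origin[1]; c0 <- origin[2]
  out_img <- matrix(fill, size, size)
  out_mask <- matrix(0L, size, size)
  rs <- max(0, r0); re <- min(h, r0 + size)
  cs <- max(0, c0); ce <- min(w, c0 + size)
  if (re > rs && ce > cs) {
    out_img[(rs - r0 + 1):(re - r0), (cs - c0 + 1):(ce - c0)] <-
      img[(rs + 1):re, (cs + 1):ce]
    out_mask[(rs - r0 + 1):(re - r0), (cs - c0 + 1):(ce - c0)] <-
      mask[(rs + 1):re, (cs + 1):ce]
  }
  list(img = out_img, mask = out_mask, origin = origin)
}

#' Random gamma transform
#'
#' `out = in^gamma` with `gamma` uniform in `range`; intensities must lie in
#' `[0,1]`. Masks are untouched by design.
#' @param img numeric matrix in `[0,1]`.
#' @param range gamma interval.
#' @param gamma `NA` to draw; fixed exponent otherwise.
#' @return transformed matrix.
#' @export
random_gamma <- function(img, range = c(0.5, 1.5), gamma = NA) {
  if (min(img) < 0 || max(img) > 1) {
    stop("random_gamma expects intensities in [0,1]", call. = FALSE)
  }
  if (is.na(gamma)) gamma <- stats::runif(1, range[1], range[2])
  img^gamma
}

#' Additive Gaussian noise
#'
#' Adds zero-mean Gaussian noise with sd equal to `sd_fraction` of the
#' image's intensity range, then clips to `[0,1]`.
#' @param img numeric matrix with finite intensities.
#' @param sd_fraction noise sd as fraction of `max - min` (default 0.05).
#' @return noisy matrix in `[0,1]`.
#' @export
add_gaussian_noise <- function(img, sd_fraction = 0.05) {
  if (!all(is.finite(img))) stop("intensities must be finite", call. = FALSE)
  if (sd_fraction == 0) return(img)
  s <- sd_fraction * diff(range(img))
  if (s == 0) return(img)
  clamp01(img + matrix(stats::rnorm(length(img), 0, s), nrow(img), ncol(img)))
}

#' Apply the full augmentation stack to one training sample
#'
#' Runs, in order: display-window jitter (processed/sfm; raw images are
#' min-max normalized instead), horizontal flip, rotation, elastic
#' deformation, cropping, gamma, Gaussian noise. Geometric steps are applied
#' jointly to image and mask; the output is `crop_size x crop_size`. With a
#' seeded session RNG the replay is bit-identical.
#'
#' @param img [mammogram()].
#' @param mask paired [label_grid()].
#' @param policy [augmentation_policy()].
#' @return list with `image` (matrix in `[0,1]`) and `mask` ([label_grid()]).
#' @export
augment_sample <- function(img, mask, policy = augmentation_policy()) {
  stopifnot_same_shape(img$pixels, mask$labels)
  window_index <- if (length(img$windows) > 1) "random" else 1
  x <- net_input(img, window_index = window_index,
                 jitter_fraction = policy$lut_jitter)
  m <- mask$labels
  # pad/fill with the image's own background level (median border pixel):
  # ~0 for processed images, bright for raw images
  bg <- stats::median(c(x[1, ], x[nrow(x), ], x[, 1], x[, ncol(x)]))
  st <- random_horizontal_flip(x, m, prob = policy$flip_prob)
  st <- random_rotation(st$img, st$mask, range_deg = policy$rotation_deg,
                        fill = bg)
  st <- elastic_deformation(st$img, st$mask, alpha = policy$elastic_alpha,
                            sigma = policy$elastic_sigma,
                            alpha_affine = policy$elastic_alpha_affine,
                            fill = bg)
  st <- random_crop(st$img, st$mask, size = policy$crop_size,
                    max_outside = policy$crop_max_outside, fill = bg)
  out <- random_gamma(clamp01(st$img), range = policy$gamma_range)
  out <- add_gaussian_noise(out, sd_fraction = policy$noise_sd_fraction)
  list(image = out, mask = label_grid(st$mask, spacing_um = mask$spacing_um))
}

#' Scale the pixel-based policy parameters to a different crop resolution
#'
#' The default augmentation magnitudes are calibrated for 512 x 512 crops
#' of 400 um images. When training on smaller grids, the pixel-based
#' parameters (elastic smoothing width and affine corner jitter, crop size
#' and overshoot) must shrink proportionally to keep the physical
#' deformation strength comparable; scale-free parameters (window jitter,
#' flip probability, rotation angle, gamma, noise fraction) are untouched.
#'
#' @param policy [augmentation_policy()].
#' @param crop_size target crop side in pixels.
#' @return rescaled [augmentation_policy()].
#' @export
scale_policy <- function(policy, crop_size) {
  f <- crop_size / policy$crop_size
  augmentation_policy(
    lut_jitter = policy$lut_jitter, flip_prob = policy$flip_prob,
    rotation_deg = policy$rotation_deg,
    elastic_alpha = policy$elastic_alpha * f,
    elastic_sigma = policy$elastic_sigma * f,
    elastic_alpha_affine = policy$elastic_alpha_affine * f,
    crop_size = crop_size,
    crop_max_outside = round(policy$crop_max_outside * f),
    gamma_range = policy$gamma_range,
    noise_sd_fraction = policy$noise_sd_fraction, seed = policy$seed)
}
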