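#' Vendor style for phantom rendering
#'
#' Parameterizes the vendor-specific look of processed mammograms: display
#' nonlinearity, contrast gain, background offset, texture correlation
#' length, additive noise and optional digitized-film artifacts (bright
#' labels/edges). A negative `contrast_gain` with a high `background_level`
#' yields an inverted-contrast style, useful as an adversarial held-out
#' style in generalization experiments.
#'
#' @param name style tag.
#' @param gamma display nonlinearity exponent (> 0).
#' @param contrast_gain multiplicative gain (may be negative for inverted
#'   styles).
#' @param background_level additive intensity offset in `[0,1]`.
#' @param texture_scale correlation length of the tissue texture in pixels.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param film_artifacts add bright film labels/edges outside the breast.
#' @return list of class `"vendor_style"`.
#' @export
vendor_style <- function(name, gamma = 1, contrast_gain = 1,
                         background_level = 0, texture_scale = 8,
                         noise_sd = 0.01, film_artifacts = FALSE) {
  stopifnot(gamma > 0, background_level >= 0, background_level <= 1,
            texture_scale > 0, noise_sd >= 0)
  structure(list(name = name, gamma = gamma, contrast_gain = contrast_gain,
                 background_level = background_level,
                 texture_scale = texture_scale, noise_sd = noise_sd,
                 film_artifacts = film_artifacts),
            class = "vendor_style")
}

#' Default vendor styles
#'
#' Two moderately different digital-mammography styles; together with
#' [inverted_style()] they exercise the cross-vendor pipeline.
#' @return named list of [vendor_style()]s.
#' @export
default_styles <- function() {
  list(vendorA = vendor_style("vendorA", gamma = 1, contrast_gain = 1,
                              background_level = 0, texture_scale = 8,
                              noise_sd = 0.015),
       vendorB = vendor_style("vendorB", gamma = 0.75, contrast_gain = 0.85,
                              background_level = 0.06, texture_scale = 14,
                              noise_sd = 0.025))
}

#' @rdname default_styles
#' @export
inverted_style <- function() {
  vendor_style("inverted", gamma = 1, contrast_gain = -0.85,
               background_level = 0.95, texture_scale = 10, noise_sd = 0.02)
}

#' Phantom generator configuration
#'
#' Defaults mirror the composition of multi-vendor screening data: half the
#' images are MLO; the pectoral muscle is present in 99% of MLO and 28% of
#' CC images; its area relative to the breast region is drawn from
#' N(0.21, 0.14) for MLO and N(0.04, 0.03) for CC, clipped to a feasible
#' range.
#'
#' @param image_size square image side in pixels (default 128).
#' @param spacing_um nominal pixel pitch (default 400).
#' @param mlo_fraction fraction of MLO views (default 0.5).
#' @param pectoral_prob named vector of pectoral presence probabilities per
#'   view (defaults `MLO = 0.99`, `CC = 0.28`).
#' @param pectoral_area list of per-view `c(mean, sd)` of the
#'   pectoral-to-breast area fraction (defaults `MLO = (0.21, 0.14)`,
#'   `CC = (0.04, 0.03)`).
#' @param styles named list of [vendor_style()]s (default
#'   [default_styles()]).
#' @param images_per_patient inclusive integer range of images per patient
#'   (default `c(2, 4)`).
#' @param right_fraction fraction of right-laterality images, stored
#'   mirrored (default 0.5).
#' @return list of class `"phantom_config"`.
#' @export
phantom_config <- function(image_size = 128, spacing_um = 400,
                           mlo_fraction = 0.5,
                           pectoral_prob = c(MLO = 0.99, CC = 0.28),
                           pectoral_area = list(MLO = c(mean = 0.21, sd = 0.14),
                                                CC = c(mean = 0.04, sd = 0.03)),
                           styles = default_styles(),
                           images_per_patient = c(2, 4),
                           right_fraction = 0.5) {
  stopifnot(image_size >= 32, mlo_fraction >= 0, mlo_fraction <= 1,
            all(pectoral_prob >= 0), all(pectoral_prob <= 1),
            length(styles) >= 1, right_fraction >= 0, right_fraction <= 1)
  structure(list(image_size = image_size, spacing_um = spacing_um,
                 mlo_fraction = mlo_fraction, pectoral_prob = pectoral_prob,
                 pectoral_area = pectoral_area, styles = styles,
                 images_per_patient = images_per_patient,
                 right_fraction = right_fraction),
            class = "phantom_config")
}

## draw an area fraction from the configured normal, rejecting draws outside
## the rasterizable range; falls back to the mean after 100 rejections
draw_area_fraction <- function(mean_sd, lo = 0.01, hi = 0.9) {
  for (i in seq_len(100)) {
    f <- stats::rnorm(1, mean_sd[["mean"]], mean_sd[["sd"]])
    if (f > lo && f < hi) return(f)
  }
  mean_sd[["mean"]]
}

## binary search the wedge/crescent scale so the rasterized pectoral area is
## the requested fraction of the breast-region (breast + pectoral) area
fit_pectoral_region <- function(region_at, ellipse, target_fraction, s) {
  frac_at <- function(t) {
    pect <- region_at(t)
    sum(pect) / sum(ellipse | pect)
  }
  lo <- 0.01 * s; hi <- 2.5 * s
  if (frac_at(hi) < target_fraction) return(region_at(hi))
  for (i in seq_len(40)) {
    mid <- (lo + hi) / 2
    if (frac_at(mid) < target_fraction) lo <- mid else hi <- mid
  }
  region_at((lo + hi) / 2)
}

#' Generate one synthetic mammographic phantom
#'
#' Builds a half-elliptical breast attached to the left (chest-wall) image
#' edge with a wiggly boundary and smooth tissue texture; MLO views are
#' sheared and, with the configured probability, carry a pectoral wedge at
#' the upper-left corner whose area fraction is drawn from the configured
#' distribution (CC views get a small chest-wall crescent instead). The
#' truth mask derives from the same geometry, so it is exact by
#' construction and shared by the paired renderings: a raw,
#' attenuation-like image (bright background, darker tissue, low contrast)
#' and a processed image (dark background, bright tissue) transformed by a
#' vendor style. Uses the session RNG; geometry primitives are deliberately
#' non-anatomical.
#'
#' @param config [phantom_config()].
#' @param view `NULL` to draw from `mlo_fraction`, else `"CC"` or `"MLO"`.
#' @param style `NULL` to draw uniformly from `config$styles`, else a
#'   [vendor_style()].
#' @param patient_id identifier recorded on the sample.
#' @return list of class `"phantom_sample"` with `raw`, `processed`
#'   ([mammogram()]s), `truth` ([label_grid()]), `view`, `style`,
#'   `patient_id` and `pectoral_fraction` (`NA` when absent).
#' @export
generate_phantom <- function(config = phantom_config(), view = NULL,
                             style = NULL, patient_id = "p1") {
  s <- config$image_size
  if (is.null(view)) {
    view <- if (stats::runif(1) < config$mlo_fraction) "MLO" else "CC"
  }
  if (is.null(style)) {
    style <- config$styles[[runif_int(1, length(config$styles))]]
  }
  rr <- matrix(seq_len(s) - 1, s, s)
  cc <- matrix(seq_len(s) - 1, s, s, byrow = TRUE)
  # breast: half-ellipse attached to the left edge; its left-edge extent is
  # kept below the top quarter of rows so only a pectoral wedge can reach
  # the corner region used by the mask initializer
  rc <- stats::runif(1, 0.48, 0.58) * s
  b <- stats::runif(1, 0.18, min(0.30, rc / s - 0.28)) * s
  a <- stats::runif(1, 0.55, 0.75) * s
  shear <- if (view == "MLO") stats::runif(1, 0.05, 0.2) else 0
  wiggle <- smooth_noise_field(s, s, s / 8)
  re <- rr - rc - shear * cc
  ellipse <- (cc / a)^2 + (re / b)^2 <= (1 + 0.06 * wiggle)^2
  ellipse <- ellipse & (cc >= 0)
  # pectoral region
  pect <- matrix(FALSE, s, s)
  frac <- NA_real_
  if (stats::runif(1) < config$pectoral_prob[[view]]) {
    frac <- draw_area_fraction(config$pectoral_area[[view]])
    if (view == "MLO") {
      rho <- stats::runif(1, 0.6, 1.1)
      # keep the wedge tall enough to meet the ellipse at the chest wall,
      # so the breast region stays connected even for small area draws
      top_left <- min(rr[ellipse & cc <= 2])
      area_w <- frac / (1 - frac) * sum(ellipse)
      rho_max <- 2 * area_w / (top_left + 3)^2
      rho <- min(rho, max(0.12, rho_max))
      region_at <- function(t) rr / t + cc / (rho * t) < 1
    } else {
      rc2 <- rc + stats::runif(1, -0.08, 0.08) * s
      region_at <- function(t) (cc / t)^2 + ((rr - rc2) / (2.2 * t))^2 <= 1
    }
    pect <- fit_pectoral_region(region_at, ellipse, frac, s)
  }
  labels <- matrix(0L, s, s)
  labels[ellipse] <- 1L
  labels[pect] <- 2L
  truth <- label_grid(labels, spacing_um = config$spacing_um)
  breast_region <- labels > 0
  # shared anatomy: smooth tissue texture per region
  tex <- smooth_noise_field(s, s, style$texture_scale)
  tex2 <- smooth_noise_field(s, s, style$texture_scale)
  dens <- matrix(0.02, s, s)
  dens[labels == 1L] <- pmin(pmax(0.5 + 0.09 * tex[labels == 1L], 0.3), 0.68)
  dens[labels == 2L] <- pmin(pmax(0.78 + 0.05 * tex2[labels == 2L], 0.7), 0.9)
  processed <- apply_style(dens, style)
  raw_px <- 0.92 - 0.45 * (dens - 0.02) +
    matrix(stats::rnorm(s * s, 0, 0.01), s, s)
  raw_px <- clamp01(raw_px)
  laterality <- if (stats::runif(1) < config$right_fraction) "R" else "L"
  if (laterality == "R") {
    processed <- flip_horizontal(processed)
    raw_px <- flip_horizontal(raw_px)
    truth$labels <- flip_horizontal(truth$labels)
  }
  structure(list(
    raw = mammogram(raw_px, spacing_um = config$spacing_um, view = view,
                    laterality = laterality, kind = "raw",
                    vendor = style$name),
    processed = mammogram(processed, spacing_um = config$spacing_um,
                          view = view, laterality = laterality,
                          kind = "processed", vendor = style$name),
    truth = truth, view = view, style = style$name,
    patient_id = patient_id, pectoral_fraction = frac),
    class = "phantom_sample")
}

#' Apply a vendor style to a normalized intensity grid
#'
#' `out = background_level + contrast_gain * x^gamma + noise`, clipped to
#' `[0,1]`; apart from the noise the map is monotone in the input. With
#' `film_artifacts`, bright label/edge regions are drawn along the right and
#' top/bottom borders, which lie outside the breast for the phantom
#' geometry (breasts attach to the left edge).
#'
#' @param x numeric matrix in `[0,1]`.
#' @param style [vendor_style()].
#' @return styled matrix in `[0,1]`.
#' @export
apply_style <- function(x, style) {
  if (min(x) < -1e-9 || max(x) > 1 + 1e-9) {
    stop("apply_style expects intensities in [0,1]", call. = FALSE)
  }
  out <- style$background_level + style$contrast_gain * x^style$gamma
  if (style$noise_sd > 0) {
    out <- out + matrix(stats::rnorm(length(x), 0, style$noise_sd),
                        nrow(x), ncol(x))
  }
  if (style$film_artifacts) {
    h <- nrow(x); w <- ncol(x)
    # film label: bright rectangle near the right border
    lh <- max(3, round(0.12 * h)); lw <- max(3, round(0.08 * w))
    r0 <- runif_int(1, max(1, h - 4 * lh)); c0 <- w - lw - 1
    out[r0:(r0 + lh - 1), c0:(c0 + lw - 1)] <- 0.95
    # film edges: thin bright top and bottom strips
    eh <- max(1, round(0.015 * h))
    out[seq_len(eh), ] <- 0.9
    out[(h - eh + 1):h, ] <- 0.9
  }
  clamp01(out)
}

#' Generate a phantom dataset with a manifest
#'
#' Draws patients with a configured number of images each; each image gets
#' a view, laterality and vendor style, and paired raw/processed renderings
#' with one truth mask. When `out_dir` is given, processed/raw images and
#' masks are written as PNGs and the manifest records their paths.
#'
#' @param config [phantom_config()].
#' @param n_patients number of patients to draw.
#' @param seed optional RNG seed.
#' @param out_dir optional output directory for PNGs + `manifest.csv`.
#' @return list of class `"phantom_dataset"` with `samples` (list of
#'   [generate_phantom()] samples) and `manifest` (data.frame).
#' @export
generate_dataset <- function(config = phantom_config(), n_patients = 10,
                             seed = NULL, out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  samples <- list()
  rows <- list()
  img_i <- 0
  for (p in seq_len(n_patients)) {
    pid <- sprintf("pt%04d", p)
    n_img <- runif_int(config$images_per_patient[1], config$images_per_patient[2])
    for (j in seq_len(n_img)) {
      img_i <- img_i + 1
      sm <- generate_phantom(config, patient_id = pid)
      iid <- sprintf("im%05d", img_i)
      path <- mask_path <- raw_path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, paste0(iid, "_proc.png"))
        raw_path <- file.path(out_dir, paste0(iid, "_raw.png"))
        mask_path <- file.path(out_dir, paste0(iid, "_mask.png"))
        write_image(sm$processed, path)
        write_image(sm$raw, raw_path)
        write_mask(sm$truth, mask_path)
      }
      samples[[img_i]] <- sm
      rows[[img_i]] <- data.frame(
        patient_id = pid, image_id = iid, path = path, raw_path = raw_path,
        mask_path = mask_path, view = sm$view,
        laterality = sm$processed$laterality, kind = "processed",
        vendor = sm$style, spacing_um = config$spacing_um,
        pectoral_present = any(sm$truth$labels == 2L),
        pectoral_fraction = sm$pectoral_fraction,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(samples = samples, manifest = manifest, config = config),
            class = "phantom_dataset")
}

#' Build per-style record sets for the leave-one-style-out harness
#'
#' Generates `n_train + n_val + n_test` phantoms per style (processed
#' renderings, chest wall oriented left) and packages them as the
#' `style_sets` input of [run_leave_one_out()].
#'
#' @param config [phantom_config()]; its `styles` field is overridden per
#'   set.
#' @param styles named list of [vendor_style()]s.
#' @param n_train,n_val,n_test images per style and split.
#' @param seed optional RNG seed.
#' @return named list of `list(train, val, test)` record sets.
#' @export
phantom_style_sets <- function(config, styles, n_train = 20, n_val = 6,
                               n_test = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_train + n_val + n_test
  out <- lapply(seq_along(styles), function(i) {
    cfg <- config
    cfg$styles <- styles[i]
    samples <- lapply(seq_len(n), function(j) {
      generate_phantom(cfg, patient_id = sprintf("%s_pt%03d", styles[[i]]$name, j))
    })
    recs <- phantom_records(samples, "processed")
    list(train = recs[seq_len(n_train)],
         val = recs[n_train + seq_len(n_val)],
         test = recs[n_train + n_val + seq_len(n_test)])
  })
  names(out) <- names(styles)
  out
}
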