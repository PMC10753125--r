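#' Read a manifest table
#'
#' The manifest CSV lists one image per row with the metadata the pipeline
#' needs when the image format itself carries none. Required columns:
#' `patient_id, image_id, path, view, laterality, kind, vendor, spacing_um`;
#' optional: `mask_path, split, window_center, window_width, photometric`.
#'
#' @param path CSV file path.
#' @return data.frame with one row per image.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "image_id", "path", "view", "laterality", "kind",
           "vendor", "spacing_um")
  missing_cols <- setdiff(req, names(m))
  if (length(missing_cols) > 0) {
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Read a mammogram from a raster file
#'
#' Reads an 8/16-bit single-channel PNG (values scaled to `[0,1]` by the
#' reader) and populates acquisition metadata from the matching manifest row.
#' Images stored "white-is-low" are inverted so that higher values are more
#' radio-opaque. DICOM input is not supported by this build; convert to
#' 16-bit PNG plus a manifest row.
#'
#' @param path image file path (`.png`).
#' @param kind optional image-kind hint overriding the manifest
#'   (`"processed"`, `"raw"` or `"sfm"`).
#' @param manifest_row single-row data.frame (see [read_manifest()]) holding
#'   view/laterality/kind/vendor/spacing and optionally a display window.
#' @return A [mammogram()].
#' @export
read_image <- function(path, kind = NULL, manifest_row = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom")) {
    stop("DICOM input is not supported; supply PNG + manifest", call. = FALSE)
  }
  if (ext != "png") stop("unsupported image format: ", ext, call. = FALSE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  meta <- function(col, default) {
    if (!is.null(manifest_row) && col %in% names(manifest_row) &&
        !is.na(manifest_row[[col]][1])) manifest_row[[col]][1] else default
  }
  spacing <- as.numeric(meta("spacing_um", NA))
  if (is.na(spacing)) {
    stop("missing pixel spacing: no manifest entry for ", path, call. = FALSE)
  }
  kind <- if (!is.null(kind)) kind else meta("kind", "processed")
  photometric <- meta("photometric", "white-is-high")
  if (identical(photometric, "white-is-low")) {
    px <- max(px) + min(px) - px
  }
  windows <- NULL
  wc <- suppressWarnings(as.numeric(meta("window_center", NA)))
  ww <- suppressWarnings(as.numeric(meta("window_width", NA)))
  if (!is.na(wc) && !is.na(ww)) {
    if (ww <= 0) stop("non-positive window width in metadata", call. = FALSE)
    windows <- list(c(center = wc, width = ww))
  }
  mammogram(px, spacing_um = spacing,
            view = as.character(meta("view", "CC")),
            laterality = {
              lat <- as.character(meta("laterality", NA))
              if (is.na(lat) || !lat %in% c("L", "R")) NA else lat
            },
            kind = kind, vendor = as.character(meta("vendor", "unknown")),
            windows = windows, photometric = photometric)
}

#' Write a mammogram's pixel grid to an 8-bit PNG
#'
#' Intensities are clipped to `[0,1]` before writing.
#' @param img [mammogram()] or numeric matrix in `[0,1]`.
#' @param path output path.
#' @export
write_image <- function(img, path) {
  px <- clamp01(as_pixel_matrix(img))
  png::writePNG(px, path)
  invisible(path)
}

#' Read / write segmentation masks
#'
#' Masks are single-channel PNGs whose 8-bit values are the labels
#' themselves (0, 1, 2); the round trip is lossless.
#'
#' @param path mask file path.
#' @param spacing_um pixel pitch recorded on the returned grid.
#' @return [label_grid()].
#' @export
read_mask <- function(path, spacing_um = 400) {
  if (!file.exists(path)) stop("cannot read mask: ", path, call. = FALSE)
  v <- png::readPNG(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  labels <- round(v * 255)
  bad <- setdiff(unique(as.vector(labels)), c(0, 1, 2))
  if (length(bad) > 0) {
    stop("mask contains values outside {0,1,2}: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  label_grid(labels, spacing_um = spacing_um)
}

#' @rdname read_mask
#' @param mask [label_grid()] to write.
#' @export
write_mask <- function(mask, path) {
  labels <- as_label_matrix(mask)
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Resample a mammogram to a target pixel spacing
#'
#' Linear interpolation; the new grid dimension is
#' `round(old_dim * old_spacing / target)` with halves rounded away from
#' zero. An image already at the target spacing is returned unchanged.
#'
#' @param img [mammogram()].
#' @param target_um target pixel pitch in micrometers (default 400).
#' @return Resampled [mammogram()].
#' @export
resample_to_spacing <- function(img, target_um = 400) {
  if (target_um <= 0) stop("target_um must be > 0", call. = FALSE)
  if (all(img$spacing_um == target_um)) return(img)
  px <- resize_grid(img$pixels, img$spacing_um, target_um, nearest = FALSE)
  img$pixels <- pmax(px, 0)
  img$spacing_um <- c(target_um, target_um)
  img
}

#' Resample a label mask to a target pixel spacing
#'
#' Nearest-neighbor interpolation, so the value set is preserved.
#' @param mask [label_grid()].
#' @param target_um target pixel pitch in micrometers.
#' @return Resampled [label_grid()].
#' @export
resample_mask <- function(mask, target_um = 400) {
  if (target_um <= 0) stop("target_um must be > 0", call. = FALSE)
  if (all(mask$spacing_um == target_um)) return(mask)
  lab <- resize_grid(mask$labels + 0, mask$spacing_um, target_um, nearest = TRUE)
  label_grid(lab, spacing_um = target_um)
}

## shared resizing backend: maps target pixel centers into the source grid
resize_grid <- function(m, spacing_um, target_um, nearest = FALSE) {
  new_h <- max(1, round_half_away(nrow(m) * spacing_um[1] / target_um))
  new_w <- max(1, round_half_away(ncol(m) * spacing_um[2] / target_um))
  sr <- (seq_len(new_h) - 0.5) * (nrow(m) / new_h) - 0.5
  sc <- (seq_len(new_w) - 0.5) * (ncol(m) / new_w) - 0.5
  sr <- pmin(pmax(sr, 0), nrow(m) - 1)
  sc <- pmin(pmax(sc, 0), ncol(m) - 1)
  map_r <- matrix(sr, new_h, new_w)
  map_c <- matrix(sc, new_h, new_w, byrow = TRUE)
  if (nearest) .warp_nearest(m, map_r, map_c, 0) else .warp_bilinear(m, map_r, map_c, 0)
}

#' Apply display windowing with optional jitter
#'
#' Maps stored intensities through a linear `(center, width)` ramp to
#' `[0,1]`. With `jitter_fraction = j > 0`, the window is perturbed as
#' `center' = center * (1 + u1)`, `width' = width * (1 + u2)` with
#' `u1, u2 ~ U(-j, +j)`; `j = 0` reproduces the metadata window exactly
#' (the test-time setting). Uses the session RNG.
#'
#' @param img [mammogram()] of kind `"processed"` or `"sfm"` with at least
#'   one window.
#' @param window_index which window to use (default 1; `"random"` picks one
#'   uniformly, mirroring training-time lookup-table choice).
#' @param jitter_fraction relative jitter, `0 <= j < 1`.
#' @return Numeric matrix in `[0,1]`.
#' @export
apply_windowing <- function(img, window_index = 1, jitter_fraction = 0) {
  if (!img$kind %in% c("processed", "sfm")) {
    stop("windowing applies to processed/sfm images; use normalize_raw() for raw",
         call. = FALSE)
  }
  if (length(img$windows) < 1) stop("image has no display window", call. = FALSE)
  if (jitter_fraction < 0 || jitter_fraction >= 1) {
    stop("jitter_fraction must be in [0, 1)", call. = FALSE)
  }
  if (identical(window_index, "random")) {
    window_index <- runif_int(1, length(img$windows))
  }
  w <- img$windows[[window_index]]
  center <- w[[1]]; width <- w[[2]]
  if (width <= 0) stop("window width must be > 0", call. = FALSE)
  if (jitter_fraction > 0) {
    center <- center * (1 + stats::runif(1, -jitter_fraction, jitter_fraction))
    width <- width * (1 + stats::runif(1, -jitter_fraction, jitter_fraction))
  }
  clamp01((img$pixels - (center - width / 2)) / width)
}

#' Min-max normalize a raw mammogram to `[0,1]`
#'
#' Raw (for-processing) images carry no display window; they enter the
#' network min-max normalized, optionally after a `log1p` transform.
#'
#' @param img [mammogram()] of kind `"raw"`.
#' @param log_transform apply `log1p` before normalizing (default `FALSE`).
#' @return Numeric matrix in `[0,1]`.
#' @export
normalize_raw <- function(img, log_transform = FALSE) {
  px <- img$pixels
  if (log_transform) px <- log1p(px)
  rng <- range(px)
  if (rng[2] - rng[1] < .Machine$double.eps) return(px * 0)
  (px - rng[1]) / (rng[2] - rng[1])
}

#' Network input intensities for any image kind
#'
#' Processed/sfm images are windowed (see [apply_windowing()]); raw images
#' are min-max normalized.
#' @inheritParams apply_windowing
#' @param log_transform passed to [normalize_raw()] for raw images.
#' @return Numeric matrix in `[0,1]`.
#' @export
net_input <- function(img, window_index = 1, jitter_fraction = 0,
                      log_transform = FALSE) {
  if (img$kind == "raw") {
    normalize_raw(img, log_transform = log_transform)
  } else {
    apply_windowing(img, window_index, jitter_fraction)
  }
}

#' Orient a mammogram so the chest wall is on the left
#'
#' Downstream pectoral logic assumes the chest wall touches the left image
#' edge. When laterality is known, `"R"` images are mirrored; otherwise the
#' chest side is inferred from which vertical half carries more breast
#' tissue. The flip is recorded so predictions can be mirrored back, and the
#' laterality field is updated so the operation is idempotent.
#'
#' @param img [mammogram()].
#' @param mask optional paired [label_grid()], flipped alongside.
#' @return list with elements `image`, `mask` (or `NULL`) and `flipped`.
#' @export
orient_chest_wall_left <- function(img, mask = NULL) {
  flip <- if (!is.na(img$laterality)) {
    img$laterality == "R"
  } else {
    x <- net_input(img)
    if (img$kind == "raw") x <- 1 - x  # raw background is bright
    thr <- tryCatch(otsu_threshold(as.vector(x))$threshold, error = function(e) 0.5)
    fg <- x > thr
    half <- ncol(fg) %/% 2
    sum(fg[, seq_len(half)]) < sum(fg[, (ncol(fg) - half + 1):ncol(fg)])
  }
  if (flip) {
    img$pixels <- flip_horizontal(img$pixels)
    img$laterality <- "L"
    if (!is.null(mask)) mask$labels <- flip_horizontal(mask$labels)
  } else if (is.na(img$laterality)) {
    img$laterality <- "L"
  }
  list(image = img, mask = mask, flipped = flip)
}
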