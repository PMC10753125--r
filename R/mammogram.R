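#' Mammogram container
#'
#' Holds a 2-D non-negative intensity grid together with the acquisition
#' metadata the pipeline needs: pixel spacing, view, laterality, image kind,
#' vendor tag, display windows and photometric interpretation. Intensities
#' are stored so that higher values are more radio-opaque ("white-is-high");
#' images read from "white-is-low" sources are inverted at load time and the
#' original interpretation is recorded in `photometric`.
#'
#' @param pixels numeric matrix of finite, non-negative intensities
#'   (rows x columns).
#' @param spacing_um pixel pitch in micrometers; scalar (isotropic) or
#'   length-2 `(row, col)` vector, all entries > 0.
#' @param view projection, `"CC"` or `"MLO"`.
#' @param laterality `"L"`, `"R"`, or `NA` when unknown.
#' @param kind `"processed"` (for presentation), `"raw"` (for processing) or
#'   `"sfm"` (digitized screen film).
#' @param vendor free-form vendor/style tag.
#' @param windows list of `c(center, width)` display windows. For processed
#'   and sfm images a full-range default window is synthesized when none is
#'   supplied, so `windows` is always non-empty for those kinds.
#' @param photometric `"white-is-high"` or `"white-is-low"` (as stored in the
#'   source file; pixels are always kept white-is-high internally).
#'
#' @return An object of class `"mammogram"`.
#' @export
mammogram <- function(pixels, spacing_um = 400, view = c("CC", "MLO"),
                      laterality = c("L", "R", NA), kind = c("processed", "raw", "sfm"),
                      vendor = "unknown", windows = NULL,
                      photometric = c("white-is-high", "white-is-low")) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(pixels))) stop("pixels must be finite", call. = FALSE)
  if (min(pixels) < 0) stop("pixels must be non-negative", call. = FALSE)
  if (any(spacing_um <= 0)) stop("spacing_um must be > 0", call. = FALSE)
  if (length(spacing_um) == 1) spacing_um <- c(spacing_um, spacing_um)
  view <- match.arg(view)
  laterality <- if (is.null(laterality) || is.na(laterality[1])) NA_character_ else match.arg(laterality)
  kind <- match.arg(kind)
  photometric <- match.arg(photometric)
  if (is.null(windows) || length(windows) == 0) {
    if (kind %in% c("processed", "sfm")) {
      rng <- range(pixels)
      width <- max(rng[2] - rng[1], .Machine$double.eps)
      windows <- list(c(center = mean(rng), width = width))
    } else {
      windows <- list()
    }
  }
  for (w in windows) {
    if (length(w) != 2) stop("each window must be c(center, width)", call. = FALSE)
  }
  structure(list(pixels = pixels, spacing_um = spacing_um, view = view,
                 laterality = laterality, kind = kind, vendor = vendor,
                 windows = windows, photometric = photometric),
            class = "mammogram")
}

#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf("<mammogram> %dx%d px, %.0f um, view=%s, laterality=%s, kind=%s, vendor=%s, %d window(s)\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_um[1], x$view,
              ifelse(is.na(x$laterality), "?", x$laterality), x$kind, x$vendor,
              length(x$windows)))
  invisible(x)
}

#' Label grid container
#'
#' A 2-D integer grid with the three segmentation classes: 0 = background,
#' 1 = breast, 2 = pectoral muscle.
#'
#' @param labels integer matrix with values in `{0, 1, 2}`.
#' @param spacing_um pixel pitch in micrometers (scalar or `(row, col)`).
#' @return An object of class `"label_grid"`.
#' @export
label_grid <- function(labels, spacing_um = 400) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), c(0L, 1L, 2L))
  if (length(bad) > 0) {
    stop("labels outside {0,1,2}: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(spacing_um <= 0)) stop("spacing_um must be > 0", call. = FALSE)
  if (length(spacing_um) == 1) spacing_um <- c(spacing_um, spacing_um)
  structure(list(labels = labels, spacing_um = spacing_um), class = "label_grid")
}

#' @export
print.label_grid <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:2))
  cat(sprintf("<label_grid> %dx%d px, %.0f um, counts 0/1/2 = %d/%d/%d\n",
              nrow(x$labels), ncol(x$labels), x$spacing_um[1],
              tab[["0"]], tab[["1"]], tab[["2"]]))
  invisible(x)
}

## coerce helpers used internally
as_label_matrix <- function(mask) {
  if (inherits(mask, "label_grid")) mask$labels else mask
}

as_pixel_matrix <- function(img) {
  if (inherits(img, "mammogram")) img$pixels else img
}
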