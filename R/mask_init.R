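#' Otsu threshold of an intensity collection
#'
#' Builds a histogram over the observed intensity range and returns the bin
#' edge maximizing the between-class variance; ties are broken toward the
#' lower bin.
#'
#' @param values numeric vector (or matrix) of intensities with at least two
#'   distinct values.
#' @param bins histogram bin count (default 256).
#' @return list of class `"otsu_result"` with `threshold`,
#'   `between_class_variance` and `histogram_bins`.
#' @export
otsu_threshold <- function(values, bins = 256) {
  v <- as.vector(values)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(v) < 2 || rng[2] - rng[1] < .Machine$double.eps) {
    stop("degenerate input: need at least two distinct intensity values",
         call. = FALSE)
  }
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), bins),
                     nbins = bins)
  centers <- (edges[-1] + edges[-(bins + 1)]) / 2
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_total <- mu[bins]
  # between-class variance for a split after bin i (i = 1..bins-1)
  w0i <- w0[-bins]
  mui <- mu[-bins]
  w1i <- 1 - w0i
  num <- (mu_total * w0i - mui)^2
  den <- w0i * w1i
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  i <- which.max(sigma_b)  # which.max returns the first (lower-bin) maximum
  structure(list(threshold = edges[i + 1],
                 between_class_variance = sigma_b[i],
                 histogram_bins = bins),
            class = "otsu_result")
}

#' Initialize a breast mask by Otsu thresholding
#'
#' Pixels above the Otsu threshold become foreground; the largest connected
#' foreground component is kept and interior holes are filled. This is the
#' automated stand-in for the first step of mask creation (the manual
#' correction that followed it in practice is out of scope). When the
#' threshold separates the histogram only weakly (between-class variance
#' below `min_separation`, e.g. an essentially flat image), an all-background
#' mask is returned with attribute `degenerate = TRUE`.
#'
#' @param intensity numeric matrix in `[0,1]` with the chest wall oriented
#'   left.
#' @param bins histogram bins for the Otsu step.
#' @param min_separation minimum between-class variance treated as a real
#'   background/breast split (intensity^2 units; default 1e-3).
#' @return [label_grid()] with values `{0, 1}` (attribute `otsu` carries the
#'   threshold result, `degenerate` flags a failed split).
#' @export
init_breast_mask <- function(intensity, bins = 256, min_separation = 1e-3) {
  ot <- otsu_threshold(intensity, bins = bins)
  if (ot$between_class_variance < min_separation) {
    out <- label_grid(matrix(0L, nrow(intensity), ncol(intensity)))
    attr(out, "otsu") <- ot
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fg <- intensity > ot$threshold
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  comp <- lab == keep
  comp <- EBImage::fillHull(EBImage::Image(comp)) > 0
  out <- label_grid(matrix(as.integer(comp), nrow(intensity), ncol(intensity)))
  attr(out, "otsu") <- ot
  attr(out, "degenerate") <- FALSE
  out
}

#' Initialize a pectoral muscle mask inside the breast (MLO only)
#'
#' For MLO views, re-applies Otsu thresholding to breast-interior
#' intensities; the above-threshold connected component reaching the
#' upper-left corner region (left image edge within the top quarter of rows)
#' is relabeled as pectoral muscle (2). CC views are returned unchanged, as
#' no pectoral initialization is defined for them. If no candidate component
#' touches the corner region, the mask is returned without a pectoral label.
#'
#' @param intensity numeric matrix in `[0,1]`, chest wall left.
#' @param breast [label_grid()] from [init_breast_mask()] (values `{0,1}`).
#' @param view `"CC"` or `"MLO"`.
#' @param bins histogram bins for the Otsu step.
#' @param corner_row_fraction top fraction of rows defining the corner
#'   region at the left edge (default 0.25).
#' @param edge_cols number of left-edge columns belonging to the corner
#'   region (default 3).
#' @return [label_grid()] with values `{0, 1, 2}`.
#' @export
init_pectoral_mask <- function(intensity, breast, view = c("MLO", "CC"),
                               bins = 256, corner_row_fraction = 0.25,
                               edge_cols = 3) {
  view <- match.arg(view)
  labels <- as_label_matrix(breast)
  stopifnot_same_shape(intensity, labels)
  if (view == "CC") return(label_grid(labels))
  inside <- labels == 1L
  if (sum(inside) < 2) return(label_grid(labels))
  ot <- tryCatch(otsu_threshold(intensity[inside], bins = bins),
                 error = function(e) NULL)
  if (is.null(ot)) return(label_grid(labels))
  cand <- inside & (intensity > ot$threshold)
  if (!any(cand)) return(label_grid(labels))
  comp <- EBImage::bwlabel(cand)
  corner_rows <- seq_len(max(1L, floor(corner_row_fraction * nrow(labels))))
  corner_cols <- seq_len(min(edge_cols, ncol(labels)))
  corner_ids <- setdiff(unique(as.vector(comp[corner_rows, corner_cols])), 0)
  if (length(corner_ids) == 0) return(label_grid(labels))
  sizes <- tabulate(comp[comp > 0])
  pect_id <- corner_ids[which.max(sizes[corner_ids])]
  labels[comp == pect_id] <- 2L
  out <- label_grid(labels)
  attr(out, "otsu") <- ot
  out
}
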