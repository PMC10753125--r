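#' Dice coefficient for one class
#'
#' `2 |pred_c intersect truth_c| / (|pred_c| + |truth_c|)`. When the truth
#' contains no pixel of class `c`, the dice is undefined and `NA` is
#' returned so the image is excluded from class averages (false-positive
#' pressure is captured by [pectoral_detection()] instead).
#'
#' @param pred,truth [label_grid()]s or integer matrices of equal shape.
#' @param c class label (0, 1 or 2).
#' @return scalar in `[0,1]`, or `NA` when undefined.
#' @export
dice_per_class <- function(pred, truth, c) {
  p <- as_label_matrix(pred); t <- as_label_matrix(truth)
  stopifnot_same_shape(p, t)
  np <- sum(p == c); nt <- sum(t == c)
  if (nt == 0) return(NA_real_)
  2 * sum(p == c & t == c) / (np + nt)
}

#' Pixel-weighted overall dice
#'
#' The breast and pectoral dice coefficients averaged with the truth pixel
#' counts of the two classes as weights; background is excluded. When the
#' truth lacks a pectoral muscle this equals the breast dice.
#'
#' @inheritParams dice_per_class
#' @return scalar in `[0,1]`.
#' @export
overall_dice <- function(pred, truth) {
  t <- as_label_matrix(truth)
  nb <- sum(t == 1); np <- sum(t == 2)
  if (nb == 0) stop("overall dice undefined: truth contains no breast pixels",
                    call. = FALSE)
  db <- dice_per_class(pred, truth, 1)
  if (np == 0) return(db)
  dp <- dice_per_class(pred, truth, 2)
  (nb * db + np * dp) / (nb + np)
}

#' Pectoral muscle detection outcome
#'
#' An image is a false positive when the truth has no pectoral muscle but
#' the prediction contains at least one pectoral pixel (any-pixel rule), and
#' a false negative when the truth has a pectoral muscle but the prediction
#' contains none. For false positives the predicted pectoral area is also
#' compared against `area_fraction_threshold` of the truth breast region.
#'
#' @inheritParams dice_per_class
#' @param area_fraction_threshold fraction of the truth breast-region area
#'   above which a false positive is flagged as large (default 0.01).
#' @return list with `outcome` (`"TP"`, `"FP"`, `"FN"` or `"TN"`),
#'   `fp_breast_fraction` (predicted pectoral pixels over truth breast-region
#'   pixels, `NA` unless the truth lacks pectoral) and `fp_large`.
#' @export
pectoral_detection <- function(pred, truth, area_fraction_threshold = 0.01) {
  p <- as_label_matrix(pred); t <- as_label_matrix(truth)
  stopifnot_same_shape(p, t)
  truth_has <- any(t == 2); pred_has <- any(p == 2)
  outcome <- if (truth_has && pred_has) "TP"
    else if (truth_has) "FN"
    else if (pred_has) "FP"
    else "TN"
  fp_frac <- NA_real_
  fp_large <- NA
  if (!truth_has) {
    breast_px <- sum(t > 0)
    fp_frac <- if (breast_px > 0) sum(p == 2) / breast_px else NA_real_
    fp_large <- isTRUE(fp_frac > area_fraction_threshold)
  }
  list(outcome = outcome, fp_breast_fraction = fp_frac, fp_large = fp_large)
}

#' Score one predicted mask against its truth
#'
#' @inheritParams dice_per_class
#' @param area_fraction_threshold passed to [pectoral_detection()].
#' @return one-row data.frame with class dices, overall dice, truth pixel
#'   counts and the detection outcome.
#' @export
score_image <- function(pred, truth, area_fraction_threshold = 0.01) {
  t <- as_label_matrix(truth)
  det <- pectoral_detection(pred, truth, area_fraction_threshold)
  data.frame(breast_dice = dice_per_class(pred, truth, 1),
             pectoral_dice = dice_per_class(pred, truth, 2),
             overall_dice = overall_dice(pred, truth),
             n_breast = sum(t == 1), n_pectoral = sum(t == 2),
             detection = det$outcome,
             fp_breast_fraction = det$fp_breast_fraction,
             fp_large = det$fp_large,
             stringsAsFactors = FALSE)
}

#' Evaluate a model over a set of records
#'
#' Runs the model on every record (processed/sfm images through their
#' metadata window, raw images min-max normalized), scores each prediction
#' against its truth, and summarizes mean and standard deviation per stratum
#' plus pectoral detection tallies per view.
#'
#' @param model [build_unet()] model.
#' @param records list of records, each with elements `image`
#'   ([mammogram()]) and `truth` ([label_grid()]); metadata is read off the
#'   image (`view`, `vendor`, `kind`).
#' @param strata character vector of metadata columns to stratify by
#'   (subset of `view`, `vendor`, `kind`; default `"view"`).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return list of class `"evaluation_report"` with `per_image`, `summary`
#'   and `detection` data.frames.
#' @export
evaluate_dataset <- function(model, records, strata = "view",
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  rows <- lapply(records, function(rec) {
    pred <- predict_labels(model, net_input(rec$image),
                           spacing_um = rec$image$spacing_um)
    cbind(data.frame(view = rec$image$view, vendor = rec$image$vendor,
                     kind = rec$image$kind, stringsAsFactors = FALSE),
          score_image(pred, rec$truth))
  })
  per_image <- do.call(rbind, rows)
  sdev <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    if (sd_type == "sample") stats::sd(x) else sqrt(mean((x - mean(x))^2))
  }
  summarize <- function(df) {
    data.frame(n = nrow(df),
               breast_dice_mean = mean(df$breast_dice, na.rm = TRUE),
               breast_dice_sd = sdev(df$breast_dice),
               pectoral_n = sum(!is.na(df$pectoral_dice)),
               pectoral_dice_mean = if (any(!is.na(df$pectoral_dice)))
                 mean(df$pectoral_dice, na.rm = TRUE) else NA_real_,
               pectoral_dice_sd = sdev(df$pectoral_dice),
               overall_dice_mean = mean(df$overall_dice, na.rm = TRUE),
               overall_dice_sd = sdev(df$overall_dice))
  }
  groups <- if (length(strata) > 0) {
    interaction(per_image[, strata, drop = FALSE], drop = TRUE, sep = "/")
  } else {
    factor(rep("all", nrow(per_image)))
  }
  summary <- do.call(rbind, lapply(levels(groups), function(g) {
    cbind(data.frame(stratum = g, stringsAsFactors = FALSE),
          summarize(per_image[groups == g, , drop = FALSE]))
  }))
  summary <- rbind(summary,
                   cbind(data.frame(stratum = "all", stringsAsFactors = FALSE),
                         summarize(per_image)))
  detection <- do.call(rbind, lapply(unique(per_image$view), function(v) {
    df <- per_image[per_image$view == v, , drop = FALSE]
    data.frame(view = v, n = nrow(df),
               TP = sum(df$detection == "TP"), FP = sum(df$detection == "FP"),
               FN = sum(df$detection == "FN"), TN = sum(df$detection == "TN"),
               fp_large = sum(df$fp_large %in% TRUE))
  }))
  structure(list(per_image = per_image, summary = summary,
                 detection = detection),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$summary, row.names = FALSE)
  cat("pectoral detection by view:\n")
  print(x$detection, row.names = FALSE)
  invisible(x)
}

#' Compare two score groups with a t-test
#'
#' Plain Student t-test (equal variances) by default; the significance flag
#' uses a Bonferroni-adjusted level `alpha / n_comparisons`.
#'
#' @param a,b numeric score vectors (`n >= 2` each; equal lengths in paired
#'   mode).
#' @param mode `"unpaired_t"` or `"paired_t"`.
#' @param alpha family significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor (default 1).
#' @param var_equal assume equal variances for the unpaired test (default
#'   `TRUE`).
#' @return list with `statistic`, `p_value`, `threshold` and `significant`.
#' @export
compare_groups <- function(a, b, mode = c("unpaired_t", "paired_t"),
                           alpha = 0.05, n_comparisons = 1, var_equal = TRUE) {
  mode <- match.arg(mode)
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group", call. = FALSE)
  if (mode == "paired_t" && length(a) != length(b)) {
    stop("paired mode requires equal lengths", call. = FALSE)
  }
  tt <- if (mode == "paired_t") {
    stats::t.test(a, b, paired = TRUE)
  } else {
    stats::t.test(a, b, var.equal = var_equal)
  }
  threshold <- alpha / n_comparisons
  stat <- unname(tt$statistic)
  if (is.nan(stat)) stat <- 0  # identical groups: zero numerator and sd
  p <- tt$p.value
  if (is.nan(p)) p <- 1
  list(statistic = stat, p_value = p, threshold = threshold,
       significant = p < threshold)
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' @param groups list of at least three numeric score vectors (`n >= 2`
#'   each); names are used as group labels.
#' @param alpha significance level (default 0.05).
#' @return list with `f_statistic`, `p_value`, `significant` and `tukey`, a
#'   data.frame of pairwise mean differences and adjusted p-values.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 3) stop("need at least 3 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(score = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, integer(1)))))
  fit <- stats::aov(score ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL, stringsAsFactors = FALSE)
  p <- an[["Pr(>F)"]][1]
  list(f_statistic = an[["F value"]][1], p_value = p,
       significant = p < alpha, tukey = tukey)
}
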