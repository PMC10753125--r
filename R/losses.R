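#' Loss configuration
#'
#' Class weights follow the convention `alpha = c(1, 1, alpha_pectoral)`:
#' background and breast keep unit weight, and the pectoral class is
#' up-weighted to counter its class imbalance (it is small or absent in
#' most CC views). The focal loss down-weights confident predictions via
#' the focusing exponent `gamma`; at `gamma = 0` it reduces exactly to the
#' weighted cross-entropy.
#'
#' @param loss_type `"cross_entropy"` or `"focal"`.
#' @param alpha_pectoral weight of the pectoral class (default 1).
#' @param gamma focusing exponent for the focal loss (default 2).
#' @param alpha optional full 3-vector of class weights overriding
#'   `alpha_pectoral`.
#' @return list of class `"loss_config"`.
#' @export
loss_config <- function(loss_type = c("cross_entropy", "focal"),
                        alpha_pectoral = 1, gamma = 2, alpha = NULL) {
  loss_type <- match.arg(loss_type)
  if (is.null(alpha)) alpha <- c(1, 1, alpha_pectoral)
  if (any(alpha <= 0)) stop("alpha must be positive elementwise", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  structure(list(loss_type = loss_type, alpha = alpha, gamma = gamma),
            class = "loss_config")
}

LOG_CLAMP <- 1e-12

## p_t per class: the predicted probability of the true class, and one
## minus the predicted probability for every other class
pt_array <- function(probs, truth) {
  K <- dim(probs)[3]
  pt <- array(0, dim(probs))
  for (k in seq_len(K)) {
    pk <- probs[, , k]
    pt[, , k] <- ifelse(truth == k - 1, pk, 1 - pk)
  }
  pt
}

check_loss_inputs <- function(probs, truth, alpha) {
  if (length(dim(probs)) != 3) stop("probs must be H x W x classes", call. = FALSE)
  if (!identical(dim(probs)[1:2], dim(truth))) {
    stop("probability grid and truth shapes differ", call. = FALSE)
  }
  if (length(alpha) != dim(probs)[3]) {
    stop("alpha length must equal the number of classes", call. = FALSE)
  }
}

#' Weighted cross-entropy loss
#'
#' Per pixel, with `p_t,c = p_c` when the truth is class `c` and `1 - p_c`
#' otherwise, the loss is `-sum_c alpha_c log(p_t,c)`; the result is the
#' mean over pixels (so its magnitude does not depend on the crop size).
#' Logs are clamped at 1e-12 for numerical safety.
#'
#' @param probs `H x W x classes` probability array.
#' @param truth [label_grid()] or integer matrix with values `0..classes-1`.
#' @param alpha positive class-weight vector.
#' @return scalar loss (>= 0; zero iff the prediction is one-hot correct at
#'   every pixel).
#' @export
weighted_cross_entropy <- function(probs, truth, alpha = c(1, 1, 1)) {
  truth <- as_label_matrix(truth)
  check_loss_inputs(probs, truth, alpha)
  pt <- pt_array(probs, truth)
  acc <- 0
  for (k in seq_len(length(alpha))) {
    acc <- acc - alpha[k] * log(pmax(pt[, , k], LOG_CLAMP))
  }
  mean(acc)
}

#' Weighted focal loss
#'
#' Per pixel `-sum_c alpha_c (1 - p_t,c)^gamma log(p_t,c)` with the same
#' `p_t` convention as [weighted_cross_entropy()]; mean over pixels. At
#' `gamma = 0` it equals the weighted cross-entropy.
#'
#' @inheritParams weighted_cross_entropy
#' @param gamma focusing exponent (>= 0).
#' @export
focal_loss <- function(probs, truth, alpha = c(1, 1, 1), gamma = 2) {
  truth <- as_label_matrix(truth)
  check_loss_inputs(probs, truth, alpha)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  pt <- pt_array(probs, truth)
  acc <- 0
  for (k in seq_len(length(alpha))) {
    ptk <- pt[, , k]
    acc <- acc - alpha[k] * (1 - ptk)^gamma * log(pmax(ptk, LOG_CLAMP))
  }
  mean(acc)
}

#' Evaluate a configured loss
#' @inheritParams weighted_cross_entropy
#' @param config [loss_config()].
#' @export
segmentation_loss <- function(probs, truth, config) {
  if (config$loss_type == "focal") {
    focal_loss(probs, truth, config$alpha, config$gamma)
  } else {
    weighted_cross_entropy(probs, truth, config$alpha)
  }
}

## Gradient of the mean-reduced loss w.r.t. the softmax logits.
## dL/dz_k = p_k * (dL/dp_k - sum_c dL/dp_c * p_c), per pixel / n_pixels.
loss_grad_logits <- function(probs, truth, config) {
  truth <- as_label_matrix(truth)
  K <- dim(probs)[3]
  gp <- array(0, dim(probs))
  for (k in seq_len(K)) {
    pk <- probs[, , k]
    is_true <- truth == k - 1
    ptk <- ifelse(is_true, pk, 1 - pk)
    ptk <- pmax(ptk, LOG_CLAMP)
    gpt <- if (config$loss_type == "focal" && config$gamma > 0) {
      g <- config$gamma
      config$alpha[k] * (g * (1 - ptk)^(g - 1) * log(ptk) - (1 - ptk)^g / ptk)
    } else {
      -config$alpha[k] / ptk
    }
    gp[, , k] <- ifelse(is_true, gpt, -gpt)
  }
  dot <- 0
  for (k in seq_len(K)) dot <- dot + gp[, , k] * probs[, , k]
  gz <- array(0, dim(probs))
  for (k in seq_len(K)) gz[, , k] <- probs[, , k] * (gp[, , k] - dot)
  gz / (dim(probs)[1] * dim(probs)[2])
}

## Loss value + parameter gradients for one training sample
unet_loss_grad <- function(model, x, truth, config, training = TRUE) {
  fw <- unet_forward(model, x, training = training, cache = TRUE)
  loss <- segmentation_loss(fw$probs, truth, config)
  gz <- loss_grad_logits(fw$probs, as_label_matrix(truth), config)
  grads <- unet_backward(model, fw$caches, gz)
  list(loss = loss, grads = grads)
}
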