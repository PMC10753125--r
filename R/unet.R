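#' U-Net configuration
#'
#' @param depth number of down/up-sampling scales (default 4).
#' @param base_filters filters at the first scale, doubled at each deeper
#'   scale (default 64).
#' @param classes output classes (default 3: background, breast, pectoral).
#' @param dropout_prob dropout probability before the final 1x1 convolution
#'   (default 0.5; active during training only).
#' @param conv_kernel spatial kernel size of the main convolutions
#'   (default 3).
#' @param in_channels input channels (default 1).
#' @return list of class `"unet_config"`.
#' @export
unet_config <- function(depth = 4, base_filters = 64, classes = 3,
                        dropout_prob = 0.5, conv_kernel = 3, in_channels = 1) {
  stopifnot(depth >= 1, base_filters >= 1, classes >= 2,
            dropout_prob >= 0, dropout_prob < 1,
            conv_kernel %% 2 == 1, in_channels >= 1)
  structure(list(depth = depth, base_filters = base_filters, classes = classes,
                 dropout_prob = dropout_prob, conv_kernel = conv_kernel,
                 in_channels = in_channels),
            class = "unet_config")
}

## Kaiming-uniform weight matrix: bound sqrt(6 / fan_in), fan_in = k^2 * cin
kaiming_conv <- function(cin, cout, k) {
  fan_in <- k * k * cin
  bound <- sqrt(6 / fan_in)
  list(W = matrix(stats::runif(cout * fan_in, -bound, bound), cout, fan_in),
       b = rep(0, cout), k = as.integer(k), cin = cin, cout = cout)
}

#' Encoder filter counts of a U-Net configuration
#'
#' Scale `s` (0-based, bottleneck included) carries
#' `base_filters * 2^s` filters.
#' @param config [unet_config()].
#' @return integer vector of length `depth + 1`.
#' @export
encoder_filters <- function(config) {
  as.integer(config$base_filters * 2^(0:config$depth))
}

#' Build a U-Net segmentation model
#'
#' Encoder: `depth` blocks of two same-padded `conv_kernel` convolutions
#' (ReLU) followed by 2x2 max pooling; filters start at `base_filters` and
#' double at each scale. Decoder: bilinear 2x upsampling, a 1x1 convolution
#' halving the filters, concatenation with the encoder skip, then two
#' `conv_kernel` convolutions (ReLU). Head: dropout, a 1x1 convolution to
#' `classes` channels, softmax. Weights use Kaiming-uniform initialization;
#' biases start at zero. Uses the session RNG.
#'
#' @param config [unet_config()].
#' @return list of class `"unet_model"` with elements `config` and `params`.
#' @export
build_unet <- function(config = unet_config()) {
  stopifnot(inherits(config, "unet_config"))
  d <- config$depth; f <- config$base_filters; k <- config$conv_kernel
  params <- list()
  cin <- config$in_channels
  for (s in seq_len(d)) {
    cout <- f * 2^(s - 1)
    params[[paste0("enc", s, "_c1")]] <- kaiming_conv(cin, cout, k)
    params[[paste0("enc", s, "_c2")]] <- kaiming_conv(cout, cout, k)
    cin <- cout
  }
  cb <- f * 2^d
  params[["bott_c1"]] <- kaiming_conv(cin, cb, k)
  params[["bott_c2"]] <- kaiming_conv(cb, cb, k)
  for (s in rev(seq_len(d))) {
    chi <- f * 2^s        # channels arriving from below
    clo <- f * 2^(s - 1)  # channels at this scale
    params[[paste0("dec", s, "_up")]] <- kaiming_conv(chi, clo, 1)
    params[[paste0("dec", s, "_c1")]] <- kaiming_conv(2 * clo, clo, k)
    params[[paste0("dec", s, "_c2")]] <- kaiming_conv(clo, clo, k)
  }
  params[["final"]] <- kaiming_conv(f, config$classes, 1)
  structure(list(config = config, params = params), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth=%d, filters=%s, classes=%d, %d parameters\n",
              x$config$depth,
              paste(encoder_filters(x$config), collapse = "-"),
              x$config$classes, n_parameters(x)))
  invisible(x)
}

#' Trainable parameter count
#' @param model [build_unet()] model.
#' @return total number of weights and biases.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

as_cube <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1)) else x
}

conv_relu_fwd <- function(x, p) {
  z <- .conv2d_fwd(x, p$W, p$b, p$k)
  a <- z
  a[a < 0] <- 0
  list(x = x, z = z, a = a)
}

conv_relu_bwd <- function(cache, p, ga) {
  gz <- ga * (cache$z > 0)
  .conv2d_bwd(cache$x, p$W, gz, p$k)
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

softmax_channels <- function(l) {
  K <- dim(l)[3]
  m <- l[, , 1]
  for (k in seq_len(K)[-1]) m <- pmax(m, l[, , k])
  e <- array(0, dim(l))
  s <- 0
  for (k in seq_len(K)) {
    e[, , k] <- exp(l[, , k] - m)
    s <- s + e[, , k]
  }
  for (k in seq_len(K)) e[, , k] <- e[, , k] / s
  e
}

## Full forward pass. training = TRUE enables dropout (inverted scaling);
## with cache = TRUE all intermediates needed by unet_backward are kept.
unet_forward <- function(model, x, training = FALSE, cache = FALSE) {
  cfg <- model$config
  p <- model$params
  cur <- as_cube(x)
  caches <- list(conv = list(), pool = list(), skips = list())
  for (s in seq_len(cfg$depth)) {
    c1 <- conv_relu_fwd(cur, p[[paste0("enc", s, "_c1")]])
    c2 <- conv_relu_fwd(c1$a, p[[paste0("enc", s, "_c2")]])
    if (cache) {
      caches$conv[[paste0("enc", s, "_c1")]] <- c1[c("x", "z")]
      caches$conv[[paste0("enc", s, "_c2")]] <- c2[c("x", "z")]
    }
    caches$skips[[s]] <- c2$a
    mp <- .maxpool2_fwd(c2$a)
    if (cache) caches$pool[[s]] <- list(idx = mp$idx, h = dim(c2$a)[1], w = dim(c2$a)[2])
    cur <- mp$y
  }
  b1 <- conv_relu_fwd(cur, p[["bott_c1"]])
  b2 <- conv_relu_fwd(b1$a, p[["bott_c2"]])
  if (cache) {
    caches$conv[["bott_c1"]] <- b1[c("x", "z")]
    caches$conv[["bott_c2"]] <- b2[c("x", "z")]
  }
  cur <- b2$a
  for (s in rev(seq_len(cfg$depth))) {
    up <- .upsample2_fwd(cur)
    if (cache) caches$pool[[paste0("updim", s)]] <- dim(cur)
    u <- conv_relu_fwd(up, p[[paste0("dec", s, "_up")]])
    cat_in <- concat_c(u$a, caches$skips[[s]])
    c1 <- conv_relu_fwd(cat_in, p[[paste0("dec", s, "_c1")]])
    c2 <- conv_relu_fwd(c1$a, p[[paste0("dec", s, "_c2")]])
    if (cache) {
      caches$conv[[paste0("dec", s, "_up")]] <- u[c("x", "z")]
      caches$conv[[paste0("dec", s, "_c1")]] <- c1[c("x", "z")]
      caches$conv[[paste0("dec", s, "_c2")]] <- c2[c("x", "z")]
    }
    cur <- c2$a
  }
  if (training && cfg$dropout_prob > 0) {
    keep <- 1 - cfg$dropout_prob
    dmask <- array(stats::rbinom(length(cur), 1, keep) / keep, dim(cur))
    cur <- cur * dmask
    if (cache) caches$dropout <- dmask
  }
  fz <- .conv2d_fwd(cur, p[["final"]]$W, p[["final"]]$b, 1L)
  if (cache) caches$conv[["final"]] <- list(x = cur)
  probs <- softmax_channels(fz)
  list(logits = fz, probs = probs, caches = if (cache) caches else NULL)
}

## Backward pass from a gradient w.r.t. the logits; returns per-layer
## gradients named like model$params.
unet_backward <- function(model, caches, glogits) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  bf <- .conv2d_bwd(caches$conv[["final"]]$x, p[["final"]]$W, glogits, 1L)
  grads[["final"]] <- list(gW = bf$gW, gb = bf$gb)
  g <- bf$gx
  if (!is.null(caches$dropout)) g <- g * caches$dropout
  gskip <- vector("list", cfg$depth)
  for (s in seq_len(cfg$depth)) {  # decoder scales, shallow -> deep
    b2 <- conv_relu_bwd(caches$conv[[paste0("dec", s, "_c2")]],
                        p[[paste0("dec", s, "_c2")]], g)
    grads[[paste0("dec", s, "_c2")]] <- list(gW = b2$gW, gb = b2$gb)
    b1 <- conv_relu_bwd(caches$conv[[paste0("dec", s, "_c1")]],
                        p[[paste0("dec", s, "_c1")]], b2$gx)
    grads[[paste0("dec", s, "_c1")]] <- list(gW = b1$gW, gb = b1$gb)
    clo <- dim(b1$gx)[3] / 2
    gup_a <- b1$gx[, , seq_len(clo), drop = FALSE]
    gskip[[s]] <- b1$gx[, , clo + seq_len(clo), drop = FALSE]
    bu <- conv_relu_bwd(caches$conv[[paste0("dec", s, "_up")]],
                        p[[paste0("dec", s, "_up")]], gup_a)
    grads[[paste0("dec", s, "_up")]] <- list(gW = bu$gW, gb = bu$gb)
    dims <- caches$pool[[paste0("updim", s)]]
    g <- .upsample2_bwd(bu$gx, dims[1], dims[2])
  }
  b2 <- conv_relu_bwd(caches$conv[["bott_c2"]], p[["bott_c2"]], g)
  grads[["bott_c2"]] <- list(gW = b2$gW, gb = b2$gb)
  b1 <- conv_relu_bwd(caches$conv[["bott_c1"]], p[["bott_c1"]], b2$gx)
  grads[["bott_c1"]] <- list(gW = b1$gW, gb = b1$gb)
  g <- b1$gx
  for (s in rev(seq_len(cfg$depth))) {  # encoder scales, deep -> shallow
    pool <- caches$pool[[s]]
    ga <- .maxpool2_bwd(pool$idx, g, pool$h, pool$w) + gskip[[s]]
    b2 <- conv_relu_bwd(caches$conv[[paste0("enc", s, "_c2")]],
                        p[[paste0("enc", s, "_c2")]], ga)
    grads[[paste0("enc", s, "_c2")]] <- list(gW = b2$gW, gb = b2$gb)
    b1 <- conv_relu_bwd(caches$conv[[paste0("enc", s, "_c1")]],
                        p[[paste0("enc", s, "_c1")]], b2$gx)
    grads[[paste0("enc", s, "_c1")]] <- list(gW = b1$gW, gb = b1$gb)
    g <- b1$gx
  }
  grads
}

#' Per-pixel class probabilities for an intensity grid
#'
#' Pads the input with zeros to the next multiple of `2^depth`, runs the
#' network in inference mode (dropout disabled) and crops the output back,
#' so the probability grid matches the input shape exactly and each pixel's
#' probabilities sum to one.
#'
#' @param model [build_unet()] model.
#' @param intensity numeric matrix in `[0,1]`.
#' @return `H x W x classes` probability array (classes ordered background,
#'   breast, pectoral).
#' @export
predict_probabilities <- function(model, intensity) {
  if (!all(is.finite(intensity))) stop("input must be finite", call. = FALSE)
  h <- nrow(intensity); w <- ncol(intensity)
  mult <- 2^model$config$depth
  hp <- ceiling(h / mult) * mult
  wp <- ceiling(w / mult) * mult
  xp <- matrix(0, hp, wp)
  xp[seq_len(h), seq_len(w)] <- intensity
  out <- unet_forward(model, xp, training = FALSE, cache = FALSE)
  out$probs[seq_len(h), seq_len(w), , drop = FALSE]
}

#' Predicted label grid for an intensity grid
#'
#' Per-pixel argmax of [predict_probabilities()]; exact ties go to the lower
#' class index.
#' @inheritParams predict_probabilities
#' @param spacing_um pixel pitch recorded on the returned grid.
#' @return [label_grid()].
#' @export
predict_labels <- function(model, intensity, spacing_um = 400) {
  probs <- predict_probabilities(model, intensity)
  label_grid(argmax_labels(probs), spacing_um = spacing_um)
}

## argmax over the class axis with ties to the lower index
argmax_labels <- function(probs) {
  K <- dim(probs)[3]
  lab <- matrix(0L, dim(probs)[1], dim(probs)[2])
  best <- probs[, , 1]
  for (k in seq_len(K)[-1]) {
    sel <- probs[, , k] > best
    lab[sel] <- as.integer(k - 1)
    best[sel] <- probs[, , k][sel]
  }
  lab
}

#' Save / load a model
#'
#' Weights and configuration are stored together in a single RDS container.
#' @param model [build_unet()] model.
#' @param path file path.
#' @export
save_unet <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "unet_model"))
  model
}
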