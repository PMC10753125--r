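## shared fixtures and independent oracles used across test files

# brute-force per-pixel, per-class loss oracles (independent of the
# vectorized implementation)
oracle_wce <- function(probs, truth, alpha) {
  H <- dim(probs)[1]; W <- dim(probs)[2]; K <- dim(probs)[3]
  total <- 0
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    for (k in seq_len(K)) {
      pt <- if (truth[r, cc] == k - 1) probs[r, cc, k] else 1 - probs[r, cc, k]
      total <- total - alpha[k] * log(max(pt, 1e-12))
    }
  }
  total / (H * W)
}

oracle_focal <- function(probs, truth, alpha, gamma) {
  H <- dim(probs)[1]; W <- dim(probs)[2]; K <- dim(probs)[3]
  total <- 0
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    for (k in seq_len(K)) {
      pt <- if (truth[r, cc] == k - 1) probs[r, cc, k] else 1 - probs[r, cc, k]
      pt_c <- max(pt, 1e-12)
      total <- total - alpha[k] * (1 - pt)^gamma * log(pt_c)
    }
  }
  total / (H * W)
}

# random valid probability grid (per-pixel simplex) + labels
random_probs <- function(h, w, k = 3) {
  raw <- array(stats::rexp(h * w * k), c(h, w, k))
  s <- 0
  for (i in seq_len(k)) s <- s + raw[, , i]
  for (i in seq_len(k)) raw[, , i] <- raw[, , i] / s
  raw
}

random_labels <- function(h, w, k = 3) {
  matrix(sample(0:(k - 1), h * w, replace = TRUE), h, w)
}

# set-counting dice oracle
oracle_dice <- function(pred, truth, c) {
  nt <- sum(truth == c)
  if (nt == 0) return(NA_real_)
  2 * length(intersect(which(pred == c), which(truth == c))) /
    (sum(pred == c) + nt)
}

# exhaustive Otsu oracle: maximize between-class variance over every bin
# boundary of the same histogram
oracle_otsu <- function(v, bins = 256) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                          bins), nbins = bins)
  centers <- (edges[-1] + edges[-(bins + 1)]) / 2
  p <- counts / sum(counts)
  best <- -Inf; best_i <- NA
  for (i in seq_len(bins - 1)) {
    w0 <- sum(p[1:i]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:i] * centers[1:i]) / w0
    mu1 <- sum(p[(i + 1):bins] * centers[(i + 1):bins]) / w1
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best) { best <- sb; best_i <- i }
  }
  list(threshold = edges[best_i + 1], between_class_variance = best)
}

# small fast phantom configuration used by most pipeline tests
tiny_phantom_config <- function(size = 64, ...) {
  phantom_config(image_size = size, ...)
}

# identity augmentation policy at a given crop size
identity_policy <- function(size) {
  augmentation_policy(lut_jitter = 0, flip_prob = 0, rotation_deg = 0,
                      elastic_alpha = 0, elastic_sigma = 1,
                      elastic_alpha_affine = 0, crop_size = size,
                      crop_max_outside = 0, gamma_range = c(1, 1),
                      noise_sd_fraction = 0)
}
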