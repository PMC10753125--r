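## internal helpers shared across modules

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

## Smooth a 2-D field with a Gaussian of width `sigma` (pixels) via FFT
## (periodic boundary). Mean is preserved; sigma = 0 is the identity.
gaussian_smooth_field <- function(field, sigma) {
  if (sigma <= 0) return(field)
  h <- nrow(field); w <- ncol(field)
  fr <- c(0:(floor(h / 2)), -(ceiling(h / 2) - 1):-1)[seq_len(h)] / h
  fc <- c(0:(floor(w / 2)), -(ceiling(w / 2) - 1):-1)[seq_len(w)] / w
  g <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, "+"))
  Re(stats::fft(stats::fft(field) * g, inverse = TRUE)) / (h * w)
}

## Smoothed white-noise texture with unit sd and zero mean; `scale` is the
## Gaussian correlation length in pixels.
smooth_noise_field <- function(h, w, scale) {
  f <- gaussian_smooth_field(matrix(stats::rnorm(h * w), h, w), scale)
  s <- stats::sd(as.vector(f))
  if (s < .Machine$double.eps) return(matrix(0, h, w))
  (f - mean(f)) / s
}

## uniform integer draw on lo..hi using one runif (avoids sample()'s
## length-1 surprise)
runif_int <- function(lo, hi) {
  lo + min(hi - lo, floor(stats::runif(1) * (hi - lo + 1)))
}

flip_horizontal <- function(m) m[, ncol(m):1, drop = FALSE]

stopifnot_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("image and mask shapes differ: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), call. = FALSE)
  }
}
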