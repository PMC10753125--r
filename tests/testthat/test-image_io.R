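test_that("mammogram constructor enforces invariants and synthesizes windows", {
  px <- matrix(runif(20), 4, 5)
  m <- mammogram(px, spacing_um = 70, view = "MLO", laterality = "L",
                 kind = "processed")
  expect_length(m$windows, 1)  # full-range default window synthesized
  expect_equal(m$spacing_um, c(70, 70))
  expect_error(mammogram(px, spacing_um = 0), "spacing")
  expect_error(mammogram(px - 10), "non-negative")
  expect_error(mammogram(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
  r <- mammogram(px, kind = "raw")
  expect_length(r$windows, 0)  # raw images carry no display window
})

test_that("label grids reject values outside the three classes", {
  expect_error(label_grid(matrix(c(0L, 3L), 1, 2)), "outside")
  lg <- label_grid(matrix(c(0L, 1L, 2L, 1L), 2, 2))
  expect_identical(sort(unique(as.vector(lg$labels))), c(0L, 1L, 2L))
})

test_that("mask PNG round trip is lossless and bad values are rejected", {
  tmp <- withr::local_tempfile(fileext = ".png")
  set.seed(1)
  lab <- matrix(sample(0:2, 30 * 20, replace = TRUE), 30, 20)
  write_mask(label_grid(lab), tmp)
  expect_identical(read_mask(tmp)$labels, matrix(as.integer(lab), 30, 20))
  # empty mask round trip
  write_mask(label_grid(matrix(0L, 5, 5)), tmp)
  expect_true(all(read_mask(tmp)$labels == 0L))
  # a file holding value 3 is a format error
  png::writePNG(matrix(3 / 255, 4, 4), tmp)
  expect_error(read_mask(tmp), "outside")
})

test_that("images load through the manifest with metadata and inversion", {
  dir <- withr::local_tempdir()
  px <- matrix(seq(0, 1, length.out = 24), 4, 6)
  p <- file.path(dir, "a.png")
  png::writePNG(px, p)
  row <- data.frame(patient_id = "p1", image_id = "a", path = p,
                    view = "MLO", laterality = "R", kind = "processed",
                    vendor = "v", spacing_um = 85, stringsAsFactors = FALSE)
  img <- read_image(p, manifest_row = row)
  expect_equal(img$spacing_um, c(85, 85))
  expect_equal(img$view, "MLO")
  expect_equal(img$laterality, "R")
  # white-is-low sources are inverted: the max raw pixel becomes the min
  row$photometric <- "white-is-low"
  inv <- read_image(p, manifest_row = row)
  expect_equal(which.max(px), which.min(inv$pixels))
  expect_equal(inv$photometric, "white-is-low")
  # missing spacing is a metadata error
  expect_error(read_image(p), "spacing")
  expect_error(read_image(file.path(dir, "none.png")), "cannot read")
})

test_that("resampling follows the dimension rounding rule", {
  img <- mammogram(matrix(runif(100 * 100), 100, 100), spacing_um = 200)
  out <- resample_to_spacing(img, 400)
  expect_equal(dim(out$pixels), c(50, 50))  # factor-2 decimation
  expect_equal(out$spacing_um, c(400, 400))
  # already at target: unchanged object
  at <- mammogram(matrix(runif(16), 4, 4), spacing_um = 400)
  expect_identical(resample_to_spacing(at, 400), at)
  # 512 rows at 70 um -> round(512 * 70/400) = 90 rows
  big <- mammogram(matrix(runif(512 * 64), 512, 64), spacing_um = 70)
  expect_equal(nrow(resample_to_spacing(big, 400)$pixels), 90)
  expect_error(resample_to_spacing(img, -1), "target_um")
})

test_that("resampling preserves the mean of smooth images within 2%", {
  g <- outer(seq(0, 1, length.out = 80), seq(0, 1, length.out = 80),
             function(a, b) 0.3 + 0.4 * sin(2 * a) * cos(1.5 * b))
  img <- mammogram(g, spacing_um = 200)
  out <- resample_to_spacing(img, 400)
  expect_lt(abs(mean(out$pixels) - mean(g)) / mean(g), 0.02)
})

test_that("mask resampling is nearest-neighbor and self-consistent", {
  set.seed(2)
  # blocky mask: upsample a coarse random grid
  coarse <- matrix(sample(0:2, 8 * 8, replace = TRUE), 8, 8)
  lab <- coarse[rep(1:8, each = 8), rep(1:8, each = 8)]
  mask <- label_grid(lab, spacing_um = 400)
  down <- resample_mask(mask, 800)
  expect_true(all(down$labels %in% 0:2))
  up <- resample_mask(down, 400)
  expect_gte(mean(up$labels == lab), 0.95)
  # constant masks stay constant under any factor
  const <- resample_mask(label_grid(matrix(1L, 20, 20)), 317)
  expect_true(all(const$labels == 1L))
})

test_that("windowing maps the linear ramp and clips", {
  px <- matrix(c(0.1, 0.25, 0.5, 0.75, 0.9, 0.05), 2, 3)
  img <- mammogram(px, windows = list(c(center = 0.5, width = 0.5)))
  out <- apply_windowing(img)
  expect_equal(out[px == 0.5], 0.5)           # ramp midpoint
  expect_true(all(out[px <= 0.25] == 0))      # below center - width/2
  expect_true(all(out[px >= 0.75] == 1))      # above center + width/2
  expect_error(apply_windowing(img, jitter_fraction = 1), "jitter")
  bad <- img; bad$windows <- list(c(center = 0.5, width = 0))
  expect_error(apply_windowing(bad), "width")
  expect_error(apply_windowing(mammogram(px, kind = "raw")), "raw")
})

test_that("window jitter stays within +/-5% and looks uniform", {
  set.seed(3)
  probe <- mammogram(matrix(c(0.48, 0.52), 1, 2),
                     windows = list(c(center = 0.5, width = 0.5)))
  centers <- widths <- numeric(2000)
  for (i in seq_len(2000)) {
    out <- apply_windowing(probe, jitter_fraction = 0.05)
    # invert the linear ramp from two interior samples
    wj <- (0.52 - 0.48) / (out[2] - out[1])
    cj <- 0.48 - (out[1] - 0.5) * wj
    centers[i] <- cj; widths[i] <- wj
  }
  expect_true(all(abs(centers / 0.5 - 1) <= 0.05 + 1e-9))
  expect_true(all(abs(widths / 0.5 - 1) <= 0.05 + 1e-9))
  # uniform on +/-5%: mean ~ 0, sd ~ 0.05/sqrt(3)
  u <- centers / 0.5 - 1
  expect_lt(abs(mean(u)), 0.002)
  expect_lt(abs(sd(u) - 0.05 / sqrt(3)), 0.003)
})

test_that("windowing is monotone non-decreasing for any jittered window", {
  set.seed(4)
  px <- matrix(sort(runif(100)), 10, 10)
  img <- mammogram(px, windows = list(c(center = 0.4, width = 0.3)))
  for (i in 1:10) {
    out <- apply_windowing(img, jitter_fraction = 0.05)
    expect_true(all(diff(as.vector(out)) >= 0))
  }
})

test_that("chest-wall orientation flips right images and is idempotent", {
  set.seed(5)
  ph <- generate_phantom(tiny_phantom_config())
  img <- ph$processed
  o1 <- orient_chest_wall_left(img, ph$truth)
  expect_equal(o1$flipped, img$laterality == "R")
  o2 <- orient_chest_wall_left(o1$image, o1$mask)
  expect_false(o2$flipped)
  expect_identical(o2$image$pixels, o1$image$pixels)
  expect_identical(o2$mask$labels, o1$mask$labels)
})

test_that("chest side inference from content matches phantom truth", {
  set.seed(6)
  ok <- 0
  for (i in 1:100) {
    ph <- generate_phantom(tiny_phantom_config())
    img <- ph$processed
    true_right <- img$laterality == "R"
    img$laterality <- NA
    o <- orient_chest_wall_left(img)
    if (o$flipped == true_right) ok <- ok + 1
  }
  expect_gte(ok, 99)
})
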