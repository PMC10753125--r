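test_that("per-class dice matches set counting on random grids", {
  set.seed(60)
  for (i in 1:100) {
    pred <- random_labels(16, 16)
    truth <- random_labels(16, 16)
    for (k in 0:2) {
      got <- dice_per_class(pred, truth, k)
      want <- oracle_dice(pred, truth, k)
      if (is.na(want)) expect_true(is.na(got))
      else expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("dice handles identity, disjoint and undefined cases", {
  m <- random_labels(10, 10)
  m[1, 1] <- 1L; m[1, 2] <- 2L
  expect_equal(dice_per_class(m, m, 1), 1)
  expect_equal(dice_per_class(m, m, 2), 1)
  a <- matrix(0L, 5, 5); a[1:2, 1] <- 1L
  b <- matrix(0L, 5, 5); b[4:5, 5] <- 1L
  expect_equal(dice_per_class(a, b, 1), 0)
  none <- matrix(0L, 5, 5)
  expect_true(is.na(dice_per_class(a, none, 1)))  # truth lacks the class
  # symmetry when both grids contain the class
  set.seed(61)
  p <- random_labels(12, 12); q <- random_labels(12, 12)
  expect_equal(dice_per_class(p, q, 1), dice_per_class(q, p, 1))
})

test_that("overall dice is the truth-pixel-weighted combination", {
  # breast 900 px at dice 0.9, pectoral 100 px at dice 0.5 -> 0.86
  truth <- matrix(0L, 40, 40)
  truth[1:30, 1:30] <- 1L           # 900 breast pixels
  truth[31:40, 31:40] <- 2L         # 100 pectoral pixels
  pred <- matrix(0L, 40, 40)
  # breast: overlap 810 of 900+900 -> padding with 90 extra outside
  pred[1:27, 1:30] <- 1L            # 810 in truth
  pred[31:33, 1:30] <- 1L           # 90 outside truth
  # pectoral: overlap 50, pred 100
  pred[31:35, 31:40] <- 2L          # 50 inside
  pred[36:40, 1:10] <- 2L           # 50 outside
  expect_equal(dice_per_class(pred, truth, 1), 0.9)
  expect_equal(dice_per_class(pred, truth, 2), 0.5)
  expect_equal(overall_dice(pred, truth), 0.86)
  # no pectoral in truth -> equals breast dice
  t2 <- truth; t2[t2 == 2L] <- 0L
  expect_equal(overall_dice(pred, t2), dice_per_class(pred, t2, 1))
  expect_equal(overall_dice(truth, truth), 1)
  expect_error(overall_dice(pred, matrix(0L, 40, 40)), "no breast")
})

test_that("overall dice lies between the contributing class dices", {
  set.seed(62)
  for (i in 1:20) {
    truth <- random_labels(12, 12)
    pred <- random_labels(12, 12)
    if (sum(truth == 1) == 0 || sum(truth == 2) == 0) next
    d1 <- dice_per_class(pred, truth, 1)
    d2 <- dice_per_class(pred, truth, 2)
    ov <- overall_dice(pred, truth)
    expect_gte(ov, min(d1, d2) - 1e-12)
    expect_lte(ov, max(d1, d2) + 1e-12)
  }
})

test_that("pectoral detection implements the any-pixel FP/FN rules", {
  none <- matrix(0L, 20, 20); none[1:10, 1:10] <- 1L  # breast only
  with_p <- none; with_p[1:3, 1:3] <- 2L
  expect_equal(pectoral_detection(none, none)$outcome, "TN")
  expect_equal(pectoral_detection(with_p, with_p)$outcome, "TP")
  expect_equal(pectoral_detection(none, with_p)$outcome, "FN")
  one_px <- none; one_px[5, 5] <- 2L
  det <- pectoral_detection(one_px, none)
  expect_equal(det$outcome, "FP")    # any single pixel counts
  # 5 predicted pectoral px on a 1000-px breast: FP but below 1%
  big <- matrix(0L, 40, 40); big[1:25, 1:40] <- 1L
  pred <- big; pred[1, 1:5] <- 2L
  det2 <- pectoral_detection(pred, big)
  expect_equal(det2$outcome, "FP")
  expect_equal(det2$fp_breast_fraction, 5 / 1000)
  expect_false(det2$fp_large)
  pred[1:2, 1:10] <- 2L              # 20/1000 > 1%
  expect_true(pectoral_detection(pred, big)$fp_large)
})

test_that("detection outcomes partition every image", {
  set.seed(63)
  for (i in 1:50) {
    pred <- random_labels(8, 8)
    truth <- random_labels(8, 8)
    out <- pectoral_detection(pred, truth)$outcome
    expect_true(out %in% c("TP", "FP", "FN", "TN"))
  }
})

test_that("dataset evaluation stratifies and summarizes correctly", {
  set.seed(64)
  m <- build_unet(unet_config(depth = 1, base_filters = 2))
  cfg <- tiny_phantom_config(48)
  recs <- lapply(1:6, function(i) {
    ph <- generate_phantom(cfg)
    o <- orient_chest_wall_left(ph$processed, ph$truth)
    list(image = o$image, truth = o$mask)
  })
  rep <- evaluate_dataset(m, recs, strata = "view")
  expect_s3_class(rep, "evaluation_report")
  expect_equal(nrow(rep$per_image), 6)
  # stratum rows partition the dataset
  strata_n <- rep$summary$n[rep$summary$stratum != "all"]
  expect_equal(sum(strata_n), 6)
  expect_equal(sum(rep$detection$n), 6)
  # summaries are recomputable from the per-image rows
  all_row <- rep$summary[rep$summary$stratum == "all", ]
  expect_equal(all_row$overall_dice_mean, mean(rep$per_image$overall_dice))
  expect_equal(all_row$overall_dice_sd, sd(rep$per_image$overall_dice))
})

test_that("two scored images give the expected mean and sample sd", {
  truth <- matrix(0L, 10, 10); truth[1:5, 1:5] <- 1L
  perfect <- truth
  off <- truth; off[1, ] <- 0L  # dice < 1
  d <- dice_per_class(off, truth, 1)
  scores <- c(d, 1)
  expect_equal(mean(scores), (d + 1) / 2)
  expect_equal(sd(scores), sqrt(sum((scores - mean(scores))^2) / 1))
})

test_that("t-test wrapper agrees with the closed-form Student computation", {
  set.seed(65)
  a <- rnorm(50, 0, 1); b <- rnorm(50, 2, 1)  # 2-sigma shift
  got <- compare_groups(a, b, "unpaired_t", alpha = 0.05)
  # independent closed form: pooled-variance two-sample t
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  pval <- 2 * pt(-abs(tstat), n1 + n2 - 2)
  expect_equal(got$statistic, tstat, tolerance = 1e-6)
  expect_equal(got$p_value, pval, tolerance = 1e-6)
  expect_true(got$significant)
  # paired closed form
  gp <- compare_groups(a, b, "paired_t")
  dd <- a - b
  tp <- mean(dd) / (sd(dd) / sqrt(n1))
  expect_equal(gp$statistic, tp, tolerance = 1e-6)
  expect_equal(gp$p_value, 2 * pt(-abs(tp), n1 - 1), tolerance = 1e-6)
})

test_that("a group against itself is a null paired comparison", {
  a <- c(0.9, 0.95, 0.92, 0.97)
  got <- compare_groups(a, a, "paired_t")
  expect_equal(got$statistic, 0)
  expect_false(got$significant)
  expect_error(compare_groups(a, a[1:3], "paired_t"), "equal lengths")
  expect_error(compare_groups(a[1], a, "unpaired_t"), "n >= 2")
})

test_that("the Bonferroni threshold is the level over the comparison count", {
  got <- compare_groups(rnorm(5), rnorm(5), alpha = 0.05, n_comparisons = 8)
  expect_equal(got$threshold, 0.00625)
})

test_that("ANOVA and Tukey agree with closed-form references", {
  set.seed(66)
  g <- list(a = rnorm(20, 0), b = rnorm(20, 0), c = rnorm(20, 3))
  got <- anova_tukey(g)
  # closed-form one-way ANOVA
  all_v <- unlist(g); k <- 3; n <- 20
  grand <- mean(all_v)
  ssb <- n * sum((vapply(g, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (k * n - k))
  expect_equal(got$f_statistic, f, tolerance = 1e-6)
  expect_equal(got$p_value, pf(f, k - 1, k * n - k, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_true(got$significant)
  # Tukey adjusted p from the studentized range distribution
  mse <- ssw / (k * n - k)
  qstat <- abs(mean(g$a) - mean(g$c)) / sqrt(mse / n)
  p_ac <- ptukey(qstat, k, k * n - k, lower.tail = FALSE)
  row <- got$tukey[got$tukey$pair == "c-a", ]
  expect_equal(row$p_adj, p_ac, tolerance = 1e-6)
  expect_true(row$significant)
  expect_equal(nrow(got$tukey), k * (k - 1) / 2)
})

test_that("identical groups give a null ANOVA with no significant pairs", {
  set.seed(67)
  base <- rnorm(15, 0.9, 0.02)
  got <- anova_tukey(list(x = base, y = base, z = base))
  expect_lt(abs(got$f_statistic), 1e-9)
  expect_false(got$significant)
  expect_false(any(got$tukey$significant))
  expect_error(anova_tukey(list(a = 1:5, b = 1:5)), "3 groups")
})
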