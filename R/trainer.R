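#' Patient-level train/validation/test split
#'
#' Whole patients are assigned greedily (in seeded random order) to the test
#' split until it holds at least `n_test` images, then to validation until
#' it holds at least `n_val` images; all remaining patients go to training.
#' No patient ever appears in two splits.
#'
#' @param manifest data.frame with at least `patient_id` (one row per
#'   image).
#' @param n_test minimum number of test images (default 100).
#' @param n_val minimum number of validation images (default 80).
#' @param seed optional RNG seed for the patient order.
#' @return the manifest with a `split` column (`"train"`, `"validation"`,
#'   `"test"`).
#' @export
split_patient_level <- function(manifest, n_test = 100, n_val = 80, seed = NULL) {
  if (!"patient_id" %in% names(manifest)) {
    stop("manifest needs a patient_id column", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  patients <- unique(manifest$patient_id)
  patients <- patients[sample.int(length(patients))]
  counts <- table(manifest$patient_id)[as.character(patients)]
  assignment <- character(length(patients))
  test_n <- 0; val_n <- 0
  for (i in seq_along(patients)) {
    if (test_n < n_test) {
      assignment[i] <- "test"; test_n <- test_n + counts[i]
    } else if (val_n < n_val) {
      assignment[i] <- "validation"; val_n <- val_n + counts[i]
    } else {
      assignment[i] <- "train"
    }
  }
  if (test_n < n_test || val_n < n_val || !any(assignment == "train")) {
    stop(sprintf(
      "dataset too small for the requested split (test %d/%d, val %d/%d)",
      test_n, n_test, val_n, n_val), call. = FALSE)
  }
  manifest$split <- assignment[match(manifest$patient_id, patients)]
  manifest
}

#' Training configuration
#'
#' @param loss [loss_config()].
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size images per gradient step (default 8).
#' @param max_epochs epoch budget (default 200).
#' @param patience early-stopping patience: training stops when the
#'   validation loss has not strictly improved its running best for this
#'   many consecutive epochs (default 10).
#' @param seed optional RNG seed for shuffling, augmentation and dropout.
#' @param include_raw add raw images as independent training samples
#'   carrying the same mask as their processed counterpart (default
#'   `FALSE`).
#' @param policy [augmentation_policy()] applied to every training sample.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(loss = loss_config(), lr = 1e-4, batch_size = 8,
                         max_epochs = 200, patience = 10, seed = NULL,
                         include_raw = FALSE, policy = augmentation_policy()) {
  stopifnot(inherits(loss, "loss_config"), lr > 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1,
            inherits(policy, "augmentation_policy"))
  structure(list(loss = loss, lr = lr, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience, seed = seed,
                 include_raw = include_raw, policy = policy),
            class = "train_config")
}

#' Replay the early-stopping rule on a validation-loss trace
#'
#' "Improve" means a strict decrease of the running best validation loss;
#' training stops after `patience` consecutive epochs without improvement
#' (or at the end of the trace).
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience consecutive non-improving epochs tolerated.
#' @return list with `stop_epoch` (last epoch run) and `best_epoch`.
#' @export
early_stopping_trace <- function(val_losses, patience = 10) {
  best <- Inf; best_epoch <- 0L; counter <- 0L
  stop_epoch <- length(val_losses)
  for (i in seq_along(val_losses)) {
    if (val_losses[i] < best) {
      best <- val_losses[i]; best_epoch <- i; counter <- 0L
    } else {
      counter <- counter + 1L
    }
    if (counter >= patience) { stop_epoch <- i; break }
  }
  list(stop_epoch = stop_epoch, best_epoch = best_epoch)
}

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$gW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$gb
    s$vb <- beta2 * s$vb + (1 - beta2) * g$gb^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

## deterministic validation pass: metadata window, no augmentation
validate_model <- function(model, val_set, loss) {
  losses <- numeric(length(val_set))
  scores <- vector("list", length(val_set))
  for (i in seq_along(val_set)) {
    x <- net_input(val_set[[i]]$image)
    probs <- predict_probabilities(model, x)
    losses[i] <- segmentation_loss(probs, val_set[[i]]$mask, loss)
    pred <- label_grid(argmax_labels(probs))
    scores[[i]] <- score_image(pred, val_set[[i]]$mask)
  }
  sc <- do.call(rbind, scores)
  list(loss = mean(losses),
       breast_dice = mean(sc$breast_dice, na.rm = TRUE),
       pectoral_dice = if (any(!is.na(sc$pectoral_dice)))
         mean(sc$pectoral_dice, na.rm = TRUE) else NA_real_,
       overall_dice = mean(sc$overall_dice, na.rm = TRUE))
}

#' Train a segmentation model with early stopping
#'
#' Runs augmented epochs over the training set with Adam, evaluates the
#' validation loss (metadata window, no augmentation) after each epoch, and
#' stops once the validation loss has not strictly improved for
#' `config$patience` consecutive epochs or the epoch budget is exhausted.
#' The returned model carries the weights of the best-validation epoch.
#'
#' @param model freshly built [build_unet()] model.
#' @param train_set,val_set lists of records with elements `image`
#'   ([mammogram()]) and `mask` ([label_grid()]).
#' @param config [train_config()].
#' @return list with `model`, `history` (per-epoch data.frame) and
#'   `best_epoch`.
#' @export
train_model <- function(model, train_set, val_set, config) {
  stopifnot(length(train_set) > 0, length(val_set) > 0,
            inherits(config, "train_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- adam_init(model$params)
  step <- 0
  best_loss <- Inf; best_params <- model$params; best_epoch <- 0L
  counter <- 0L
  history <- NULL
  for (epoch in seq_len(config$max_epochs)) {
    order <- sample.int(length(train_set))
    epoch_losses <- numeric(0)
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    for (batch in batches) {
      acc <- NULL
      bl <- 0
      for (i in batch) {
        aug <- augment_sample(train_set[[i]]$image, train_set[[i]]$mask,
                              config$policy)
        lg <- unet_loss_grad(model, aug$image, aug$mask, config$loss,
                             training = TRUE)
        if (!is.finite(lg$loss)) {
          stop(sprintf("non-finite training loss at epoch %d", epoch),
               call. = FALSE)
        }
        bl <- bl + lg$loss
        if (is.null(acc)) {
          acc <- lg$grads
        } else {
          for (nm in names(acc)) {
            acc[[nm]]$gW <- acc[[nm]]$gW + lg$grads[[nm]]$gW
            acc[[nm]]$gb <- acc[[nm]]$gb + lg$grads[[nm]]$gb
          }
        }
      }
      nb <- length(batch)
      if (nb > 1) {
        for (nm in names(acc)) {
          acc[[nm]]$gW <- acc[[nm]]$gW / nb
          acc[[nm]]$gb <- acc[[nm]]$gb / nb
        }
      }
      step <- step + 1
      upd <- adam_step(model$params, acc, state, config$lr, step)
      model$params <- upd$params
      state <- upd$state
      epoch_losses <- c(epoch_losses, bl / nb)
    }
    val <- validate_model(model, val_set, config$loss)
    if (!is.finite(val$loss)) {
      stop(sprintf("non-finite validation loss at epoch %d", epoch),
           call. = FALSE)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(epoch_losses), val_loss = val$loss,
      val_breast_dice = val$breast_dice, val_pectoral_dice = val$pectoral_dice,
      val_overall_dice = val$overall_dice))
    if (val$loss < best_loss) {
      best_loss <- val$loss; best_params <- model$params
      best_epoch <- epoch; counter <- 0L
    } else {
      counter <- counter + 1L
    }
    if (counter >= config$patience) break
  }
  model$params <- best_params
  list(model = model, history = history, best_epoch = best_epoch)
}

## validation dice per candidate, pectoral restricted to images whose truth
## contains the class
grid_candidate_score <- function(model, val_set) {
  sc <- do.call(rbind, lapply(val_set, function(rec) {
    pred <- predict_labels(model, net_input(rec$image))
    score_image(pred, rec$mask)
  }))
  list(pectoral_dice = if (any(!is.na(sc$pectoral_dice)))
         mean(sc$pectoral_dice, na.rm = TRUE) else NA_real_,
       overall_dice = mean(sc$overall_dice, na.rm = TRUE),
       breast_dice = mean(sc$breast_dice, na.rm = TRUE))
}

#' Pick the winning candidate from a grid-search table
#'
#' Winner is the maximal mean validation pectoral dice; ties go to the
#' higher overall dice, then to the lower `alpha_pectoral`.
#' @param table data.frame with columns `loss_type`, `alpha_pectoral`,
#'   `val_pectoral_dice`, `val_overall_dice`.
#' @return row index of the winner.
#' @export
select_grid_winner <- function(table) {
  pect <- ifelse(is.na(table$val_pectoral_dice), -Inf, table$val_pectoral_dice)
  ov <- ifelse(is.na(table$val_overall_dice), -Inf, table$val_overall_dice)
  order(-pect, -ov, table$alpha_pectoral)[1]
}

#' Grid search over loss type and pectoral class weight
#'
#' Trains one model per `(loss, alpha_pectoral)` candidate and selects the
#' configuration with the highest mean validation pectoral dice (computed
#' only on validation images whose truth contains the pectoral class); ties
#' break toward higher overall dice, then lower alpha. Candidates share the
#' same seed so they see identical shuffling and augmentation streams.
#'
#' @inheritParams train_model
#' @param unet_cfg [unet_config()] used to build each candidate's model.
#' @param losses character vector of loss types.
#' @param alphas numeric vector of `alpha_pectoral` candidates.
#' @return list of class `"selected_config"` with `loss_type`,
#'   `alpha_pectoral`, `table` (per-candidate validation dice) and `model`
#'   (the winning trained model).
#' @export
grid_search <- function(train_set, val_set, unet_cfg, config,
                        losses = c("cross_entropy", "focal"),
                        alphas = c(1, 1.5, 2, 2.5)) {
  if (length(losses) < 1 || length(alphas) < 1) {
    stop("need at least one candidate", call. = FALSE)
  }
  grid <- expand.grid(loss_type = losses, alpha_pectoral = alphas,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  models <- vector("list", nrow(grid))
  failures <- 0
  for (i in seq_len(nrow(grid))) {
    cand_cfg <- config
    cand_cfg$loss <- loss_config(grid$loss_type[i],
                                 alpha_pectoral = grid$alpha_pectoral[i],
                                 gamma = config$loss$gamma)
    if (!is.null(config$seed)) set.seed(config$seed)
    fit <- tryCatch(
      train_model(build_unet(unet_cfg), train_set, val_set, cand_cfg),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- failures + 1
      rows[[i]] <- data.frame(loss_type = grid$loss_type[i],
                              alpha_pectoral = grid$alpha_pectoral[i],
                              val_pectoral_dice = NA_real_,
                              val_overall_dice = NA_real_,
                              val_breast_dice = NA_real_,
                              error = conditionMessage(fit))
      next
    }
    sc <- grid_candidate_score(fit$model, val_set)
    models[[i]] <- fit$model
    rows[[i]] <- data.frame(loss_type = grid$loss_type[i],
                            alpha_pectoral = grid$alpha_pectoral[i],
                            val_pectoral_dice = sc$pectoral_dice,
                            val_overall_dice = sc$overall_dice,
                            val_breast_dice = sc$breast_dice,
                            error = NA_character_)
  }
  if (failures == nrow(grid)) {
    stop("all grid candidates failed to train", call. = FALSE)
  }
  table <- do.call(rbind, rows)
  win <- select_grid_winner(table)
  structure(list(loss_type = table$loss_type[win],
                 alpha_pectoral = table$alpha_pectoral[win],
                 table = table, model = models[[win]]),
            class = "selected_config")
}

#' @export
print.selected_config <- function(x, ...) {
  cat(sprintf("<selected_config> loss=%s, alpha_pectoral=%g\n",
              x$loss_type, x$alpha_pectoral))
  print(x$table[, c("loss_type", "alpha_pectoral", "val_pectoral_dice",
                    "val_overall_dice")], row.names = FALSE)
  invisible(x)
}

## phantom samples -> trainer/evaluate records, chest wall oriented left
phantom_records <- function(samples, kind = c("processed", "raw")) {
  kind <- match.arg(kind)
  lapply(samples, function(s) {
    img <- if (kind == "raw") s$raw else s$processed
    o <- orient_chest_wall_left(img, s$truth)
    list(image = o$image, mask = o$mask, truth = o$mask)
  })
}

#' Raw-image inclusion experiment
#'
#' Trains two models on phantom data: one on processed renderings only, one
#' additionally including the raw renderings as independent samples carrying
#' the same masks. Both are evaluated on the processed and raw test images
#' and compared per image with paired t-tests.
#'
#' @param train,val,test lists of phantom samples (see
#'   [generate_phantom()]), each holding paired `raw`/`processed` images and
#'   one `truth` mask.
#' @param unet_cfg [unet_config()].
#' @param config [train_config()]; `include_raw` is managed internally.
#' @return list with per-model mean dice on processed and raw test images,
#'   per-image scores, and paired-test results.
#' @export
run_raw_inclusion <- function(train, val, test, unet_cfg, config) {
  tr_proc <- phantom_records(train, "processed")
  va_proc <- phantom_records(val, "processed")
  te_proc <- phantom_records(test, "processed")
  te_raw <- phantom_records(test, "raw")
  if (!is.null(config$seed)) set.seed(config$seed)
  fit_proc <- train_model(build_unet(unet_cfg), tr_proc, va_proc, config)
  tr_both <- c(tr_proc, phantom_records(train, "raw"))
  va_both <- c(va_proc, phantom_records(val, "raw"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fit_both <- train_model(build_unet(unet_cfg), tr_both, va_both, config)
  dice_on <- function(model, records) {
    vapply(records, function(rec) {
      overall_dice(predict_labels(model, net_input(rec$image)), rec$mask)
    }, numeric(1))
  }
  proc_only_raw <- dice_on(fit_proc$model, te_raw)
  proc_only_proc <- dice_on(fit_proc$model, te_proc)
  both_raw <- dice_on(fit_both$model, te_raw)
  both_proc <- dice_on(fit_both$model, te_proc)
  list(
    processed_only = list(model = fit_proc$model,
                          raw_dice = mean(proc_only_raw),
                          processed_dice = mean(proc_only_proc)),
    with_raw = list(model = fit_both$model,
                    raw_dice = mean(both_raw),
                    processed_dice = mean(both_proc)),
    raw_gain = mean(both_raw) - mean(proc_only_raw),
    processed_change = mean(both_proc) - mean(proc_only_proc),
    raw_test = compare_groups(both_raw, proc_only_raw, "paired_t"),
    processed_test = compare_groups(both_proc, proc_only_proc, "paired_t"),
    scores = data.frame(proc_only_raw = proc_only_raw,
                        proc_only_proc = proc_only_proc,
                        both_raw = both_raw, both_proc = both_proc))
}

#' Leave-one-style-out generalization experiment
#'
#' For each vendor style, trains on the training images of all other styles
#' and evaluates on (1) the held-out style's train+test images and (2) the
#' included styles' test images. Mean overall dice differences are compared
#' with unpaired t-tests at a Bonferroni-adjusted level `alpha / k` for `k`
#' styles.
#'
#' @param style_sets named list; each element holds `train`, `val` and
#'   `test` lists of records (`image` + `mask`).
#' @param unet_cfg [unet_config()].
#' @param config [train_config()].
#' @param alpha family significance level (default 0.05).
#' @param holdouts style names to actually hold out (default: all). The
#'   Bonferroni threshold always uses the full style count `k`.
#' @return list with `results` (one row per held-out style) and `threshold`
#'   (`alpha / k`).
#' @export
run_leave_one_out <- function(style_sets, unet_cfg, config, alpha = 0.05,
                              holdouts = names(style_sets)) {
  k <- length(style_sets)
  if (k < 2) stop("need at least two styles", call. = FALSE)
  threshold <- alpha / k
  dice_on <- function(model, records) {
    vapply(records, function(rec) {
      overall_dice(predict_labels(model, net_input(rec$image)), rec$mask)
    }, numeric(1))
  }
  idx <- match(holdouts, names(style_sets))
  if (anyNA(idx)) stop("unknown holdout style", call. = FALSE)
  rows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    held <- style_sets[[i]]
    others <- style_sets[-i]
    tr <- do.call(c, lapply(others, `[[`, "train"))
    va <- do.call(c, lapply(others, `[[`, "val"))
    te_inc <- do.call(c, lapply(others, `[[`, "test"))
    te_held <- c(held$train, held$test)
    if (!is.null(config$seed)) set.seed(config$seed)
    fit <- train_model(build_unet(unet_cfg), tr, va, config)
    d_inc <- dice_on(fit$model, te_inc)
    d_held <- dice_on(fit$model, te_held)
    cmp <- compare_groups(d_held, d_inc, "unpaired_t", alpha = alpha,
                          n_comparisons = k)
    rows[[j]] <- data.frame(style = names(style_sets)[i],
                            n_included = length(d_inc),
                            dice_included = mean(d_inc),
                            n_heldout = length(d_held),
                            dice_heldout = mean(d_held),
                            diff = mean(d_held) - mean(d_inc),
                            p_value = cmp$p_value,
                            significant = cmp$significant,
                            stringsAsFactors = FALSE)
  }
  list(results = do.call(rbind, rows), threshold = threshold)
}
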