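#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)`
#' with a small smoothing constant `eps` so the empty-prediction /
#' empty-target case is 0 by convention. Always in \[0, 1\].
#'
#' @param pred score array in \[0, 1\].
#' @param target binary array of the same shape.
#' @param eps smoothing constant (default 1e-6).
#' @return Scalar loss.
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

#' Pixel-mean binary cross-entropy
#'
#' Scores are clipped to `[delta, 1 - delta]` for numerical safety.
#'
#' @param pred score array in \[0, 1\].
#' @param target binary array of the same shape.
#' @param delta clipping constant (default 1e-7).
#' @return Scalar loss.
#' @export
bce_loss <- function(pred, target, delta = 1e-7) {
  p <- pmin(pmax(pred, delta), 1 - delta)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Combined 6:1 BCE + Dice training loss
#'
#' The training objective: `w_bce * BCE + w_dice * Dice` with the 6:1
#' default weighting.
#'
#' @param pred,target as in [dice_loss()].
#' @param w_bce,w_dice loss weights (defaults 6 and 1).
#' @param eps,delta smoothing/clipping constants.
#' @return Scalar loss.
#' @export
combined_loss <- function(pred, target, w_bce = 6, w_dice = 1, eps = 1e-6,
                          delta = 1e-7) {
  w_bce * bce_loss(pred, target, delta) +
    w_dice * dice_loss(pred, target, eps)
}

# Gradient of the combined loss w.r.t. the prediction (same shape).
combined_loss_grad <- function(pred, target, w_bce = 6, w_dice = 1,
                               eps = 1e-6, delta = 1e-7) {
  p <- pmin(pmax(pred, delta), 1 - delta)
  d_bce <- (-(target / p) + (1 - target) / (1 - p)) / length(pred)
  num <- 2 * sum(pred * target) + eps
  den <- sum(pred) + sum(target) + eps
  d_dice <- -(2 * target * den - num) / den^2
  w_bce * d_bce + w_dice * d_dice
}

#' Paired random augmentation of an image and its label
#'
#' Applies the same random transform to both: horizontal flip (p = 0.5),
#' rotation within +/- `max_rotation_deg`, and translation within +/-
#' `max_translation_frac` of the image size. The image is resampled
#' bilinearly, the label with nearest neighbor so it stays binary.
#' Uses the current RNG state.
#'
#' @param image,label matrices of equal size.
#' @param max_rotation_deg rotation bound, degrees (default 10).
#' @param max_translation_frac translation bound as a fraction (default 0.05).
#' @return List with transformed `image` and `label`.
#' @export
augment <- function(image, label, max_rotation_deg = 10,
                    max_translation_frac = 0.05) {
  h <- nrow(image); w <- ncol(image)
  flip <- runif(1) < 0.5
  ang <- runif(1, -max_rotation_deg, max_rotation_deg) * pi / 180
  tr <- runif(2, -max_translation_frac, max_translation_frac) * c(h, w)
  if (flip) {
    image <- image[, rev(seq_len(w)), drop = FALSE]
    label <- label[, rev(seq_len(w)), drop = FALSE]
  }
  if (abs(ang) < 1e-12 && all(abs(tr) < 1e-12)) {
    return(list(image = image, label = label))
  }
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  g <- expand.grid(row = seq_len(h), col = seq_len(w))
  # inverse map: rotate about the center, then translate
  rr <- g$row - cr - tr[1]; cc2 <- g$col - cc - tr[2]
  sr <- cr + cos(ang) * rr + sin(ang) * cc2
  sc <- cc - sin(ang) * rr + cos(ang) * cc2
  img2 <- matrix(bilinear_at(image, sr, sc), h, w)
  ri <- round(sr); ci <- round(sc)
  inb <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
  lv <- numeric(length(ri))
  lv[inb] <- label[cbind(ri[inb], ci[inb])]
  list(image = img2, label = matrix(lv, h, w))
}

#' Training configuration
#'
#' @param w_bce,w_dice loss weights (6:1 default).
#' @param learning_rate,momentum SGD settings (defaults 0.01 and 0.9).
#' @param lr_poly_power polynomial decay exponent of
#'   `lr * (1 - it/max)^power`; 0 disables decay.
#' @param max_iterations mini-batch iteration budget (study default 100000).
#' @param patience_iterations stop when the validation metric has not
#'   improved for this many successive iterations (study default 20000).
#' @param validation_interval iterations between validation passes; must
#'   divide `patience_iterations`.
#' @param batch_size slices per mini-batch.
#' @param n_replicates independent training runs for aggregation (default 5).
#' @param augment_train apply random augmentation to training slices.
#' @param val_metric validation metric for early stopping: lesion-level F1
#'   on the validation split at `val_detection` settings.
#' @param val_detection a [detection_config()] used for the validation F1.
#' @param seed master seed.
#' @return A `dotapet_train_config` list.
#' @export
train_config <- function(w_bce = 6, w_dice = 1, learning_rate = 0.01,
                         momentum = 0.9, lr_poly_power = 0.9,
                         max_iterations = 100000L,
                         patience_iterations = 20000L,
                         validation_interval = 2000L,
                         batch_size = 4L, n_replicates = 5L,
                         augment_train = TRUE,
                         val_metric = "lesion_f1",
                         val_detection = detection_config(
                           binarize_threshold = 0.05, area_filter_px = 5L),
                         seed = 1L) {
  stopifnot(w_bce > 0, w_dice >= 0, learning_rate > 0,
            patience_iterations < max_iterations,
            patience_iterations %% validation_interval == 0,
            batch_size >= 1, n_replicates >= 1)
  structure(
    list(w_bce = w_bce, w_dice = w_dice, learning_rate = learning_rate,
         momentum = momentum, lr_poly_power = lr_poly_power,
         max_iterations = as.integer(max_iterations),
         patience_iterations = as.integer(patience_iterations),
         validation_interval = as.integer(validation_interval),
         batch_size = as.integer(batch_size),
         n_replicates = as.integer(n_replicates),
         augment_train = isTRUE(augment_train),
         val_metric = val_metric, val_detection = val_detection,
         seed = as.integer(seed)),
    class = "dotapet_train_config"
  )
}

# Flatten the studies of a dataset split into per-slice training samples
# (liver-masked, per-study max-normalized images + binary labels).
slice_samples <- function(studies) {
  xs <- list(); ys <- list()
  for (s in studies) {
    norm <- normalize_stack(s$pet, s$liver)
    lab <- s$lesions > 0
    for (z in seq_len(dim(s$pet)[1])) {
      xs[[length(xs) + 1L]] <- norm$x[z, , ]
      ys[[length(ys) + 1L]] <- lab[z, , ] * 1
    }
  }
  list(x = xs, y = ys)
}

# Validation lesion-level F1 at the configured detection settings.
validation_f1 <- function(model, val_studies, config) {
  preds <- lapply(val_studies, function(s) predict_study(model, s))
  golds <- lapply(val_studies, function(s) s$lesions)
  evaluate_detections(preds, golds, config$val_detection)$f1
}

#' Train one model by SGD on the combined loss
#'
#' Mini-batches of (optionally augmented) liver-masked slices are drawn
#' uniformly from the training split; the network is updated by momentum
#' SGD with polynomial learning-rate decay. Every `validation_interval`
#' iterations the lesion-level validation F1 is computed; training stops at
#' the iteration budget or once the metric has not improved for
#' `patience_iterations` successive iterations, and the best-validation
#' weights are restored.
#'
#' @param train_studies,val_studies lists of `dotapet_study` objects.
#' @param model_config a [model_config()].
#' @param config a [train_config()].
#' @param seed integer seed for initialization, batching and augmentation.
#' @param val_metric_fn optional override: `function(model, iteration)`
#'   returning the validation metric (used for contract tests / custom
#'   schedules).
#' @param verbose print progress lines.
#' @return List: `model` (best-validation weights) and `history`, a
#'   `dotapet_train_history` tibble-backed record with per-interval
#'   training loss, validation metric, the best marker, and the stop
#'   reason (`"budget"` or `"patience"`).
#' @export
train_model <- function(train_studies, val_studies,
                        model_config = dotapet::model_config(),
                        config = train_config(), seed = 1L,
                        val_metric_fn = NULL, verbose = FALSE) {
  if (!length(train_studies)) stop("empty training split")
  if (!length(val_studies) && is.null(val_metric_fn)) {
    stop("empty validation split")
  }
  samples <- slice_samples(train_studies)
  n <- length(samples$x)
  model <- build_model(model_config, seed = seed)
  vel <- tree_zero(model$params)
  metric_fn <- val_metric_fn %||%
    function(m, it) validation_f1(m, val_studies, config)

  best_metric <- -Inf
  best_it <- 0L
  best_params <- model$params
  best_state <- model$bn_state
  hist_rows <- list()
  stop_reason <- "budget"
  loss_acc <- 0; loss_n <- 0L
  stopped_at <- config$max_iterations

  with_seed(seed + 1L, {
    for (it in seq_len(config$max_iterations)) {
      idx <- sample.int(n, config$batch_size, replace = n < config$batch_size)
      hh <- nrow(samples$x[[1]]); ww <- ncol(samples$x[[1]])
      xb <- array(0, c(hh, ww, 1, length(idx)))
      yb <- array(0, c(hh, ww, 1, length(idx)))
      for (k in seq_along(idx)) {
        xi <- samples$x[[idx[k]]]; yi <- samples$y[[idx[k]]]
        if (config$augment_train) {
          au <- augment(xi, yi)
          xi <- au$image; yi <- au$label
        }
        xb[, , 1, k] <- xi
        yb[, , 1, k] <- yi
      }
      fw <- unet_forward(model, xb, training = TRUE)
      model$bn_state <- fw$bn_state
      loss <- combined_loss(fw$scores, yb, config$w_bce, config$w_dice)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at iteration %d", it))
      }
      loss_acc <- loss_acc + loss; loss_n <- loss_n + 1L
      dp <- combined_loss_grad(fw$scores, yb, config$w_bce, config$w_dice)
      dz <- dp * fw$scores * (1 - fw$scores)
      grads <- unet_backward(model, fw$cache, dz)
      lr <- config$learning_rate *
        (1 - (it - 1) / config$max_iterations)^config$lr_poly_power
      vel <- tree_map2(function(v, g) config$momentum * v - lr * g, vel, grads)
      model$params <- tree_add(model$params, vel)

      if (it %% config$validation_interval == 0L) {
        vm <- metric_fn(model, it)
        improved <- vm > best_metric
        if (improved) {
          best_metric <- vm
          best_it <- it
          best_params <- model$params
          best_state <- model$bn_state
        }
        hist_rows[[length(hist_rows) + 1L]] <- tibble::tibble(
          iteration = it, train_loss = loss_acc / max(1L, loss_n),
          val_metric = vm, best = improved
        )
        if (verbose) {
          message(sprintf("it %d: loss %.4f, val %.4f%s", it,
                          loss_acc / max(1L, loss_n), vm,
                          if (improved) " *" else ""))
        }
        loss_acc <- 0; loss_n <- 0L
        if (it - best_it >= config$patience_iterations) {
          stop_reason <- "patience"
          stopped_at <- it
          break
        }
      }
    }
  })
  model$params <- best_params
  model$bn_state <- best_state
  history <- structure(
    list(
      intervals = if (length(hist_rows)) dplyr::bind_rows(hist_rows) else
        tibble::tibble(iteration = integer(), train_loss = numeric(),
                       val_metric = numeric(), best = logical()),
      best_iteration = best_it,
      best_metric = best_metric,
      stopped_at = stopped_at,
      stop_reason = stop_reason,
      seed = as.integer(seed)
    ),
    class = "dotapet_train_history"
  )
  list(model = model, history = history)
}

#' @export
print.dotapet_train_history <- function(x, ...) {
  cat(sprintf(
    "<dotapet_train_history> stopped at %d (%s); best val %.4f at %d\n",
    x$stopped_at, x$stop_reason, x$best_metric, x$best_iteration
  ))
  invisible(x)
}

#' @export
tidy.dotapet_train_history <- function(x, ...) x$intervals

#' @export
glance.dotapet_train_history <- function(x, ...) {
  tibble::tibble(best_iteration = x$best_iteration,
                 best_metric = x$best_metric,
                 stopped_at = x$stopped_at,
                 stop_reason = x$stop_reason,
                 seed = x$seed)
}

#' Train replicate models
#'
#' Runs [train_model()] `n_replicates` times with distinct seeds derived
#' deterministically from the master seed, for downstream mean +/- SD
#' aggregation across runs.
#'
#' @inheritParams train_model
#' @return List of `list(model, history, seed)` entries.
#' @export
train_replicates <- function(train_studies, val_studies,
                             model_config = dotapet::model_config(),
                             config = train_config(), verbose = FALSE) {
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max - 1L,
                                config$n_replicates))
  lapply(seq_len(config$n_replicates), function(i) {
    fit <- train_model(train_studies, val_studies, model_config, config,
                       seed = seeds[i], verbose = verbose)
    fit$seed <- seeds[i]
    fit
  })
}
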