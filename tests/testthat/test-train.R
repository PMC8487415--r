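test_that("dice loss matches hand-computed values", {
  t <- array(c(1, 0, 1, 0), c(2, 2, 1, 1))
  expect_lt(dice_loss(t, t), 1e-6)
  # uniform 0.5 prediction against all-ones target: 1 - N/(1.5N) = 1/3
  n <- 64
  pred <- array(0.5, c(8, 8, 1, 1))
  ones <- array(1, c(8, 8, 1, 1))
  expect_equal(dice_loss(pred, ones), 1 / 3, tolerance = 1e-6)
  # empty-empty is 0 by the smoothing convention
  z <- array(0, c(4, 4, 1, 1))
  expect_equal(dice_loss(z, z), 0)
})

test_that("combined loss equals the 6:1 weighted sum and vanishes at the optimum", {
  t <- array(rbinom(64, 1, 0.4), c(8, 8, 1, 1))
  expect_lt(combined_loss(t, t), 1e-5)
  pred <- array(0.5, c(8, 8, 1, 1))
  ones <- array(1, c(8, 8, 1, 1))
  expect_equal(combined_loss(pred, ones), 6 * log(2) + 1 / 3,
               tolerance = 1e-6)
  expect_gte(combined_loss(array(runif(64), c(8, 8, 1, 1)), t), 0)
})

test_that("the loss gradient agrees with central differences on a 4x4 map", {
  set.seed(31)
  pred <- array(runif(16, 0.05, 0.95), c(4, 4, 1, 1))
  tg <- array(rbinom(16, 1, 0.5), c(4, 4, 1, 1))
  g <- dotapet:::combined_loss_grad(pred, tg)
  eps <- 1e-6
  for (i in seq_len(16)) {
    p1 <- pred; p1[i] <- p1[i] + eps
    p2 <- pred; p2[i] <- p2[i] - eps
    fd <- (combined_loss(p1, tg) - combined_loss(p2, tg)) / (2 * eps)
    expect_lt(abs(g[i] - fd) / max(1e-8, abs(fd)), 1e-4)
  }
})

test_that("augmentation transforms image and label together", {
  set.seed(5)
  img <- matrix(runif(32 * 32), 32, 32)
  lab <- matrix(0, 32, 32)
  lab[10:14, 20:26] <- 1
  # identity transform: no rotation/translation and (seeded) no flip
  repeat {
    st <- .Random.seed
    if (runif(1) >= 0.5) { assign(".Random.seed", st, globalenv()); break }
  }
  out <- augment(img, lab, max_rotation_deg = 0, max_translation_frac = 0)
  expect_identical(out$image, img)
  expect_identical(out$label, lab)
  # a flip applies to both members of the pair
  repeat {
    st <- .Random.seed
    if (runif(1) < 0.5) { assign(".Random.seed", st, globalenv()); break }
  }
  out <- augment(img, lab, max_rotation_deg = 0, max_translation_frac = 0)
  expect_identical(out$image, img[, 32:1])
  expect_identical(out$label, lab[, 32:1])
  # labels stay binary under rotation/translation resampling
  set.seed(6)
  vals <- unlist(lapply(1:200, function(i) augment(img, lab)$label))
  expect_true(all(vals %in% c(0, 1)))
})

# Small training fixture: low-resolution studies so loops stay fast.
tiny_studies <- function(n, abnormal = TRUE, seed0 = 100) {
  spec <- phantom_spec(grid_shape = c(32L, 32L), pixel_spacing_mm = 8,
                       n_slices_range = c(8L, 10L),
                       lesion_count_mean = 2, lesion_count_sd = 1,
                       lesion_slice_span_range = c(2L, 5L),
                       lesion_radius_range_mm = c(10, 14),
                       liver_semi_axes_frac = c(0.4, 0.34))
  lapply(seq_len(n), function(i) {
    generate_study(spec, abnormal = abnormal, seed = seed0 + i)
  })
}

test_that("training reduces the loss and is reproducible", {
  tr <- tiny_studies(2)
  va <- tiny_studies(1, seed0 = 200)
  tc <- train_config(max_iterations = 120L, patience_iterations = 100L,
                     validation_interval = 20L, batch_size = 2L,
                     n_replicates = 1L)
  fit1 <- train_model(tr, va, model_config(base_channels = 4L), tc, seed = 3)
  fit2 <- train_model(tr, va, model_config(base_channels = 4L), tc, seed = 3)
  expect_identical(tidy(fit1$history), tidy(fit2$history))
  expect_identical(fit1$model$params, fit2$model$params)
  h <- tidy(fit1$history)
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  expect_true(fit1$history$stop_reason %in% c("budget", "patience"))
  expect_lte(fit1$history$stopped_at, tc$max_iterations)
})

test_that("early stopping halts exactly patience iterations after the best marker", {
  tr <- tiny_studies(1)
  tc <- train_config(max_iterations = 400L, patience_iterations = 60L,
                     validation_interval = 20L, batch_size = 1L,
                     n_replicates = 1L)
  # constant (never-improving) stubbed metric: best is the first evaluation
  fit <- train_model(tr, list(), model_config(base_channels = 2L), tc,
                     seed = 4, val_metric_fn = function(m, it) 0.5)
  expect_equal(fit$history$stop_reason, "patience")
  expect_equal(fit$history$best_iteration, 20L)
  expect_equal(fit$history$stopped_at, 20L + 60L)
  # improving stub never triggers patience within the budget
  fit2 <- train_model(tr, list(), model_config(base_channels = 2L),
                      train_config(max_iterations = 100L,
                                   patience_iterations = 60L,
                                   validation_interval = 20L,
                                   batch_size = 1L, n_replicates = 1L),
                      seed = 4, val_metric_fn = function(m, it) it)
  expect_equal(fit2$history$stop_reason, "budget")
  expect_equal(fit2$history$stopped_at, 100L)
  expect_equal(fit2$history$best_iteration, 100L)
})

test_that("the best-validation checkpoint is restored", {
  tr <- tiny_studies(1)
  snaps <- list()
  # metric peaks at iteration 40 then degrades
  fit <- train_model(tr, list(), model_config(base_channels = 2L),
                     train_config(max_iterations = 100L,
                                  patience_iterations = 80L,
                                  validation_interval = 20L,
                                  batch_size = 1L, n_replicates = 1L),
                     seed = 8,
                     val_metric_fn = function(m, it) {
                       snaps[[as.character(it)]] <<- m$params
                       if (it == 40L) 1 else 0.1
                     })
  expect_equal(fit$history$best_iteration, 40L)
  expect_identical(fit$model$params, snaps[["40"]])
})

test_that("replicates use distinct, deterministically derived seeds", {
  tr <- tiny_studies(1)
  va <- tiny_studies(1, seed0 = 300)
  tc <- train_config(max_iterations = 40L, patience_iterations = 20L,
                     validation_interval = 20L, batch_size = 1L,
                     n_replicates = 2L, seed = 11L)
  reps <- train_replicates(tr, va, model_config(base_channels = 2L), tc)
  expect_length(reps, 2)
  seeds <- vapply(reps, function(r) r$seed, numeric(1))
  expect_false(seeds[1] == seeds[2])
  reps2 <- train_replicates(tr, va, model_config(base_channels = 2L), tc)
  expect_identical(vapply(reps2, function(r) r$seed, numeric(1)), seeds)
  single <- train_replicates(tr, va, model_config(base_channels = 2L),
                             train_config(max_iterations = 40L,
                                          patience_iterations = 20L,
                                          validation_interval = 20L,
                                          batch_size = 1L,
                                          n_replicates = 1L, seed = 11L))
  expect_length(single, 1)
})
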