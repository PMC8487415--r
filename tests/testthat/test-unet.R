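test_that("the network is shape-preserving with scores in [0, 1]", {
  m <- build_model(model_config(base_channels = 4L), seed = 1)
  x <- array(runif(32 * 48), c(32, 48, 1, 1))
  fw <- dotapet:::unet_forward(m, x)
  expect_equal(dim(fw$scores), c(32, 48, 1, 1))
  expect_true(all(fw$scores >= 0 & fw$scores <= 1))
  # all-zero input still yields finite scores in range
  fw0 <- dotapet:::unet_forward(m, array(0, c(32, 32, 1, 2)))
  expect_true(all(is.finite(fw0$scores)))
  expect_true(all(fw0$scores >= 0 & fw0$scores <= 1))
})

test_that("the padding contract handles sizes not divisible by 16", {
  m <- build_model(model_config(base_channels = 4L), seed = 1)
  stack <- array(runif(3 * 24 * 40, 50, 150), c(3, 24, 40))
  liver <- array(TRUE, c(3, 24, 40))
  p <- predict_study(m, stack, liver)
  expect_equal(dim(p), c(3, 24, 40))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("parameter count matches the hand-enumerated layer table", {
  C <- 8L
  m <- build_model(model_config(base_channels = C), seed = 2)
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  bn_n <- function(c) 2 * c
  res_n <- function(cin, cout) {
    n <- conv_n(3, cin, cout) + bn_n(cout) + conv_n(3, cout, cout) + bn_n(cout)
    if (cin != cout) n <- n + conv_n(1, cin, cout)
    n
  }
  cbr_n <- function(cin, cout) conv_n(3, cin, cout) + bn_n(cout)
  tbr_n <- function(k, cin, cout) conv_n(k, cin, cout) + bn_n(cout)
  expected <-
    res_n(1, C) +
    cbr_n(C, 2 * C) + res_n(2 * C, 2 * C) +
    cbr_n(2 * C, 4 * C) + res_n(4 * C, 4 * C) +
    cbr_n(4 * C, 8 * C) + res_n(8 * C, 8 * C) +
    cbr_n(8 * C, 16 * C) +
    tbr_n(2, 16 * C, 8 * C) + res_n(8 * C, 8 * C) +
    tbr_n(2, 16 * C, 4 * C) + res_n(4 * C, 4 * C) +
    tbr_n(2, 8 * C, 2 * C) + res_n(2 * C, 2 * C) +
    tbr_n(2, 4 * C, C) + res_n(C, C) +
    tbr_n(4, 8 * C, C) + tbr_n(8, 16 * C, C) +
    conv_n(1, 4 * C, 1)
  expect_identical(n_parameters(m), as.integer(expected))
})

test_that("weight initialization and inference are deterministic", {
  a <- build_model(model_config(base_channels = 4L), seed = 9)
  b <- build_model(model_config(base_channels = 4L), seed = 9)
  expect_identical(a$params, b$params)
  c <- build_model(model_config(base_channels = 4L), seed = 10)
  expect_false(identical(a$params, c$params))

  x <- array(runif(32 * 32 * 3, 0, 1), c(3, 32, 32))
  liver <- array(TRUE, c(3, 32, 32))
  p1 <- predict_study(a, x, liver)
  p2 <- predict_study(a, x, liver)
  expect_identical(p1, p2)
})

test_that("slices are independent entities: permutation equivariance", {
  m <- build_model(model_config(base_channels = 4L), seed = 3)
  stack <- array(runif(4 * 32 * 32, 0, 200), c(4, 32, 32))
  liver <- array(TRUE, c(4, 32, 32))
  liver[, 1:4, ] <- FALSE
  p <- predict_study(m, stack, liver)
  perm <- c(3, 1, 4, 2)
  pp <- predict_study(m, stack[perm, , ], liver[perm, , ])
  expect_equal(pp, p[perm, , ], tolerance = 1e-12)
})

test_that("network gradients agree with finite differences", {
  m <- build_model(model_config(base_channels = 2L), seed = 5)
  set.seed(17)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  tg <- array(rbinom(16 * 16 * 2, 1, 0.2), c(16, 16, 1, 2))
  lossfn <- function(model) {
    fw <- dotapet:::unet_forward(model, x, training = TRUE)
    combined_loss(fw$scores, tg)
  }
  fw <- dotapet:::unet_forward(m, x, training = TRUE)
  dz <- dotapet:::combined_loss_grad(fw$scores, tg) * fw$scores *
    (1 - fw$scores)
  g <- dotapet:::unet_backward(m, fw$cache, dz)
  poke <- function(lst, pth, val) {
    if (length(pth) == 1) { lst[[pth]] <- val; lst }
    else { lst[[pth[1]]] <- poke(lst[[pth[1]]], pth[-1], val); lst }
  }
  sel <- function(lst, pth) Reduce(function(a, k) a[[k]], pth, lst)
  paths <- list(c("enc1", "c1", "w"), c("down2", "conv", "w"),
                c("up3", "conv", "w"), c("agg8", "conv", "w"),
                c("final", "w"), c("dec2", "n2", "g"), c("enc3", "n1", "b"))
  rel <- c()
  eps <- 1e-6
  for (path in paths) {
    arr <- sel(m$params, path)
    ga <- sel(g, path)
    for (i in sample(length(arr), 2)) {
      a2 <- arr; a2[i] <- a2[i] + eps
      mp <- m; mp$params <- poke(m$params, path, a2)
      a3 <- arr; a3[i] <- a3[i] - eps
      mm <- m; mm$params <- poke(m$params, path, a3)
      fd <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      rel <- c(rel, abs(ga[i] - fd) / max(1e-6, abs(fd)))
    }
  }
  # exact up to FD error away from ReLU kinks; allow a stray kink crossing
  expect_lt(median(rel), 1e-4)
  expect_lt(max(rel), 0.05)
})

test_that("the model has capacity to overfit a single slice", {
  set.seed(21)
  x <- matrix(runif(32 * 32, 0, 0.5), 32, 32)
  y <- matrix(0, 32, 32)
  y[10:16, 12:20] <- 1
  x[y == 1] <- 1
  xb <- array(x, c(32, 32, 1, 1))
  yb <- array(y, c(32, 32, 1, 1))
  m <- build_model(model_config(base_channels = 8L), seed = 2)
  vel <- dotapet:::tree_zero(m$params)
  loss <- Inf
  for (it in 1:500) {
    fw <- dotapet:::unet_forward(m, xb, training = TRUE)
    m$bn_state <- fw$bn_state
    loss <- combined_loss(fw$scores, yb)
    if (loss < 0.05) break
    dz <- dotapet:::combined_loss_grad(fw$scores, yb) * fw$scores *
      (1 - fw$scores)
    g <- dotapet:::unet_backward(m, fw$cache, dz)
    vel <- dotapet:::tree_map2(function(v, gr) 0.9 * v - 0.01 * gr, vel, g)
    m$params <- dotapet:::tree_add(m$params, vel)
  }
  expect_lt(loss, 0.05)
})
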