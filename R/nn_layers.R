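# Building blocks of the CPU CNN engine. Activations are 4D arrays
# (H, W, C, N); convolution kernels live in src/conv_ops.cpp. Every block
# has a forward returning (y, cache) and a backward returning (dx, grads),
# with gradients exact (finite-difference checked in the test suite).

relu_f <- function(x) {
  x[x < 0] <- 0
  x
}

# Batch-norm (+ ReLU) wrapper around the fused C++ kernels. `state` is the
# running-statistics list; the forward returns the updated state alongside
# the cache the backward needs.
bnr_f <- function(x, bn, state, training, relu = TRUE) {
  r <- .bnrelu_fwd(x, bn$g, bn$b, state$mean, state$var, training, 0.1,
                   1e-5, relu)
  list(y = r$y,
       cache = list(x = x, y = r$y, mu = r$mu, inv = r$inv, gamma = bn$g,
                    training = training, relu = relu),
       state = list(mean = r$mean, var = r$var))
}

bnr_b <- function(dy, cache) {
  r <- .bnrelu_bwd(dy, cache$x, cache$y, cache$gamma, cache$mu, cache$inv,
                   cache$training, cache$relu)
  list(dx = r$dx, dg = r$dg, db = r$db)
}

# conv (stride, pad) + batch norm + ReLU
cbr_f <- function(x, p, key, env, training, stride, pad) {
  a <- .conv2d_fwd(x, p$conv$w, p$conv$b, stride, pad)
  bn <- bnr_f(a, p$bn, env$state[[key]], training)
  env$state[[key]] <- bn$state
  list(y = bn$y, cache = list(x = x, bn = bn$cache, stride = stride,
                              pad = pad))
}

cbr_b <- function(dy, p, cache) {
  bnb <- bnr_b(dy, cache$bn)
  cb <- .conv2d_bwd(cache$x, p$conv$w, bnb$dx, cache$stride, cache$pad)
  list(dx = cb$dx,
       g = list(conv = list(w = cb$dw, b = cb$db),
                bn = list(g = bnb$dg, b = bnb$db)))
}

# transposed conv (kernel = stride) + batch norm + ReLU
tbr_f <- function(x, p, key, env, training, stride) {
  a <- .convt2d_fwd(x, p$conv$w, p$conv$b, stride)
  bn <- bnr_f(a, p$bn, env$state[[key]], training)
  env$state[[key]] <- bn$state
  list(y = bn$y, cache = list(x = x, bn = bn$cache, stride = stride))
}

tbr_b <- function(dy, p, cache) {
  bnb <- bnr_b(dy, cache$bn)
  cb <- .convt2d_bwd(cache$x, p$conv$w, bnb$dx, cache$stride)
  list(dx = cb$dx,
       g = list(conv = list(w = cb$dw, b = cb$db),
                bn = list(g = bnb$dg, b = bnb$db)))
}

# Residual block: conv3x3-BN-ReLU-conv3x3-BN + shortcut, final ReLU.
# The shortcut is the identity when channel counts match, else a 1x1
# projection convolution.
res_f <- function(x, p, key, env, training) {
  a1 <- .conv2d_fwd(x, p$c1$w, p$c1$b, 1L, 1L)
  b1 <- bnr_f(a1, p$n1, env$state[[paste0(key, ".1")]], training)
  env$state[[paste0(key, ".1")]] <- b1$state
  a2 <- .conv2d_fwd(b1$y, p$c2$w, p$c2$b, 1L, 1L)
  b2 <- bnr_f(a2, p$n2, env$state[[paste0(key, ".2")]], training,
              relu = FALSE)
  env$state[[paste0(key, ".2")]] <- b2$state
  sc <- if (is.null(p$proj)) x else .conv2d_fwd(x, p$proj$w, p$proj$b, 1L, 0L)
  s <- b2$y + sc
  y <- relu_f(s)
  list(y = y,
       cache = list(x = x, bn1 = b1$cache, r1 = b1$y,
                    bn2 = b2$cache, mask_out = s > 0,
                    has_proj = !is.null(p$proj)))
}

res_b <- function(dy, p, cache) {
  ds <- dy * cache$mask_out
  bn2b <- bnr_b(ds, cache$bn2)
  c2b <- .conv2d_bwd(cache$r1, p$c2$w, bn2b$dx, 1L, 1L)
  bn1b <- bnr_b(c2b$dx, cache$bn1)
  c1b <- .conv2d_bwd(cache$x, p$c1$w, bn1b$dx, 1L, 1L)
  g <- list(c1 = list(w = c1b$dw, b = c1b$db),
            n1 = list(g = bn1b$dg, b = bn1b$db),
            c2 = list(w = c2b$dw, b = c2b$db),
            n2 = list(g = bn2b$dg, b = bn2b$db))
  if (cache$has_proj) {
    pb <- .conv2d_bwd(cache$x, p$proj$w, ds, 1L, 0L)
    dx <- c1b$dx + pb$dx
    g$proj <- list(w = pb$dw, b = pb$db)
  } else {
    dx <- c1b$dx + ds
  }
  list(dx = dx, g = g)
}

# Parameter constructors (He-normal weights; uses the current RNG state).
init_conv <- function(kh, kw, cin, cout) {
  list(w = array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

init_tconv <- function(k, cin, cout) {
  list(w = array(rnorm(k * k * cin * cout, 0, sqrt(2 / cin)),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}

init_bn <- function(c) list(g = rep(1, c), b = numeric(c))

init_cbr <- function(kh, kw, cin, cout) {
  list(conv = init_conv(kh, kw, cin, cout), bn = init_bn(cout))
}

init_tbr <- function(k, cin, cout) {
  list(conv = init_tconv(k, cin, cout), bn = init_bn(cout))
}

init_res <- function(cin, cout) {
  p <- list(c1 = init_conv(3, 3, cin, cout), n1 = init_bn(cout),
            c2 = init_conv(3, 3, cout, cout), n2 = init_bn(cout))
  if (cin != cout) p$proj <- init_conv(1, 1, cin, cout)
  p
}

bn_state0 <- function(c) list(mean = numeric(c), var = rep(1, c))

# Elementwise recursion over two parameter trees with identical structure.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

tree_add <- function(a, b) tree_map2(`+`, a, b)
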