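# Internal helpers: seeded evaluation, Gaussian blur, padding, array glue.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Truncated, renormalized 1D Gaussian kernel (sums to 1).
gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable 2D Gaussian blur of one slice via band-matrix products
# (zero-padding semantics; exact and fast at phantom sizes).
gauss_blur_2d <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  k <- gauss_kernel_1d(sigma_px)
  r <- (length(k) - 1L) / 2L
  band <- function(n) {
    A <- matrix(0, n, n)
    for (d in -r:r) {
      i <- seq_len(n - abs(d))
      A[cbind(i + max(0, -d), i + max(0, d))] <- k[d + r + 1L]
    }
    A
  }
  band(nrow(mat)) %*% mat %*% band(ncol(mat))
}

# Reflect-pad a (H, W) matrix on the bottom/right to the next multiple of m.
pad_to_multiple <- function(mat, m = 16L) {
  h <- nrow(mat); w <- ncol(mat)
  H <- as.integer(ceiling(h / m) * m)
  W <- as.integer(ceiling(w / m) * m)
  if (H == h && W == w) return(list(mat = mat, h = h, w = w))
  ri <- c(seq_len(h), rev(seq_len(h))[seq_len(H - h)])
  ci <- c(seq_len(w), rev(seq_len(w))[seq_len(W - w)])
  list(mat = mat[ri, ci, drop = FALSE], h = h, w = w)
}

# Concatenate 4D arrays (H, W, C, N) along the channel axis.
cat_channels <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], numeric(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    cx <- dim(x)[3]
    out[, , at + seq_len(cx), ] <- x
    at <- at + cx
  }
  out
}

# Split channel gradient back into parts with the given channel counts.
split_channels <- function(dx, counts) {
  at <- 0L
  lapply(counts, function(cx) {
    part <- dx[, , at + seq_len(cx), , drop = FALSE]
    at <<- at + cx
    part
  })
}

# Linear voxel keys for (slice, row, col) coordinate matrices on a fixed grid.
voxel_keys <- function(coords, grid_dim) {
  (coords[, 1] - 1) + grid_dim[1] * ((coords[, 2] - 1) +
    grid_dim[2] * (coords[, 3] - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
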