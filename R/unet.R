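#' Model configuration for the 2D residual U-Net
#'
#' The architecture is fixed by design — four residual encoder blocks
#' joined by stride-2 convolutions, four residual decoder blocks joined by
#' stride-2 transposed convolutions, four long-range skip connections from
#' encoder-block outputs to the matching decoder-block outputs, and two
#' contextual aggregation branches that carry the two deepest decoder-level
#' feature maps back to full resolution through stride-4 and stride-8
#' transposed convolutions before fusion (channel concatenation) with the
#' last residual block's features and a final 1x1 convolution + sigmoid —
#' while the channel widths and normalization remain configurable.
#'
#' @param base_channels channels of the first encoder level (default 32;
#'   doubled at each of the four levels).
#' @param norm_kind normalization; `"batch"` is the only built-in.
#' @param activation_kind activation; `"relu"` is the only built-in.
#' @return A `dotapet_model_config` list, including the fixed
#'   `n_down_blocks = n_up_blocks = 4` and `agg_strides = c(4, 8)`.
#' @export
model_config <- function(base_channels = 32L, norm_kind = "batch",
                         activation_kind = "relu") {
  stopifnot(base_channels >= 1, norm_kind == "batch",
            activation_kind == "relu")
  structure(
    list(n_down_blocks = 4L, n_up_blocks = 4L,
         base_channels = as.integer(base_channels),
         channel_growth = 2L, agg_strides = c(4L, 8L),
         norm_kind = norm_kind, activation_kind = activation_kind),
    class = "dotapet_model_config"
  )
}

#' Build the 2D residual U-Net
#'
#' Instantiates all weights (He-normal initialization, deterministic under
#' `seed`) and the batch-norm running statistics. Input slices must have
#' spatial dimensions divisible by 16 (four stride-2 levels);
#' [predict_study()] applies the reflect-pad/crop contract for other sizes.
#'
#' @param config a [model_config()].
#' @param seed integer seed for the weight initialization.
#' @return A `dotapet_model`: `config`, `params` (nested list of arrays),
#'   `bn_state` (running means/vars).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  C <- config$base_channels
  with_seed(seed, {
    params <- list(
      enc1 = init_res(1, C),
      down1 = init_cbr(3, 3, C, 2 * C),
      enc2 = init_res(2 * C, 2 * C),
      down2 = init_cbr(3, 3, 2 * C, 4 * C),
      enc3 = init_res(4 * C, 4 * C),
      down3 = init_cbr(3, 3, 4 * C, 8 * C),
      enc4 = init_res(8 * C, 8 * C),
      down4 = init_cbr(3, 3, 8 * C, 16 * C),
      up4 = init_tbr(2, 16 * C, 8 * C),
      dec4 = init_res(8 * C, 8 * C),
      up3 = init_tbr(2, 16 * C, 4 * C),
      dec3 = init_res(4 * C, 4 * C),
      up2 = init_tbr(2, 8 * C, 2 * C),
      dec2 = init_res(2 * C, 2 * C),
      up1 = init_tbr(2, 4 * C, C),
      dec1 = init_res(C, C),
      agg4 = init_tbr(4, 8 * C, C),
      agg8 = init_tbr(8, 16 * C, C),
      final = init_conv(1, 1, 4 * C, 1)
    )
    widths <- c(enc1.1 = C, enc1.2 = C, down1 = 2 * C,
                enc2.1 = 2 * C, enc2.2 = 2 * C, down2 = 4 * C,
                enc3.1 = 4 * C, enc3.2 = 4 * C, down3 = 8 * C,
                enc4.1 = 8 * C, enc4.2 = 8 * C, down4 = 16 * C,
                up4 = 8 * C, dec4.1 = 8 * C, dec4.2 = 8 * C,
                up3 = 4 * C, dec3.1 = 4 * C, dec3.2 = 4 * C,
                up2 = 2 * C, dec2.1 = 2 * C, dec2.2 = 2 * C,
                up1 = C, dec1.1 = C, dec1.2 = C,
                agg4 = C, agg8 = C)
    bn_state <- lapply(widths, bn_state0)
    structure(list(config = config, params = params, bn_state = bn_state),
              class = "dotapet_model")
  })
}

#' @export
print.dotapet_model <- function(x, ...) {
  cat(sprintf(
    "<dotapet_model> residual U-Net, base %d channels, %d parameters\n",
    x$config$base_channels, n_parameters(x)
  ))
  invisible(x)
}

#' Count trainable parameters of a model
#' @param model a `dotapet_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  length(unlist(model$params))
}

# Full forward pass. x: (H, W, 1, N) with H, W divisible by 16.
# Returns scores p = sigmoid(z) plus everything backward needs.
unet_forward <- function(model, x, training = FALSE) {
  p <- model$params
  env <- new.env(parent = emptyenv())
  env$state <- model$bn_state
  ca <- list()
  r <- res_f(x, p$enc1, "enc1", env, training); e1 <- r$y; ca$enc1 <- r$cache
  r <- cbr_f(e1, p$down1, "down1", env, training, 2L, 1L); d1 <- r$y; ca$down1 <- r$cache
  r <- res_f(d1, p$enc2, "enc2", env, training); e2 <- r$y; ca$enc2 <- r$cache
  r <- cbr_f(e2, p$down2, "down2", env, training, 2L, 1L); d2 <- r$y; ca$down2 <- r$cache
  r <- res_f(d2, p$enc3, "enc3", env, training); e3 <- r$y; ca$enc3 <- r$cache
  r <- cbr_f(e3, p$down3, "down3", env, training, 2L, 1L); d3 <- r$y; ca$down3 <- r$cache
  r <- res_f(d3, p$enc4, "enc4", env, training); e4 <- r$y; ca$enc4 <- r$cache
  r <- cbr_f(e4, p$down4, "down4", env, training, 2L, 1L); br <- r$y; ca$down4 <- r$cache
  r <- tbr_f(br, p$up4, "up4", env, training, 2L); u4 <- r$y; ca$up4 <- r$cache
  r <- res_f(u4, p$dec4, "dec4", env, training); q4 <- r$y; ca$dec4 <- r$cache
  k4 <- cat_channels(q4, e4)
  r <- tbr_f(k4, p$up3, "up3", env, training, 2L); u3 <- r$y; ca$up3 <- r$cache
  r <- res_f(u3, p$dec3, "dec3", env, training); q3 <- r$y; ca$dec3 <- r$cache
  k3 <- cat_channels(q3, e3)
  r <- tbr_f(k3, p$up2, "up2", env, training, 2L); u2 <- r$y; ca$up2 <- r$cache
  r <- res_f(u2, p$dec2, "dec2", env, training); q2 <- r$y; ca$dec2 <- r$cache
  k2 <- cat_channels(q2, e2)
  r <- tbr_f(k2, p$up1, "up1", env, training, 2L); u1 <- r$y; ca$up1 <- r$cache
  r <- res_f(u1, p$dec1, "dec1", env, training); q1 <- r$y; ca$dec1 <- r$cache
  k1 <- cat_channels(q1, e1)
  r <- tbr_f(k3, p$agg4, "agg4", env, training, 4L); a4 <- r$y; ca$agg4 <- r$cache
  r <- tbr_f(k4, p$agg8, "agg8", env, training, 8L); a8 <- r$y; ca$agg8 <- r$cache
  f <- cat_channels(k1, a4, a8)
  z <- .conv2d_fwd(f, p$final$w, p$final$b, 1L, 0L)
  scores <- 1 / (1 + exp(-z))
  ca$final_in <- f
  ca$C <- model$config$base_channels
  list(scores = scores, z = z, cache = ca, bn_state = env$state)
}

# Full backward pass from dL/dz (the pre-sigmoid gradient).
unet_backward <- function(model, cache, dz) {
  p <- model$params
  C <- cache$C
  g <- list()
  fb <- .conv2d_bwd(cache$final_in, p$final$w, dz, 1L, 0L)
  g$final <- list(w = fb$dw, b = fb$db)
  parts <- split_channels(fb$dx, c(2 * C, C, C))
  dk1 <- parts[[1]]; da4 <- parts[[2]]; da8 <- parts[[3]]
  b <- tbr_b(da8, p$agg8, cache$agg8); g$agg8 <- b$g; dk4 <- b$dx
  b <- tbr_b(da4, p$agg4, cache$agg4); g$agg4 <- b$g; dk3 <- b$dx
  parts <- split_channels(dk1, c(C, C)); dq1 <- parts[[1]]; de1 <- parts[[2]]
  b <- res_b(dq1, p$dec1, cache$dec1); g$dec1 <- b$g
  b <- tbr_b(b$dx, p$up1, cache$up1); g$up1 <- b$g; dk2 <- b$dx
  parts <- split_channels(dk2, c(2 * C, 2 * C))
  dq2 <- parts[[1]]; de2 <- parts[[2]]
  b <- res_b(dq2, p$dec2, cache$dec2); g$dec2 <- b$g
  b <- tbr_b(b$dx, p$up2, cache$up2); g$up2 <- b$g
  dk3 <- dk3 + b$dx
  parts <- split_channels(dk3, c(4 * C, 4 * C))
  dq3 <- parts[[1]]; de3 <- parts[[2]]
  b <- res_b(dq3, p$dec3, cache$dec3); g$dec3 <- b$g
  b <- tbr_b(b$dx, p$up3, cache$up3); g$up3 <- b$g
  dk4 <- dk4 + b$dx
  parts <- split_channels(dk4, c(8 * C, 8 * C))
  dq4 <- parts[[1]]; de4 <- parts[[2]]
  b <- res_b(dq4, p$dec4, cache$dec4); g$dec4 <- b$g
  b <- tbr_b(b$dx, p$up4, cache$up4); g$up4 <- b$g
  b <- cbr_b(b$dx, p$down4, cache$down4); g$down4 <- b$g
  de4 <- de4 + b$dx
  b <- res_b(de4, p$enc4, cache$enc4); g$enc4 <- b$g
  b <- cbr_b(b$dx, p$down3, cache$down3); g$down3 <- b$g
  de3 <- de3 + b$dx
  b <- res_b(de3, p$enc3, cache$enc3); g$enc3 <- b$g
  b <- cbr_b(b$dx, p$down2, cache$down2); g$down2 <- b$g
  de2 <- de2 + b$dx
  b <- res_b(de2, p$enc2, cache$enc2); g$enc2 <- b$g
  b <- cbr_b(b$dx, p$down1, cache$down1); g$down1 <- b$g
  de1 <- de1 + b$dx
  b <- res_b(de1, p$enc1, cache$enc1); g$enc1 <- b$g
  g[names(model$params)]
}

# Normalize a study for the network: zero outside the liver, divide by the
# in-liver maximum (a deterministic, scale-invariant intensity window).
normalize_stack <- function(stack, liver) {
  masked <- stack * liver
  scale <- max(masked)
  if (scale <= 0) scale <- 1
  list(x = masked / scale, scale = scale)
}

#' Predict per-pixel lesion scores for a study
#'
#' Masks every slice by the liver (outside-liver pixels zeroed), normalizes
#' by the in-liver maximum, reflect-pads to the next multiple of 16 if
#' needed, and feeds each slice independently through the network in
#' inference mode (batch-norm running statistics; deterministic). Slices
#' are independent entities: permuting them permutes the output.
#'
#' @param model a trained or freshly built `dotapet_model`.
#' @param stack activity array (slices x rows x cols) or `dotapet_study`.
#' @param liver logical mask (taken from the study if given).
#' @param batch_size slices per forward batch.
#' @return Numeric score array in \[0, 1\] with the shape of `stack`.
#' @export
predict_study <- function(model, stack, liver = NULL, batch_size = 8L) {
  if (inherits(stack, "dotapet_study")) {
    liver <- stack$liver
    stack <- stack$pet
  }
  if (!identical(dim(stack), dim(liver))) {
    stop("stack and liver mask shapes differ")
  }
  d <- dim(stack)
  norm <- normalize_stack(stack, liver)
  pads <- pad_to_multiple(matrix(0, d[2], d[3]))
  H <- nrow(pads$mat); W <- ncol(pads$mat)
  out <- array(0, d)
  zs <- seq_len(d[1])
  for (start in seq(1, d[1], by = batch_size)) {
    zi <- zs[start:min(start + batch_size - 1, d[1])]
    xb <- array(0, c(H, W, 1, length(zi)))
    for (k in seq_along(zi)) {
      xb[, , 1, k] <- pad_to_multiple(norm$x[zi[k], , ])$mat
    }
    fw <- unet_forward(model, xb, training = FALSE)
    for (k in seq_along(zi)) {
      out[zi[k], , ] <- fw$scores[seq_len(d[2]), seq_len(d[3]), 1, k]
    }
  }
  out
}
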