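# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own kernels: flood fill by explicit queue, IoU by set
# arithmetic on voxel keys, matching by exhaustive pair enumeration, PR-AUC
# recomputed per threshold from scratch.

# Flood-fill labeling of a 2D binary matrix (4 or 8 connectivity) or a 3D
# binary array (26-connectivity). Labels in first-pixel scan order
# (rows, then cols, then slices) to mirror the package's convention; but
# comparisons should treat labels as partitions.
oracle_label <- function(mask, connectivity = 8L) {
  d <- dim(mask)
  is3d <- length(d) == 3L
  if (!is3d) d <- c(d, 1L)
  H <- d[1]; W <- d[2]; D <- d[3]
  nb <- if (is3d) {
    g <- expand.grid(di = -1:1, dj = -1:1, dz = -1:1)
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else if (connectivity == 8L) {
    g <- expand.grid(di = -1:1, dj = -1:1, dz = 0)
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else {
    data.frame(di = c(1, -1, 0, 0), dj = c(0, 0, 1, -1), dz = 0)
  }
  m <- array(as.integer(mask != 0), d)
  lab <- array(0L, d)
  nxt <- 0L
  stack <- integer(H * W * D)
  for (p0 in seq_len(H * W * D)) {
    if (m[p0] == 0L || lab[p0] != 0L) next
    nxt <- nxt + 1L
    top <- 1L
    stack[1L] <- p0
    lab[p0] <- nxt
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      i <- ((p - 1L) %% H) + 1L
      j <- (((p - 1L) %/% H) %% W) + 1L
      z <- ((p - 1L) %/% (H * W)) + 1L
      for (k in seq_len(nrow(nb))) {
        ii <- i + nb$di[k]; jj <- j + nb$dj[k]; zz <- z + nb$dz[k]
        if (ii < 1 || ii > H || jj < 1 || jj > W || zz < 1 || zz > D) next
        q <- ii + H * ((jj - 1L) + W * (zz - 1L))
        if (m[q] != 0L && lab[q] == 0L) {
          lab[q] <- nxt
          top <- top + 1L
          stack[top] <- q
        }
      }
    }
  }
  if (is3d) lab else lab[, , 1]
}

# Two labelings describe the same partition of foreground pixels:
# the label-pair mapping must be a bijection.
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  pairs <- unique(cbind(a[a > 0], b[b > 0]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}

# IoU oracle on two binary arrays.
oracle_iou <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

# Greedy one-to-one matching oracle from explicit component pixel lists.
oracle_match <- function(pred_masks, gold_masks, iou_min = 0.05) {
  np <- length(pred_masks); ng <- length(gold_masks)
  cand <- NULL
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    v <- oracle_iou(pred_masks[[i]], gold_masks[[j]])
    if (v > iou_min) cand <- rbind(cand, c(i, j, v))
  }
  tp <- 0L
  if (!is.null(cand)) {
    cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    up <- logical(np); ug <- logical(ng)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!up[i] && !ug[j]) { up[i] <- TRUE; ug[j] <- TRUE; tp <- tp + 1L }
    }
  }
  list(tp = tp, fp = np - tp, fn = ng - tp)
}

# Independent per-threshold precision/recall and trapezoidal AUC.
oracle_pr <- function(preds, golds, thresholds, area_filter_px,
                      iou_min = 0.05) {
  pts <- t(vapply(thresholds, function(th) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(preds)) {
      sc <- preds[[i]]
      d <- dim(sc)
      pred_masks <- list()
      for (z in seq_len(d[1])) {
        bin <- matrix(as.integer(sc[z, , ] > th), d[2], d[3])
        lab <- oracle_label(bin, 8L)
        for (id in setdiff(unique(as.integer(lab)), 0L)) {
          if (sum(lab == id) < area_filter_px) next
          m3 <- array(FALSE, d)
          m3[z, , ][lab == id] <- TRUE
          pred_masks[[length(pred_masks) + 1L]] <- m3
        }
      }
      gold_masks <- list()
      gl <- golds[[i]]
      for (id in setdiff(unique(as.integer(gl)), 0L)) {
        for (z in seq_len(d[1])) {
          sl <- gl[z, , ] == id
          if (any(sl)) {
            m3 <- array(FALSE, d)
            m3[z, , ][sl] <- TRUE
            gold_masks[[length(gold_masks) + 1L]] <- m3
          }
        }
      }
      m <- oracle_match(pred_masks, gold_masks, iou_min)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    c(prec = if (tp + fp > 0) tp / (tp + fp) else if (tp + fn == 0) 1 else 0,
      rec = if (tp + fn > 0) tp / (tp + fn) else if (tp + fp == 0) 1 else 0)
  }, numeric(2)))
  r <- pts[, "rec"]; p <- pts[, "prec"]
  ord <- order(r, p)
  r <- r[ord]; p <- p[ord]
  ur <- unique(r)
  up <- vapply(ur, function(v) mean(p[r == v]), numeric(1))
  if (ur[1] > 0) { ur <- c(0, ur); up <- c(up[1], up) }
  auc <- if (length(ur) == 1L) ur * up else
    sum(diff(ur) * (head(up, -1) + tail(up, -1)) / 2)
  list(recall = r, precision = p, auc = auc)
}

# Small phantom spec shared by tests that only need a handful of slices.
test_spec <- function(...) {
  phantom_spec(n_slices_range = c(23L, 27L), ...)
}

# Build a component set directly from a named list of 3D logical masks
# (one per prediction), used to feed match_lesions with constructed cases.
cs_from_masks <- function(masks, grid_dim) {
  lab <- array(0L, grid_dim)
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  dotapet:::component_set_from_labels(lab, NULL, slicewise = FALSE)
}
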