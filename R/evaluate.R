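#' Intersection over union of two voxel sets
#'
#' `|a n b| / |a u b|` over coordinate matrices (slice, row, col) on a
#' common grid; the empty-empty case is defined as 0.
#'
#' @param a,b coordinate matrices (columns slice, row, col).
#' @param grid_dim grid dimensions c(slices, rows, cols) used to key voxels.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(a, b, grid_dim) {
  if (nrow(a) == 0 && nrow(b) == 0) return(0)
  ka <- voxel_keys(a, grid_dim)
  kb <- voxel_keys(b, grid_dim)
  ni <- length(intersect(ka, kb))
  nu <- length(unique(c(ka, kb)))
  ni / nu
}

#' Lesion-level matching of predictions against the gold standard
#'
#' Greedy one-to-one matching by descending IoU: candidate pairs with
#' IoU strictly greater than `iou_min` are accepted best-first, each
#' prediction and each gold object matched at most once; leftovers become
#' false positives / false negatives. Works for in-slice 2D components
#' (cross-slice IoU is naturally 0) and for 3D lesion objects alike.
#'
#' @param pred,gold `dotapet_component_set`s on the same grid.
#' @param iou_min strict IoU acceptance threshold (default 0.05).
#' @return A `dotapet_match` list: counts `tp`, `fp`, `fn`; `pairs` tibble
#'   (pred_id, gold_id, iou); `unmatched_pred`, `unmatched_gold` id vectors.
#' @export
match_lesions <- function(pred, gold, iou_min = 0.05) {
  stopifnot(identical(pred$grid_dim, gold$grid_dim))
  gd <- pred$grid_dim
  np <- nrow(pred$components); ng <- nrow(gold$components)
  cand <- NULL
  if (np > 0 && ng > 0) {
    pk <- lapply(pred$components$voxels, voxel_keys, grid_dim = gd)
    gk <- lapply(gold$components$voxels, voxel_keys, grid_dim = gd)
    rows <- list()
    for (i in seq_len(np)) {
      for (j in seq_len(ng)) {
        ni <- length(intersect(pk[[i]], gk[[j]]))
        if (ni == 0) next
        nu <- length(pk[[i]]) + length(gk[[j]]) - ni
        v <- ni / nu
        if (v > iou_min) {
          rows[[length(rows) + 1L]] <- c(i, j, v)
        }
      }
    }
    if (length(rows)) cand <- do.call(rbind, rows)
  }
  acc <- integer(0)
  if (!is.null(cand)) {
    cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    used_p <- logical(np); used_g <- logical(ng)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_p[i] || used_g[j]) next
      used_p[i] <- TRUE; used_g[j] <- TRUE
      acc <- c(acc, k)
    }
  }
  pairs <- if (is.null(cand) || !length(acc)) {
    tibble::tibble(pred_id = integer(), gold_id = integer(), iou = numeric())
  } else {
    tibble::tibble(pred_id = pred$components$id[cand[acc, 1]],
                   gold_id = gold$components$id[cand[acc, 2]],
                   iou = cand[acc, 3])
  }
  tp <- nrow(pairs)
  structure(
    list(
      tp = tp, fp = np - tp, fn = ng - tp,
      pairs = pairs,
      unmatched_pred = setdiff(pred$components$id, pairs$pred_id),
      unmatched_gold = setdiff(gold$components$id, pairs$gold_id)
    ),
    class = "dotapet_match"
  )
}

#' @export
print.dotapet_match <- function(x, ...) {
  cat(sprintf("<dotapet_match> TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' @export
tidy.dotapet_match <- function(x, ...) x$pairs

#' PPV, sensitivity and F1 from match counts
#'
#' `ppv = tp/(tp+fp)`, `sensitivity = tp/(tp+fn)`, `f1` their harmonic
#' mean. Undefined 0/0 ratios follow the documented convention: 1.0 when
#' there is nothing to find and nothing predicted (`tp+fp+fn == 0`),
#' otherwise 0.0.
#'
#' @param m a `dotapet_match`, or a list with `tp`, `fp`, `fn`.
#' @return Named numeric: `ppv`, `sensitivity`, `f1`.
#' @export
ppv_sensitivity_f1 <- function(m) {
  tp <- m$tp; fp <- m$fp; fn <- m$fn
  empty <- (tp + fp + fn) == 0
  ppv <- if (tp + fp > 0) tp / (tp + fp) else if (empty) 1 else 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else if (empty) 1 else 0
  f1 <- if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else if (empty) 1 else 0
  c(ppv = ppv, sensitivity = sens, f1 = f1)
}

# Convert a gold lesion label array into per-slice 2D gold objects: each
# (lesion, slice) footprint is one object, the granularity at which a 2D
# slice-wise detector is scored.
gold_slicewise_components <- function(lesions) {
  d <- dim(lesions)
  idx <- which(lesions > 0L)
  cs_empty <- component_set_from_labels(array(0L, d), NULL, slicewise = TRUE)
  if (!length(idx)) return(cs_empty)
  z <- ((idx - 1L) %% d[1]) + 1L
  relab <- array(0L, d)
  key <- paste(lesions[idx], z)
  relab[idx] <- as.integer(factor(key, levels = unique(key[order(z, lesions[idx])])))
  component_set_from_labels(relab, NULL, slicewise = TRUE)
}

# Convert a gold lesion label array into 3D gold objects (one per lesion id).
gold_volume_components <- function(lesions) {
  component_set_from_labels(array(as.integer(lesions), dim(lesions)),
                            NULL, slicewise = FALSE)
}

#' Evaluate prediction maps against gold lesions over a study set
#'
#' Runs the detection pipeline on each study's prediction map, matches the
#' surviving in-slice components against the per-slice footprints of the
#' gold lesions (IoU strictly above `iou_min`, one-to-one), pools counts
#' over studies (micro-average, the default) or averages metrics per study,
#' and returns a metrics row.
#'
#' @param preds named list of prediction score arrays (one per study).
#' @param golds named list of gold lesion label arrays, aligned with `preds`.
#' @param config a [detection_config()].
#' @param iou_min strict IoU match threshold.
#' @param mode `"micro"` (pool counts; default) or `"per_study"`.
#' @return A one-row tibble: `filter_px`, `binarize_threshold`, `tp`, `fp`,
#'   `fn`, `ppv`, `sensitivity`, `f1`.
#' @export
evaluate_detections <- function(preds, golds, config = detection_config(),
                                iou_min = 0.05, mode = c("micro", "per_study")) {
  mode <- match.arg(mode)
  stopifnot(length(preds) == length(golds))
  counts <- list()
  per <- list()
  for (i in seq_along(preds)) {
    cs <- detect_lesions(preds[[i]], config)
    gs <- gold_slicewise_components(golds[[i]])
    m <- match_lesions(cs, gs, iou_min)
    counts[[i]] <- c(m$tp, m$fp, m$fn)
    per[[i]] <- ppv_sensitivity_f1(m)
  }
  cm <- do.call(rbind, counts)
  if (mode == "micro") {
    met <- ppv_sensitivity_f1(list(tp = sum(cm[, 1]), fp = sum(cm[, 2]),
                                   fn = sum(cm[, 3])))
  } else {
    pm <- do.call(rbind, per)
    met <- colMeans(pm)
  }
  tibble::tibble(
    filter_px = config$area_filter_px,
    binarize_threshold = config$binarize_threshold,
    tp = sum(cm[, 1]), fp = sum(cm[, 2]), fn = sum(cm[, 3]),
    ppv = met[["ppv"]], sensitivity = met[["sensitivity"]], f1 = met[["f1"]]
  )
}

#' Precision-recall curve over the binarization threshold
#'
#' Sweeps the score threshold over a fixed grid; at each threshold the
#' detection pipeline (with the fixed pixel-area filter) runs on every
#' study and counts are pooled before computing precision and recall.
#' The area under the curve uses the trapezoidal rule over the recall
#' axis, anchoring the curve at recall 0 with the precision of the
#' lowest-recall point and integrating only up to the largest observed
#' recall (no extrapolation towards recall 1).
#'
#' @param preds,golds named lists as in [evaluate_detections()].
#' @param area_filter_px fixed pixel-area filter for the whole curve.
#' @param thresholds score grid (default `seq(0.02, 0.98, by = 0.04)`).
#' @param iou_min strict IoU match threshold.
#' @param connectivity in-slice connectivity.
#' @return A `dotapet_pr_curve`: tibble `curve` (threshold, tp, fp, fn,
#'   precision, recall) and scalar `auc`.
#' @export
pr_curve <- function(preds, golds, area_filter_px = 5L,
                     thresholds = seq(0.02, 0.98, by = 0.04),
                     iou_min = 0.05, connectivity = 8L) {
  golds_cs <- lapply(golds, gold_slicewise_components)
  rows <- lapply(thresholds, function(th) {
    cfg <- detection_config(binarize_threshold = th,
                            area_filter_px = area_filter_px,
                            connectivity = connectivity)
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(preds)) {
      cs <- detect_lesions(preds[[i]], cfg)
      m <- match_lesions(cs, golds_cs[[i]], iou_min)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    met <- ppv_sensitivity_f1(list(tp = tp, fp = fp, fn = fn))
    tibble::tibble(threshold = th, tp = tp, fp = fp, fn = fn,
                   precision = met[["ppv"]], recall = met[["sensitivity"]])
  })
  curve <- dplyr::bind_rows(rows)
  structure(
    list(curve = curve, auc = pr_auc_trapezoid(curve$recall, curve$precision),
         area_filter_px = as.integer(area_filter_px)),
    class = "dotapet_pr_curve"
  )
}

# Trapezoid over the recall axis with the documented endpoint handling:
# sort by recall, average precision at tied recalls, anchor (0, p_first).
pr_auc_trapezoid <- function(recall, precision) {
  if (!length(recall)) return(0)
  ord <- order(recall, precision)
  r <- recall[ord]; p <- precision[ord]
  ur <- unique(r)
  up <- vapply(ur, function(v) mean(p[r == v]), numeric(1))
  if (ur[1] > 0) {
    ur <- c(0, ur)
    up <- c(up[1], up)
  }
  if (length(ur) == 1L) return(ur * up)
  sum(diff(ur) * (head(up, -1) + tail(up, -1)) / 2)
}

#' @export
print.dotapet_pr_curve <- function(x, ...) {
  cat(sprintf("<dotapet_pr_curve> filter %d px, %d thresholds, AUC %.4f\n",
              x$area_filter_px, nrow(x$curve), x$auc))
  invisible(x)
}

#' @export
tidy.dotapet_pr_curve <- function(x, ...) {
  dplyr::mutate(x$curve, filter_px = x$area_filter_px)
}

#' @export
glance.dotapet_pr_curve <- function(x, ...) {
  tibble::tibble(filter_px = x$area_filter_px, pr_auc = x$auc,
                 n_thresholds = nrow(x$curve))
}

#' Aggregate replicate metrics into a filter-by-metric report
#'
#' Sample mean and SD (n-1 denominator) per (metric, filter) cell over
#' replicate runs, presented with filters as columns. Alongside the mean of
#' per-replicate F1 values, the F1 recomputed from the mean PPV and mean
#' sensitivity is reported as `f1_of_means` — the two orders of averaging
#' need not agree, so both are given.
#'
#' @param records tibble of per-replicate metric rows with columns
#'   `replicate`, `filter_px`, and the metric columns (`ppv`,
#'   `sensitivity`, `f1`, optionally `pr_auc`).
#' @return A `dotapet_aggregate`: `long` tibble (metric, filter_px, mean,
#'   sd, n) and `grid` (metric rows, one column per filter,
#'   "mean (sd)" strings); single replicates get `NA` SD.
#' @export
aggregate_runs <- function(records) {
  stopifnot(all(c("replicate", "filter_px") %in% names(records)))
  metric_cols <- intersect(c("ppv", "sensitivity", "f1", "pr_auc"),
                           names(records))
  long <- records |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$metric, .data$filter_px) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
      n = dplyr::n(), .groups = "drop"
    )
  f1m <- long |>
    dplyr::filter(.data$metric %in% c("ppv", "sensitivity")) |>
    dplyr::select("metric", "filter_px", "mean") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "mean") |>
    dplyr::mutate(
      metric = "f1_of_means",
      mean = ifelse(.data$ppv + .data$sensitivity > 0,
                    2 * .data$ppv * .data$sensitivity /
                      (.data$ppv + .data$sensitivity), 0),
      sd = NA_real_,
      n = NA_integer_
    ) |>
    dplyr::select("metric", "filter_px", "mean", "sd", "n")
  long <- dplyr::bind_rows(long, f1m)
  grid <- long |>
    dplyr::mutate(cell = ifelse(
      is.na(.data$sd), sprintf("%.2f", .data$mean),
      sprintf("%.2f (%.2f)", .data$mean, .data$sd)
    )) |>
    dplyr::select("metric", "filter_px", "cell") |>
    tidyr::pivot_wider(names_from = "filter_px", values_from = "cell")
  structure(list(long = long, grid = grid), class = "dotapet_aggregate")
}

#' @export
print.dotapet_aggregate <- function(x, ...) {
  cat("<dotapet_aggregate> mean (sd) over replicates, by pixel filter\n")
  print(x$grid, ...)
  invisible(x)
}

#' @export
tidy.dotapet_aggregate <- function(x, ...) x$long
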