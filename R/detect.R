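#' Detection configuration
#'
#' Settings that turn a per-pixel prediction map into candidate lesions:
#' the binarization threshold (strictly-above rule), the in-slice pixel-area
#' noise filter, and the in-slice connectivity.
#'
#' @param binarize_threshold score threshold in (0, 1); default 0.05.
#' @param area_filter_px minimum component area kept, pixels; the study
#'   sweep uses 5, 7, 10, 15 and 20.
#' @param connectivity 4 or 8 (default 8, in-slice).
#' @return A `dotapet_detection_config` list.
#' @export
detection_config <- function(binarize_threshold = 0.05,
                             area_filter_px = 5L,
                             connectivity = 8L) {
  stopifnot(binarize_threshold > 0, binarize_threshold < 1,
            area_filter_px >= 0, connectivity %in% c(4L, 8L))
  structure(
    list(binarize_threshold = binarize_threshold,
         area_filter_px = as.integer(area_filter_px),
         connectivity = as.integer(connectivity)),
    class = "dotapet_detection_config"
  )
}

#' Binarize a prediction map
#'
#' A pixel is lesion (1) iff its score is strictly above the threshold;
#' a score exactly equal to the threshold is background.
#'
#' @param map numeric array of scores in \[0, 1\] (2D slice or 3D study).
#' @param threshold scalar threshold.
#' @return Integer array of 0/1 with the same shape.
#' @export
binarize <- function(map, threshold = 0.05) {
  out <- array(as.integer(map > threshold), dim(map))
  out
}

#' Connected components of a binary map
#'
#' Standard component labeling with deterministic label order (scan order
#' of each component's first pixel: rows, then columns, then slices).
#' 2D inputs use the configured in-slice connectivity (4 or 8); 3D inputs
#' are labeled slice by slice, so components never span slices — matching
#' a 2D network whose slices are independent entities. Use
#' [detect_candidates()] for 3D/26-connected annotation components.
#'
#' @param bin binary array (2D matrix or 3D slices x rows x cols).
#' @param connectivity 4 or 8.
#' @param scores optional array of scores aligned with `bin`, used to fill
#'   the per-component mean/peak score columns.
#' @return A `dotapet_component_set`, a tibble-backed container; see
#'   [component_set()].
#' @export
connected_components <- function(bin, connectivity = 8L, scores = NULL) {
  if (length(dim(bin)) == 2L) {
    lab2 <- .label_components(matrix(as.integer(bin), nrow(bin), ncol(bin)),
                              as.integer(connectivity))
    lab <- array(lab2, c(1L, dim(bin)))
    if (!is.null(scores)) scores <- array(scores, c(1L, dim(bin)))
    return(component_set_from_labels(lab, scores, slicewise = TRUE))
  }
  d <- dim(bin)
  lab <- array(0L, d)
  at <- 0L
  for (z in seq_len(d[1])) {
    lz <- .label_components(matrix(as.integer(bin[z, , ]), d[2], d[3]),
                            as.integer(connectivity))
    kz <- max(lz)
    pos <- lz > 0L
    lz[pos] <- lz[pos] + at
    at <- at + kz
    lab[z, , ] <- lz
  }
  component_set_from_labels(lab, scores, slicewise = TRUE)
}

# Build the tibble-backed component container from an integer label array
# (slices x rows x cols). `slicewise = TRUE` marks in-slice 2D components.
component_set_from_labels <- function(labels, scores = NULL,
                                      slicewise = TRUE) {
  d <- dim(labels)
  idx <- which(labels > 0L)
  if (!length(idx)) {
    comp <- tibble::tibble(
      id = integer(), slice = integer(), area = integer(),
      mean_score = numeric(), peak_score = numeric(),
      peak_slice = integer(), peak_row = integer(), peak_col = integer(),
      voxels = list()
    )
    return(structure(list(components = comp, labels = labels,
                          grid_dim = d, slicewise = slicewise),
                     class = "dotapet_component_set"))
  }
  z <- ((idx - 1L) %% d[1]) + 1L
  r <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  cc <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  ids <- labels[idx]
  vals <- if (!is.null(scores)) scores[idx] else rep(NA_real_, length(idx))
  ord <- order(ids)
  z <- z[ord]; r <- r[ord]; cc <- cc[ord]; vals <- vals[ord]; ids <- ids[ord]
  splits <- split(seq_along(ids), ids)
  uid <- as.integer(names(splits))
  voxl <- lapply(splits, function(ii) cbind(slice = z[ii], row = r[ii],
                                            col = cc[ii]))
  pk <- vapply(splits, function(ii) {
    if (all(is.na(vals[ii]))) ii[1L] else ii[which.max(vals[ii])]
  }, integer(1))
  comp <- tibble::tibble(
    id = uid,
    slice = if (slicewise) {
      unname(z[vapply(splits, `[`, integer(1), 1L)])
    } else {
      rep(NA_integer_, length(splits))
    },
    area = unname(lengths(splits)),
    mean_score = unname(vapply(splits, function(ii) mean(vals[ii]),
                               numeric(1))),
    peak_score = unname(vapply(splits, function(ii) max(vals[ii]),
                               numeric(1))),
    peak_slice = unname(z[pk]), peak_row = unname(r[pk]),
    peak_col = unname(cc[pk]),
    voxels = unname(voxl)
  )
  comp <- comp[order(comp$id), , drop = FALSE]
  structure(list(components = comp, labels = labels, grid_dim = d,
                 slicewise = slicewise),
            class = "dotapet_component_set")
}

#' Component container
#'
#' A `dotapet_component_set` couples an integer label array with a tibble of
#' per-component records: `id`, `slice` (for in-slice 2D components; `NA`
#' for 3D annotation components), `area` in pixels, `mean_score`,
#' `peak_score`, the peak voxel, and a `voxels` list-column of
#' (slice, row, col) coordinate matrices.
#'
#' @param x object to coerce/inspect.
#' @name component_set
NULL

#' Extract one component's voxels and peak
#'
#' @param cs a `dotapet_component_set`.
#' @param i row index into `cs$components`.
#' @return List with `voxels` (coordinate matrix) and `peak` (slice/row/col).
#' @export
component_voxels <- function(cs, i) {
  row <- cs$components[i, ]
  list(voxels = row$voxels[[1]],
       peak = c(row$peak_slice, row$peak_row, row$peak_col))
}

#' @export
print.dotapet_component_set <- function(x, ...) {
  cat(sprintf("<dotapet_component_set> %d component(s), %s\n",
              nrow(x$components),
              if (x$slicewise) "in-slice (2D)" else "volumetric (3D)"))
  if (nrow(x$components)) print(x$components[, c("id", "slice", "area",
                                                 "peak_score")], ...)
  invisible(x)
}

#' Pixel-area noise filter
#'
#' Removes components whose pixel area lies below the threshold; a
#' component exactly at the threshold is kept. Never adds components.
#'
#' @param cs a `dotapet_component_set`.
#' @param min_area_px minimum area kept (0 = identity).
#' @return A filtered `dotapet_component_set`.
#' @export
area_filter <- function(cs, min_area_px) {
  keep <- cs$components$area >= min_area_px
  dropped <- cs$components$id[!keep]
  labels <- cs$labels
  if (length(dropped)) labels[labels %in% dropped] <- 0L
  structure(list(components = cs$components[keep, , drop = FALSE],
                 labels = labels, grid_dim = cs$grid_dim,
                 slicewise = cs$slicewise),
            class = "dotapet_component_set")
}

#' Full detection pipeline for one prediction map
#'
#' Binarization (strictly above the score threshold), in-slice connected
#' components, then the pixel-area noise filter.
#'
#' @param map prediction score array (2D or 3D).
#' @param config a [detection_config()].
#' @return A `dotapet_component_set` of surviving in-slice components.
#' @export
detect_lesions <- function(map, config = detection_config()) {
  bin <- binarize(map, config$binarize_threshold)
  cs <- connected_components(bin, config$connectivity, scores = map)
  area_filter(cs, config$area_filter_px)
}
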