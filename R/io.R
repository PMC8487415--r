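#' Write one study to the PNG dataset layout
#'
#' A study directory holds three aligned image directories — `pet`,
#' `liver`, `lesion` — with one 8-bit grayscale PNG per trans-axial slice,
#' plus a JSON sidecar. PET activity is scaled to 8 bits through a fixed
#' intensity window `[0, window_max]` recorded in the sidecar, so the
#' scaling is invertible up to quantization; masks are binary
#' \{0, 255\} maps. Without its sidecar a study's intensities are not
#' interpreted quantitatively.
#'
#' @param study a `dotapet_study`.
#' @param dir study directory (created if needed).
#' @param window_max top of the intensity window; defaults to the study's
#'   maximum activity.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, window_max = NULL) {
  d <- dim(study$pet)
  window_max <- window_max %||% max(study$pet)
  if (window_max <= 0) window_max <- 1
  for (sub in c("pet", "liver", "lesion")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  for (z in seq_len(d[1])) {
    fn <- sprintf("%03d.png", z)
    pet8 <- pmin(pmax(study$pet[z, , ] / window_max, 0), 1)
    png::writePNG(round(pet8 * 255) / 255, file.path(dir, "pet", fn))
    png::writePNG((study$liver[z, , ]) * 1, file.path(dir, "liver", fn))
    png::writePNG((study$lesions[z, , ] > 0) * 1, file.path(dir, "lesion", fn))
  }
  meta <- list(
    n_slices = d[1], rows = d[2], cols = d[3],
    window = c(0, window_max),
    pixel_spacing_mm = study$pixel_spacing_mm,
    slice_thickness_mm = study$slice_thickness_mm,
    abnormal = study$abnormal,
    n_lesions = nrow(study$lesion_table)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read one study from the PNG dataset layout
#'
#' Inverts [write_study()] using the sidecar window. Lesion ids are
#' recovered by 3D (26-connectivity) labeling of the binary lesion map —
#' valid because lesions are non-confluent.
#'
#' @param dir study directory.
#' @return A `dotapet_study` (with an empty `lesion_table`; geometry and
#'   activity are restored up to 8-bit quantization).
#' @export
read_study <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) {
    stop("missing sidecar meta.json: refusing to interpret PET intensities quantitatively")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- lapply(c("pet", "liver", "lesion"), function(sub) {
    sort(list.files(file.path(dir, sub), pattern = "\\.png$"))
  })
  if (!all(vapply(files, identical, logical(1), y = files[[1]])) ||
      length(files[[1]]) != meta$n_slices) {
    stop("layout error: pet/liver/lesion slice filename sets differ or do not match the sidecar")
  }
  d <- c(meta$n_slices, meta$rows, meta$cols)
  pet <- array(0, d); liver <- array(FALSE, d); lesion_bin <- array(0L, d)
  for (z in seq_len(d[1])) {
    fn <- files[[1]][z]
    pet[z, , ] <- png::readPNG(file.path(dir, "pet", fn)) * meta$window[2]
    liver[z, , ] <- png::readPNG(file.path(dir, "liver", fn)) > 0.5
    lesion_bin[z, , ] <- (png::readPNG(file.path(dir, "lesion", fn)) > 0.5) * 1L
  }
  perm <- aperm(lesion_bin, c(2, 3, 1))
  lab <- aperm(.label_components(perm, 26L), c(3, 1, 2))
  structure(
    list(pet = pet, liver = liver, lesions = lab,
         lesion_table = tibble::tibble(lesion_id = sort(unique(lab[lab > 0]))),
         pixel_spacing_mm = meta$pixel_spacing_mm,
         slice_thickness_mm = meta$slice_thickness_mm,
         abnormal = isTRUE(meta$abnormal), seed = NA_integer_),
    class = "dotapet_study"
  )
}

#' Write a whole dataset
#'
#' One subdirectory per study (named by its five-digit ID) plus a
#' `manifest.json`.
#'
#' @param dataset a `dotapet_dataset` from [generate_dataset()].
#' @param dir dataset root directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(dataset$studies)) {
    write_study(dataset$studies[[id]], file.path(dir, id))
  }
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Stratified train/validation/test split
#'
#' Seeded random assignment of studies to the three splits, stratified by
#' the abnormal flag, with either exact per-split counts or fractions.
#' The study protocol splits 125 studies into 75 training (36 abnormal,
#' 39 normal), 25 validation (11, 14) and 25 testing (11, 14).
#'
#' @param manifest tibble with `study_id` and `abnormal` columns.
#' @param counts named list `list(train =, validation =, test =)`; each
#'   entry is either a per-split total (allocated across strata by largest
#'   remainder) or an explicit `c(abnormal =, normal =)` pair (the study
#'   protocol's exact allocation). `NULL` to use `fractions`.
#' @param fractions length-3 split fractions summing to 1 (used when
#'   `counts` is `NULL`; default `c(0.6, 0.2, 0.2)`).
#' @param seed split seed.
#' @return A `dotapet_split_manifest` tibble: `study_id`, `abnormal`,
#'   `split`; attributes record counts and the seed.
#' @export
split_dataset <- function(manifest, counts = NULL,
                          fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(all(c("study_id", "abnormal") %in% names(manifest)))
  n <- nrow(manifest)
  splits <- c("train", "validation", "test")
  out <- with_seed(seed, {
    res <- character(n)
    for (ab in c(TRUE, FALSE)) {
      sel <- which(manifest$abnormal == ab)
      if (!length(sel)) next
      k3 <- if (!is.null(counts)) {
        stratum_counts(counts, manifest, ab)
      } else {
        k <- floor(fractions * length(sel))
        k[1] <- length(sel) - sum(k[-1])
        as.integer(k)
      }
      if (sum(k3) != length(sel)) {
        stop(sprintf(
          "infeasible split: %d %s studies available, %d requested",
          length(sel), if (ab) "abnormal" else "normal", sum(k3)
        ))
      }
      sh <- sample(sel)
      res[sh] <- rep(splits, k3)
    }
    res
  })
  sm <- tibble::tibble(study_id = manifest$study_id,
                       abnormal = manifest$abnormal, split = out)
  attr(sm, "seed") <- as.integer(seed)
  attr(sm, "counts") <- table(sm$split, sm$abnormal)
  class(sm) <- c("dotapet_split_manifest", class(sm))
  sm
}

# Per-stratum split counts. Entries of `counts` may be explicit
# c(abnormal =, normal =) pairs (used directly) or per-split totals
# (allocated across strata by largest remainder).
stratum_counts <- function(counts, manifest, abnormal) {
  splits <- c("train", "validation", "test")
  counts <- counts[splits]
  if (all(vapply(counts, length, integer(1)) == 2L)) {
    return(vapply(counts, function(v) {
      as.integer(v[[if (abnormal) "abnormal" else "normal"]])
    }, integer(1)))
  }
  totals <- vapply(counts, function(v) as.integer(v[[1]]), integer(1))
  if (sum(totals) != nrow(manifest)) {
    stop("split counts must sum to the number of studies")
  }
  n_here <- sum(manifest$abnormal == abnormal)
  exact <- totals * n_here / nrow(manifest)
  k <- floor(exact)
  rem <- n_here - sum(k)
  if (rem > 0) {
    bump <- order(exact - k, decreasing = TRUE)[seq_len(rem)]
    k[bump] <- k[bump] + 1
  }
  as.integer(k)
}

#' Serialize / read a split manifest
#' @param sm a `dotapet_split_manifest`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_split_manifest()` returns the tibble.
#' @export
write_split_manifest <- function(sm, path) {
  jsonlite::write_json(
    list(seed = attr(sm, "seed"), assignment = as.data.frame(sm)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sm <- tibble::as_tibble(obj$assignment)
  attr(sm, "seed") <- obj$seed
  class(sm) <- c("dotapet_split_manifest", class(sm))
  sm
}
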