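#' Specification of a synthetic DOTATATE-like liver phantom
#'
#' Bundles every tunable of the phantom generator: grid geometry, liver
#' ellipse, uniform background activity with additive Gaussian noise, lesion
#' count/size/contrast statistics, and the in-plane point-spread blur. The
#' defaults emulate the study population the pipeline is designed for:
#' 4.0 +/- 2.75 lesions per abnormal study (clamped to 1..9, i.e. fewer than
#' ten well-defined non-confluent lesions), lesions spanning 4-5 consecutive
#' trans-axial slices, and studies of 23-71 slices.
#'
#' @param grid_shape integer (rows, cols) of each trans-axial slice.
#' @param pixel_spacing_mm in-plane pixel size, mm.
#' @param slice_anisotropy slice thickness as a multiple of `pixel_spacing_mm`.
#' @param n_slices_range integer interval for the per-study slice count.
#' @param liver_semi_axes_frac liver ellipse semi-axes as fractions of the grid.
#' @param liver_center_jitter_px uniform +/- jitter of the liver center, pixels.
#' @param background_mean uniform liver background activity (arbitrary units).
#' @param noise_sigma per-pixel SD of the additive Gaussian noise.
#' @param lesion_count_mean,lesion_count_sd normal draw for the lesion count
#'   of an abnormal study, rounded then clamped to `[1, lesion_count_max]`.
#' @param lesion_count_max maximum lesions per study (at most 9).
#' @param lesion_slice_span_range allowed number of consecutive slices a
#'   lesion may span; spheres are trimmed to the upper bound.
#' @param lesion_radius_range_mm lesion sphere radius interval, mm.
#' @param lesion_contrast_range multiplicative uptake ratio over background.
#' @param blur_fwhm_mm in-plane Gaussian point-spread FWHM, mm.
#' @param ensure_detectable when `TRUE` (default), require the lowest lesion
#'   uptake `min(contrast) * background_mean` to exceed the modified PERCIST
#'   threshold of the configured background,
#'   `1.5 * background_mean + 2 * noise_sigma`.
#' @return A `dotapet_phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L),
                         pixel_spacing_mm = 4,
                         slice_anisotropy = 1,
                         n_slices_range = c(23L, 71L),
                         liver_semi_axes_frac = c(0.36, 0.28),
                         liver_center_jitter_px = 2,
                         background_mean = 100,
                         noise_sigma = 15,
                         lesion_count_mean = 4.0,
                         lesion_count_sd = 2.75,
                         lesion_count_max = 9L,
                         lesion_slice_span_range = c(4L, 5L),
                         lesion_radius_range_mm = c(8, 10),
                         lesion_contrast_range = c(2, 4),
                         blur_fwhm_mm = 6,
                         ensure_detectable = TRUE) {
  spec <- list(
    grid_shape = as.integer(grid_shape),
    pixel_spacing_mm = pixel_spacing_mm,
    slice_anisotropy = slice_anisotropy,
    n_slices_range = as.integer(n_slices_range),
    liver_semi_axes_frac = liver_semi_axes_frac,
    liver_center_jitter_px = liver_center_jitter_px,
    background_mean = background_mean,
    noise_sigma = noise_sigma,
    lesion_count_mean = lesion_count_mean,
    lesion_count_sd = lesion_count_sd,
    lesion_count_max = as.integer(lesion_count_max),
    lesion_slice_span_range = as.integer(lesion_slice_span_range),
    lesion_radius_range_mm = lesion_radius_range_mm,
    lesion_contrast_range = lesion_contrast_range,
    blur_fwhm_mm = blur_fwhm_mm,
    ensure_detectable = isTRUE(ensure_detectable)
  )
  class(spec) <- "dotapet_phantom_spec"
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  stopifnot(
    length(spec$grid_shape) == 2, all(spec$grid_shape > 0),
    spec$pixel_spacing_mm > 0, spec$slice_anisotropy > 0,
    length(spec$n_slices_range) == 2,
    spec$n_slices_range[1] >= 1,
    spec$n_slices_range[1] <= spec$n_slices_range[2],
    all(spec$liver_semi_axes_frac > 0),
    spec$background_mean > 0, spec$noise_sigma >= 0,
    spec$lesion_count_sd >= 0,
    spec$lesion_count_max >= 1,
    diff(spec$lesion_slice_span_range) >= 0,
    all(spec$lesion_radius_range_mm > 0),
    diff(spec$lesion_radius_range_mm) >= 0,
    all(spec$lesion_contrast_range > 1),
    spec$blur_fwhm_mm >= 0
  )
  if (spec$lesion_count_max > 9L) {
    stop("lesion_count_max must be at most 9 (studies have fewer than 10 lesions)")
  }
  if (spec$ensure_detectable) {
    peak <- spec$lesion_contrast_range[1] * spec$background_mean
    thr <- 1.5 * spec$background_mean + 2 * spec$noise_sigma
    if (peak <= thr) {
      stop(sprintf(
        paste0("lesion_contrast_range[1] too low for detectability: ",
               "peak %.3g <= PERCIST threshold %.3g; raise the contrast, ",
               "lower the noise, or set ensure_detectable = FALSE"),
        peak, thr
      ))
    }
  }
  spec
}

#' Draw lesion counts for abnormal studies
#'
#' Counts are drawn from a normal distribution with the configured mean and
#' SD, rounded to the nearest integer, then clamped to
#' `[1, lesion_count_max]` — an abnormal study always holds at least one
#' lesion and fewer than ten. Uses the current RNG state.
#'
#' @param spec a [phantom_spec()].
#' @param n number of draws.
#' @return Integer vector of length `n`.
#' @export
sample_lesion_count <- function(spec, n = 1L) {
  raw <- rnorm(n, spec$lesion_count_mean, spec$lesion_count_sd)
  pmin(pmax(as.integer(round(raw)), 1L), spec$lesion_count_max)
}

# Per-slice liver ellipse scale: full in the mid-section, tapering at the ends.
liver_slice_scale <- function(z, n_slices) {
  zc <- (n_slices + 1) / 2
  sqrt(pmax(0.2, 1 - ((z - zc) / (0.58 * n_slices))^2))
}

render_liver <- function(spec, n_slices, center_rc) {
  h <- spec$grid_shape[1]; w <- spec$grid_shape[2]
  a <- spec$liver_semi_axes_frac[1] * h
  b <- spec$liver_semi_axes_frac[2] * w
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- array(FALSE, c(n_slices, h, w))
  for (z in seq_len(n_slices)) {
    s <- liver_slice_scale(z, n_slices)
    el <- ((rows - center_rc[1]) / (a * s))^2 +
      ((cols - center_rc[2]) / (b * s))^2 <= 1
    mask[z, , ] <- el
  }
  mask
}

# Rasterize a sphere on the anisotropic voxel grid. Center is (z, r, c) in
# voxel units (z may be half-integer), radius in mm. Returns an index matrix
# (slice, row, col), trimmed axially to at most `max_span` slices.
rasterize_sphere <- function(center, radius_mm, spec, n_slices, max_span) {
  dx <- spec$pixel_spacing_mm
  dz <- spec$pixel_spacing_mm * spec$slice_anisotropy
  zs <- seq_len(n_slices)
  keep_z <- zs[abs(zs - center[1]) * dz <= radius_mm]
  if (length(keep_z) > max_span) {
    ord <- order(abs(keep_z - center[1]))
    keep_z <- sort(keep_z[ord][seq_len(max_span)])
  }
  out <- list()
  h <- spec$grid_shape[1]; w <- spec$grid_shape[2]
  for (z in keep_z) {
    rho <- sqrt(radius_mm^2 - ((z - center[1]) * dz)^2) / dx
    rr <- seq(max(1, floor(center[2] - rho)), min(h, ceiling(center[2] + rho)))
    cc <- seq(max(1, floor(center[3] - rho)), min(w, ceiling(center[3] + rho)))
    if (!length(rr) || !length(cc)) next
    g <- expand.grid(row = rr, col = cc)
    d2 <- (g$row - center[2])^2 + (g$col - center[3])^2
    g <- g[d2 <= rho^2 + 1e-12, , drop = FALSE]
    if (nrow(g)) out[[length(out) + 1L]] <- cbind(slice = z, row = g$row, col = g$col)
  }
  if (!length(out)) matrix(integer(0), 0, 3) else do.call(rbind, out)
}

#' Generate one synthetic PET study
#'
#' Renders a per-slice elliptical liver filled with uniform background
#' activity, inserts non-confluent spherical lesions with uptake
#' `contrast * background_mean` (abnormal studies only), blurs each slice
#' with the in-plane Gaussian point spread, then adds i.i.d. Gaussian noise
#' (clipped at zero). The lesion label map records the pre-blur sphere
#' extents, so the ground truth is independent of the point spread and of
#' any downstream annotation.
#'
#' @param spec a [phantom_spec()].
#' @param abnormal logical; if `FALSE` the lesion map is empty.
#' @param seed integer seed; identical `(spec, abnormal, seed)` give
#'   bit-identical output.
#' @return A list with class `dotapet_study`: `pet` (slices x rows x cols
#'   activity array), `liver` (logical array), `lesions` (integer label
#'   array, 0 = background), `lesion_table` (tibble of per-lesion centers,
#'   radii, contrasts), `pixel_spacing_mm`, `slice_thickness_mm`, `abnormal`,
#'   `seed`.
#' @export
generate_study <- function(spec, abnormal = TRUE, seed = 1L) {
  validate_phantom_spec(spec)
  with_seed(seed, {
    n_slices <- sample(seq(spec$n_slices_range[1], spec$n_slices_range[2]), 1L)
    h <- spec$grid_shape[1]; w <- spec$grid_shape[2]
    jitter <- runif(2, -spec$liver_center_jitter_px, spec$liver_center_jitter_px)
    center_rc <- c((h + 1) / 2, (w + 1) / 2) + jitter
    liver <- render_liver(spec, n_slices, center_rc)

    labels <- array(0L, c(n_slices, h, w))
    lesion_rows <- list()
    if (abnormal) {
      n_lesions <- sample_lesion_count(spec, 1L)
      dx <- spec$pixel_spacing_mm
      dz <- dx * spec$slice_anisotropy
      placed <- list()  # (z, r, c, radius_mm)
      for (li in seq_len(n_lesions)) {
        ok <- FALSE
        for (try in seq_len(400L)) {
          radius <- runif(1, spec$lesion_radius_range_mm[1],
                          spec$lesion_radius_range_mm[2])
          z <- sample(seq_len(n_slices), 1L) + sample(c(0, 0.5), 1L)
          rpx <- radius / dx
          r <- runif(1, 1 + rpx, h - rpx)
          cc <- runif(1, 1 + rpx, w - rpx)
          vox <- rasterize_sphere(c(z, r, cc), radius, spec, n_slices,
                                  spec$lesion_slice_span_range[2])
          if (nrow(vox) == 0) next
          span <- length(unique(vox[, 1]))
          if (span < spec$lesion_slice_span_range[1]) next
          # whole pre-blur extent must lie inside the liver
          if (!all(liver[vox])) next
          # non-confluence: keep surfaces clearly separated (anisotropic metric)
          margin <- 2.5 * max(dx, dz)
          clash <- FALSE
          for (p in placed) {
            dist <- sqrt(((z - p[1]) * dz)^2 + ((r - p[2]) * dx)^2 +
                           ((cc - p[3]) * dx)^2)
            if (dist <= radius + p[4] + margin) { clash <- TRUE; break }
          }
          if (clash) next
          labels[vox] <- li
          placed[[length(placed) + 1L]] <- c(z, r, cc, radius)
          contrast <- runif(1, spec$lesion_contrast_range[1],
                            spec$lesion_contrast_range[2])
          lesion_rows[[li]] <- tibble::tibble(
            lesion_id = li, slice = z, row = r, col = cc,
            radius_mm = radius, contrast = contrast,
            n_voxels = nrow(vox)
          )
          ok <- TRUE
          break
        }
        if (!ok) {
          stop(sprintf(
            "lesion placement failed: could not fit lesion %d of %d non-confluent lesions inside the liver",
            li, n_lesions
          ))
        }
      }
    }
    lesion_table <- if (length(lesion_rows)) {
      dplyr::bind_rows(lesion_rows)
    } else {
      tibble::tibble(lesion_id = integer(), slice = numeric(), row = numeric(),
                     col = numeric(), radius_mm = numeric(),
                     contrast = numeric(), n_voxels = integer())
    }

    pet <- array(0, dim(liver))
    pet[liver] <- spec$background_mean
    if (nrow(lesion_table)) {
      for (li in lesion_table$lesion_id) {
        pet[labels == li] <- lesion_table$contrast[lesion_table$lesion_id == li] *
          spec$background_mean
      }
    }
    sigma_px <- spec$blur_fwhm_mm / (2 * sqrt(2 * log(2))) / spec$pixel_spacing_mm
    if (sigma_px > 0) {
      for (z in seq_len(n_slices)) {
        pet[z, , ] <- gauss_blur_2d(pet[z, , ], sigma_px)
      }
    }
    if (spec$noise_sigma > 0) {
      pet <- pet + array(rnorm(length(pet), 0, spec$noise_sigma), dim(pet))
      pet[pet < 0] <- 0
    }

    structure(
      list(
        pet = pet, liver = liver, lesions = labels,
        lesion_table = lesion_table,
        pixel_spacing_mm = spec$pixel_spacing_mm,
        slice_thickness_mm = spec$pixel_spacing_mm * spec$slice_anisotropy,
        abnormal = isTRUE(abnormal) && nrow(lesion_table) > 0,
        seed = as.integer(seed)
      ),
      class = "dotapet_study"
    )
  })
}

#' @export
print.dotapet_study <- function(x, ...) {
  d <- dim(x$pet)
  cat(sprintf(
    "<dotapet_study> %d slices of %dx%d px (%.3g mm), %s, %d lesion(s)\n",
    d[1], d[2], d[3], x$pixel_spacing_mm,
    if (x$abnormal) "abnormal" else "normal",
    nrow(x$lesion_table)
  ))
  invisible(x)
}

#' Generate a collection of synthetic studies
#'
#' Emits exactly `n_abnormal` abnormal and `n_normal` normal studies with
#' unique sequential five-digit numeric IDs and a per-study metadata tibble.
#'
#' @param spec a [phantom_spec()].
#' @param n_abnormal,n_normal study counts (non-negative).
#' @param seed master seed; per-study seeds are derived deterministically.
#' @return A list of class `dotapet_dataset`: `studies` (named list of
#'   [generate_study()] results) and `manifest` (tibble with `study_id`,
#'   `abnormal`, `n_slices`, `n_lesions`, `seed`).
#' @export
generate_dataset <- function(spec, n_abnormal, n_normal, seed = 1L) {
  stopifnot(n_abnormal >= 0, n_normal >= 0)
  n <- n_abnormal + n_normal
  flags <- rep(c(TRUE, FALSE), c(n_abnormal, n_normal))
  ids <- sprintf("%05d", 10000L + seq_len(n))
  study_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  studies <- vector("list", n)
  names(studies) <- ids
  for (i in seq_len(n)) {
    studies[[i]] <- generate_study(spec, abnormal = flags[i],
                                   seed = study_seeds[i])
  }
  manifest <- tibble::tibble(
    study_id = ids,
    abnormal = flags,
    n_slices = vapply(studies, function(s) dim(s$pet)[1], integer(1)),
    n_lesions = vapply(studies, function(s) nrow(s$lesion_table), integer(1)),
    seed = study_seeds
  )
  structure(list(studies = studies, manifest = manifest, spec = spec,
                 seed = as.integer(seed)),
            class = "dotapet_dataset")
}

#' @export
print.dotapet_dataset <- function(x, ...) {
  cat(sprintf("<dotapet_dataset> %d studies (%d abnormal, %d normal)\n",
              nrow(x$manifest), sum(x$manifest$abnormal),
              sum(!x$manifest$abnormal)))
  invisible(x)
}
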