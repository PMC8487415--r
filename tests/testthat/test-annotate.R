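test_that("the modified PERCIST threshold is exact arithmetic", {
  stats <- list(mean_activity = 10, sd_activity = 2)
  expect_identical(percist_threshold(stats)$value, 19)
  expect_identical(percist_threshold(list(mean_activity = 0,
                                          sd_activity = 0))$value, 0)
  expect_identical(percist_threshold(list(mean_activity = 4,
                                          sd_activity = 1))$value, 8)
})

test_that("background spheres report exact statistics on a uniform liver", {
  hard <- phantom_spec(noise_sigma = 0, blur_fwhm_mm = 0,
                       n_slices_range = c(23L, 25L))
  s <- generate_study(hard, abnormal = FALSE, seed = 4)
  st <- place_background_spheres(s)
  expect_equal(st$mean_activity, 100)
  expect_equal(st$sd_activity, 0)
  expect_equal(nrow(st$sphere_centers), 3L)
  expect_gt(st$n_pixels_sampled, 100)
})

test_that("sphere placement errors when the liver cannot host three spheres", {
  small <- array(0, c(10, 24, 24))
  liver <- array(FALSE, c(10, 24, 24))
  liver[3:8, 8:16, 8:16] <- TRUE  # too small for three 30 mm spheres at 4 mm
  small[liver] <- 50
  expect_error(place_background_spheres(small, liver, pixel_spacing_mm = 4,
                                        slice_thickness_mm = 4),
               "sphere")
})

test_that("pooled sphere SD tracks the phantom noise level", {
  spec <- test_spec()
  sds <- vapply(1:10, function(sd) {
    s <- generate_study(spec, abnormal = FALSE, seed = sd)
    place_background_spheres(s)$sd_activity
  }, numeric(1))
  expect_lt(abs(mean(sds) / spec$noise_sigma - 1), 0.10)
})

test_that("candidate detection groups supra-threshold voxels into 3D components", {
  d <- c(8, 20, 20)
  stack <- array(10, d)
  liver <- array(TRUE, d)
  thr <- percist_threshold(list(mean_activity = 10, sd_activity = 1))  # 17
  # everything below threshold -> empty
  cs <- detect_candidates(stack, liver, thr)
  expect_equal(nrow(cs$components), 0)
  # two separated blobs -> two components; bridge them -> one
  stack[3:5, 4:6, 4:6] <- 30
  stack[3:5, 12:14, 12:14] <- 30
  cs2 <- detect_candidates(stack, liver, thr)
  expect_equal(nrow(cs2$components), 2)
  for (k in 6:12) stack[4, k, k] <- 30  # diagonal bridge joins the blobs
  cs1 <- detect_candidates(stack, liver, thr)
  expect_equal(nrow(cs1$components), 1)
  # partition agrees with the flood-fill oracle (note oracle layout (H,W,D))
  bin <- (stack > thr$value) & liver
  orc <- oracle_label(aperm(array(as.integer(bin), d), c(2, 3, 1)))
  expect_true(same_partition(aperm(orc, c(3, 1, 2)), cs1$labels))
  # strict inequality at the boundary
  stack2 <- array(17, d)
  expect_equal(nrow(detect_candidates(stack2, liver, thr)$components), 0)
})

test_that("gradient-edge refinement recovers hard disk boundaries exactly", {
  hard <- phantom_spec(noise_sigma = 0, blur_fwhm_mm = 0,
                       n_slices_range = c(23L, 27L))
  for (sd in c(2, 9)) {
    s <- generate_study(hard, abnormal = TRUE, seed = sd)
    ann <- annotate_study(s)
    expect_identical(ann$lesions > 0, s$lesions > 0)
  }
})

test_that("per-ray boundary radius matches the 1D blurred-profile argmax oracle", {
  # Gaussian-blurred disk: radius 6 px, blur sigma 1.5 px, background 0
  h <- 48
  rr <- matrix(seq_len(h), h, h)
  cc <- t(rr)
  disk <- matrix(0, h, h)
  disk[(rr - 24.5)^2 + (cc - 24.5)^2 <= 6^2] <- 100
  blurred <- dotapet:::gauss_blur_2d(disk, 1.5)
  # 1D oracle: blurred step profile along a dense ray through the center
  prof_r <- seq(0, 15, by = 0.01)
  prof <- vapply(prof_r, function(r) {
    dotapet:::bilinear_at(blurred, 24.5, 24.5 + r)
  }, numeric(1))
  oracle_radius <- prof_r[which.min(diff(prof))]
  for (th in c(0, pi / 3, 5 * pi / 4)) {
    rb <- dotapet:::ray_boundary_radius(blurred, 24.5, 24.5, th,
                                        bg_level = 10)
    expect_lt(abs(rb - oracle_radius), 1)
  }
})

test_that("refinement keeps the peak voxel and handles degenerate components", {
  spec <- test_spec()
  checked <- 0L
  for (sd in 1:4) {
    s <- generate_study(spec, abnormal = TRUE, seed = sd)
    st <- place_background_spheres(s)
    thr <- percist_threshold(st)
    cs <- detect_candidates(s$pet, s$liver, thr)
    for (i in seq_len(nrow(cs$components))) {
      comp <- component_voxels(cs, i)
      ref <- gradient_edge_refine(s$pet, comp, bg_level = thr$value)
      pk <- comp$peak
      hit <- any(ref$voxels[, 1] == pk[1] & ref$voxels[, 2] == pk[2] &
                   ref$voxels[, 3] == pk[3])
      expect_true(hit)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 3L)
  # degenerate single-voxel component comes back unchanged with a warning note
  one <- list(voxels = cbind(slice = 3L, row = 5L, col = 5L),
              peak = c(3L, 5L, 5L))
  out <- gradient_edge_refine(array(1, c(6, 10, 10)), one, bg_level = 0.5)
  expect_identical(out$voxels, one$voxels)
  expect_match(out$warning, "degenerate")
})

test_that("annotate_study recovers exactly the detectable lesions", {
  quiet <- phantom_spec(noise_sigma = 0)
  s <- generate_study(quiet, abnormal = TRUE, seed = 6)
  ann <- annotate_study(s)
  expect_equal(nrow(ann$components), nrow(s$lesion_table))
  expect_true(all(ann$components$peak_activity > ann$threshold$value))

  nrm <- generate_study(quiet, abnormal = FALSE, seed = 6)
  ann0 <- annotate_study(nrm)
  expect_equal(nrow(ann0$components), 0)
  expect_true(all(ann0$lesions == 0))

  # a lesion whose contrast sits below the PERCIST threshold is absent
  faint <- phantom_spec(noise_sigma = 0, lesion_contrast_range = c(1.2, 1.3),
                        ensure_detectable = FALSE)
  sf <- generate_study(faint, abnormal = TRUE, seed = 8)
  annf <- annotate_study(sf)
  expect_equal(nrow(annf$components), 0)
})

test_that("raising a lesion's uptake never removes it from the annotation", {
  quiet <- phantom_spec(noise_sigma = 0)
  s <- generate_study(quiet, abnormal = TRUE, seed = 9)
  base <- annotate_study(s)
  boosted <- s
  boosted$pet[s$lesions > 0] <- boosted$pet[s$lesions > 0] * 1.5
  up <- annotate_study(boosted)
  expect_gte(nrow(up$components), nrow(base$components))
  # every true lesion still recovered
  m <- match_lesions(dotapet:::gold_volume_components(up$lesions),
                     dotapet:::gold_volume_components(s$lesions), 0.05)
  expect_equal(m$fn, 0)
})
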