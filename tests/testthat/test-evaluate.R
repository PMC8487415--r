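grid3 <- c(4L, 10L, 10L)

vox_rect <- function(slice, rows, cols) {
  g <- expand.grid(row = rows, col = cols)
  cbind(slice = slice, row = g$row, col = g$col)
}

test_that("IoU matches brute-force pixel counting", {
  a <- vox_rect(1, 1:3, 1:4)  # 12 px
  expect_equal(iou(a, a, grid3), 1)
  b <- vox_rect(2, 1:3, 1:4)
  expect_equal(iou(a, b, grid3), 0)
  # 9 px vs 9 px sharing two columns: |intersection| = 6, |union| = 12
  c1 <- vox_rect(1, 1:3, 1:3)
  c2 <- vox_rect(1, 1:3, 2:4)
  expect_equal(iou(c1, c2, grid3), 0.5)
  expect_equal(iou(matrix(integer(0), 0, 3), matrix(integer(0), 0, 3),
                   grid3), 0)
})

test_that("greedy one-to-one matching honors the strict IoU rule", {
  d <- c(2L, 20L, 20L)
  mk <- function(masks) cs_from_masks(masks, d)
  blob <- function(slice, rows, cols) {
    m <- array(FALSE, d)
    m[slice, rows, cols] <- TRUE
    m
  }
  # identical sets of k lesions
  gold <- mk(list(blob(1, 1:3, 1:3), blob(2, 10:12, 10:12)))
  m <- match_lesions(gold, gold, 0.05)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))
  expect_equal(nrow(tidy(m)), 2)
  # one prediction, one gold, intersection 1 px, union 25 px:
  # IoU = 1/25 = 0.04 <= 0.05 is rejected by the strict rule
  p <- mk(list(blob(1, 1:13, 1)))       # 13 px column
  g_mask <- array(FALSE, d)             # 13 px, sharing exactly (13, 1)
  g_mask[1, 13:18, 1] <- TRUE
  g_mask[1, 13:19, 2] <- TRUE
  g <- mk(list(g_mask))
  mm <- match_lesions(p, g, 0.05)
  expect_equal(sum(p$components$area), 13)
  expect_equal(sum(g$components$area), 13)
  expect_equal(iou(p$components$voxels[[1]], g$components$voxels[[1]], d),
               0.04)
  expect_equal(c(mm$tp, mm$fp, mm$fn), c(0L, 1L, 1L))
  # two predictions over one gold: exactly one TP, one FP
  p2 <- mk(list(blob(1, 1:3, 1:3), blob(1, 5:7, 1:3)))
  g2 <- mk(list(blob(1, 1:7, 1:3)))
  m2 <- match_lesions(p2, g2, 0.05)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 0L))
})

test_that("matching counts agree with an exhaustive oracle on random cases", {
  set.seed(61)
  d <- c(3L, 16L, 16L)
  for (rep in 1:25) {
    mk_masks <- function(k) {
      lapply(seq_len(k), function(i) {
        m <- array(FALSE, d)
        z <- sample(3, 1)
        r0 <- sample(12, 1); c0 <- sample(12, 1)
        m[z, r0:(r0 + sample(3, 1)), c0:(c0 + sample(3, 1))] <- TRUE
        m
      })
    }
    # predictions must be disjoint (they come from component labeling);
    # enforce by subtracting earlier masks
    preds <- mk_masks(sample(0:4, 1))
    if (length(preds) > 1) {
      for (i in 2:length(preds)) {
        for (j in 1:(i - 1)) preds[[i]] <- preds[[i]] & !preds[[j]]
      }
      preds <- preds[vapply(preds, any, logical(1))]
    }
    golds <- mk_masks(sample(0:4, 1))
    if (length(golds) > 1) {
      for (i in 2:length(golds)) {
        for (j in 1:(i - 1)) golds[[i]] <- golds[[i]] & !golds[[j]]
      }
      golds <- golds[vapply(golds, any, logical(1))]
    }
    m <- match_lesions(cs_from_masks(preds, d), cs_from_masks(golds, d), 0.05)
    o <- oracle_match(preds, golds, 0.05)
    expect_equal(m$tp, o$tp)
    expect_equal(m$fp, o$fp)
    expect_equal(m$fn, o$fn)
    # conservation identities
    expect_equal(m$tp + m$fp, length(preds))
    expect_equal(m$tp + m$fn, length(golds))
  }
})

test_that("PPV, sensitivity and F1 follow the documented conventions", {
  expect_equal(ppv_sensitivity_f1(list(tp = 1, fp = 0, fn = 0)),
               c(ppv = 1, sensitivity = 1, f1 = 1))
  expect_equal(ppv_sensitivity_f1(list(tp = 0, fp = 1, fn = 1)),
               c(ppv = 0, sensitivity = 0, f1 = 0))
  expect_equal(ppv_sensitivity_f1(list(tp = 0, fp = 0, fn = 0)),
               c(ppv = 1, sensitivity = 1, f1 = 1))
  expect_equal(ppv_sensitivity_f1(list(tp = 0, fp = 0, fn = 2)),
               c(ppv = 0, sensitivity = 0, f1 = 0))
  # harmonic mean arithmetic: ppv 0.75, sens 0.6 -> 0.6667
  m <- list(tp = 3, fp = 1, fn = 2)
  met <- ppv_sensitivity_f1(m)
  expect_equal(met[["ppv"]], 0.75)
  expect_equal(met[["sensitivity"]], 0.6)
  expect_equal(met[["f1"]], 2 * 0.45 / 1.35, tolerance = 1e-12)
})

test_that("PR curves hit the trivial endpoints", {
  d <- c(3L, 16L, 16L)
  gold <- array(0L, d)
  gold[1, 3:7, 3:7] <- 1L
  gold[2, 3:7, 3:7] <- 1L
  # perfect detector: scores 1 on gold, 0 elsewhere
  perfect <- array(0, d)
  perfect[gold > 0] <- 1
  pr <- pr_curve(list(perfect), list(gold), area_filter_px = 5L,
                 thresholds = seq(0.1, 0.9, by = 0.2))
  expect_equal(pr$auc, 1)
  # silent detector
  none <- array(0, d)
  pr0 <- pr_curve(list(none), list(gold), area_filter_px = 5L,
                  thresholds = seq(0.1, 0.9, by = 0.2))
  expect_equal(pr0$auc, 0)
})

test_that("sensitivity is non-increasing in the area filter on fixed predictions", {
  set.seed(77)
  spec <- test_spec()
  golds <- list()
  preds <- list()
  for (i in 1:3) {
    s <- generate_study(spec, abnormal = TRUE, seed = 400 + i)
    golds[[i]] <- s$lesions
    # surrogate score map: noisy gold with blur, so components shrink as
    # thresholds/filters grow
    sc <- array(0, dim(s$lesions))
    for (z in seq_len(dim(sc)[1])) {
      sc[z, , ] <- dotapet:::gauss_blur_2d((s$lesions[z, , ] > 0) * 1, 1)
    }
    sc <- pmin(sc + array(runif(length(sc), 0, 0.04), dim(sc)), 1)
    preds[[i]] <- sc
  }
  prev <- Inf
  for (f in c(5, 7, 10, 15, 20)) {
    r <- evaluate_detections(preds, golds,
                             detection_config(binarize_threshold = 0.3,
                                              area_filter_px = f))
    expect_lte(r$sensitivity, prev)
    prev <- r$sensitivity
  }
})

test_that("replicate aggregation reports mean, n-1 SD and both F1 orderings", {
  recs <- tibble::tibble(
    replicate = rep(1:5, times = 2),
    filter_px = rep(c(5L, 20L), each = 5),
    ppv = c(rep(0.7, 5), c(0.9, 0.9, 0.9, 0.9, 0.9)),
    sensitivity = c(rep(0.7, 5), c(0.6, 0.8, 0.6, 0.8, 0.7)),
    f1 = c(rep(0.7, 5), c(0.6, 0.8, 0.6, 0.8, 0.7))
  )
  agg <- aggregate_runs(recs)
  long <- tidy(agg)
  ident <- long[long$metric == "ppv" & long$filter_px == 5L, ]
  expect_equal(ident$mean, 0.7)
  expect_equal(ident$sd, 0)
  spread <- long[long$metric == "sensitivity" & long$filter_px == 20L, ]
  expect_equal(spread$mean, 0.7)
  expect_equal(spread$sd, sd(c(0.6, 0.8, 0.6, 0.8, 0.7)))
  # two-value hand case
  two <- aggregate_runs(tibble::tibble(replicate = 1:2, filter_px = 5L,
                                       ppv = c(0.6, 0.8),
                                       sensitivity = c(0.6, 0.8),
                                       f1 = c(0.6, 0.8)))
  row <- tidy(two)
  expect_equal(row$mean[row$metric == "f1"], 0.7)
  expect_equal(row$sd[row$metric == "f1"], 0.1414, tolerance = 1e-3)
  # single replicate: SD undefined, flagged NA
  one <- aggregate_runs(tibble::tibble(replicate = 1L, filter_px = 5L,
                                       ppv = 0.5, sensitivity = 0.5,
                                       f1 = 0.5))
  expect_true(all(is.na(tidy(one)$sd[tidy(one)$metric == "ppv"])))
  # f1 recomputed from mean ppv/sensitivity is reported alongside
  fom <- long[long$metric == "f1_of_means" & long$filter_px == 20L, ]
  expect_equal(fom$mean, 2 * 0.9 * 0.7 / 1.6, tolerance = 1e-12)
})
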