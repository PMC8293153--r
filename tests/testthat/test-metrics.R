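test_that("perfect segmentation scores 1 on every metric", {
  ph <- generate_phantom(phantom_spec(n_subunits = 3, seed = 17,
                                      grid_shape = c(24L, 24L, 24L)))
  truth <- ph$truth
  expect_equal(matched_iou(truth, truth, "all")$value, 1.0)
  expect_equal(matched_iou(truth, truth, "matched_only")$value, 1.0)
  expect_equal(homogeneity(truth, truth), 1.0)
  expect_equal(proportion_segments(truth, truth), 1.0)
  expect_identical(consistency(truth, truth, "largest_volume"), 1L)
  expect_identical(consistency(truth, truth, "max_si"), 1L)
})

test_that("matched IoU is invariant to label permutations of either side", {
  ph <- generate_phantom(phantom_spec(n_subunits = 2, seed = 23))
  truth <- ph$truth
  swapped <- truth$labels
  swapped[truth$labels == 1L] <- 2L
  swapped[truth$labels == 2L] <- 1L
  swapped <- label_map(swapped)
  expect_equal(matched_iou(swapped, truth, "all")$value, 1.0)

  ws <- watershed_segment(ph$map)
  k <- n_segments(ws)
  perm <- withr::with_seed(3, sample(k))
  relab <- array(0L, dim(ws$labels))
  relab[ws$labels > 0L] <- perm[ws$labels[ws$labels > 0L]]
  expect_equal(matched_iou(label_map(relab), truth, "all")$value,
               matched_iou(ws, truth, "all")$value)
})

test_that("the 8-voxel worked example reproduces all hand counts", {
  toy <- toy_eight()
  m <- matched_iou(toy$pred, toy$truth, "matched_only")
  expect_equal(m$value, 0.6)
  expect_equal(sort(m$matching$iou), c(0.6, 0.6))
  expect_equal(matched_iou(toy$pred, toy$truth, "all")$value, 0.6)
  expect_equal(homogeneity(toy$pred, toy$truth), 0.75)
  expect_equal(proportion_segments(toy$pred, toy$truth), 2.0)
  expect_identical(consistency(toy$pred, toy$truth, "largest_volume"), 2L)
  expect_identical(consistency(toy$pred, toy$truth, "max_si"), 2L)
})

test_that("assignment matching equals exhaustive permutation on random maps", {
  withr::with_seed(777, {
    for (trial in 1:100) {
      d <- c(6L, 6L, 2L)
      p <- sample(0:sample(2:6, 1), prod(d), replace = TRUE)
      t <- sample(0:sample(2:6, 1), prod(d), replace = TRUE)
      pred <- canonicalize_labels(label_map(array(p, d)))
      truth <- canonicalize_labels(label_map(array(t, d)))
      if (n_segments(pred) == 0L || n_segments(truth) == 0L) next
      expect_equal(matched_iou(pred, truth, "all")$value,
                   oracle_matched_iou_all(pred, truth),
                   tolerance = 1e-12)
    }
  })
})

test_that("matched-only IoU never falls below the all-slots IoU", {
  withr::with_seed(31, {
    for (trial in 1:20) {
      d <- c(8L, 8L, 2L)
      pred <- canonicalize_labels(label_map(array(
        sample(0:5, prod(d), replace = TRUE), d)))
      truth <- canonicalize_labels(label_map(array(
        sample(0:3, prod(d), replace = TRUE), d)))
      if (n_segments(pred) == 0L || n_segments(truth) == 0L) next
      expect_gte(matched_iou(pred, truth, "matched_only")$value,
                 matched_iou(pred, truth, "all")$value)
    }
  })
})

test_that("homogeneity penalizes segments that straddle subunits", {
  # one predicted segment covering two equal truth segments: half the voxels
  # are false positives
  truth <- array(0L, c(8L, 2L, 1L))
  truth[1:4, , 1] <- 1L
  truth[5:8, , 1] <- 2L
  pred <- array(0L, c(8L, 2L, 1L))
  pred[1:8, , 1] <- 1L
  expect_equal(homogeneity(label_map(pred), label_map(truth)), 0.5)
  expect_error(homogeneity(label_map(array(0L, c(2L, 2L, 2L))),
                           label_map(truth)), "foreground")
})

test_that("proportion counts splits per subunit; consistency variants differ", {
  # each truth segment split into exactly 3 predictions -> P = 3
  truth <- array(0L, c(9L, 2L, 1L))
  truth[1:9, 1, 1] <- 1L
  truth[1:9, 2, 1] <- 2L
  pred <- array(0L, c(9L, 2L, 1L))
  pred[, 1, 1] <- rep(1:3, each = 3L)
  pred[, 2, 1] <- rep(4:6, each = 3L)
  expect_equal(proportion_segments(label_map(pred), label_map(truth)), 3.0)

  # big subunit hit by 1 prediction, small one by 4: the variants separate
  truth2 <- array(0L, c(12L, 1L, 1L))
  truth2[1:8, 1, 1] <- 1L
  truth2[9:12, 1, 1] <- 2L
  pred2 <- array(0L, c(12L, 1L, 1L))
  pred2[1:8, 1, 1] <- 1L
  pred2[9:12, 1, 1] <- c(2L, 3L, 4L, 5L)
  expect_identical(consistency(label_map(pred2), label_map(truth2),
                               "largest_volume"), 1L)
  expect_identical(consistency(label_map(pred2), label_map(truth2),
                               "max_si"), 4L)
  # and with the default variant C can be below P
  expect_lt(consistency(label_map(pred2), label_map(truth2)),
            proportion_segments(label_map(pred2), label_map(truth2)))
})

test_that("volume ratio filter keeps the inclusive 0.8-1.2 window", {
  expect_true(volume_ratio_filter(100, 100))
  expect_false(volume_ratio_filter(50, 100))
  expect_true(volume_ratio_filter(80, 100))     # boundary is inclusive
  expect_true(volume_ratio_filter(120, 100))
  expect_false(volume_ratio_filter(121, 100))
  expect_error(volume_ratio_filter(0, 10), "positive")
})

test_that("evaluate_segmentation assembles a coherent tidy report", {
  toy <- toy_eight()
  rep <- evaluate_segmentation(toy$pred, toy$truth)
  td <- tidy(rep)
  expect_equal(td$matched_iou_matched_only, 0.6)
  expect_equal(td$homogeneity, 0.75)
  expect_equal(td$proportion, 2.0)
  expect_equal(td$consistency, 2L)
  expect_equal(td$n_predicted, 2L)
  expect_gte(td$matched_iou_matched_only, td$matched_iou_all)
})
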