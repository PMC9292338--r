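test_that("homographies fit and apply exactly on known correspondences", {
  H <- rbind(c(1.1, 0.05, 12), c(-0.04, 0.95, -7), c(1e-4, -2e-4, 1))
  src <- cbind(c(0, 100, 100, 0, 37, 81), c(0, 0, 80, 80, 11, 63))
  dst <- apply_homography(H, src)
  Hf <- homography_from_points(src, dst)
  expect_equal(Hf / Hf[3, 3], H / H[3, 3], tolerance = 1e-8)
  expect_equal(apply_homography(Hf, src), dst, tolerance = 1e-6)
})

test_that("feature extraction is deterministic and respects bounds", {
  card <- paint_card_template(default_layout())
  f1 <- extract_features(card)
  f2 <- extract_features(card)
  expect_identical(f1$keypoints, f2$keypoints)
  expect_identical(f1$descriptors, f2$descriptors)
  expect_gt(nrow(f1$keypoints), 50)
  expect_identical(nrow(f1$keypoints), nrow(f1$descriptors))
  expect_true(all(f1$keypoints$x >= 0 & f1$keypoints$x < dim(card)[1]))
  expect_true(all(f1$keypoints$y >= 0 & f1$keypoints$y < dim(card)[2]))
  expect_true(all(f1$descriptors %in% c(0L, 1L)))
})

test_that("a featureless image yields an empty feature set", {
  flat <- matrix(0.5, 120, 90)
  f <- extract_features(flat)
  expect_identical(nrow(f$keypoints), 0L)
  expect_identical(nrow(f$descriptors), 0L)
})

test_that("an untransformed template paste is recovered to within 2 px", {
  layout <- small_layout()
  card <- paint_card_template(layout)
  cw <- dim(card)[1]; ch <- dim(card)[2]
  scene <- array(0.35, dim = c(420, 300, 3))
  dx <- 95; dy <- 60
  scene[dx + seq_len(cw), dy + seq_len(ch), ] <- card
  res <- detect_and_rectify(scene, card, seed = 3)
  want <- rbind(c(0, 0), c(cw - 1, 0), c(cw - 1, ch - 1), c(0, ch - 1)) +
    matrix(c(dx, dy), 4, 2, byrow = TRUE)
  expect_lt(max(abs(res$detection$corners - want)), 2)
  expect_lte(res$detection$n_inliers, res$detection$n_matches_kept)

  # translation equivariance: shifting the paste shifts the corners
  scene2 <- array(0.35, dim = c(420, 300, 3))
  scene2[dx + 17 + seq_len(cw), dy + 9 + seq_len(ch), ] <- card
  res2 <- detect_and_rectify(scene2, card, seed = 3)
  shift <- res2$detection$corners - res$detection$corners
  expect_lt(max(abs(shift - matrix(c(17, 9), 4, 2, byrow = TRUE))), 1)
})

test_that("warp consistency: the homography maps corners to the canonical frame", {
  layout <- default_layout()
  card <- paint_card_template(layout)
  sc <- render_scene(layout, clean_config(301))
  res <- detect_and_rectify(sc$image, card, seed = 5)
  canon <- apply_homography(res$detection$homography, res$detection$corners)
  want <- rbind(c(0, 0), c(dim(card)[1] - 1, 0),
                c(dim(card)[1] - 1, dim(card)[2] - 1), c(0, dim(card)[2] - 1))
  expect_lt(max(abs(canon - want)), 1e-3)
  # and the corners sit on the true quad
  err <- sqrt(rowSums((res$detection$corners - sc$truth$card_quad)^2))
  expect_lt(max(err), 3)
})

test_that("a scene without the card signals a detection failure", {
  layout <- small_layout()
  card <- paint_card_template(layout)
  set.seed(8)
  scene <- stripreader:::render_background(300, 220, "photo-like")
  err <- tryCatch(detect_and_rectify(scene, card, seed = 1),
                  error = function(e) e)
  expect_s3_class(err, "detection_failure")
  expect_true(is.list(err$diagnostics))
  expect_true("n_matches_kept" %in% names(err$diagnostics))
})

test_that("hamming matching returns sorted best matches", {
  card <- paint_card_template(default_layout())
  f <- extract_features(card, max_features = 120)
  m <- match_features(f, f, n_keep = 50)
  expect_identical(nrow(m), 50L)
  expect_true(all(m$dist == 0))
  expect_identical(m$i, m$j)  # self-matching is the identity
  expect_true(!is.unsorted(m$dist))
})
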