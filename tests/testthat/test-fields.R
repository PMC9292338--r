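test_that("reference fields come off the card at constant coordinates", {
  layout <- small_layout()
  card <- paint_card_template(layout)
  patches <- extract_reference_fields(card, layout)
  expect_length(patches, stripreader:::n_levels_total(layout))
  for (fp in patches) {
    want <- stripreader:::hex_to_rgb(
      layout$parameters[[fp$parameter]]$levels[[fp$level]]$color)
    got <- apply(fp$pixels, 3, mean)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # doubled rectified size: same colors at doubled coordinates
  big <- stripreader:::resize_image(card, 2 * dim(card)[1], 2 * dim(card)[2])
  patches2 <- extract_reference_fields(big, layout)
  for (i in seq_along(patches)) {
    expect_equal(patches2[[i]]$origin[1:2], 2 * patches[[i]]$origin[1:2],
                 tolerance = 1e-9)
    expect_equal(apply(patches2[[i]]$pixels, 3, mean),
                 apply(patches[[i]]$pixels, 3, mean), tolerance = 1e-3)
  }
  expect_error(extract_reference_fields(card[1:5, 1:5, , drop = FALSE], layout),
               "smaller than 10 px")
})

test_that("candidate squares cover every field of a clean strip", {
  layout <- default_layout()
  strip <- paint_strip_template(layout)
  cands <- find_candidate_squares(strip)
  expect_gt(length(cands), 0)
  for (cand in cands) {
    expect_gte(cand$aspect, 1)
    expect_lte(cand$aspect, 1.06)
    expect_gte(cand$side, 0.2 * dim(strip)[2])
  }
  rects <- stripreader:::strip_field_rects(layout)
  centers <- do.call(rbind, lapply(cands, `[[`, "center"))
  for (r in rects) {
    hit <- centers[, 1] >= r[1] & centers[, 1] <= r[1] + r[3] &
      centers[, 2] >= r[2] & centers[, 2] <= r[2] + r[4]
    expect_true(any(hit))
  }
})

test_that("blank and non-square images yield no candidates", {
  blank <- array(1, dim = c(200, 50, 3))
  expect_length(find_candidate_squares(blank), 0L)
  # a single 2:1 rectangle fails the aspect filter
  rect_img <- array(0.95, dim = c(200, 60, 3))
  rect_img <- stripreader:::fill_rect(rect_img, c(40, 10, 80, 40),
                                      c(0.2, 0.3, 0.8))
  expect_length(find_candidate_squares(rect_img), 0L)
})

test_that("k-means with the elbow rule recovers well-separated blobs", {
  set.seed(11)
  blob <- function(cx, cy, n, r) cbind(cx + rnorm(n, 0, r), cy + rnorm(n, 0, r))
  pts <- rbind(blob(0, 0, 10, 0.5), blob(50, 0, 10, 0.5), blob(100, 5, 10, 0.5))
  centers <- cluster_field_centers(pts, k_max = 8, seed = 4)
  expect_identical(nrow(centers), 3L)
  means <- rbind(colMeans(pts[1:10, ]), colMeans(pts[11:20, ]),
                 colMeans(pts[21:30, ]))
  for (i in 1:3) {
    d <- sqrt(rowSums(sweep(means, 2, centers[i, ])^2))
    expect_lt(min(d), 1)
  }
  # four blobs: the elbow picks k = 4
  pts4 <- rbind(blob(0, 0, 10, 0.4), blob(40, 0, 10, 0.4),
                blob(80, 0, 10, 0.4), blob(120, 0, 10, 0.4))
  expect_identical(nrow(cluster_field_centers(pts4, k_max = 8, seed = 4)), 4L)
  # five identical points collapse to one center
  same <- matrix(c(7, 3), 5, 2, byrow = TRUE)
  c1 <- cluster_field_centers(same, k_max = 4, seed = 1)
  expect_identical(nrow(c1), 1L)
  expect_equal(c1[1, ], c(7, 3))
  expect_error(cluster_field_centers(matrix(numeric(0), 0, 2), 3, 1))
})

test_that("clustering matches exhaustive optimal assignments on small instances", {
  # brute force: enumerate all assignments of n points to k clusters and
  # minimize the within-cluster sum of squares
  brute_wcss <- function(pts, k) {
    n <- nrow(pts)
    best <- Inf
    grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
    for (r in seq_len(nrow(grid))) {
      a <- as.integer(grid[r, ])
      if (length(unique(a)) < k) next
      w <- 0
      for (j in seq_len(k)) {
        sub <- pts[a == j, , drop = FALSE]
        w <- w + sum(sweep(sub, 2, colMeans(sub))^2)
      }
      best <- min(best, w)
    }
    best
  }
  set.seed(21)
  for (case in 1:5) {
    k <- sample(2:3, 1)
    n <- sample(6:9, 1)
    pts <- matrix(runif(2 * n, 0, 60), n, 2)
    centers <- stripreader:::with_seed(case, stripreader:::kmeans_pp(pts, k))
    d2 <- sapply(seq_len(k), function(j) rowSums(sweep(pts, 2, centers$centers[j, ])^2))
    expect_equal(centers$tot.withinss, brute_wcss(pts, k), tolerance = 1e-6)
  }
})

test_that("clustering is invariant to the input point order", {
  set.seed(31)
  pts <- rbind(cbind(rnorm(8, 0, 0.5), rnorm(8, 0, 0.5)),
               cbind(rnorm(8, 30, 0.5), rnorm(8, 0, 0.5)),
               cbind(rnorm(8, 60, 0.5), rnorm(8, 0, 0.5)))
  a <- cluster_field_centers(pts, k_max = 6, seed = 9)
  b <- cluster_field_centers(pts[nrow(pts):1, ], k_max = 6, seed = 9)
  sort_rows <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
  expect_equal(sort_rows(a), sort_rows(b), tolerance = 1e-6)
})

test_that("grid completion fills gaps and extrapolates as specified", {
  # gap of two pitches: one midpoint inserted
  centers <- cbind(c(0, 10, 20, 30, 50, 60, 70, 80, 90), 0)
  g <- complete_field_grid(centers, 10)
  expect_equal(g$n_inserted, 1)
  expect_equal(g$centers[, 1], seq(0, 90, by = 10), tolerance = 1e-9)
  expect_equal(g$centers[5, ], c(40, 0), tolerance = 1e-9)
  # complete grid passes through unchanged
  full <- cbind(seq(0, 90, by = 10), 5)
  g2 <- complete_field_grid(full, 10)
  expect_equal(g2$n_inserted, 0)
  expect_equal(g2$centers, full, tolerance = 1e-9)
  # short run: one point extrapolated at each end
  g3 <- complete_field_grid(cbind(seq(0, 70, by = 10), 0), 10)
  expect_equal(g3$n_inserted, 2)
  expect_equal(g3$centers[, 1], seq(-10, 80, by = 10), tolerance = 1e-9)
  # idempotence
  g4 <- complete_field_grid(g3$centers, 10)
  expect_equal(g4$centers, g3$centers, tolerance = 1e-9)
  expect_equal(g4$n_inserted, 0)
})

test_that("grid completion honours bounds when choosing the end", {
  short <- cbind(seq(20, 90, by = 10), 0)  # 8 fields, low end at x = 20
  # without bounds the first extrapolation goes low
  free <- complete_field_grid(short, 10)
  expect_equal(free$centers[1, 1], 10, tolerance = 1e-9)
  # bounds starting at x = 15 force both extrapolations high
  bounded <- complete_field_grid(short, 10, bounds = c(15, 300, -5, 5))
  expect_equal(bounded$centers[, 1], seq(20, 110, by = 10), tolerance = 1e-9)
})

test_that("grid completion rejects degenerate input", {
  expect_error(complete_field_grid(matrix(c(4, 4, 2, 2), 2, 2), 5),
               "identical")
  # needing more than half the fields extrapolated is a failure
  expect_error(complete_field_grid(cbind(c(0, 10), 0), 10),
               class = "grid_completion_failure")
})

test_that("test fields are located and ordered on a clean strip", {
  layout <- default_layout()
  cfg <- scene_config(seed = 6101, warp_magnitude = 0.03, blur_sigma_px = 0.5,
                      brightness_delta = 0, noise_sigma = 0.005)
  sc <- render_strip_crop(layout, cfg)
  patches <- locate_test_fields(sc$image, layout, seed = 2)
  expect_length(patches, 10L)
  expect_identical(vapply(patches, `[[`, character(1), "parameter"),
                   names(layout$parameters))
  grid <- attr(patches, "grid")
  for (i in seq_along(patches)) {
    quad <- sc$truth$field_rects[[i]]
    expect_true(stripreader:::points_in_poly(grid$centers[i, 1],
                                             grid$centers[i, 2], quad))
    got <- hsv_peak(patches[[i]])
    expect_peak_equal(got, sc$truth$planted_colors[[i]], tol_h = 10,
                      tol_sv = 0.1)
  }
})

test_that("degraded fields are completed from the grid", {
  layout <- default_layout()
  cfg <- scene_config(seed = 6202, warp_magnitude = 0.03, blur_sigma_px = 0.5,
                      brightness_delta = 0, noise_sigma = 0.005,
                      degrade_fields = c("ketone", "protein"))
  sc <- render_strip_crop(layout, cfg)
  patches <- locate_test_fields(sc$image, layout, seed = 2)
  expect_length(patches, 10L)
  grid <- attr(patches, "grid")
  expect_gte(grid$n_inserted, 2)
  hits <- vapply(seq_along(patches), function(i) {
    stripreader:::points_in_poly(grid$centers[i, 1], grid$centers[i, 2],
                                 sc$truth$field_rects[[i]])
  }, logical(1))
  expect_true(all(hits))
})

test_that("a rotated strip is read identically along its axis", {
  layout <- default_layout()
  strip <- paint_strip_template(layout)
  rot <- aperm(strip, c(2, 1, 3))[, dim(strip)[1]:1, , drop = FALSE]
  p1 <- locate_test_fields(strip, layout, seed = 3)
  p2 <- locate_test_fields(rot, layout, seed = 3)
  g1 <- attr(p1, "grid"); g2 <- attr(p2, "grid")
  # the 90-degree rotation maps (x, y) -> (y, H - 1 - x); order along the
  # axis is preserved up to global reversal
  mapped <- cbind(g1$centers[, 2], dim(strip)[1] - 1 - g1$centers[, 1])
  d_fwd <- max(abs(g2$centers - mapped))
  d_rev <- max(abs(g2$centers - mapped[nrow(mapped):1, ]))
  expect_lt(min(d_fwd, d_rev), 2)
})
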