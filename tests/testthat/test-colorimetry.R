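const_patch <- function(rgb, w = 12, h = 12) {
  array(rep(rgb, each = w * h), dim = c(w, h, 3))
}

test_that("hsv_peak reads a constant patch to within one histogram bin", {
  p <- hsv_peak(const_patch(c(1, 0, 0)))  # pure red
  expect_lt(min(p$h %% 360, 360 - p$h %% 360), 1)
  expect_gt(p$s, 1 - 2 / 256)
  expect_gt(p$v, 1 - 2 / 256)
  # achromatic convention: gray reports hue 0
  g <- hsv_peak(const_patch(c(0.5, 0.5, 0.5)))
  expect_identical(g$h, 0)
  expect_lt(g$s, 1 / 256)
})

test_that("hsv_peak is the per-channel histogram mode", {
  # 70/30 two-color patch resolves to the majority color
  a <- c(0.8, 0.3, 0.1); b <- c(0.1, 0.5, 0.9)
  px <- array(0, dim = c(10, 10, 3))
  for (c in 1:3) px[, , c] <- b[c]
  for (c in 1:3) px[1:7, , c] <- a[c]
  pk <- hsv_peak(px)
  ha <- grDevices::rgb2hsv(a[1], a[2], a[3], maxColorValue = 1)
  expect_peak_equal(pk, hsv_peak_value(ha[1] * 360, ha[2], ha[3]))

  # against a brute-force per-channel mode count on random patches
  for (seed in 1:10) {
    set.seed(seed)
    px <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
    pk <- hsv_peak(px)
    hsv <- grDevices::rgb2hsv(rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                                    as.vector(px[, , 3])), maxColorValue = 1)
    mode_of <- function(vals, nbins, scale) {
      bins <- pmin(floor(vals * scale), nbins - 1)
      counts <- table(factor(bins, levels = 0:(nbins - 1)))
      as.integer(names(counts)[which.max(counts)])
    }
    expect_equal(pk$h, mode_of(hsv[1, ] %% 1 * 360, 360, 1) + 0.5)
    expect_equal(pk$s, (mode_of(hsv[2, ], 256, 256) + 0.5) / 256)
    expect_equal(pk$v, (mode_of(hsv[3, ], 256, 256) + 0.5) / 256)
  }
})

test_that("hsv_peak rejects empty patches", {
  expect_error(hsv_peak(array(0, dim = c(0, 4, 3))), "empty")
})

test_that("hue similarity follows the circular difference formula", {
  pk <- function(h, s = 0.8, v = 0.8) hsv_peak_value(h, s, v)
  expect_identical(similarity_hue(pk(120), pk(120)), 1)
  expect_equal(similarity_hue(pk(0), pk(180)), 0.5)
  # wrap-around: 350 vs 10 degrees differ by 20, not 340
  expect_equal(similarity_hue(pk(350), pk(10)), 1 - 20 / 360)
  # invariant under saturation and value of either argument
  expect_equal(similarity_hue(pk(40, 0.2, 0.9), pk(200, 0.9, 0.1)),
               similarity_hue(pk(40, 0.7, 0.3), pk(200, 0.31, 0.99)))
})

test_that("hue similarity guards achromatic colors", {
  a <- hsv_peak_value(0, 0.01, 0.5)
  b <- hsv_peak_value(180, 0.8, 0.5)
  # falls back to saturation/value terms: 1 - beta * dS / 3
  expect_equal(similarity_hue(a, b), 1 - 0.1786 * 0.79 / 3)
  expect_equal(similarity_hue(a, b, achromatic_guard = FALSE), 0.5)
})

test_that("matching factor reproduces hand-computed values", {
  pk <- hsv_peak_value
  expect_identical(similarity_matching_factor(pk(77, 0.4, 0.6),
                                              pk(77, 0.4, 0.6)), 1)
  # maximal circular hue difference, no S/V difference
  expect_equal(similarity_matching_factor(pk(0, 0.5, 0.5), pk(180, 0.5, 0.5)),
               1 - 0.6429 * 0.5 / 3)
  # full saturation difference only (hue 0 on both sides: the achromatic
  # member reports hue 0 by convention)
  expect_equal(similarity_matching_factor(pk(0, 0, 0.5), pk(0, 1, 0.5)),
               1 - 0.1786 / 3)
})

test_that("euclidean similarity works on HSV cylinder coordinates", {
  pk <- hsv_peak_value
  expect_identical(similarity_euclidean(pk(10, 0.3, 0.3), pk(10, 0.3, 0.3)), 1)
  # antipodal rim points with opposite value saturate the normalizer
  expect_equal(similarity_euclidean(pk(0, 1, 0), pk(180, 1, 1)), 0)
  # two grays differing in value by dv
  for (dv in c(0.1, 0.5, 0.9)) {
    expect_equal(similarity_euclidean(pk(0, 0, 0.05), pk(0, 0, 0.05 + dv)),
                 1 - dv / sqrt(5))
  }
})

test_that("similarity properties hold over random peak pairs", {
  set.seed(424)
  for (i in 1:300) {
    a <- hsv_peak_value(runif(1, 0, 360), runif(1), runif(1))
    b <- hsv_peak_value(runif(1, 0, 360), runif(1), runif(1))
    for (m in c("hue", "matching_factor", "euclidean")) {
      sab <- similarity(a, b, m)
      expect_identical(similarity(a, a, m), 1)
      expect_equal(sab, similarity(b, a, m))
      expect_gte(sab, 0)
      expect_lte(sab, 1)
    }
  }
})

test_that("determine_result picks the argmax with low-level tie-breaking", {
  layout <- small_layout()
  levels <- layout$parameters$ph$levels
  refs <- list(list(level = levels[["6.0"]], peak = hsv_peak_value(40, 0.8, 0.8)),
               list(level = levels[["7.0"]], peak = hsv_peak_value(80, 0.8, 0.8)),
               list(level = levels[["8.0"]], peak = hsv_peak_value(160, 0.8, 0.8)))
  # exact match dominates
  r <- determine_result(hsv_peak_value(80, 0.8, 0.8), refs, "hue")
  expect_identical(r$level$label, "7.0")
  expect_identical(r$score, 1)
  # equidistant between two levels: the lower wins
  r <- determine_result(hsv_peak_value(60, 0.8, 0.8), refs, "hue")
  expect_identical(r$level$label, "6.0")
  expect_error(determine_result(hsv_peak_value(1, 1, 1), refs, "cosine"))
})

test_that("determine_result equals an independent scalar argmax loop", {
  set.seed(77)
  layout <- small_layout()
  levels <- layout$parameters$glucose$levels
  circ <- function(x, y) {
    d <- abs(x - y) %% 360
    min(d, 360 - d)
  }
  # independently coded scalar formulas
  oracle <- list(
    hue = function(a, b) 1 - circ(a$h, b$h) / 360,
    matching_factor = function(a, b) {
      1 - (0.6429 * circ(a$h, b$h) / 360 + 0.1786 * abs(a$s - b$s) +
             0.1786 * abs(a$v - b$v)) / 3
    },
    euclidean = function(a, b) {
      p <- function(z) c(z$s * cos(z$h * pi / 180), z$s * sin(z$h * pi / 180), z$v)
      1 - sqrt(sum((p(a) - p(b))^2)) / sqrt(5)
    })
  for (i in 1:100) {
    refs <- lapply(seq_along(levels), function(j) {
      list(level = levels[[j]],
           peak = hsv_peak_value(runif(1, 0, 360), runif(1, 0.1, 1), runif(1)))
    })
    test <- hsv_peak_value(runif(1, 0, 360), runif(1, 0.1, 1), runif(1))
    for (m in names(oracle)) {
      got <- determine_result(test, refs, m, achromatic_guard = FALSE)
      sc <- vapply(refs, function(r) oracle[[m]](test, r$peak), numeric(1))
      expect_identical(got$level$label, refs[[which.max(sc)]]$level$label)
      expect_equal(got$score, max(sc))
    }
  }
})

test_that("a perturbed planted color is matched to its level by all methods", {
  set.seed(99)
  hues <- c(20, 60, 110, 170, 230)
  levels <- lapply(seq_along(hues), function(i) {
    list(label = paste0("L", i), value = i)
  })
  refs <- lapply(seq_along(hues), function(i) {
    list(level = levels[[i]], peak = hsv_peak_value(hues[i], 0.8, 0.7))
  })
  for (i in 1:40) {
    planted <- sample(length(hues), 1)
    noisy <- hsv_peak_value((hues[planted] + rnorm(1, 0, 5)) %% 360,
                            min(1, max(0, 0.8 + rnorm(1, 0, 0.03))),
                            min(1, max(0, 0.7 + rnorm(1, 0, 0.03))))
    for (m in c("hue", "matching_factor", "euclidean")) {
      expect_identical(determine_result(noisy, refs, m)$level$label,
                       levels[[planted]]$label)
    }
  }
})
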