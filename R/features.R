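# Binary local features: oriented FAST keypoints with rotated BRIEF
# descriptors over a small image pyramid, matched by Hamming distance.
# This is the classic ORB construction (segment-test corners, intensity-
# centroid orientation, steered binary intensity comparisons).

# 16-point Bresenham circle of radius 3, clockwise from 12 o'clock (y down).
FAST_CIRCLE <- cbind(
  dx = c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1),
  dy = c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3))

# 256 fixed sampling pairs for the binary descriptor, drawn once from an
# isotropic Gaussian (sd = patch/5) clamped to radius 12. Deterministic:
# generated under a private seed at first use.
brief_pattern <- local({
  pat <- NULL
  function() {
    if (is.null(pat)) {
      pat <<- with_seed(60601, {
        draw <- function(n) {
          p <- matrix(stats::rnorm(2 * n, sd = 6.2), n, 2)
          r <- sqrt(rowSums(p^2))
          p[r > 12, ] <- p[r > 12, ] * (12 / r[r > 12])
          round(p)
        }
        list(a = draw(256), b = draw(256))
      })
    }
    pat
  }
})

#' Detect oriented-FAST keypoints and binary descriptors
#'
#' Runs a segment-test corner detector over a small image pyramid, assigns
#' each keypoint an orientation from the patch intensity centroid, and
#' computes a 256-bit rotated binary descriptor by pairwise intensity
#' comparisons on a smoothed patch. Deterministic: the same image always
#' yields the same features.
#'
#' @param image Grayscale matrix in `[0, 1]` (a color array is converted).
#' @param max_features Keep at most this many keypoints, ranked by corner
#'   score across all pyramid levels.
#' @param n_levels,scale_factor Pyramid depth and per-level downscale.
#' @param fast_threshold Minimum contrast (in `[0, 1]` units) between the
#'   center and the contiguous circle arc; 0.08 is about 20/255.
#' @return A `feature_set`: list with `keypoints` (data.frame `x`, `y`
#'   0-based level-0 coordinates, `scale`, `angle` radians, `score`) and
#'   `descriptors` (n x 256 integer 0/1 matrix). Zero rows when the image is
#'   empty or featureless.
#' @export
extract_features <- function(image, max_features = 500, n_levels = 4,
                             scale_factor = 1.2, fast_threshold = 0.08) {
  stopifnot(max_features >= 1)
  gray <- to_gray(unclass(image))
  empty <- list(
    keypoints = data.frame(x = numeric(0), y = numeric(0), scale = numeric(0),
                           angle = numeric(0), score = numeric(0)),
    descriptors = matrix(0L, 0, 256))
  class(empty) <- "feature_set"

  kps <- list()
  imgs <- list()
  for (lev in seq_len(n_levels)) {
    s <- scale_factor^(lev - 1)
    lw <- round(img_width(gray) / s); lh <- round(img_height(gray) / s)
    if (lw < 40 || lh < 40) break
    g <- if (lev == 1) gray else resize_image(gray, lw, lh)
    imgs[[lev]] <- g
    kp <- fast_detect(g, fast_threshold)
    if (nrow(kp) > 0) {
      kp$level <- lev
      kp$scale <- s
      kps[[lev]] <- kp
    }
  }
  if (length(kps) == 0) return(empty)
  kp <- do.call(rbind, kps)

  # keep only keypoints with a full descriptor patch at their level
  keep <- logical(nrow(kp))
  for (lev in unique(kp$level)) {
    i <- kp$level == lev
    w <- img_width(imgs[[lev]]); h <- img_height(imgs[[lev]])
    keep[i] <- kp$x[i] >= 16 & kp$x[i] < w - 16 & kp$y[i] >= 16 & kp$y[i] < h - 16
  }
  kp <- kp[keep, , drop = FALSE]
  if (nrow(kp) == 0) return(empty)

  ord <- order(-kp$score, kp$level, kp$x, kp$y)
  kp <- kp[utils::head(ord, max_features), , drop = FALSE]

  desc <- matrix(0L, nrow(kp), 256)
  ang <- numeric(nrow(kp))
  pat <- brief_pattern()
  for (lev in unique(kp$level)) {
    idx <- which(kp$level == lev)
    g <- imgs[[lev]]
    gs <- blur_image(g, 2)
    for (ii in idx) {
      a <- orientation_ic(g, kp$x[ii], kp$y[ii])
      ang[ii] <- a
      desc[ii, ] <- brief_descriptor(gs, kp$x[ii], kp$y[ii], a, pat)
    }
  }

  out <- list(
    keypoints = data.frame(x = kp$x * kp$scale, y = kp$y * kp$scale,
                           scale = kp$scale, angle = ang, score = kp$score),
    descriptors = desc)
  class(out) <- "feature_set"
  out
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d keypoints\n", nrow(x$keypoints)))
  invisible(x)
}

# Segment-test (FAST-9) corner detection on a grayscale matrix.
# Returns data.frame(x, y, score) with 0-based coordinates.
fast_detect <- function(g, t) {
  w <- img_width(g); h <- img_height(g)
  m <- 3L
  xs <- (1L + m):(w - m); ys <- (1L + m):(h - m)
  C <- g[xs, ys]
  nb <- length(C)
  # high-speed pretest on the 4 compass points
  cnt_b <- matrix(0L, length(xs), length(ys))
  cnt_d <- matrix(0L, length(xs), length(ys))
  for (k in c(1L, 5L, 9L, 13L)) {
    P <- g[xs + FAST_CIRCLE[k, 1], ys + FAST_CIRCLE[k, 2]]
    cnt_b <- cnt_b + (P > C + t)
    cnt_d <- cnt_d + (P < C - t)
  }
  cand <- which(cnt_b >= 3L | cnt_d >= 3L)
  if (length(cand) == 0) return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))

  cx <- ((cand - 1L) %% length(xs)) + 1L
  cy <- ((cand - 1L) %/% length(xs)) + 1L
  n <- length(cand)
  B <- matrix(FALSE, n, 16); D <- matrix(FALSE, n, 16)
  diffs <- matrix(0, n, 16)
  cc <- C[cand]
  for (k in 1:16) {
    P <- g[cbind(cx + m + FAST_CIRCLE[k, 1], cy + m + FAST_CIRCLE[k, 2])]
    B[, k] <- P > cc + t
    D[, k] <- P < cc - t
    diffs[, k] <- P - cc
  }
  run9 <- function(M) {
    M2 <- cbind(M, M[, 1:8, drop = FALSE])
    ok <- rep(FALSE, nrow(M))
    for (s in 1:16) {
      win <- M2[, s:(s + 8), drop = FALSE]
      ok <- ok | (rowSums(win) == 9L)
    }
    ok
  }
  is_b <- run9(B); is_d <- run9(D)
  pass <- is_b | is_d
  if (!any(pass)) return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))

  score <- rowSums(pmax(diffs - t, 0) * B) * is_b +
    rowSums(pmax(-diffs - t, 0) * D) * is_d
  px <- cx[pass]; py <- cy[pass]; sc <- score[pass]

  # 3x3 non-maximum suppression on the sparse score map
  S <- matrix(0, length(xs) + 2L, length(ys) + 2L)
  S[cbind(px + 1L, py + 1L)] <- sc
  keep <- rep(TRUE, length(px))
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    keep <- keep & (sc >= S[cbind(px + 1L + dx, py + 1L + dy)])
  }
  data.frame(x = px[keep] + m - 1, y = py[keep] + m - 1, score = sc[keep])
}

# Intensity-centroid orientation over a radius-15 disc (0-based center).
IC_DISC <- local({
  r <- 15
  g <- expand.grid(u = -r:r, v = -r:r)
  g[g$u^2 + g$v^2 <= r^2, ]
})

orientation_ic <- function(g, x, y) {
  u <- IC_DISC$u; v <- IC_DISC$v
  vals <- g[cbind(x + 1 + u, y + 1 + v)]
  atan2(sum(v * vals), sum(u * vals))
}

# 256-bit rotated BRIEF descriptor at an oriented keypoint.
brief_descriptor <- function(gs, x, y, angle, pat) {
  ca <- cos(angle); sa <- sin(angle)
  rot <- function(p) cbind(round(p[, 1] * ca - p[, 2] * sa),
                           round(p[, 1] * sa + p[, 2] * ca))
  pa <- rot(pat$a); pb <- rot(pat$b)
  va <- gs[cbind(x + 1 + pa[, 1], y + 1 + pa[, 2])]
  vb <- gs[cbind(x + 1 + pb[, 1], y + 1 + pb[, 2])]
  as.integer(va < vb)
}

#' Brute-force Hamming matching of binary descriptors
#'
#' For every descriptor in `a`, finds its nearest neighbour in `b` by
#' exhaustive Hamming distance, sorts all matches by ascending distance and
#' keeps the best `n_keep`.
#'
#' @param a,b `feature_set` objects.
#' @param n_keep Maximum number of matches returned (all if fewer).
#' @return data.frame with columns `i` (index into `a`), `j` (index into
#'   `b`), `dist` (Hamming distance, bits), ordered by `dist`.
#' @export
match_features <- function(a, b, n_keep = 50) {
  na <- nrow(a$descriptors); nb <- nrow(b$descriptors)
  if (na == 0 || nb == 0) {
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  }
  A <- a$descriptors; B <- b$descriptors
  D <- A %*% (1 - t(B)) + (1 - A) %*% t(B)
  j <- max.col(-D, ties.method = "first")
  d <- D[cbind(seq_len(na), j)]
  ord <- order(d, seq_len(na))
  out <- data.frame(i = ord, j = j[ord], dist = d[ord])
  utils::head(out, n_keep)
}
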