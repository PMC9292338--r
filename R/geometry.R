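# Planar projective geometry: homography estimation (normalized DLT),
# perspective warping, and polygon utilities.

#' Fit a homography through point correspondences
#'
#' Estimates the 3x3 projective transform `H` mapping `src` points to `dst`
#' points by the normalized direct linear transform. With exactly four
#' correspondences the fit is exact; with more it is least squares.
#'
#' @param src,dst n x 2 matrices of 0-based pixel coordinates, n >= 4.
#' @return 3x3 matrix `H`, scaled so `H[3, 3] == 1`, with
#'   `dst ~ project(H, src)`.
#' @export
homography_from_points <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 4, ncol(src) == 2)
  norm_t <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
  }
  T1 <- norm_t(src); T2 <- norm_t(dst)
  sp <- cbind(src, 1) %*% t(T1)
  dp <- cbind(dst, 1) %*% t(T2)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- sp[i, ]; x <- dp[i, 1]; y <- dp[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, x * X)
    A[2 * i, ] <- c(0, 0, 0, -X, y * X)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  H <- solve(T2) %*% matrix(h, 3, 3, byrow = TRUE) %*% T1
  if (abs(H[3, 3]) < 1e-12) return(H / sqrt(sum(H^2)))
  H / H[3, 3]
}

#' Apply a homography to points
#'
#' @param H 3x3 projective transform.
#' @param pts n x 2 matrix of points.
#' @return n x 2 matrix of transformed points.
#' @export
apply_homography <- function(H, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  p <- cbind(pts, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}

#' Warp an image through a homography
#'
#' Renders an `out_w` x `out_h` output by inverse mapping: for every output
#' pixel, `H_out_to_in` gives the source location, which is sampled
#' bilinearly (border-clamped).
#'
#' @param img Color array or grayscale matrix.
#' @param H_out_to_in 3x3 transform from output to input coordinates.
#' @param out_w,out_h Output size in pixels.
#' @return Warped image of the requested size.
#' @export
warp_image <- function(img, H_out_to_in, out_w, out_h) {
  gx <- rep(seq_len(out_w) - 1, times = out_h)
  gy <- rep(seq_len(out_h) - 1, each = out_w)
  p <- apply_homography(H_out_to_in, cbind(gx, gy))
  if (length(dim(unclass(img))) == 2L) {
    matrix(bilinear_sample(img, p[, 1], p[, 2]), out_w, out_h)
  } else {
    array(bilinear_sample(img, p[, 1], p[, 2]), dim = c(out_w, out_h, 3))
  }
}

# Signed area of a polygon (shoelace); positive when vertices run clockwise
# in the y-down image frame.
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

# TRUE when the 4 vertices form a convex quadrilateral (any orientation).
is_convex_quad <- function(pts) {
  if (nrow(pts) != 4) return(FALSE)
  cr <- numeric(4)
  for (i in 1:4) {
    a <- pts[i, ]; b <- pts[i %% 4 + 1, ]; c <- pts[(i + 1) %% 4 + 1, ]
    cr[i] <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
  }
  all(cr > 0) || all(cr < 0)
}

# Order 4 points as top-left, top-right, bottom-right, bottom-left.
order_quad <- function(pts) {
  s <- pts[, 1] + pts[, 2]
  d <- pts[, 1] - pts[, 2]
  rbind(pts[which.min(s), ], pts[which.max(d), ],
        pts[which.max(s), ], pts[which.min(d), ])
}

# Point-in-convex-polygon test (vectorized over points).
points_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(TRUE, length(px))
  orient <- sign(polygon_area(poly))
  if (orient == 0) return(rep(FALSE, length(px)))
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[i %% n + 1, ]
    cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & (orient * cr >= 0)
  }
  inside
}

# Ramer-Douglas-Peucker simplification of a closed contour (n x 2).
# Splits at the two mutually farthest vertices, then simplifies each open
# chain with tolerance eps; returns the simplified closed polygon.
approx_polygon <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 3) return(pts)
  # farthest pair along the contour: approximate with farthest from centroid,
  # then farthest from that point (adequate for convex-ish blobs)
  ctr <- colMeans(pts)
  i1 <- which.max((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  i2 <- which.max((pts[, 1] - pts[i1, 1])^2 + (pts[, 2] - pts[i1, 2])^2)
  lo <- min(i1, i2); hi <- max(i1, i2)
  chain1 <- pts[lo:hi, , drop = FALSE]
  chain2 <- pts[c(hi:n, 1:lo), , drop = FALSE]
  out <- rbind(rdp_open(chain1, eps),
               rdp_open(chain2, eps)[-1, , drop = FALSE])
  out[-nrow(out), , drop = FALSE]
}

rdp_open <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  a <- pts[1, ]; b <- pts[n, ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len < 1e-12) {
    d <- sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2)
  } else {
    d <- abs(ab[1] * (pts[, 2] - a[2]) - ab[2] * (pts[, 1] - a[1])) / len
  }
  i <- which.max(d)
  if (d[i] <= eps) return(pts[c(1, n), , drop = FALSE])
  rbind(rdp_open(pts[1:i, , drop = FALSE], eps),
        rdp_open(pts[i:n, , drop = FALSE], eps)[-1, , drop = FALSE])
}
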