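# Field localization.
#
# Reference fields come off the rectified card at constant (scaled) layout
# coordinates. Test fields on the strip are found by running an edge/threshold
# detector under many preprocessing settings, keeping near-square contours,
# clustering their centers with k-means (k chosen by an elbow rule), and
# completing the regular 1-D grid where fields were missed.

new_field_patch <- function(pixels, origin, role, parameter, level = NULL) {
  structure(list(pixels = pixels, origin = origin, role = role,
                 parameter = parameter, level = level),
            class = "field_patch")
}

#' @export
print.field_patch <- function(x, ...) {
  cat(sprintf("<field_patch> %s %s%s at (%.0f, %.0f) %dx%d\n", x$role,
              x$parameter, if (is.null(x$level)) "" else paste0(":", x$level),
              x$origin[1], x$origin[2], dim(x$pixels)[1], dim(x$pixels)[2]))
  invisible(x)
}

#' Extract reference patches from a rectified card
#'
#' Crops one patch per (parameter, level) at the layout's constant card
#' coordinates, scaled to the rectified image's actual size. Each patch is
#' the central `central_fraction` of the configured rectangle, avoiding
#' swatch borders and bleed.
#'
#' @param rectified_card Color array in the canonical card frame (any size).
#' @param layout A `strip_layout`.
#' @param central_fraction Side fraction of the rectangle retained (0.5
#'   keeps the central quarter by area).
#' @return List of `field_patch` objects with `role = "reference-field"`,
#'   in layout order.
#' @export
extract_reference_fields <- function(rectified_card, layout,
                                     central_fraction = 0.5) {
  w <- img_width(rectified_card); h <- img_height(rectified_card)
  if (w < 10 || h < 10) {
    stop("rectified card smaller than 10 px in a dimension", call. = FALSE)
  }
  sx <- w / layout$card_size[1]; sy <- h / layout$card_size[2]
  out <- list()
  for (pname in names(layout$parameters)) {
    for (lname in names(layout$parameters[[pname]]$levels)) {
      r <- layout$card_coords[[pname]][[lname]]
      r <- c(r[1] * sx, r[2] * sy, r[3] * sx, r[4] * sy)
      cw <- r[3] * central_fraction; ch <- r[4] * central_fraction
      rc <- c(r[1] + (r[3] - cw) / 2, r[2] + (r[4] - ch) / 2, cw, ch)
      patch <- crop_rect(rectified_card, rc)
      out[[length(out) + 1]] <- new_field_patch(patch, rc, "reference-field",
                                                pname, lname)
    }
  }
  out
}

#' Square-detection preprocessing grid
#'
#' @param blur_sigmas Gaussian blur sigmas tried (0 = no blur).
#' @param methods Binarization/edge settings tried: Otsu global threshold,
#'   adaptive mean threshold, and a gradient-magnitude edge map.
#' @param channels Channels the settings run on: luma, and saturation —
#'   weakly pigmented pads (pale cream on a white strip) are nearly
#'   invisible in luma but stand out in saturation.
#' @param approx_eps_frac Polygon approximation tolerance as a fraction of
#'   the contour perimeter.
#' @param min_side_frac Minimum square side as a fraction of image height.
#' @param max_aspect Maximum side aspect ratio of an accepted square.
#' @return A list of class `square_settings`.
#' @export
square_settings <- function(blur_sigmas = c(0, 1, 1.7, 2.3),
                            methods = c("otsu", "adaptive", "edge",
                                        "quantile"),
                            channels = c("luma", "saturation"),
                            approx_eps_frac = 0.02,
                            min_side_frac = 0.2,
                            max_aspect = 1.06,
                            min_fill = 0.8) {
  structure(list(blur_sigmas = blur_sigmas, methods = methods,
                 channels = channels, approx_eps_frac = approx_eps_frac,
                 min_side_frac = min_side_frac, max_aspect = max_aspect,
                 min_fill = min_fill),
            class = "square_settings")
}

#' Find candidate squares in a strip image
#'
#' Preprocesses the image under every (blur, binarization) setting in the
#' grid, traces the contours of connected components in both polarities,
#' simplifies each contour to a polygon, and keeps convex quadrilaterals
#' whose shorter side is at least `min_side_frac` of the image height and
#' whose side aspect ratio is within `max_aspect`. Duplicate detections of
#' the same field across settings are retained deliberately: they carry
#' weight in the later clustering.
#'
#' @param strip_image Color array: a roughly axis-aligned crop containing
#'   the strip.
#' @param settings A [square_settings()] grid.
#' @return List of `square_candidate` objects (fields `corners`, `center`,
#'   `side`, `aspect`); may be empty.
#' @export
find_candidate_squares <- function(strip_image, settings = square_settings()) {
  strip_image <- unclass(strip_image)
  # "image height" of a landscape strip crop = its short dimension; using
  # min(w, h) keeps the size filter meaningful for rotated crops
  h <- min(dim(strip_image)[1:2])
  min_side <- settings$min_side_frac * h
  chans <- lapply(settings$channels, function(ch) {
    switch(ch,
           luma = to_gray(strip_image),
           saturation = if (length(dim(strip_image)) == 3L) {
             to_hsv(strip_image)[, , 2]
           },
           stop("unknown channel: ", ch, call. = FALSE))
  })
  chans <- chans[!vapply(chans, is.null, logical(1))]
  out <- list()
  for (chan in chans) {
    for (sigma in settings$blur_sigmas) {
      g <- if (sigma > 0) blur_image(chan, sigma) else chan
      for (method in settings$methods) {
        for (bin in binarize(g, method)) {
          for (cand in squares_from_binary(bin, settings, min_side)) {
            out[[length(out) + 1]] <- cand
          }
        }
      }
    }
  }
  out
}

# Binary maps for one preprocessing method; both polarities where sensible.
binarize <- function(g, method) {
  if (method == "otsu") {
    rng <- range(g)
    if (diff(rng) < 1e-6) return(list())
    t <- EBImage::otsu(EBImage::Image(g), range = rng)
    list(g < t, g > t)
  } else if (method == "adaptive") {
    win <- max(9, 2 * floor(img_height(g) / 2) + 1)
    local_mean <- blur_image(g, win / 4)
    list(g < local_mean - 0.02, g > local_mean + 0.02)
  } else if (method == "quantile") {
    out <- list()
    for (q in c(0.25, 0.5, 0.75)) {
      t <- stats::quantile(g, q, names = FALSE)
      out <- c(out, list(g < t, g > t))
    }
    out
  } else if (method == "edge") {
    # gradient-magnitude edges; components are the regions between edges
    gx <- g; gy <- g
    w <- img_width(g); h <- img_height(g)
    gx[2:(w - 1), ] <- (g[3:w, ] - g[1:(w - 2), ]) / 2
    gy[, 2:(h - 1)] <- (g[, 3:h] - g[, 1:(h - 2)]) / 2
    mag <- sqrt(gx^2 + gy^2)
    list(mag < 0.04 & !is_border(g))
  } else {
    stop("unknown binarization method: ", method, call. = FALSE)
  }
}

is_border <- function(g) {
  w <- img_width(g); h <- img_height(g)
  b <- matrix(FALSE, w, h)
  b[c(1, w), ] <- TRUE; b[, c(1, h)] <- TRUE
  b
}

squares_from_binary <- function(bin, settings, min_side) {
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  n <- max(lab)
  if (n == 0) return(list())
  areas <- tabulate(as.integer(EBImage::imageData(lab)), nbins = n)
  big <- which(areas >= (0.8 * min_side)^2)
  if (length(big) == 0) return(list())
  contours <- EBImage::ocontour(lab)
  out <- list()
  for (i in big) {
    ct <- contours[[i]]
    if (is.null(ct) || nrow(ct) < 8) next
    per <- sum(sqrt(rowSums((ct - ct[c(2:nrow(ct), 1), ])^2)))
    poly <- quad_from_contour(ct, settings$approx_eps_frac * per)
    if (is.null(poly) || !is_convex_quad(poly)) next
    # +1: contour pixel centers under-span the region by one pixel
    sides <- sqrt(rowSums((poly - poly[c(2, 3, 4, 1), ])^2)) + 1
    if (min(sides) < min_side) next
    aspect <- max(sides) / min(sides)
    if (aspect > settings$max_aspect) next
    # true squares fill their quadrilateral; ragged blobs do not
    qa <- abs(polygon_area(poly))
    if (qa < 1 || areas[i] / qa < settings$min_fill) next
    out[[length(out) + 1]] <- structure(
      list(corners = order_quad(poly), center = colMeans(poly),
           side = mean(sides), aspect = aspect),
      class = "square_candidate")
  }
  out
}

# Minimum-area enclosing rectangle of a point set (rotating calipers over
# convex hull edges). Returns corners (4 x 2), long and short side lengths.
min_area_rect <- function(pts) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  m <- nrow(hull)
  best <- NULL
  for (i in seq_len(m)) {
    e <- hull[i %% m + 1, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-9) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    du <- max(pu) - min(pu); dv <- max(pv) - min(pv)
    if (is.null(best) || du * dv < best$area) {
      c0 <- min(pu) * u + min(pv) * v
      best <- list(area = du * dv,
                   corners = rbind(c0, c0 + du * u, c0 + du * u + dv * v,
                                   c0 + dv * v),
                   long = max(du, dv), short = min(du, dv))
    }
  }
  best
}

# Median color of the square patch of radius r at 0-based point p (clamped).
sample_patch_median <- function(img, p, r) {
  w <- img_width(img); h <- img_height(img)
  xs <- max(1, round(p[1]) + 1 - r):min(w, round(p[1]) + 1 + r)
  ys <- max(1, round(p[2]) + 1 - r):min(h, round(p[2]) + 1 + r)
  apply(img[xs, ys, , drop = FALSE], 3, stats::median)
}

# Locate the strip body: the connected component of strip-colored pixels
# containing the inter-pad surface. The surface color is sampled at the
# midpoints between adjacent detected pad centers; pixels close to it in RGB
# form the strip mask (pads punch holes but the surrounding surface stays
# connected). Returns the body's axis-aligned bounding box
# c(xmin, xmax, ymin, ymax), or NULL when it cannot be established. The
# pads must lie within this extent, which resolves toward which end missing
# outer fields are completed.
estimate_strip_extent <- function(strip_image, centers, side, pitch) {
  strip_image <- unclass(strip_image)
  if (length(dim(strip_image)) != 3L || nrow(centers) < 2) return(NULL)
  X <- sweep(centers, 2, colMeans(centers))
  ax <- principal_axis(X)
  # the surface between pads sits half a pitch to either side of each pad
  # center along the axis (midpoints between *detected* centers can land on
  # undetected pads when fields are missing)
  off <- (pitch / 2) * ax
  mids <- rbind(sweep(centers, 2, off, `+`), sweep(centers, 2, off, `-`))
  w <- img_width(strip_image); h <- img_height(strip_image)
  mids <- mids[mids[, 1] >= 0 & mids[, 1] <= w - 1 &
                 mids[, 2] >= 0 & mids[, 2] <= h - 1, , drop = FALSE]
  if (nrow(mids) == 0) return(NULL)
  r <- max(2L, as.integer(side * 0.12))
  cols <- t(apply(mids, 1, function(p) sample_patch_median(strip_image, p, r)))
  bg <- apply(cols, 2, stats::median)
  spread <- stats::median(sqrt(rowSums(sweep(cols, 2, bg)^2)))
  thr <- max(0.12, 3 * spread)
  D <- sqrt((strip_image[, , 1] - bg[1])^2 + (strip_image[, , 2] - bg[2])^2 +
              (strip_image[, , 3] - bg[3])^2)
  lab <- EBImage::bwlabel(EBImage::Image((D < thr) * 1))
  labs <- lab[cbind(pmin(pmax(round(mids[, 1]) + 1, 1), img_width(lab)),
                    pmin(pmax(round(mids[, 2]) + 1, 1), img_height(lab)))]
  labs <- labs[labs > 0]
  if (length(labs) == 0) return(NULL)
  keep <- as.integer(names(which.max(table(labs))))
  idx <- which(EBImage::imageData(lab) == keep, arr.ind = TRUE)
  c(min(idx[, 1]) - 1, max(idx[, 1]) - 1, min(idx[, 2]) - 1, max(idx[, 2]) - 1)
}

# Simplify a closed contour to exactly four vertices, growing the tolerance
# until at most four remain (rounded corners defeat a fixed tolerance).
quad_from_contour <- function(ct, eps) {
  for (k in 1:8) {
    poly <- approx_polygon(ct, eps)
    if (nrow(poly) <= 4) break
    eps <- eps * 1.5
  }
  if (nrow(poly) != 4) NULL else poly
}

#' Cluster square centers with k-means and an elbow rule
#'
#' Computes the within-cluster sum of squares for k = 1..k_max (k-means with
#' k-means++ seeding, 10 restarts, deterministic given `seed`) and picks k
#' at the elbow of the log-WCSS curve: the k maximizing
#' `log W(k-1) - 2 log W(k) + log W(k+1)`, i.e. the largest relative drop
#' followed by flattening; ties break toward smaller k. A k whose WCSS is
#' already numerically zero short-circuits the search.
#'
#' @param points n x 2 matrix of (x, y) centers, n >= 1.
#' @param k_max Largest cluster count considered.
#' @param seed Integer seed; results are deterministic given it.
#' @return k x 2 matrix of cluster centers (row order unspecified).
#' @export
cluster_field_centers <- function(points, k_max, seed = 1) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) == 0) stop("no points to cluster", call. = FALSE)
  stopifnot(k_max >= 1)
  n_distinct <- nrow(unique(points))
  kmax <- min(k_max, n_distinct)
  with_seed(seed, {
    fits <- lapply(seq_len(kmax), function(k) kmeans_pp(points, k))
    W <- vapply(fits, `[[`, numeric(1), "tot.withinss")
    scale0 <- sum(scale(points, scale = FALSE)^2)
    tol <- max(scale0, 1) * 1e-9
    zero <- which(W <= tol)
    k <- if (length(zero) > 0) {
      zero[1]
    } else if (kmax <= 2) {
      kmax
    } else {
      lw <- log(W)
      d2 <- lw[1:(kmax - 2)] - 2 * lw[2:(kmax - 1)] + lw[3:kmax]
      which.max(d2) + 1L
    }
    unname(fits[[k]]$centers)
  })
}

# k-means with k-means++ seeding and restarts; deterministic under the
# caller's RNG state.
kmeans_pp <- function(points, k, restarts = 10) {
  n <- nrow(points)
  if (k == 1) {
    ctr <- matrix(colMeans(points), 1, 2)
    return(list(centers = ctr,
                tot.withinss = sum(sweep(points, 2, ctr[1, ])^2)))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    ctrs <- matrix(0, k, 2)
    ctrs[1, ] <- points[sample.int(n, 1), ]
    d2 <- rowSums(sweep(points, 2, ctrs[1, ])^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      ctrs[j, ] <- points[sample.int(n, 1, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(points, 2, ctrs[j, ])^2))
    }
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(points, centers = ctrs, iter.max = 50,
                                     nstart = 1)),
      error = function(e) lloyd_assign(points, ctrs))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

# Single assignment + recentering pass, used when stats::kmeans rejects a
# degenerate seeding (e.g. coincident points).
lloyd_assign <- function(points, ctrs) {
  d2 <- sapply(seq_len(nrow(ctrs)), function(j) {
    rowSums(sweep(points, 2, ctrs[j, ])^2)
  })
  d2 <- matrix(d2, nrow = nrow(points))
  a <- max.col(-d2, ties.method = "first")
  centers <- do.call(rbind, lapply(sort(unique(a)), function(j) {
    colMeans(points[a == j, , drop = FALSE])
  }))
  w <- sum(vapply(sort(unique(a)), function(j) {
    sum(sweep(points[a == j, , drop = FALSE], 2,
              colMeans(points[a == j, , drop = FALSE]))^2)
  }, numeric(1)))
  list(centers = centers, tot.withinss = w)
}

# Average together centers closer than min_sep (single linkage), repeatedly.
merge_close_centers <- function(centers, min_sep) {
  repeat {
    n <- nrow(centers)
    if (n < 2) return(centers)
    d <- as.matrix(stats::dist(centers))
    diag(d) <- Inf
    mi <- which.min(d)
    if (d[mi] >= min_sep) return(centers)
    i <- (mi - 1) %% n + 1; j <- (mi - 1) %/% n + 1
    merged <- (centers[i, ] + centers[j, ]) / 2
    centers <- rbind(centers[-c(i, j), , drop = FALSE], merged)
  }
}

grid_completion_failure <- function(msg, diagnostics = list()) {
  stop(structure(class = c("grid_completion_failure", "stripreader_error",
                           "error", "condition"),
                 list(message = msg, call = NULL, diagnostics = diagnostics)))
}

#' Complete a 1-D field grid from detected centers
#'
#' Projects the centers onto their principal axis, sorts them, takes the
#' median consecutive spacing as the grid pitch, fills any gap larger than
#' 1.5x the pitch with `round(gap / pitch) - 1` equally spaced points, and,
#' if still short of `expected_count`, extrapolates by one pitch beyond the
#' ends (alternating, starting at the low-projection end, which is the
#' dipped end under the layout's left-to-right order).
#'
#' @param centers n x 2 matrix, n >= 2.
#' @param expected_count Target number of fields, `>= nrow(centers)`.
#' @param bounds Optional `c(xmin, xmax, ymin, ymax)` the completed centers
#'   must stay within (the strip crop, for instance): an end whose next
#'   extrapolated point would fall outside is not extended, resolving which
#'   end the missing outer fields belong to. `NULL` applies no constraint.
#' @param pitch Optional externally estimated grid pitch (pixels); when
#'   `NULL` the median consecutive spacing of the projected centers is used.
#' @return A `field_grid`: list with `centers` (expected_count x 2, ordered
#'   along the axis), `axis` (unit vector), `pitch`, `n_inserted`.
#' @section Failure: identical centers raise an error; needing to
#'   extrapolate more than `expected_count / 2` points, or overshooting
#'   `expected_count` through gap filling, signals a condition of class
#'   `grid_completion_failure`.
#' @export
complete_field_grid <- function(centers, expected_count, bounds = NULL,
                                pitch = NULL) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  n <- nrow(centers)
  stopifnot(n >= 2, expected_count >= n)
  ctr <- colMeans(centers)
  X <- sweep(centers, 2, ctr)
  if (sum(X^2) < 1e-9) stop("centers are all identical", call. = FALSE)
  axis <- principal_axis(X)
  proj <- X %*% axis
  ord <- order(proj)
  proj <- proj[ord]
  perp <- (X %*% c(-axis[2], axis[1]))[ord]
  gaps <- diff(proj)
  if (is.null(pitch)) pitch <- stats::median(gaps)
  if (!is.finite(pitch) || pitch <= 0) {
    grid_completion_failure("degenerate pitch (coincident centers)")
  }

  new_proj <- numeric(0); new_perp <- numeric(0)
  for (i in seq_along(gaps)) {
    if (gaps[i] > 1.5 * pitch) {
      k <- round(gaps[i] / pitch) - 1
      if (k >= 1) {
        f <- seq_len(k) / (k + 1)
        new_proj <- c(new_proj, proj[i] + f * gaps[i])
        new_perp <- c(new_perp, perp[i] + f * (perp[i + 1] - perp[i]))
      }
    }
  }
  proj_all <- c(proj, new_proj)
  perp_all <- c(perp, new_perp)
  o <- order(proj_all)
  proj_all <- proj_all[o]; perp_all <- perp_all[o]
  n_inserted <- length(new_proj)
  if (length(proj_all) > expected_count) {
    grid_completion_failure(
      sprintf("gap filling yields %d centers for %d expected fields",
              length(proj_all), expected_count),
      list(n_after_fill = length(proj_all)))
  }

  n_extrap <- expected_count - length(proj_all)
  if (n_extrap > expected_count / 2) {
    grid_completion_failure(
      sprintf("%d of %d fields would be extrapolated", n_extrap,
              expected_count),
      list(n_extrapolated = n_extrap))
  }
  to_xy <- function(pr, pe) {
    ctr + pr * axis + pe * c(-axis[2], axis[1])
  }
  oob <- function(p) {
    if (is.null(bounds)) return(0)
    max(0, bounds[1] - p[1], p[1] - bounds[2]) +
      max(0, bounds[3] - p[2], p[2] - bounds[4])
  }
  at_low <- TRUE
  while (length(proj_all) < expected_count) {
    m <- length(proj_all)
    v_low <- oob(to_xy(proj_all[1] - pitch, perp_all[1]))
    v_high <- oob(to_xy(proj_all[m] + pitch, perp_all[m]))
    ok_low <- v_low == 0; ok_high <- v_high == 0
    go_low <- if (ok_low == ok_high) {
      # both fit (or neither does: take the lesser violation, ties by the
      # alternating rule)
      if (v_low < v_high) TRUE else if (v_low > v_high) FALSE else at_low
    } else ok_low
    if (go_low) {
      proj_all <- c(proj_all[1] - pitch, proj_all)
      perp_all <- c(perp_all[1], perp_all)
    } else {
      proj_all <- c(proj_all, proj_all[m] + pitch)
      perp_all <- c(perp_all, perp_all[m])
    }
    if (ok_low == ok_high && v_low == v_high) at_low <- !at_low
    n_inserted <- n_inserted + 1
  }

  pts <- sweep(outer(proj_all, axis) + outer(perp_all, c(-axis[2], axis[1])),
               2, ctr, `+`)
  structure(list(centers = pts, axis = axis,
                 pitch = stats::median(diff(proj_all)),
                 n_inserted = as.integer(n_inserted)),
            class = "field_grid")
}

# Unit principal axis of centered points, oriented toward +x (ties +y) so
# that grid order is left-to-right / top-to-bottom.
principal_axis <- function(X) {
  v <- eigen(crossprod(X), symmetric = TRUE)$vectors[, 1]
  if (v[1] < 0 || (abs(v[1]) < 1e-12 && v[2] < 0)) v <- -v
  v / sqrt(sum(v^2))
}

# Pad centers are collinear to within half a pad side; centers far off the
# common axis are background artifacts and are removed (worst first, axis
# refitted each round).
drop_off_axis <- function(centers, side) {
  while (nrow(centers) > 2) {
    X <- sweep(centers, 2, colMeans(centers))
    if (sum(X^2) < 1e-9) break
    ax <- principal_axis(X)
    perp <- X %*% c(-ax[2], ax[1])
    dev <- abs(perp - stats::median(perp))
    if (max(dev) <= 0.6 * side) break
    centers <- centers[-which.max(dev), , drop = FALSE]
  }
  centers
}

# Pitch estimate robust to missing fields: the plain median spacing fails
# when half the gaps are double-pitch, so each gap is first folded by the
# integer multiple suggested by the pad side (adjacent pads on a strip sit
# roughly 1.5 sides apart and can never overlap).
robust_pitch <- function(centers, side) {
  X <- sweep(centers, 2, colMeans(centers))
  if (sum(X^2) < 1e-9) return(NULL)
  d <- diff(sort(X %*% principal_axis(X)))
  d <- d[d > 1e-6]
  if (length(d) == 0) return(NULL)
  k <- pmax(1, round(d / (1.45 * side)))
  max(stats::median(d / k), side)
}

field_detection_failure <- function(msg, diagnostics = list()) {
  stop(structure(class = c("field_detection_failure", "stripreader_error",
                           "error", "condition"),
                 list(message = msg, call = NULL, diagnostics = diagnostics)))
}

#' Locate the strip's test fields
#'
#' Composition of the square detector, the k-means/elbow clustering and the
#' grid completion: candidate square centers are clustered, spurious extra
#' clusters (farthest off the principal axis) are dropped, the grid is
#' completed to the layout's parameter count, and a patch of side
#' `0.5 x median candidate side` is cropped at every center. Patches are
#' assigned to parameters in layout order along the axis (dipped end at the
#' low end).
#'
#' @param strip_image Color array: roughly axis-aligned crop containing the
#'   strip.
#' @param layout A `strip_layout`; its parameter count is the expected
#'   field count.
#' @param seed Integer seed for the clustering.
#' @param settings A [square_settings()] grid.
#' @return List of `field_patch` objects (`role = "test-field"`), one per
#'   parameter in layout order, with the `field_grid` attached as attribute
#'   `"grid"` and the candidate count as attribute `"n_candidates"`.
#' @section Failure: fewer than 2 candidate squares signals
#'   `field_detection_failure`; grid completion failures propagate.
#' @export
locate_test_fields <- function(strip_image, layout, seed = 1,
                               settings = square_settings()) {
  expected <- length(layout$parameters)
  cluster_pass <- function(cands) {
    pts <- do.call(rbind, lapply(cands, `[[`, "center"))
    side <- stats::median(vapply(cands, `[[`, numeric(1), "side"))
    centers <- cluster_field_centers(pts, k_max = expected + 2, seed = seed)
    # two fields cannot lie closer than a field side: such centers are
    # sub-clusters of one field and are merged before grid fitting;
    # centers off the strip axis are artifacts and are dropped
    centers <- merge_close_centers(centers, 0.75 * side)
    list(centers = drop_off_axis(centers, side), side = side)
  }
  cands <- find_candidate_squares(strip_image, settings)
  cp <- if (length(cands) >= 2) cluster_pass(cands)
  if (length(cands) < 2 || nrow(cp$centers) < ceiling(0.6 * expected)) {
    # perspective foreshortening stretches square pads past the strict
    # aspect filter; when too few fields survive it, retry with an aspect
    # allowance for off-square projections
    relaxed <- settings
    relaxed$max_aspect <- max(1.25, settings$max_aspect)
    cands2 <- find_candidate_squares(strip_image, relaxed)
    if (length(cands2) >= 2) {
      cp2 <- cluster_pass(cands2)
      if (is.null(cp) || nrow(cp2$centers) > nrow(cp$centers)) {
        cands <- cands2
        cp <- cp2
      }
    }
  }
  if (length(cands) < 2) {
    field_detection_failure(
      sprintf("only %d candidate squares found", length(cands)),
      list(n_candidates = length(cands)))
  }
  centers <- cp$centers
  side <- cp$side
  if (nrow(centers) > expected) {
    # spurious clusters: drop those farthest from the principal axis
    X <- sweep(centers, 2, colMeans(centers))
    ax <- principal_axis(X)
    off <- abs(X %*% c(-ax[2], ax[1]))
    keep <- order(off)[seq_len(expected)]
    centers <- centers[keep, , drop = FALSE]
  }
  if (nrow(centers) < 2) {
    field_detection_failure("all candidates collapse to a single cluster",
                            list(n_candidates = length(cands)))
  }
  w <- img_width(strip_image); h <- img_height(strip_image)
  inset <- 0.5 * side
  pitch <- robust_pitch(centers, side) %||% (1.45 * side)
  extent <- estimate_strip_extent(strip_image, centers, side, pitch)
  bounds <- if (is.null(extent)) {
    c(inset, w - 1 - inset, inset, h - 1 - inset)
  } else {
    c(max(extent[1] + inset, inset), min(extent[2] - inset, w - 1 - inset),
      max(extent[3], inset * 0.5), min(extent[4], h - 1 - inset * 0.5))
  }
  # pads lie on the strip: detected centers outside its extent are artifacts
  inb <- centers[, 1] >= bounds[1] - 2 & centers[, 1] <= bounds[2] + 2 &
    centers[, 2] >= bounds[3] - 2 & centers[, 2] <= bounds[4] + 2
  if (sum(inb) >= 2 && any(!inb)) {
    centers <- centers[inb, , drop = FALSE]
    pitch <- robust_pitch(centers, side) %||% pitch
  }
  grid <- complete_field_grid(centers, expected, bounds = bounds,
                              pitch = pitch)
  half <- side * 0.5 / 2
  patches <- vector("list", expected)
  pnames <- names(layout$parameters)
  for (i in seq_len(expected)) {
    c_i <- grid$centers[i, ]
    c_i[1] <- min(max(c_i[1], half), w - half)
    c_i[2] <- min(max(c_i[2], half), h - half)
    rc <- c(c_i[1] - half, c_i[2] - half, 2 * half, 2 * half)
    patches[[i]] <- new_field_patch(crop_rect(strip_image, rc), rc,
                                    "test-field", pnames[i])
  }
  attr(patches, "grid") <- grid
  attr(patches, "n_candidates") <- length(cands)
  patches
}
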