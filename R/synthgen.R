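# Synthetic scene generation.
#
# Renders the canonical reference card and a dipped strip with planted level
# colors, composites them onto a procedurally generated background under a
# seeded perspective warp, applies brightness shift, Gaussian blur and pixel
# noise (in that fixed order), and records a full ground-truth manifest so
# every pipeline stage can be tested without a photograph.

CARD_BASE_RGB <- c(0.97, 0.97, 0.95)
STRIP_BASE_RGB <- c(0.93, 0.93, 0.90)

#' Render the canonical reference card
#'
#' Paints every (parameter, level) swatch at its layout coordinates on a
#' near-white card, with dark swatch outlines and a deterministic
#' high-contrast fiducial block border (the texture that binary-descriptor
#' matching locks onto). The rendering is the package's canonical card
#' template: card coordinates in the layout are measured in this frame.
#'
#' @param layout A `strip_layout` whose levels carry `color` entries.
#' @return Color array of size `layout$card_size`.
#' @export
paint_card_template <- function(layout) {
  w <- layout$card_size[1]; h <- layout$card_size[2]
  img <- array(rep(CARD_BASE_RGB, each = w * h), dim = c(w, h, 3))
  # fiducial art: an aperiodic constellation of discs and squares in the
  # card margins (outside the swatch area), at mixed sizes and gray levels.
  # Deterministic (private seed), high contrast, and unique everywhere, so
  # that binary descriptors remain discriminative under blur and rescaling.
  sw_area <- swatch_bbox(layout)
  img <- with_seed(71501, {
    margins <- margin_rects(w, h, sw_area)
    total <- sum(vapply(margins, function(r) r[3] * r[4], numeric(1)))
    for (i in 1:110) {
      r <- margins[[sample.int(length(margins), 1,
                               prob = vapply(margins, function(m) m[3] * m[4],
                                             numeric(1)) / total)]]
      rad <- min(stats::runif(1, 2.5, 9), (r[3] - 1) / 2, (r[4] - 1) / 2)
      cx <- stats::runif(1, r[1] + rad, r[1] + r[3] - rad)
      cy <- stats::runif(1, r[2] + rad, r[2] + r[4] - rad)
      g <- stats::runif(1, 0, 0.75)
      if (stats::runif(1) < 0.5) {
        img <- fill_disc(img, cx, cy, rad, rep(g, 3))
      } else {
        img <- fill_rect(img, c(cx - rad, cy - rad, 2 * rad, 2 * rad),
                         rep(g, 3))
      }
    }
    img
  })
  # frame line around the swatch area
  bb <- sw_area
  img <- fill_rect(img, c(bb[1] - 4, bb[2] - 4, bb[3] + 8, 2), c(0.1, 0.1, 0.1))
  img <- fill_rect(img, c(bb[1] - 4, bb[2] + bb[4] + 2, bb[3] + 8, 2), c(0.1, 0.1, 0.1))
  img <- fill_rect(img, c(bb[1] - 4, bb[2] - 4, 2, bb[4] + 8), c(0.1, 0.1, 0.1))
  img <- fill_rect(img, c(bb[1] + bb[3] + 2, bb[2] - 4, 2, bb[4] + 8), c(0.1, 0.1, 0.1))
  for (pname in names(layout$parameters)) {
    p <- layout$parameters[[pname]]
    for (lname in names(p$levels)) {
      col <- p$levels[[lname]]$color
      if (is.null(col)) {
        stop(sprintf("level '%s' of '%s' has no color; the template cannot %s",
                     lname, pname, "be painted"), call. = FALSE)
      }
      r <- layout$card_coords[[pname]][[lname]]
      img <- fill_rect(img, r + c(-1, -1, 2, 2), c(0.15, 0.15, 0.15))
      img <- fill_rect(img, r, hex_to_rgb(col))
    }
  }
  img
}

#' Render the canonical strip with planted levels
#'
#' @param layout A `strip_layout`.
#' @param planted_levels Named character vector/list mapping every parameter
#'   to one of its level labels; defaults to each parameter's lowest level.
#' @param degrade_fields Parameters whose field is rendered with suppressed
#'   contrast (washed out toward the strip background), emulating a pad
#'   whose edges the detector cannot see.
#' @return Color array of size `layout$strip_size`.
#' @export
paint_strip_template <- function(layout, planted_levels = NULL,
                                 degrade_fields = character()) {
  planted_levels <- resolve_planted(layout, planted_levels)
  w <- layout$strip_size[1]; h <- layout$strip_size[2]
  img <- array(rep(STRIP_BASE_RGB, each = w * h), dim = c(w, h, 3))
  rects <- strip_field_rects(layout)
  for (i in seq_along(rects)) {
    pname <- names(rects)[i]
    lv <- layout$parameters[[pname]]$levels[[planted_levels[[pname]]]]
    if (is.null(lv)) {
      stop(sprintf("planted level '%s' not defined for parameter '%s'",
                   planted_levels[[pname]], pname), call. = FALSE)
    }
    rgb <- hex_to_rgb(lv$color)
    if (pname %in% degrade_fields) {
      rgb <- 0.9 * STRIP_BASE_RGB + 0.1 * rgb
    }
    img <- fill_rect(img, rects[[i]], rgb)
  }
  img
}

# Bounding box of all swatch rectangles, c(x, y, w, h).
swatch_bbox <- function(layout) {
  rr <- do.call(rbind, lapply(unlist(layout$card_coords, recursive = FALSE),
                              function(r) c(r[1], r[2], r[1] + r[3], r[2] + r[4])))
  x0 <- min(rr[, 1]); y0 <- min(rr[, 2])
  c(x0, y0, max(rr[, 3]) - x0, max(rr[, 4]) - y0)
}

# Rectangles covering the card outside the (framed) swatch area, inset from
# the physical border so keypoints there survive descriptor margins.
margin_rects <- function(w, h, sw) {
  inset <- 4
  x0 <- sw[1] - 8; y0 <- sw[2] - 8
  x1 <- sw[1] + sw[3] + 8; y1 <- sw[2] + sw[4] + 8
  out <- list(c(inset, inset, w - 2 * inset, y0 - inset),          # top
              c(inset, y1, w - 2 * inset, h - inset - y1),         # bottom
              c(inset, y0, x0 - inset, y1 - y0),                   # left
              c(x1, y0, w - inset - x1, y1 - y0))                  # right
  out[vapply(out, function(r) r[3] > 12 && r[4] > 12, logical(1))]
}

# Filled disc, color rgb (length 3).
fill_disc <- function(img, cx, cy, rad, rgb) {
  w <- img_width(img); h <- img_height(img)
  xs <- max(1, floor(cx - rad)):min(w, ceiling(cx + rad))
  ys <- max(1, floor(cy - rad)):min(h, ceiling(cy + rad))
  gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
  m <- (gx - 1 - cx)^2 + (gy - 1 - cy)^2 <= rad^2
  for (c in 1:3) img[cbind(gx[m], gy[m], c)] <- rgb[c]
  img
}

# Canonical strip field rectangles c(x, y, w, h), named by parameter, evenly
# pitched along the strip from the dipped (left) end.
strip_field_rects <- function(layout) {
  n <- length(layout$parameters)
  side <- layout$field_side; pitch <- layout$field_pitch
  w <- layout$strip_size[1]; h <- layout$strip_size[2]
  x0 <- (w - (n - 1) * pitch - side) / 2
  y0 <- (h - side) / 2
  rects <- lapply(seq_len(n) - 1, function(i) c(x0 + i * pitch, y0, side, side))
  names(rects) <- names(layout$parameters)
  rects
}

resolve_planted <- function(layout, planted_levels) {
  if (is.null(planted_levels)) {
    planted_levels <- vapply(layout$parameters,
                             function(p) names(p$levels)[1], character(1))
  }
  planted_levels <- as.list(planted_levels)
  for (pname in names(layout$parameters)) {
    if (is.null(planted_levels[[pname]])) {
      stop(sprintf("no planted level for parameter '%s'", pname),
           call. = FALSE)
    }
    if (!planted_levels[[pname]] %in% names(layout$parameters[[pname]]$levels)) {
      stop(sprintf("planted level '%s' not defined for parameter '%s'",
                   planted_levels[[pname]], pname), call. = FALSE)
    }
  }
  planted_levels[names(layout$parameters)]
}

#' Scene configuration for the synthetic generator
#'
#' Defaults emulate the study conditions: handheld photographs of the card
#' and strip on a varied surface with moderate perspective, mild defocus and
#' sensor noise.
#'
#' @param seed Integer seed; every random choice derives from it.
#' @param planted_levels Named mapping parameter -> level label, or `NULL`
#'   to draw one uniformly at random per parameter.
#' @param warp_magnitude Corner displacement as a fraction of object size,
#'   in `[0, 0.3]`.
#' @param blur_sigma_px Gaussian blur sigma (pixels), `>= 0`.
#' @param brightness_delta Additive brightness shift in `[-0.3, 0.3]`.
#' @param noise_sigma Gaussian pixel noise sd in `[0, 0.1]`.
#' @param background `"solid"`, `"texture"` or `"photo-like"`.
#' @param degrade_fields Parameters rendered with suppressed contrast.
#' @param scene_size Scene width and height in pixels.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(seed, planted_levels = NULL, warp_magnitude = 0.12,
                         blur_sigma_px = 0.8, brightness_delta = 0,
                         noise_sigma = 0.01, background = "texture",
                         degrade_fields = character(),
                         scene_size = c(640, 480)) {
  stopifnot(warp_magnitude >= 0, warp_magnitude <= 0.3,
            blur_sigma_px >= 0,
            brightness_delta >= -0.3, brightness_delta <= 0.3,
            noise_sigma >= 0, noise_sigma <= 0.1)
  background <- match.arg(background, c("solid", "texture", "photo-like"))
  structure(list(seed = as.integer(seed), planted_levels = planted_levels,
                 warp_magnitude = warp_magnitude,
                 blur_sigma_px = blur_sigma_px,
                 brightness_delta = brightness_delta,
                 noise_sigma = noise_sigma, background = background,
                 degrade_fields = degrade_fields, scene_size = scene_size),
            class = "scene_config")
}

#' Render a synthetic scene with ground truth
#'
#' Composites the painted card (left half) and strip (right half) onto a
#' procedural background under independent seeded perspective warps, then
#' applies brightness shift, blur and noise in that fixed order.
#'
#' @param layout A `strip_layout`.
#' @param config A [scene_config()].
#' @return List `image` (color array) and `truth` (a `ground_truth`:
#'   `card_homography` / `strip_homography` canonical-to-scene 3x3
#'   transforms, `card_quad` / `strip_quad` 4x2 scene corner quads (TL, TR,
#'   BR, BL), `field_rects_scene` per-parameter 4x2 quads,
#'   `planted_levels`, `planted_colors` (per-parameter `hsv_peak` of the
#'   planted reference color), `seed`, `config`).
#' @export
render_scene <- function(layout, config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    planted <- resolve_planted(layout, config$planted_levels %||%
                                 sample_planted(layout))
    sw <- config$scene_size[1]; sh <- config$scene_size[2]
    img <- render_background(sw, sh, config$background)

    card <- paint_card_template(layout)
    strip <- paint_strip_template(layout, planted, config$degrade_fields)

    cw <- img_width(card); ch <- img_height(card)
    f_c <- stats::runif(1, 0.62, 0.78) * min(sw * 0.52 / cw, sh * 0.95 / ch) /
      0.78 * 0.95
    card_quad <- place_quad(cw, ch, f_c, config$warp_magnitude,
                            xlim = c(6, sw * 0.52), ylim = c(6, sh - 6))
    H_card <- homography_from_points(obj_corners(cw, ch), card_quad)
    img <- composite_warped(img, card, H_card, card_quad)

    tw <- img_width(strip); th <- img_height(strip)
    f_s <- stats::runif(1, 0.5, 0.62)
    strip_quad <- place_quad(tw, th, f_s, config$warp_magnitude,
                             xlim = c(sw * 0.54, sw - 6), ylim = c(6, sh - 6))
    H_strip <- homography_from_points(obj_corners(tw, th), strip_quad)
    img <- composite_warped(img, strip, H_strip, strip_quad)

    img <- clamp01(img + config$brightness_delta)
    if (config$blur_sigma_px > 0) img <- blur_image(img, config$blur_sigma_px)
    if (config$noise_sigma > 0) {
      img <- clamp01(img + stats::rnorm(length(img), 0, config$noise_sigma))
    }

    rects <- strip_field_rects(layout)
    field_quads <- lapply(rects, function(r) {
      apply_homography(H_strip, rect_corners(r))
    })
    colors <- lapply(names(layout$parameters), function(pn) {
      rgb <- hex_to_rgb(layout$parameters[[pn]]$levels[[planted[[pn]]]]$color)
      hsv <- grDevices::rgb2hsv(rgb[1], rgb[2], rgb[3], maxColorValue = 1)
      hsv_peak_value((hsv[1] * 360) %% 360, hsv[2], hsv[3])
    })
    names(colors) <- names(layout$parameters)

    truth <- structure(list(card_homography = H_card,
                            strip_homography = H_strip,
                            card_quad = card_quad, strip_quad = strip_quad,
                            field_rects_scene = field_quads,
                            planted_levels = planted,
                            planted_colors = colors,
                            seed = config$seed, config = config),
                       class = "ground_truth")
    list(image = img, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a synthetic strip crop with ground truth
#'
#' The roughly axis-aligned strip crop a user (or an upstream strip
#' detector) would hand to [locate_test_fields()]: the painted strip under a
#' mild seeded warp on a background margin, followed by the standard
#' brightness/blur/noise degradations. The warp magnitude is capped at 0.06
#' because the crop is axis-aligned by construction.
#'
#' @param layout A `strip_layout`.
#' @param config A [scene_config()]; `planted_levels`, `degrade_fields`,
#'   `blur_sigma_px`, `brightness_delta`, `noise_sigma`, `background` and
#'   `seed` are honoured, `warp_magnitude` is capped.
#' @param margin Background margin around the strip, pixels.
#' @return List `image` (crop) and `truth` (`field_rects` per-parameter 4x2
#'   quads in crop coordinates, `planted_levels`, `planted_colors`,
#'   `strip_homography`, `seed`).
#' @export
render_strip_crop <- function(layout, config, margin = 14) {
  stopifnot(inherits(config, "scene_config"))
  warp <- min(config$warp_magnitude, 0.06)
  with_seed(config$seed + 1L, {
    planted <- resolve_planted(layout, config$planted_levels %||%
                                 sample_planted(layout))
    strip <- paint_strip_template(layout, planted, config$degrade_fields)
    tw <- img_width(strip); th <- img_height(strip)
    cw <- tw + 2 * margin; ch <- th + 2 * margin
    img <- render_background(cw, ch, config$background)
    jx <- warp * tw; jy <- warp * th
    base <- rbind(c(margin, margin), c(margin + tw, margin),
                  c(margin + tw, margin + th), c(margin, margin + th))
    quad <- base + cbind(stats::runif(4, -jx, jx), stats::runif(4, -jy, jy))
    H <- homography_from_points(obj_corners(tw, th), quad)
    img <- composite_warped(img, strip, H, quad)
    img <- clamp01(img + config$brightness_delta)
    if (config$blur_sigma_px > 0) img <- blur_image(img, config$blur_sigma_px)
    if (config$noise_sigma > 0) {
      img <- clamp01(img + stats::rnorm(length(img), 0, config$noise_sigma))
    }
    rects <- strip_field_rects(layout)
    field_quads <- lapply(rects, function(r) apply_homography(H, rect_corners(r)))
    colors <- lapply(names(layout$parameters), function(pn) {
      rgb <- hex_to_rgb(layout$parameters[[pn]]$levels[[planted[[pn]]]]$color)
      hsv <- grDevices::rgb2hsv(rgb[1], rgb[2], rgb[3], maxColorValue = 1)
      hsv_peak_value((hsv[1] * 360) %% 360, hsv[2], hsv[3])
    })
    names(colors) <- names(layout$parameters)
    list(image = img,
         truth = list(field_rects = field_quads, planted_levels = planted,
                      planted_colors = colors, strip_homography = H,
                      seed = config$seed))
  })
}

sample_planted <- function(layout) {
  vapply(layout$parameters, function(p) {
    names(p$levels)[sample.int(length(p$levels), 1)]
  }, character(1))
}

obj_corners <- function(w, h) {
  rbind(c(0, 0), c(w - 1, 0), c(w - 1, h - 1), c(0, h - 1))
}

rect_corners <- function(r) {
  rbind(c(r[1], r[2]), c(r[1] + r[3], r[2]),
        c(r[1] + r[3], r[2] + r[4]), c(r[1], r[2] + r[4]))
}

# Random placement quad: the object scaled by f, placed inside [xlim, ylim],
# each corner then displaced uniformly within warp * scaled size.
place_quad <- function(w, h, f, warp, xlim, ylim) {
  ww <- w * f; hh <- h * f
  jx <- warp * ww; jy <- warp * hh
  x0 <- stats::runif(1, xlim[1] + jx, max(xlim[1] + jx,
                                          xlim[2] - ww - jx))
  y0 <- stats::runif(1, ylim[1] + jy, max(ylim[1] + jy,
                                          ylim[2] - hh - jy))
  base <- rbind(c(x0, y0), c(x0 + ww, y0),
                c(x0 + ww, y0 + hh), c(x0, y0 + hh))
  base + cbind(stats::runif(4, -jx, jx), stats::runif(4, -jy, jy))
}

# Paste `obj` into `img` through the canonical-to-scene homography H,
# sampling bilinearly; only scene pixels inside the quad are touched.
composite_warped <- function(img, obj, H, quad) {
  Hi <- solve(H)
  x0 <- max(1, floor(min(quad[, 1]))); x1 <- min(img_width(img), ceiling(max(quad[, 1])) + 1)
  y0 <- max(1, floor(min(quad[, 2]))); y1 <- min(img_height(img), ceiling(max(quad[, 2])) + 1)
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs - 1, times = length(ys))
  gy <- rep(ys - 1, each = length(xs))
  inside <- points_in_poly(gx, gy, quad)
  if (!any(inside)) return(img)
  p <- apply_homography(Hi, cbind(gx[inside], gy[inside]))
  ok <- p[, 1] >= 0 & p[, 1] <= img_width(obj) - 1 &
    p[, 2] >= 0 & p[, 2] <= img_height(obj) - 1
  if (!any(ok)) return(img)
  vals <- bilinear_sample(obj, p[ok, 1], p[ok, 2])
  ix <- gx[inside][ok] + 1; iy <- gy[inside][ok] + 1
  for (c in 1:3) img[cbind(ix, iy, c)] <- vals[, c]
  img
}

render_background <- function(w, h, kind) {
  base <- stats::runif(3, 0.15, 0.85)
  img <- array(rep(base, each = w * h), dim = c(w, h, 3))
  if (kind == "solid") return(img)
  # smooth low-frequency texture
  coarse <- array(stats::runif(ceiling(w / 16) * ceiling(h / 16) * 3, -0.5, 0.5),
                  dim = c(ceiling(w / 16), ceiling(h / 16), 3))
  tex <- resize_image(coarse, w, h)
  img <- clamp01(img + 0.25 * tex)
  if (kind == "texture") {
    fine <- array(stats::runif(w * h, -0.5, 0.5), dim = c(w, h))
    for (c in 1:3) img[, , c] <- img[, , c] + 0.06 * fine
    return(clamp01(img))
  }
  # photo-like: add random soft shapes at several scales
  for (i in 1:8) {
    cx <- stats::runif(1, 0, w); cy <- stats::runif(1, 0, h)
    r <- stats::runif(1, 20, 120)
    col <- stats::runif(3, 0, 1)
    a <- stats::runif(1, 0.2, 0.6)
    xs <- pmax(1, floor(cx - r)):pmin(w, ceiling(cx + r))
    ys <- pmax(1, floor(cy - r)):pmin(h, ceiling(cy + r))
    gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
    m <- (gx - cx)^2 + (gy - cy)^2 <= r^2
    for (c in 1:3) {
      v <- img[cbind(gx[m], gy[m], c)]
      img[cbind(gx[m], gy[m], c)] <- (1 - a) * v + a * col[c]
    }
  }
  clamp01(img)
}

#' Generate a seeded synthetic dataset
#'
#' Renders `n` scenes with per-scene seeds derived from the master seed and
#' planted levels drawn uniformly per parameter, writes `scene_<i>.png`
#' images and a JSON-lines manifest linking each image to its ground truth.
#'
#' @param layout A `strip_layout`.
#' @param n Number of scenes, `>= 1`.
#' @param base_config A [scene_config()] providing the degradation settings
#'   (its seed and planted levels are overridden per scene).
#' @param seed Master seed.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list of records (`image`, `seed`,
#'   `planted_levels`, `truth_classes`, `strip_quad`); also written to
#'   `manifest.jsonl` in `dir`.
#' @export
generate_dataset <- function(layout, n, base_config, seed, dir) {
  stopifnot(n >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- with_seed(seed, sample.int(2147483646L, n))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- base_config
    cfg$seed <- seeds[i]
    cfg$planted_levels <- NULL
    sc <- render_scene(layout, cfg)
    file <- sprintf("scene_%04d.png", i)
    write_image(sc$image, file.path(dir, file))
    truth_classes <- lapply(names(layout$parameters), function(pn) {
      classify(layout$parameters[[pn]], sc$truth$planted_levels[[pn]])
    })
    names(truth_classes) <- names(layout$parameters)
    records[[i]] <- list(image = file, seed = seeds[i],
                         planted_levels = sc$truth$planted_levels,
                         truth_classes = truth_classes,
                         strip_quad = sc$truth$strip_quad,
                         card_quad = sc$truth$card_quad)
  }
  con <- file(file.path(dir, "manifest.jsonl"), "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(records)
}
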