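# Template detection and rectification: match binary features between a
# canonical template and a scene, estimate the homography robustly, and warp
# the scene into the template frame.

#' Detection configuration
#'
#' @param max_features Keypoint budget per image for [extract_features()].
#' @param matches_kept How many best (lowest Hamming distance) matches feed
#'   the homography estimate.
#' @param ransac_threshold_px Reprojection threshold for consensus counting.
#' @param min_matches,min_inliers Minimum kept matches / consensus inliers
#'   for a detection to be accepted.
#' @param ransac_iter Maximum random 4-point samples.
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(max_features = 500, matches_kept = 50,
                          ransac_threshold_px = 5, min_matches = 10,
                          min_inliers = 8, ransac_iter = 1000) {
  structure(list(max_features = max_features, matches_kept = matches_kept,
                 ransac_threshold_px = ransac_threshold_px,
                 min_matches = min_matches, min_inliers = min_inliers,
                 ransac_iter = ransac_iter),
            class = "detect_params")
}

detection_failure <- function(msg, diagnostics = list()) {
  stop(structure(class = c("detection_failure", "stripreader_error",
                           "error", "condition"),
                 list(message = msg, call = NULL, diagnostics = diagnostics)))
}

#' Locate a planar template in a scene and rectify it
#'
#' Extracts binary features from the grayscale template and scene, matches
#' them exhaustively by Hamming distance keeping the best matches, estimates
#' the template-to-scene homography with a RANSAC consensus (reprojection
#' threshold `ransac_threshold_px`, least-squares refit on the inliers), and
#' warps the scene into the template's canonical frame.
#'
#' @param scene Color array (the photograph).
#' @param template Color array (the canonical card or strip rendering).
#' @param params A [detect_params()] configuration.
#' @param seed Integer seed for the random consensus sampling.
#' @param template_features Optional precomputed [extract_features()] result
#'   for `template` (an optimization for batch runs).
#' @return List with `detection` (a `detected_object`: `corners` 4x2 scene
#'   coordinates ordered TL, TR, BR, BL; `homography` mapping scene to
#'   canonical coordinates; `n_matches_kept`; `n_inliers`) and `rectified`
#'   (the scene warped to the template's size).
#' @section Failure: when too few matches or inliers are found, or the
#'   recovered quadrilateral is non-convex or degenerate, a condition of
#'   class `detection_failure` is signalled carrying the match diagnostics.
#' @export
detect_and_rectify <- function(scene, template, params = detect_params(),
                               seed = 1, template_features = NULL) {
  tf <- if (is.null(template_features)) {
    template_feature_bank(template, params)
  } else template_features
  sf <- extract_features(scene, params$max_features)
  m <- match_features(tf, sf, n_keep = params$matches_kept)
  diag <- list(n_template_keypoints = nrow(tf$keypoints),
               n_scene_keypoints = nrow(sf$keypoints),
               n_matches_kept = nrow(m))
  if (nrow(m) < params$min_matches) {
    detection_failure(sprintf("only %d matches kept (minimum %d)",
                              nrow(m), params$min_matches), diag)
  }
  # estimation hygiene: a scene keypoint may be the nearest neighbour of
  # many template keypoints; keep only its lowest-distance match, so that
  # many-to-one collapses cannot masquerade as consensus.
  mu <- m[!duplicated(m$j), , drop = FALSE]
  src <- as.matrix(tf$keypoints[mu$i, c("x", "y")])
  dst <- as.matrix(sf$keypoints[mu$j, c("x", "y")])
  fit <- with_seed(seed, ransac_homography(src, dst,
                                           thr = params$ransac_threshold_px,
                                           max_iter = params$ransac_iter))
  diag$n_inliers <- fit$n_inliers
  if (is.null(fit$H) || fit$n_inliers < params$min_inliers) {
    detection_failure(sprintf("only %d consensus inliers (minimum %d)",
                              fit$n_inliers, params$min_inliers), diag)
  }
  tw <- img_width(template); th <- img_height(template)
  tpl_corners <- rbind(c(0, 0), c(tw - 1, 0), c(tw - 1, th - 1), c(0, th - 1))
  corners <- apply_homography(fit$H, tpl_corners)
  if (!is_convex_quad(corners)) {
    detection_failure("recovered quadrilateral is not convex", diag)
  }
  area <- abs(polygon_area(corners))
  if (area < 0.01 * img_width(scene) * img_height(scene)) {
    detection_failure(sprintf("recovered area %.0f px^2 below 1%% of scene",
                              area), diag)
  }
  rectified <- warp_image(scene, fit$H, tw, th)
  det <- structure(list(corners = corners,
                        homography = solve(fit$H) / solve(fit$H)[3, 3],
                        n_matches_kept = nrow(m),
                        n_inliers = fit$n_inliers),
                   class = "detected_object")
  list(detection = det, rectified = rectified)
}

#' Template feature bank
#'
#' Features of the canonical template extracted from both the sharp
#' rendering and a defocused (Gaussian sigma 1.2 px) one, concatenated.
#' Photographs are frequently slightly out of focus, and binary descriptors
#' computed on a sharp template stop matching under defocus; the blurred
#' variant restores those matches. Precompute this once when detecting the
#' same template in many scenes.
#'
#' @param template Color array.
#' @param params A [detect_params()] configuration.
#' @return A `feature_set` with up to `2 * max_features` keypoints.
#' @export
template_feature_bank <- function(template, params = detect_params()) {
  a <- extract_features(template, params$max_features)
  b <- extract_features(blur_image(template, 1.2), params$max_features)
  structure(list(keypoints = rbind(a$keypoints, b$keypoints),
                 descriptors = rbind(a$descriptors, b$descriptors)),
            class = "feature_set")
}

#' @export
print.detected_object <- function(x, ...) {
  cat(sprintf("<detected_object> %d/%d inliers/matches\n",
              x$n_inliers, x$n_matches_kept))
  cat("corners (TL TR BR BL):\n")
  print(round(x$corners, 2))
  invisible(x)
}

# A consensus set is degenerate when its scene points barely spread beyond
# the inlier threshold (a collapsing transform can "explain" such a set).
degenerate_consensus <- function(dst, inl, thr) {
  if (sum(inl) < 4) return(TRUE)
  p <- dst[inl, , drop = FALSE]
  stats::sd(p[, 1]) + stats::sd(p[, 2]) < 4 * thr
}

# RANSAC homography src -> dst. Returns list(H, inliers, n_inliers).
# Caller is responsible for seeding the RNG.
ransac_homography <- function(src, dst, thr = 5, max_iter = 1000) {
  n <- nrow(src)
  if (n < 4) return(list(H = NULL, inliers = logical(n), n_inliers = 0))
  best <- list(H = NULL, inliers = logical(n), n_inliers = 0)
  collinear <- function(p) {
    for (tri in utils::combn(4, 3, simplify = FALSE)) {
      a <- p[tri[1], ]; b <- p[tri[2], ]; c <- p[tri[3], ]
      cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
      if (abs(cr) < 1e-6) return(TRUE)
    }
    FALSE
  }
  iter_needed <- max_iter
  i <- 0
  while (i < min(max_iter, iter_needed)) {
    i <- i + 1
    pick <- sample.int(n, 4)
    s4 <- src[pick, ]; d4 <- dst[pick, ]
    if (anyDuplicated(s4) || anyDuplicated(d4)) next
    if (collinear(s4) || collinear(d4)) next
    H <- tryCatch(homography_from_points(s4, d4), error = function(e) NULL)
    if (is.null(H) || abs(det(H)) < 1e-12) next
    proj <- apply_homography(H, src)
    err <- sqrt(rowSums((proj - dst)^2))
    inl <- err < thr
    ni <- sum(inl)
    if (ni > best$n_inliers && !degenerate_consensus(dst, inl, thr)) {
      best <- list(H = H, inliers = inl, n_inliers = ni)
      # adaptive stopping (99.9% confidence)
      w <- ni / n
      if (w > 0) {
        p_out <- 1 - w^4
        iter_needed <- if (p_out < 1e-12) i else log(0.001) / log(p_out)
      }
    }
  }
  if (best$n_inliers >= 4) {
    # least-squares refit on the consensus set, two rounds
    for (r in 1:2) {
      H <- tryCatch(homography_from_points(src[best$inliers, , drop = FALSE],
                                           dst[best$inliers, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(H)) break
      err <- sqrt(rowSums((apply_homography(H, src) - dst)^2))
      inl <- err < thr
      if (sum(inl) >= best$n_inliers && !degenerate_consensus(dst, inl, thr)) {
        best <- list(H = H, inliers = inl, n_inliers = sum(inl))
      }
    }
  }
  best
}
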