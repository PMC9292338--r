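# Dominant-color extraction and HSV color similarity.
#
# A patch's color is summarized per channel by the peak of its histogram
# (360 hue bins, 256 saturation/value bins), and two colors are compared by
# one of three measures: circular hue difference, a weighted HSV matching
# factor (hue weighted alpha = 0.6429, saturation/value beta = 0.1786), or
# Euclidean distance between HSV cylinder coordinates. All three are
# normalized similarities in [0, 1].

MF_ALPHA <- 0.6429
MF_BETA <- 0.1786

#' Construct an HSV peak
#'
#' @param h Hue in degrees, `[0, 360)`.
#' @param s,v Saturation and value in `[0, 1]`.
#' @return An `hsv_peak` object. Achromatic colors (`s = 0`) report hue 0.
#' @export
hsv_peak_value <- function(h, s, v) {
  stopifnot(s >= 0, s <= 1, v >= 0, v <= 1)
  h <- h %% 360
  if (s == 0) h <- 0
  structure(list(h = h, s = s, v = v), class = "hsv_peak")
}

#' @export
print.hsv_peak <- function(x, ...) {
  cat(sprintf("<hsv_peak> h=%.1f deg s=%.3f v=%.3f\n", x$h, x$s, x$v))
  invisible(x)
}

#' Dominant HSV color of a patch by histogram peak
#'
#' Converts the patch to HSV and, independently per channel, histograms the
#' pixel values (360 one-degree bins for hue; 256 bins for saturation and
#' value) and returns the center of the most populated bin. Ties break toward
#' the lowest bin.
#'
#' @param patch A color array (width x height x 3), or a `field_patch` as
#'   produced by the field-extraction functions.
#' @param achromatic_eps Saturation below which the patch is treated as
#'   achromatic and hue is reported as 0.
#' @return An `hsv_peak`.
#' @export
hsv_peak <- function(patch, achromatic_eps = 1 / 256) {
  if (inherits(patch, "field_patch")) patch <- patch$pixels
  patch <- unclass(patch)
  if (length(patch) == 0 || any(dim(patch)[1:2] == 0)) {
    stop("empty patch", call. = FALSE)
  }
  hsv <- to_hsv(patch)
  hch <- as.vector(hsv[, , 1]); sch <- as.vector(hsv[, , 2])
  vch <- as.vector(hsv[, , 3])
  hbin <- pmin(floor(hch), 359)
  sbin <- pmin(floor(sch * 256), 255)
  vbin <- pmin(floor(vch * 256), 255)
  peak_bin <- function(bins, n) {
    counts <- tabulate(bins + 1L, nbins = n)
    which.max(counts) - 1L  # first maximum = lowest bin on ties
  }
  h <- peak_bin(hbin, 360L) + 0.5
  s <- (peak_bin(sbin, 256L) + 0.5) / 256
  v <- (peak_bin(vbin, 256L) + 0.5) / 256
  if (s < achromatic_eps) h <- 0
  hsv_peak_value(h %% 360, s, v)
}

# circular hue difference in degrees, in [0, 180]
hue_delta <- function(ha, hb) {
  d <- abs(ha - hb) %% 360
  pmin(d, 360 - d)
}

#' Hue-channel similarity
#'
#' `1 - dH / 360` with `dH` the circular hue difference in degrees; ranges
#' over `[0.5, 1]` for chromatic colors. When `achromatic_guard` is on and
#' either color is nearly achromatic (saturation < 0.05), hue is unreliable
#' and the score falls back to the matching factor's saturation/value terms.
#'
#' @param a,b `hsv_peak` objects.
#' @param achromatic_guard Logical; see above.
#' @return Similarity in `[0, 1]`.
#' @export
similarity_hue <- function(a, b, achromatic_guard = TRUE) {
  if (achromatic_guard && (a$s < 0.05 || b$s < 0.05)) {
    return(1 - (MF_BETA * abs(a$s - b$s) + MF_BETA * abs(a$v - b$v)) / 3)
  }
  1 - hue_delta(a$h, b$h) / 360
}

#' Weighted HSV matching factor
#'
#' `1 - (alpha dH + beta dS + beta dV) / 3` with all channel differences on
#' the unit scale (`dH` = circular hue difference / 360) and the weights
#' `alpha = 0.6429`, `beta = 0.1786`.
#'
#' @param a,b `hsv_peak` objects.
#' @return Similarity in `[0, 1]`.
#' @export
similarity_matching_factor <- function(a, b) {
  dh <- hue_delta(a$h, b$h) / 360
  1 - (MF_ALPHA * dh + MF_BETA * abs(a$s - b$s) + MF_BETA * abs(a$v - b$v)) / 3
}

#' Euclidean similarity in HSV cylinder coordinates
#'
#' Each color maps to `(s cos h, s sin h, v)`; the similarity is
#' `1 - d / sqrt((2 S_max)^2 + V_max^2) = 1 - d / sqrt(5)` where `d` is the
#' Euclidean distance between the two points.
#'
#' @param a,b `hsv_peak` objects.
#' @return Similarity in `[0, 1]`.
#' @export
similarity_euclidean <- function(a, b) {
  ta <- a$h * pi / 180; tb <- b$h * pi / 180
  dx <- a$s * cos(ta) - b$s * cos(tb)
  dy <- a$s * sin(ta) - b$s * sin(tb)
  dz <- a$v - b$v
  1 - sqrt(dx^2 + dy^2 + dz^2) / sqrt(5)
}

SIMILARITY_METHODS <- c("hue", "matching_factor", "euclidean")

#' Compare two colors with a named method
#'
#' @param a,b `hsv_peak` objects.
#' @param method One of `"hue"`, `"matching_factor"`, `"euclidean"`.
#' @param achromatic_guard Passed to [similarity_hue()].
#' @return Similarity in `[0, 1]`.
#' @export
similarity <- function(a, b, method, achromatic_guard = TRUE) {
  switch(match.arg(method, SIMILARITY_METHODS),
         hue = similarity_hue(a, b, achromatic_guard),
         matching_factor = similarity_matching_factor(a, b),
         euclidean = similarity_euclidean(a, b))
}

#' Match a test color to the most similar reference level
#'
#' Scores the test color against every reference level with the chosen
#' method and returns the level with the highest similarity; ties break
#' toward the lowest-concentration level (first in the reference order).
#'
#' @param test `hsv_peak` of the test field.
#' @param references List of `list(level = <level>, peak = <hsv_peak>)`,
#'   ordered from lowest to highest concentration.
#' @param method One of `"hue"`, `"matching_factor"`, `"euclidean"`.
#' @param achromatic_guard Passed to [similarity_hue()].
#' @return List with `level`, `score`, `method`, and `scores` (all levels).
#' @export
determine_result <- function(test, references, method,
                             achromatic_guard = TRUE) {
  method <- match.arg(method, SIMILARITY_METHODS)
  stopifnot(length(references) >= 1)
  scores <- vapply(references, function(r) {
    similarity(test, r$peak, method, achromatic_guard)
  }, numeric(1))
  best <- which.max(scores)  # first maximum = lowest level on ties
  list(level = references[[best]]$level, score = scores[best],
       method = method, scores = scores)
}
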