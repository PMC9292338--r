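# Image containers and low-level raster helpers.
#
# Images are numeric arrays in [0, 1] with dim c(width, height, 3) for color
# (EBImage convention; an EBImage::Image is accepted anywhere) or a
# width x height matrix for grayscale. Pixel coordinates are 0-based, x to the
# right, y downward; rectangles are c(x, y, width, height).

#' Read an image file
#'
#' Thin wrapper around [EBImage::readImage()] that always returns a
#' width x height x 3 array in `[0, 1]` (alpha channels are dropped,
#' grayscale is replicated across channels).
#'
#' @param path Path to a PNG or JPEG file.
#' @return Numeric array with dim `c(width, height, 3)`.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- unclass(EBImage::imageData(img))
  if (length(dim(a)) == 2L) {
    a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  } else if (dim(a)[3] > 3L) {
    a <- a[, , 1:3, drop = FALSE]
  } else if (dim(a)[3] == 1L) {
    a <- array(rep(a[, , 1], 3L), dim = c(dim(a)[1:2], 3L))
  }
  clamp01(a)
}

#' Write an image to a PNG file
#'
#' @param img Color array (width x height x 3) or grayscale matrix in `[0, 1]`.
#' @param path Output path; format follows the file extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- clamp01(unclass(img))
  mode <- if (length(dim(img)) == 3L) "Color" else "Grayscale"
  EBImage::writeImage(EBImage::Image(img, colormode = mode), path)
  invisible(path)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

img_width <- function(img) dim(img)[1]
img_height <- function(img) dim(img)[2]

#' Convert a color image to grayscale
#'
#' Uses the Rec. 601 luma weights (0.299, 0.587, 0.114).
#'
#' @param img Color array (width x height x 3); a grayscale matrix is
#'   returned unchanged.
#' @return width x height matrix in `[0, 1]`.
#' @export
to_gray <- function(img) {
  img <- unclass(img)
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# HSV conversion: returns array (w x h x 3) with h in degrees [0, 360),
# s and v in [0, 1].
to_hsv <- function(img) {
  img <- unclass(img)
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  out <- array(0, dim = d)
  out[, , 1] <- (hsv[1, ] * 360) %% 360
  out[, , 2] <- hsv[2, ]
  out[, , 3] <- hsv[3, ]
  out
}

# hex "#RRGGBB" -> length-3 rgb in [0,1]
hex_to_rgb <- function(hex) as.vector(grDevices::col2rgb(hex)) / 255

# Crop a rectangle rect = c(x, y, w, h), 0-based, from a color image or matrix.
# The rectangle is clipped to the image; an error is raised if nothing remains.
crop_rect <- function(img, rect) {
  img <- unclass(img)
  w <- img_width(img); h <- img_height(img)
  x0 <- max(0L, as.integer(round(rect[1])))
  y0 <- max(0L, as.integer(round(rect[2])))
  x1 <- min(w, as.integer(round(rect[1] + rect[3])))
  y1 <- min(h, as.integer(round(rect[2] + rect[4])))
  if (x1 <= x0 || y1 <= y0) {
    stop("crop rectangle [", paste(rect, collapse = ", "),
         "] lies outside the image", call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    img[(x0 + 1):x1, (y0 + 1):y1, , drop = FALSE]
  } else {
    img[(x0 + 1):x1, (y0 + 1):y1, drop = FALSE]
  }
}

# Gaussian blur of a color image or grayscale matrix (sigma in pixels).
# Sigma is clamped so the kernel fits inside the image.
blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  img <- unclass(img)
  sigma <- min(sigma, (min(dim(img)[1:2]) - 3) / 7)
  if (sigma <= 0) return(img)
  mode <- if (length(dim(img)) == 3L) "Color" else "Grayscale"
  out <- EBImage::gblur(EBImage::Image(img, colormode = mode), sigma = sigma)
  a <- unclass(EBImage::imageData(out))
  dim(a) <- dim(img)
  a
}

# Fill an axis-aligned rectangle with a solid color (rgb length-3), in place.
fill_rect <- function(img, rect, rgb) {
  w <- img_width(img); h <- img_height(img)
  xs <- max(1L, round(rect[1]) + 1L):min(w, round(rect[1] + rect[3]))
  ys <- max(1L, round(rect[2]) + 1L):min(h, round(rect[2] + rect[4]))
  for (c in 1:3) img[xs, ys, c] <- rgb[c]
  img
}

# Bilinear sampling of a grayscale matrix or color image at continuous
# 0-based coordinates (vectors x, y). Points outside the image are clamped to
# the border. Returns a vector (gray) or n x 3 matrix (color).
bilinear_sample <- function(img, x, y) {
  img <- unclass(img)
  w <- img_width(img); h <- img_height(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- x0 + 1 + y0 * w; i10 <- x1 + 1 + y0 * w
  i01 <- x0 + 1 + y1 * w; i11 <- x1 + 1 + y1 * w
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  if (length(dim(img)) == 2L) {
    v <- img
    return(w00 * v[i00] + w10 * v[i10] + w01 * v[i01] + w11 * v[i11])
  }
  n <- length(x)
  out <- matrix(0, n, 3)
  npix <- w * h
  for (c in 1:3) {
    v <- img[, , c]
    out[, c] <- w00 * v[i00] + w10 * v[i10] + w01 * v[i01] + w11 * v[i11]
  }
  out
}

# Nearest-neighbour resize of a grayscale matrix or color image by a scale
# factor (bilinear for downscale smoothness).
resize_image <- function(img, new_w, new_h) {
  img <- unclass(img)
  w <- img_width(img); h <- img_height(img)
  xs <- (seq_len(new_w) - 0.5) * w / new_w - 0.5
  ys <- (seq_len(new_h) - 0.5) * h / new_h - 0.5
  gx <- rep(xs, times = new_h)
  gy <- rep(ys, each = new_w)
  if (length(dim(img)) == 2L) {
    matrix(bilinear_sample(img, gx, gy), new_w, new_h)
  } else {
    s <- bilinear_sample(img, gx, gy)
    array(s, dim = c(new_w, new_h, 3))
  }
}

# Run code with a private, restored RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
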