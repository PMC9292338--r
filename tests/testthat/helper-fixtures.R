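# Shared fixtures: a small 3-parameter layout for fast unit tests, and a
# few scene helpers. Everything is generated in code; no stored images.

small_layout <- function() {
  lev <- function(label, value = NULL, unit = NULL, color) {
    out <- list(label = label)
    if (!is.null(value)) out$value <- value
    if (!is.null(unit)) out$unit <- unit
    out$color <- color
    out
  }
  doc <- list(
    parameters = list(
      list(name = "glucose", read_time_s = 30L,
           levels = list(lev("negative", NULL, NULL, "#3BA8A0"),
                         lev("100", 100, "mg/dl", "#8FAE4B"),
                         lev("500", 500, "mg/dl", "#8B6B2E"))),
      list(name = "ph", read_time_s = 60L,
           levels = list(lev("6.0", 6.0, "pH", "#E8A83A"),
                         lev("7.0", 7.0, "pH", "#A8B84A"),
                         lev("8.0", 8.0, "pH", "#4E8A78"))),
      list(name = "protein", read_time_s = 60L,
           levels = list(lev("negative", NULL, NULL, "#E8D84A"),
                         lev("30", 30, "mg/dl", "#A8BE55")))),
    field_side = 30, field_pitch = 44,
    card_size = c(200, 160), strip_size = c(180, 46),
    card_coords = list(
      glucose = list(negative = c(56, 36, 24, 24), "100" = c(88, 36, 24, 24),
                     "500" = c(120, 36, 24, 24)),
      ph = list("6.0" = c(56, 70, 24, 24), "7.0" = c(88, 70, 24, 24),
                "8.0" = c(120, 70, 24, 24)),
      protein = list(negative = c(56, 104, 24, 24),
                     "30" = c(88, 104, 24, 24))))
  as_strip_layout(doc)
}

# A scene config used by several end-to-end tests: moderate perspective,
# no photometric degradation.
clean_config <- function(seed, planted = NULL, ...) {
  scene_config(seed = seed, planted_levels = planted, warp_magnitude = 0.08,
               blur_sigma_px = 0, brightness_delta = 0, noise_sigma = 0, ...)
}

# Strip ROI (x, y, w, h) from a scene ground truth, with margin.
truth_strip_roi <- function(truth, margin = 10) {
  q <- truth$strip_quad
  c(min(q[, 1]) - margin, min(q[, 2]) - margin,
    diff(range(q[, 1])) + 2 * margin, diff(range(q[, 2])) + 2 * margin)
}

# Planted levels that classify negative for every parameter of the default
# layout (the lowest level is positive for specific gravity, whose healthy
# range starts at 1.005).
all_negative_levels <- function(layout) {
  planted <- vapply(layout$parameters, function(p) names(p$levels)[1],
                    character(1))
  if ("specific_gravity" %in% names(planted)) {
    planted[["specific_gravity"]] <- "1.010"
  }
  if ("ph" %in% names(planted)) planted[["ph"]] <- "6.0"
  planted
}

expect_peak_equal <- function(a, b, tol_h = 1.5, tol_sv = 2 / 256) {
  dh <- abs(a$h - b$h) %% 360
  expect_lt(min(dh, 360 - dh), tol_h)
  expect_lt(abs(a$s - b$s), tol_sv)
  expect_lt(abs(a$v - b$v), tol_sv)
}
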