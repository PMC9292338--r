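# Declarative strip/card layout: the single source of truth for parameter
# order, read times, graded levels, and the reference card's field grid.
#
# Conventions used throughout the package: coordinates are 0-based pixels,
# x to the right, y downward; rectangles are c(x, y, width, height) measured
# in the canonical card/strip frames defined by the template renderers.

ALLOWED_READ_TIMES <- c(30L, 40L, 45L, 60L, 120L)

#' Load and validate a strip layout
#'
#' Reads a layout document (JSON or YAML) describing the strip's ordered
#' parameters (with read times and graded levels) and the reference card's
#' level grid, validates it, and returns a `strip_layout` object.
#'
#' @param path Path to a `.json`, `.yaml`/`.yml` layout file.
#' @return A validated `strip_layout`.
#' @export
#' @examples
#' layout <- default_layout()
#' names(layout$parameters)
load_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  as_strip_layout(doc)
}

#' The layout shipped with the package
#'
#' A Multistix-10-SG-style layout: 10 parameters in their physical order from
#' the dipped end, manufacturer read times, and plausible level labels, values
#' and reference colors. Clinical deployments must substitute the actual
#' manufacturer values and measured card coordinates.
#'
#' @return A validated `strip_layout`.
#' @export
default_layout <- function() {
  path <- system.file("extdata", "multistix10sg.json", package = "stripreader")
  if (!nzchar(path)) stop("default layout file not found", call. = FALSE)
  load_layout(path)
}

layout_fail <- function(path, msg) {
  stop(structure(
    class = c("layout_validation_error", "error", "condition"),
    list(message = sprintf("layout invalid at %s: %s", path, msg),
         call = NULL)))
}

#' Construct a strip layout from a parsed document
#'
#' Validates the document against the layout contract: unique parameter and
#' level names, read times in \{30, 40, 45, 60, 120\} s, non-empty ordered
#' levels, a card rectangle for every (parameter, level) lying inside the
#' canonical card, and `field_pitch >= field_side > 0`.
#'
#' @param doc A nested list, as produced by parsing the JSON/YAML schema.
#' @return A `strip_layout` object.
#' @export
as_strip_layout <- function(doc) {
  need <- c("parameters", "field_side", "field_pitch", "card_size",
            "strip_size", "card_coords")
  for (k in need) if (is.null(doc[[k]])) layout_fail(paste0("$", k), "missing")
  field_side <- as.numeric(doc$field_side)
  field_pitch <- as.numeric(doc$field_pitch)
  if (!(field_side > 0)) layout_fail("$field_side", "must be > 0")
  if (field_pitch < field_side) {
    layout_fail("$field_pitch", "must be >= field_side")
  }
  card_size <- as.numeric(unlist(doc$card_size))
  strip_size <- as.numeric(unlist(doc$strip_size))
  if (length(card_size) != 2 || any(card_size <= 0)) {
    layout_fail("$card_size", "must be two positive numbers (width, height)")
  }
  if (length(strip_size) != 2 || any(strip_size <= 0)) {
    layout_fail("$strip_size", "must be two positive numbers (width, height)")
  }

  params <- list()
  for (i in seq_along(doc$parameters)) {
    p <- doc$parameters[[i]]
    where <- sprintf("$parameters[[%d]]", i)
    if (is.null(p$name) || !nzchar(p$name)) layout_fail(where, "missing name")
    if (p$name %in% names(params)) {
      layout_fail(paste0(where, "$name"), sprintf("duplicate '%s'", p$name))
    }
    rt <- as.integer(p$read_time_s)
    if (length(rt) != 1 || is.na(rt) || !(rt %in% ALLOWED_READ_TIMES)) {
      layout_fail(paste0(where, "$read_time_s"),
                  sprintf("must be one of {%s}",
                          paste(ALLOWED_READ_TIMES, collapse = ", ")))
    }
    if (length(p$levels) == 0) layout_fail(paste0(where, "$levels"), "empty")
    levels <- list()
    for (j in seq_along(p$levels)) {
      l <- p$levels[[j]]
      lw <- sprintf("%s$levels[[%d]]", where, j)
      if (is.null(l$label) || !nzchar(l$label)) layout_fail(lw, "missing label")
      if (l$label %in% names(levels)) {
        layout_fail(paste0(lw, "$label"), sprintf("duplicate '%s'", l$label))
      }
      levels[[l$label]] <- list(
        label = as.character(l$label),
        value = if (is.null(l$value)) NULL else as.numeric(l$value),
        unit = if (is.null(l$unit)) NULL else as.character(l$unit),
        color = if (is.null(l$color)) NULL else as.character(l$color))
    }
    params[[p$name]] <- list(name = as.character(p$name),
                             read_time_s = rt, levels = levels)
  }
  if (length(params) == 0) layout_fail("$parameters", "empty")

  cc <- doc$card_coords
  card_coords <- list()
  for (pname in names(params)) {
    if (is.null(cc[[pname]])) {
      layout_fail(sprintf("$card_coords$%s", pname), "missing parameter entry")
    }
    card_coords[[pname]] <- list()
    for (lname in names(params[[pname]]$levels)) {
      r <- cc[[pname]][[lname]]
      lw <- sprintf("$card_coords$%s$%s", pname, lname)
      if (is.null(r)) layout_fail(lw, "missing card rectangle")
      r <- as.numeric(unlist(r))
      if (length(r) != 4 || any(is.na(r)) || r[3] <= 0 || r[4] <= 0) {
        layout_fail(lw, "rectangle must be (x, y, w, h) with w, h > 0")
      }
      if (r[1] < 0 || r[2] < 0 || r[1] + r[3] > card_size[1] ||
          r[2] + r[4] > card_size[2]) {
        layout_fail(lw, "rectangle outside the canonical card")
      }
      card_coords[[pname]][[lname]] <- r
    }
  }

  structure(list(parameters = params,
                 field_side = field_side,
                 field_pitch = field_pitch,
                 card_size = card_size,
                 strip_size = strip_size,
                 card_coords = card_coords),
            class = "strip_layout")
}

#' Serialize a strip layout
#'
#' Writes a layout back to JSON (or YAML, by extension); re-loading the file
#' yields an equal layout.
#'
#' @param layout A `strip_layout`.
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  doc <- list(
    parameters = lapply(unname(layout$parameters), function(p) {
      list(name = p$name, read_time_s = p$read_time_s,
           levels = lapply(unname(p$levels), function(l) {
             out <- list(label = l$label)
             if (!is.null(l$value)) out$value <- l$value
             if (!is.null(l$unit)) out$unit <- l$unit
             if (!is.null(l$color)) out$color <- l$color
             out
           }))
    }),
    field_side = layout$field_side,
    field_pitch = layout$field_pitch,
    card_size = layout$card_size,
    strip_size = layout$strip_size,
    card_coords = layout$card_coords)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.strip_layout <- function(x, ...) {
  cat(sprintf("<strip_layout> %d parameters, card %dx%d, strip %dx%d\n",
              length(x$parameters), x$card_size[1], x$card_size[2],
              x$strip_size[1], x$strip_size[2]))
  for (p in x$parameters) {
    cat(sprintf("  %-18s %3ds  %s\n", p$name, p$read_time_s,
                paste(names(p$levels), collapse = " | ")))
  }
  invisible(x)
}

# Number of (parameter, level) pairs in a layout.
n_levels_total <- function(layout) {
  sum(vapply(layout$parameters, function(p) length(p$levels), integer(1)))
}
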