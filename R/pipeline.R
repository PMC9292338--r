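# End-to-end analysis and the evaluation harness.
#
# analyze() chains card detection -> reference field extraction -> strip
# field localization -> histogram-peak color extraction -> similarity-based
# level matching -> negative/positive classification, for the three
# similarity methods. evaluate() scores predicted classifications against a
# ground-truth manifest as per-parameter confusion matrices with F1.

#' Analyze a scene image
#'
#' Runs the full reading pipeline on one photograph (or one photograph per
#' read time) containing the reference card and the dipped strip.
#'
#' @param image A color array or image path; or, for timed reading, a named
#'   list of arrays/paths keyed by read time in seconds (e.g. `"30"`,
#'   `"60"`) — each parameter is then read from the image matching its
#'   `read_time_s`, and a missing time falls back to the first image with a
#'   warning recorded in the report.
#' @param layout A `strip_layout`.
#' @param strip_roi Rectangle `c(x, y, w, h)` in scene coordinates locating
#'   the strip crop (per image, a list keyed like `image`, or one rectangle
#'   for all). When `NULL` the field search runs on the whole scene, which
#'   is only reliable when the strip dominates the frame.
#' @param methods Similarity methods to report (default all three).
#' @param seed Integer seed (consensus sampling and clustering).
#' @param detect_cfg A [detect_params()] configuration.
#' @param strict When TRUE, detection failures are signalled as errors;
#'   when FALSE (default) they are recorded in the report.
#' @return An `analysis_report`: list with `image_path`, `card_detection`
#'   (diagnostics or a failure record), `results` (per method, a list of
#'   per-parameter results: `parameter`, `level`, `value`, `scores`,
#'   `classification`, `read_time_s`), and `warnings`.
#' @export
analyze <- function(image, layout, strip_roi = NULL,
                    methods = SIMILARITY_METHODS, seed = 1,
                    detect_cfg = detect_params(), strict = FALSE) {
  methods <- match.arg(methods, SIMILARITY_METHODS, several.ok = TRUE)
  images <- if (is.list(image) && !is.array(image)) image else list(image)
  paths <- vapply(images, function(im) {
    if (is.character(im)) im else "<in-memory>"
  }, character(1))
  imgs <- lapply(images, function(im) {
    if (is.character(im)) read_image(im) else unclass(im)
  })
  rois <- if (is.null(strip_roi)) {
    rep(list(NULL), length(imgs))
  } else if (is.list(strip_roi)) {
    strip_roi[seq_along(imgs)]
  } else rep(list(strip_roi), length(imgs))

  warnings <- character(0)
  template <- paint_card_template(layout)

  # card detection + per-image field reading
  per_image <- vector("list", length(imgs))
  card_diag <- NULL
  for (k in seq_along(imgs)) {
    res <- tryCatch({
      det <- detect_and_rectify(imgs[[k]], template, detect_cfg, seed = seed)
      refs <- reference_peaks(det$rectified, layout)
      strip_img <- if (is.null(rois[[k]])) imgs[[k]] else {
        crop_rect(imgs[[k]], rois[[k]])
      }
      patches <- locate_test_fields(strip_img, layout, seed = seed)
      peaks <- lapply(patches, hsv_peak)
      names(peaks) <- vapply(patches, `[[`, character(1), "parameter")
      list(detection = det$detection, refs = refs, peaks = peaks,
           failed = FALSE)
    }, stripreader_error = function(e) {
      if (strict) stop(e)
      list(failed = TRUE, message = conditionMessage(e),
           diagnostics = e$diagnostics,
           stage = if (inherits(e, "detection_failure")) "card_detection"
           else "field_localization")
    })
    per_image[[k]] <- res
    if (k == 1) {
      card_diag <- if (res$failed && res$stage == "card_detection") {
        list(failed = TRUE, message = res$message,
             diagnostics = res$diagnostics)
      } else if (res$failed) {
        list(failed = FALSE)
      } else {
        d <- res$detection
        list(failed = FALSE, corners = d$corners,
             n_matches_kept = d$n_matches_kept, n_inliers = d$n_inliers)
      }
    }
    if (res$failed) {
      warnings <- c(warnings, sprintf("image %d (%s): %s failed: %s", k,
                                      paths[k], res$stage, res$message))
    }
  }

  # map each parameter to the image holding its read time
  times <- names(images)
  pick_image <- function(rt) {
    if (length(imgs) == 1 || is.null(times)) return(1L)
    hit <- match(as.character(rt), times)
    if (is.na(hit)) {
      warnings <<- c(warnings, sprintf(
        "no image for read time %d s; falling back to the first image", rt))
      return(1L)
    }
    hit
  }
  if (length(imgs) == 1 && length(unique(vapply(
    layout$parameters, `[[`, integer(1), "read_time_s"))) > 1) {
    warnings <- c(warnings, paste(
      "single-image mode: all parameters read from one photograph;",
      "manufacturer read times differ per parameter"))
  }

  results <- NULL
  usable <- !vapply(per_image, `[[`, logical(1), "failed")
  if (any(usable)) {
    results <- list()
    for (method in methods) {
      mres <- list()
      for (pname in names(layout$parameters)) {
        p <- layout$parameters[[pname]]
        k <- pick_image(p$read_time_s)
        if (!usable[k]) k <- which(usable)[1]
        ri <- per_image[[k]]
        dr <- determine_result(ri$peaks[[pname]], ri$refs[[pname]], method)
        mres[[pname]] <- list(
          parameter = pname,
          level = dr$level$label,
          value = dr$level$value,
          score = dr$score,
          classification = classify(p, dr$level),
          read_time_s = p$read_time_s)
      }
      results[[method]] <- mres
    }
  }

  structure(list(image_path = paths, card_detection = card_diag,
                 results = results, warnings = warnings),
            class = "analysis_report")
}

# Per-parameter reference lists for determine_result(), from a rectified card.
reference_peaks <- function(rectified_card, layout) {
  patches <- extract_reference_fields(rectified_card, layout)
  refs <- lapply(names(layout$parameters), function(pn) list())
  names(refs) <- names(layout$parameters)
  for (fp in patches) {
    refs[[fp$parameter]][[length(refs[[fp$parameter]]) + 1]] <- list(
      level = layout$parameters[[fp$parameter]]$levels[[fp$level]],
      peak = hsv_peak(fp))
  }
  refs
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>", x$image_path[1], "\n")
  if (isTRUE(x$card_detection$failed)) {
    cat("  card detection FAILED:", x$card_detection$message, "\n")
  } else {
    cat(sprintf("  card detected (%d/%d inliers/matches)\n",
                x$card_detection$n_inliers, x$card_detection$n_matches_kept))
  }
  for (m in names(x$results)) {
    cat("  method:", m, "\n")
    for (r in x$results[[m]]) {
      cat(sprintf("    %-18s %-10s %s (score %.3f, %ds)\n", r$parameter,
                  r$level, r$classification, r$score, r$read_time_s))
    }
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' @param report An `analysis_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

#' Analysis reports as a CSV-ready data frame
#'
#' One row per (image, parameter, method).
#'
#' @param reports A single `analysis_report` or a list of them.
#' @return data.frame with columns `image`, `method`, `parameter`, `level`,
#'   `value`, `score`, `classification`, `read_time_s`.
#' @export
reports_to_table <- function(reports) {
  if (inherits(reports, "analysis_report")) reports <- list(reports)
  rows <- list()
  for (rep in reports) {
    for (m in names(rep$results)) {
      for (r in rep$results[[m]]) {
        rows[[length(rows) + 1]] <- data.frame(
          image = rep$image_path[1], method = m, parameter = r$parameter,
          level = r$level, value = if (is.null(r$value)) NA_real_ else r$value,
          score = r$score, classification = r$classification,
          read_time_s = r$read_time_s, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(image = character(0), method = character(0),
                      parameter = character(0), level = character(0),
                      value = numeric(0), score = numeric(0),
                      classification = character(0),
                      read_time_s = integer(0)))
  }
  do.call(rbind, rows)
}

#' Evaluate predictions against a ground-truth manifest
#'
#' Joins analysis reports to manifest records by image id and accumulates
#' binary (negative/positive) confusion counts per parameter and method,
#' with precision, recall and F1 (0/0 convention: 0), plus the macro-average
#' F1 over parameters and the pooled (micro) F1 per method.
#'
#' @param reports Named list of `analysis_report`s keyed by image id, or a
#'   list whose reports carry the image file name in `image_path`.
#' @param manifest List of manifest records as produced by
#'   [generate_dataset()] (fields `image` and `truth_classes`), or a path
#'   to a `manifest.jsonl` file.
#' @return An `evaluation_summary`: list with `table` (data.frame: method,
#'   parameter, tp, fp, tn, fn, precision, recall, f1), `macro_f1` and
#'   `pooled_f1` (named by method), and `n_pairs`.
#' @export
evaluate <- function(reports, manifest) {
  if (is.character(manifest)) {
    manifest <- lapply(readLines(manifest), jsonlite::fromJSON,
                       simplifyVector = TRUE)
  }
  truth_by_id <- stats::setNames(manifest,
                                 vapply(manifest, `[[`, character(1), "image"))
  ids <- names(reports)
  if (is.null(ids)) {
    ids <- vapply(reports, function(r) basename(r$image_path[1]), character(1))
  }
  missing <- setdiff(ids, names(truth_by_id))
  if (length(missing) > 0) {
    stop("no manifest record for image id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  counts <- list()
  n_pairs <- 0
  for (k in seq_along(reports)) {
    rep <- reports[[k]]
    truth <- truth_by_id[[ids[k]]]$truth_classes
    if (is.null(rep$results)) next
    for (m in names(rep$results)) {
      for (r in rep$results[[m]]) {
        key <- paste(m, r$parameter, sep = "\r")
        if (is.null(counts[[key]])) {
          counts[[key]] <- c(tp = 0, fp = 0, tn = 0, fn = 0)
        }
        pred_pos <- r$classification == "positive"
        true_pos <- truth[[r$parameter]] == "positive"
        cell <- if (pred_pos && true_pos) "tp" else if (pred_pos) "fp"
        else if (true_pos) "fn" else "tn"
        counts[[key]][cell] <- counts[[key]][cell] + 1
        n_pairs <- n_pairs + 1
      }
    }
  }

  rows <- lapply(names(counts), function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    cc <- counts[[key]]
    prec <- if (cc["tp"] + cc["fp"] > 0) cc["tp"] / (cc["tp"] + cc["fp"]) else 0
    rec <- if (cc["tp"] + cc["fn"] > 0) cc["tp"] / (cc["tp"] + cc["fn"]) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(method = parts[1], parameter = parts[2],
               tp = cc[["tp"]], fp = cc[["fp"]], tn = cc[["tn"]],
               fn = cc[["fn"]], precision = unname(prec),
               recall = unname(rec), f1 = unname(f1),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  macro_f1 <- pooled_f1 <- stats::setNames(numeric(0), character(0))
  if (!is.null(tab)) {
    for (m in unique(tab$method)) {
      sub <- tab[tab$method == m, ]
      macro_f1[m] <- mean(sub$f1)
      tp <- sum(sub$tp); fp <- sum(sub$fp); fn <- sum(sub$fn)
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      pooled_f1[m] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    }
  }
  structure(list(table = tab, macro_f1 = macro_f1, pooled_f1 = pooled_f1,
                 n_pairs = n_pairs),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("<evaluation_summary> %d (image, parameter) decisions\n",
              x$n_pairs))
  for (m in names(x$macro_f1)) {
    cat(sprintf("  %-16s macro-F1 %.3f  pooled-F1 %.3f\n", m, x$macro_f1[m],
                x$pooled_f1[m]))
  }
  invisible(x)
}
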