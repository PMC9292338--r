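# Clinical interpretation: negative/positive classification of a matched
# level and the per-parameter read-time schedule.
#
# Rules: pH is pathological (positive) strictly above 7.0; specific gravity
# is negative within [1.005, 1.025] g/ml inclusive; urobilinogen is negative
# strictly below 1 mg/dl; every other parameter is negative exactly when the
# matched level is the lowest (below-detection-limit) level of its scale.

#' Classify a matched level as negative or positive
#'
#' @param parameter A parameter entry from a `strip_layout` (list with
#'   `name` and ordered `levels`).
#' @param level A level of that parameter (list with `label`, `value`), or a
#'   level label.
#' @return `"negative"` or `"positive"`.
#' @export
#' @examples
#' layout <- default_layout()
#' classify(layout$parameters$ph, "8.0")       # positive
#' classify(layout$parameters$ph, "7.0")       # negative
classify <- function(parameter, level) {
  if (is.character(level)) {
    lv <- parameter$levels[[level]]
    if (is.null(lv)) {
      stop(sprintf("level '%s' not defined for parameter '%s'",
                   level, parameter$name), call. = FALSE)
    }
    level <- lv
  }
  name <- tolower(parameter$name)
  if (name %in% c("ph", "ph_value")) {
    need_value(level, parameter)
    return(if (level$value > 7.0) "positive" else "negative")
  }
  if (name %in% c("specific_gravity", "sg")) {
    need_value(level, parameter)
    return(if (level$value >= 1.005 && level$value <= 1.025) "negative"
           else "positive")
  }
  if (name == "urobilinogen") {
    need_value(level, parameter)
    return(if (level$value < 1) "negative" else "positive")
  }
  # detection-limit parameters: negative iff matched level is the lowest
  lowest <- names(parameter$levels)[1]
  if (identical(level$label, lowest)) "negative" else "positive"
}

need_value <- function(level, parameter) {
  if (is.null(level$value) || is.na(level$value)) {
    stop(sprintf("level '%s' of '%s' needs a numeric value to classify",
                 level$label, parameter$name), call. = FALSE)
  }
}

#' Read schedule of a layout
#'
#' Groups the parameters by their manufacturer read time, ordered by time.
#'
#' @param layout A `strip_layout`.
#' @return data.frame with columns `time_s` (integer, ascending) and
#'   `parameters` (list column of character vectors); the groups partition
#'   the layout's parameters.
#' @export
read_schedule <- function(layout) {
  times <- vapply(layout$parameters, `[[`, integer(1), "read_time_s")
  ts <- sort(unique(times))
  data.frame(
    time_s = ts,
    parameters = I(lapply(ts, function(t) names(times)[times == t])))
}
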