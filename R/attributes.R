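#' Define a single choice attribute
#'
#' An attribute is a product property that varies across the hypothetical
#' contrast agents shown in a choice task: a set of numeric levels, a
#' preference direction, and the axis (linear or logarithmic) on which
#' utilities are interpolated between levels.
#'
#' @param name Attribute identifier (snake_case string).
#' @param levels Strictly increasing numeric vector of at least two finite
#'   level values, in the attribute's natural units.
#' @param direction `"higher_better"` or `"lower_better"`: which end of the
#'   level range a rational respondent prefers.
#' @param scale `"linear"` or `"log"`: the axis used when interpolating
#'   utilities at off-design values. Log-scaled attributes must have strictly
#'   positive levels.
#' @param unit Free-text unit label used in printing and plots.
#'
#' @return A one-row tibble with a `levels` list-column; rows from several
#'   calls are combined by [attribute_space()].
#' @export
#' @examples
#' attribute_spec("cost", c(25, 50, 75, 100), "lower_better", "linear", "USD")
attribute_spec <- function(name, levels, direction = c("higher_better", "lower_better"),
                           scale = c("linear", "log"), unit = "") {
  direction <- match.arg(direction)
  scale <- match.arg(scale)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  levels <- as.numeric(levels)
  if (length(levels) < 2L || anyNA(levels) || any(!is.finite(levels))) {
    abort(sprintf("Attribute '%s' needs >= 2 finite levels.", name))
  }
  if (any(diff(levels) <= 0)) {
    abort(sprintf("Levels of attribute '%s' must be strictly increasing.", name))
  }
  if (scale == "log" && any(levels <= 0)) {
    abort(sprintf("Log-scaled attribute '%s' requires strictly positive levels.", name))
  }
  tibble::tibble(
    attribute = name,
    direction = direction,
    scale = scale,
    unit = unit,
    levels = list(levels)
  )
}

#' Combine attribute definitions into an attribute space
#'
#' @param ... One-row tibbles from [attribute_spec()].
#' @return A tibble of class `attribute_space`, one row per attribute.
#' @export
attribute_space <- function(...) {
  out <- dplyr::bind_rows(...)
  if (nrow(out) == 0L) abort("An attribute space needs at least one attribute.")
  if (anyDuplicated(out$attribute)) abort("Attribute names must be unique.")
  class(out) <- c("attribute_space", class(out))
  out
}

#' Default GBCM attribute space
#'
#' The five attributes along which the hypothetical gadolinium-based contrast
#' media (GBCM) differ, with level grids spanning the published ranges:
#' cancer-detection sensitivity 80--95%, intracranial gadolinium retention
#' 1--100 molecules per 100 million administered, severe allergic-like
#' reaction rate 1--19 per 100,000 administrations, mild allergic-like
#' reaction rate 10--1000 per 100,000, and out-of-pocket cost $25--$100.
#' Four levels per attribute; retention and the two reaction rates span
#' orders of magnitude and interpolate on a log axis, sensitivity and cost
#' on a linear axis. Sensitivity is the lone benefit (higher is better);
#' all risks and cost are lower-better.
#'
#' @return An `attribute_space` tibble with five rows.
#' @export
#' @examples
#' build_default_attribute_space()
build_default_attribute_space <- function() {
  attribute_space(
    attribute_spec("sensitivity", c(80, 85, 90, 95), "higher_better", "linear", "%"),
    attribute_spec("cost", c(25, 50, 75, 100), "lower_better", "linear", "USD"),
    attribute_spec("retention", c(1, 10, 50, 100), "lower_better", "log", "molecules/100M"),
    attribute_spec("severe_reaction", c(1, 7, 13, 19), "lower_better", "log", "events/100k"),
    attribute_spec("mild_reaction", c(10, 100, 500, 1000), "lower_better", "log", "events/100k")
  )
}

#' @export
print.attribute_space <- function(x, ...) {
  cat(sprintf("<attribute_space: %d attributes>\n", nrow(x)))
  NextMethod()
}

# internal: named list of level vectors
space_levels <- function(space) {
  setNames(space$levels, space$attribute)
}

# internal: stop unless `space` is a valid attribute_space
check_attribute_space <- function(space) {
  if (!inherits(space, "attribute_space")) {
    abort("Expected an `attribute_space` (see `attribute_space()`).")
  }
  invisible(space)
}
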