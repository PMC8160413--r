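#' Per-respondent attribute importance
#'
#' For each respondent, an attribute's importance is the range (max minus
#' min) of that respondent's part-worth utilities for the attribute,
#' divided by the sum of the ranges over all attributes, times 100. Each
#' respondent's importances are non-negative and sum to 100 exactly, and
#' are invariant to rescaling all of a respondent's utilities by a positive
#' constant.
#'
#' @param partworths Tidy part-worths (`respondent_id`, `attribute`,
#'   `level`, `utility`), e.g. from [extract_partworths()] or
#'   [sample_population()].
#' @return Tibble of class `importance_table`: `respondent_id`,
#'   `attribute`, `importance` (percent). Respondents whose utility ranges
#'   are all zero (no expressed preference) are dropped with a warning.
#' @export
importance_per_respondent <- function(partworths) {
  need <- c("respondent_id", "attribute", "level", "utility")
  if (!all(need %in% names(partworths))) {
    abort(sprintf("`partworths` must have columns %s.", paste(need, collapse = ", ")))
  }
  ranges <- dplyr::summarise(
    dplyr::group_by(partworths, .data$respondent_id, .data$attribute),
    n_levels = dplyr::n(),
    range = max(.data$utility) - min(.data$utility),
    .groups = "drop"
  )
  if (any(ranges$n_levels < 2L)) {
    abort("Every attribute needs >= 2 level utilities per respondent.")
  }
  totals <- dplyr::summarise(
    dplyr::group_by(ranges, .data$respondent_id),
    total = sum(.data$range), .groups = "drop"
  )
  flat <- totals$respondent_id[totals$total == 0]
  if (length(flat)) {
    warn(sprintf(
      "Excluding %d respondent(s) with all-zero utility ranges (importance undefined).",
      length(flat)
    ))
    ranges <- ranges[!ranges$respondent_id %in% flat, , drop = FALSE]
  }
  tab <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(ranges, .data$respondent_id),
    importance = 100 * .data$range / sum(.data$range)
  ))
  tab <- tibble::as_tibble(tab[c("respondent_id", "attribute", "importance")])
  structure(tab, class = c("importance_table", class(tab)))
}

#' Across-respondent summary of attribute importances
#'
#' Mean importance per attribute with a t-based confidence interval of the
#' mean across respondents.
#'
#' @param table An `importance_table`.
#' @param confidence Interval coverage (default 0.95).
#' @return Tibble of class `importance_summary`: `attribute`, `mean`,
#'   `conf.low`, `conf.high`, `n`. The means sum to 100 (before rounding).
#' @export
summarize_importance <- function(table, confidence = 0.95) {
  n_resp <- dplyr::n_distinct(table$respondent_id)
  if (n_resp < 2L) abort("Need >= 2 respondents to summarise importances.")
  a <- (1 - confidence) / 2
  out <- dplyr::summarise(
    dplyr::group_by(table, .data$attribute),
    n = dplyr::n(),
    mean = mean(.data$importance),
    se = sd(.data$importance) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  tcrit <- qt(1 - a, df = out$n - 1)
  out$conf.low <- out$mean - tcrit * out$se
  out$conf.high <- out$mean + tcrit * out$se
  out <- out[c("attribute", "mean", "conf.low", "conf.high", "n")]
  structure(out, class = c("importance_summary", class(out)))
}

#' Subgroup regression of attribute importances on a covariate
#'
#' Univariable ordinary least squares of per-respondent importance on a
#' covariate, fitted separately for each attribute. For a binary covariate
#' the coefficient equals the difference in group mean importances (second
#' factor level minus the reference level); for a numeric covariate it is
#' the slope per unit (rescale beforehand for, e.g., a per-10-years age
#' effect). Differences in attribute importance are secondary endpoints,
#' so the default interval/alpha is 99% / 0.01 to account for multiple
#' comparisons.
#'
#' @param table An `importance_table`.
#' @param covariates Tibble keyed by `respondent_id` holding the covariate.
#' @param covariate Name of the covariate column.
#' @param confidence Interval coverage (default 0.99).
#' @return Tibble of class `subgroup_effect`: `attribute`, `contrast`,
#'   `estimate`, `conf.low`, `conf.high`, `p.value`, `n`.
#' @export
subgroup_regression <- function(table, covariates, covariate, confidence = 0.99) {
  if (!covariate %in% names(covariates)) {
    abort(sprintf("Covariate '%s' not found.", covariate))
  }
  dat <- dplyr::inner_join(
    table, covariates[c("respondent_id", covariate)],
    by = "respondent_id"
  )
  x <- dat[[covariate]]
  if (is.character(x) || is.logical(x)) x <- factor(x)
  if (is.factor(x)) {
    x <- droplevels(x)
    if (nlevels(x) < 2L) abort("Degenerate covariate: a single group.")
    if (nlevels(x) > 2L) {
      abort("Categorical covariates must be binarized before regression.")
    }
    tab <- table(x[!duplicated(dat$respondent_id)])
    if (any(tab < 2L)) abort("Each group needs >= 2 respondents.")
    contrast <- sprintf("%s vs %s", levels(x)[2], levels(x)[1])
  } else {
    if (length(unique(x)) < 2L) abort("Degenerate covariate: no variation.")
    contrast <- sprintf("per unit %s", covariate)
  }
  dat$.x <- x
  out <- purrr::map_dfr(split(dat, dat$attribute), function(d) {
    fit <- lm(importance ~ .x, data = d)
    ci <- suppressMessages(confint(fit, level = confidence))
    s <- summary(fit)$coefficients
    tibble::tibble(
      attribute = d$attribute[1],
      contrast = contrast,
      estimate = unname(coef(fit)[2]),
      conf.low = ci[2, 1],
      conf.high = ci[2, 2],
      p.value = s[2, 4],
      n = nrow(d)
    )
  })
  structure(out, class = c("subgroup_effect", class(out)))
}

#' Sample size for a target confidence-interval half-width
#'
#' Number of respondents needed so that a normal-theory confidence interval
#' of a mean utility with standard deviation `sd` has half-width at most
#' `half_width`: `n = ceil((z * sd / half_width)^2)`.
#'
#' @param sd Across-respondent standard deviation of the quantity.
#' @param half_width Target half-width of the interval (same units).
#' @param confidence Interval coverage (default 0.95).
#' @return Required number of respondents (integer).
#' @export
#' @examples
#' sample_size_for_ci(66, 10) # ~170 respondents
sample_size_for_ci <- function(sd, half_width, confidence = 0.95) {
  if (!is.numeric(sd) || sd <= 0) abort("`sd` must be positive.")
  if (!is.numeric(half_width) || half_width <= 0) abort("`half_width` must be positive.")
  if (confidence <= 0 || confidence >= 1) abort("`confidence` must be in (0, 1).")
  z <- qnorm(1 - (1 - confidence) / 2)
  as.integer(ceiling((z * sd / half_width)^2))
}

#' @describeIn summarize_importance Bar chart of mean importances with
#'   confidence intervals.
#' @param object An `importance_summary`.
#' @param ... Unused.
#' @export
autoplot.importance_summary <- function(object, ...) {
  d <- dplyr::arrange(tibble::as_tibble(object), dplyr::desc(.data$mean))
  d$attribute <- factor(d$attribute, levels = d$attribute)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$attribute, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high), width = 0.2
    ) +
    ggplot2::labs(
      x = NULL, y = "mean attribute importance (%)",
      title = "Attribute importance"
    )
}
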