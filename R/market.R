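#' Interpolate a part-worth utility at an arbitrary attribute value
#'
#' Simulation products can carry attribute values between (or outside) the
#' levels used in the survey design, so level utilities are interpolated:
#' piecewise-linearly between adjacent levels on the attribute's metric
#' (its raw value for linear-scaled attributes, log10 of the value for
#' log-scaled ones), and linearly extrapolated from the two boundary
#' levels for values outside the design range.
#'
#' @param attribute_spec A one-row slice of an [attribute_space()].
#' @param level_utilities Numeric utilities, one per level, in level order.
#' @param value Numeric value(s) at which to evaluate the utility.
#' @return Interpolated utility, same length as `value`.
#' @export
#' @examples
#' sp <- attribute_spec("cost", c(25, 50), "lower_better", "linear")
#' utility_at_value(sp, c(1, 0), 37.5) # 0.5
utility_at_value <- function(attribute_spec, level_utilities, value) {
  lv <- attribute_spec$levels[[1]]
  if (length(level_utilities) != length(lv)) {
    abort("`level_utilities` must have one entry per level.")
  }
  if (any(!is.finite(value))) abort("`value` must be finite.")
  x <- lv
  v <- value
  if (attribute_spec$scale == "log") {
    if (any(value <= 0)) {
      abort(sprintf("Log-scaled attribute '%s' requires positive values.",
                    attribute_spec$attribute))
    }
    x <- log10(x)
    v <- log10(value)
  }
  .interp_extrap(x, level_utilities, v)
}

# piecewise-linear interpolation with linear extrapolation from the
# boundary segments; x strictly increasing
.interp_extrap <- function(x, y, v) {
  n <- length(x)
  seg <- findInterval(v, x, all.inside = TRUE) # 1..n-1
  x0 <- x[seg]; x1 <- x[seg + 1]
  y0 <- y[seg]; y1 <- y[seg + 1]
  y0 + (v - x0) * (y1 - y0) / (x1 - x0)
}

#' Total utility of a product for each respondent
#'
#' Sums each respondent's interpolated part-worth utilities over the five
#' attributes at the product's attribute values.
#'
#' @param partworths Tidy part-worths (`respondent_id`, `attribute`,
#'   `level`, `utility`).
#' @param product Named list or one-row data frame with one numeric value
#'   per attribute.
#' @param attribute_space The [attribute_space()]; defaults to the one
#'   attached to `partworths`.
#' @return Named numeric vector of total utilities, one per respondent.
#' @export
product_utility <- function(partworths, product, attribute_space = NULL) {
  space <- attribute_space %||% attr(partworths, "attribute_space")
  if (is.null(space)) abort("No attribute space supplied or attached.")
  check_attribute_space(space)
  missing <- setdiff(space$attribute, names(product))
  if (length(missing)) {
    abort(sprintf("Product is missing attribute(s): %s.", paste(missing, collapse = ", ")))
  }
  ids <- unique(partworths$respondent_id)
  total <- setNames(numeric(length(ids)), ids)
  for (a in space$attribute) {
    spec <- space[space$attribute == a, ]
    sub <- partworths[partworths$attribute == a, ]
    lv <- spec$levels[[1]]
    # utilities per respondent in level order
    um <- matrix(
      sub$utility[order(match(sub$respondent_id, ids), match(sub$level, lv))],
      nrow = length(lv), ncol = length(ids)
    )
    x <- lv; v <- as.numeric(product[[a]])
    if (spec$scale == "log") {
      if (v <= 0) abort(sprintf("Log-scaled attribute '%s' requires positive values.", a))
      x <- log10(x); v <- log10(v)
    }
    seg <- findInterval(v, x, all.inside = TRUE)
    w <- (v - x[seg]) / (x[seg + 1] - x[seg])
    total <- total + (1 - w) * um[seg, ] + w * um[seg + 1, ]
  }
  total
}

#' Preference shares of competing products
#'
#' Computes each respondent's share of preference for every product in a
#' competitive set and averages across respondents. Three methods:
#' \describe{
#'   \item{`logit`}{Share of preference: the antilog (exponential) of each
#'     product's total utility, rescaled to sum to 100% within respondent
#'     (the default and the formula the simulator is built on).}
#'   \item{`first_choice`}{Indicator of each respondent's highest-utility
#'     product (ties split equally).}
#'   \item{`rfc`}{Randomized first choice: total utilities are perturbed
#'     with independent Gumbel noise (scale `rfc_noise`) on each of
#'     `rfc_draws` draws and first choices are tallied; as the noise scale
#'     shrinks this approaches the first-choice rule.}
#' }
#' Overall shares are the mean of respondent-level shares, times 100.
#'
#' @param partworths Tidy part-worths with attached attribute space (or
#'   pass `attribute_space`).
#' @param products Tibble with a `product` name column and one numeric
#'   column per attribute (e.g. rows of [gbcm_products()]).
#' @param attribute_space Optional [attribute_space()].
#' @param method `"logit"`, `"first_choice"`, or `"rfc"`.
#' @param rfc_draws,rfc_noise Monte-Carlo draws and Gumbel noise scale for
#'   `method = "rfc"`.
#' @param seed Seed for `method = "rfc"` (required).
#' @param scenario Label attached to the result.
#' @return Tibble of class `share_result` (`product`, `share` in percent,
#'   summing to 100) with the respondent-by-product share matrix attached
#'   as attribute `"respondent_shares"`.
#' @export
share_of_preference <- function(partworths, products, attribute_space = NULL,
                                method = c("logit", "first_choice", "rfc"),
                                rfc_draws = 1000, rfc_noise = 1, seed = NULL,
                                scenario = "scenario") {
  method <- match.arg(method)
  space <- attribute_space %||% attr(partworths, "attribute_space")
  if (is.null(space)) abort("No attribute space supplied or attached.")
  if (!"product" %in% names(products)) abort("`products` needs a `product` name column.")
  if (nrow(products) < 2L) abort("Need >= 2 products to simulate shares.")
  if (anyDuplicated(products$product)) abort("Duplicate product names.")
  ids <- unique(partworths$respondent_id)
  if (length(ids) == 0L) abort("Empty respondent set.")

  U <- vapply(
    seq_len(nrow(products)),
    function(i) product_utility(partworths, products[i, ], space),
    numeric(length(ids))
  )
  U <- matrix(U, nrow = length(ids))

  shares <- switch(method,
    logit = {
      E <- exp(U - apply(U, 1, max))
      E / rowSums(E)
    },
    first_choice = .first_choice_shares(U),
    rfc = {
      if (is.null(seed)) abort("`seed` is required for randomized first choice.")
      if (rfc_noise <= 0) abort("`rfc_noise` must be positive.")
      withr::with_seed(seed, {
        acc <- matrix(0, nrow(U), ncol(U))
        for (d in seq_len(rfc_draws)) {
          noise <- -log(-log(runif(length(U)))) * rfc_noise
          acc <- acc + .first_choice_shares(U + matrix(noise, nrow(U)))
        }
        acc / rfc_draws
      })
    }
  )
  out <- tibble::tibble(
    product = products$product,
    share = 100 * colMeans(shares)
  )
  structure(
    out,
    respondent_shares = 100 * shares,
    respondent_ids = ids,
    method = method,
    scenario = scenario,
    seed = seed,
    class = c("share_result", class(out))
  )
}

# per-respondent first-choice indicator matrix, ties split equally
.first_choice_shares <- function(U) {
  t(apply(U, 1, function(u) {
    best <- u == max(u)
    best / sum(best)
  }))
}

#' GBCM product profiles for market simulation
#'
#' The six contrast-agent profiles used in the shipped simulation
#' scenarios: three existing products (A--C) with published attribute
#' values and three hypothetical test products (D--F). Values are in the
#' attribute space's natural units; several (retention 0.2 or 0.1,
#' sensitivity 78) lie between or outside the survey design levels and are
#' handled by interpolation/extrapolation.
#'
#' @return Tibble: `product`, `structure`, and the five attribute columns.
#' @export
gbcm_products <- function() {
  tibble::tribble(
    ~product, ~structure, ~sensitivity, ~cost, ~retention, ~severe_reaction, ~mild_reaction,
    "A", "linear ionic",      83,  83,  4.5,  2.1,  39,
    "B", "linear ionic",      94, 100,  4.0, 12,   130,
    "C", "macrocyclic",       94,  72,  0.2,  5.7, 150,
    "D", "linear nonionic",   83,  25, 20,    1.6,  12,
    "E", "macrocyclic",       78, 100,  0.2, 12,    72,
    "F", "macrocyclic",       83,  75,  0.1, 18,   130
  )
}

#' Shipped simulation scenarios
#'
#' Five competitive sets over the [gbcm_products()] profiles: the three
#' existing products alone, each test product added to that set in turn,
#' and all six products together.
#'
#' @return Named list of product-name vectors.
#' @export
gbcm_scenarios <- function() {
  list(
    scenario_1 = c("A", "B", "C"),
    scenario_2 = c("D", "A", "B", "C"),
    scenario_3 = c("E", "A", "B", "C"),
    scenario_4 = c("F", "A", "B", "C"),
    scenario_5 = c("A", "B", "C", "D", "E", "F")
  )
}

#' Run a set of market-simulation scenarios
#'
#' @param partworths Tidy part-worths with attached attribute space.
#' @param scenarios Named list of product-name vectors
#'   (default [gbcm_scenarios()]).
#' @param products Product profile tibble (default [gbcm_products()]).
#' @param ... Passed to [share_of_preference()] (method, seed, ...).
#' @return Tibble (`scenario`, `product`, `share`); the individual
#'   `share_result` objects are attached as attribute `"results"`.
#' @export
run_scenarios <- function(partworths, scenarios = gbcm_scenarios(),
                          products = gbcm_products(), ...) {
  results <- purrr::imap(scenarios, function(set, name) {
    unknown <- setdiff(set, products$product)
    if (length(unknown)) {
      abort(sprintf("Scenario '%s' references unknown product(s): %s.",
                    name, paste(unknown, collapse = ", ")))
    }
    share_of_preference(
      partworths, products[match(set, products$product), ],
      scenario = name, ...
    )
  })
  out <- purrr::imap_dfr(results, function(res, name) {
    tibble::tibble(scenario = name, product = res$product, share = res$share)
  })
  attr(out, "results") <- results
  out
}

#' @describeIn share_of_preference Bar chart of overall preference shares.
#' @param object A `share_result`.
#' @param ... Unused.
#' @export
autoplot.share_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$product, y = .data$share)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(
      x = "product", y = "share of preference (%)",
      title = sprintf("Preference shares (%s)", attr(object, "method") %||% "")
    )
}
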