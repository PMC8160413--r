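#' MCMC configuration for the hierarchical Bayes choice model
#'
#' Defaults follow standard hierarchical Bayes choice-based-conjoint
#' practice: 50,000 posterior simulation iterations with the first half
#' discarded as burn-in and the rest thinned by 10; a diffuse normal prior
#' on the population mean (precision 0.01, i.e. prior sd 10 on the
#' effects-coded utility scale); an inverse-Wishart prior on the population
#' covariance with degrees of freedom `dim + 5` and identity scale; and a
#' per-respondent random-walk proposal whose scalar step adapts during
#' burn-in toward an acceptance rate in [0.23, 0.44].
#'
#' @param n_iterations Total MCMC iterations (default 50,000).
#' @param n_burn_in Burn-in iterations (default half of `n_iterations`).
#' @param thinning Keep every `thinning`-th post-burn-in draw.
#' @param proposal_step Initial random-walk step (utility units).
#' @param adapt Adapt the step during burn-in?
#' @param prior_mean_precision Prior precision on the population mean.
#' @param prior_df Inverse-Wishart degrees of freedom; `NULL` means
#'   `dim + 5`, resolved when the coded dimension is known.
#' @param prior_scale Scalar s in the inverse-Wishart scale matrix s*I.
#' @param seed Integer seed driving every random draw of the sampler.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 50000, n_burn_in = NULL, thinning = 10,
                        proposal_step = 0.1, adapt = TRUE,
                        prior_mean_precision = 0.01, prior_df = NULL,
                        prior_scale = 1, seed = 1L) {
  n_burn_in <- n_burn_in %||% floor(n_iterations / 2)
  if (n_iterations <= 0 || n_burn_in < 0 || thinning < 1) {
    abort("Iteration counts must be positive and thinning >= 1.")
  }
  if (n_burn_in >= n_iterations) abort("`n_burn_in` must be < `n_iterations`.")
  if (proposal_step <= 0 || prior_mean_precision <= 0 || prior_scale <= 0) {
    abort("`proposal_step`, `prior_mean_precision`, `prior_scale` must be positive.")
  }
  if (!is.null(prior_df) && prior_df <= 0) abort("`prior_df` must be positive.")
  structure(
    list(
      n_iterations = as.integer(n_iterations),
      n_burn_in = as.integer(n_burn_in),
      thinning = as.integer(thinning),
      proposal_step = proposal_step,
      adapt = isTRUE(adapt),
      prior_mean_precision = prior_mean_precision,
      prior_df = prior_df,
      prior_scale = prior_scale,
      seed = as.integer(seed)
    ),
    class = "mcmc_config"
  )
}

#' Fit the hierarchical Bayes multinomial logit to choice data
#'
#' Respondent-level coefficient vectors `beta_i` (effects-coded part-worth
#' utilities) are modelled as draws from a population multivariate normal
#' `N(alpha, Sigma)`; choices follow a multinomial logit given `beta_i`.
#' Estimation is Metropolis-within-Gibbs: conjugate normal draws for
#' `alpha`, inverse-Wishart draws for `Sigma`, and per-respondent
#' random-walk Metropolis for `beta_i` with burn-in step adaptation
#' targeting a 0.23--0.44 acceptance rate. Draws are exactly reproducible
#' given the seed in `config`.
#'
#' @param responses Long-format choice data: `respondent_id`, `task_id`,
#'   `alt_id`, one numeric level column per attribute, and `chosen` (0/1,
#'   exactly one chosen alternative per respondent-task).
#' @param attribute_space The [attribute_space()]; defaults to the one
#'   attached to `responses`.
#' @param config An [mcmc_config()].
#' @param min_tasks Minimum number of answered tasks a respondent must have
#'   to enter the fit; the default (`NULL`) keeps only complete responders
#'   (the maximum task count observed in the data), mirroring the exclusion
#'   of incomplete surveys.
#' @param allow_prior_only If `TRUE` and `responses` has zero rows, returns
#'   prior draws for the population mean instead of erroring (useful to
#'   check the prior-only limit).
#' @return An object of class `hb_fit` holding the retained draws of
#'   `alpha` (matrix, draws by coefficients), `Sigma` (array), `beta`
#'   (array, respondents by coefficients by draws), acceptance rates,
#'   the log-likelihood trace, the coded design map, and the configuration.
#' @seealso [extract_partworths()], [tidy.hb_fit()], [glance.hb_fit()]
#' @export
fit_hb <- function(responses, attribute_space = NULL, config = mcmc_config(),
                   min_tasks = NULL, allow_prior_only = FALSE) {
  space <- attribute_space %||% attr(responses, "attribute_space")
  if (is.null(space)) abort("No attribute space supplied or attached to `responses`.")
  check_attribute_space(space)
  stopifnot(inherits(config, "mcmc_config"))

  if (nrow(responses) == 0L) {
    if (!allow_prior_only) abort("Empty response set.")
    return(.fit_prior_only(space, config))
  }
  responses <- validate_responses(responses, space)

  # drop incomplete responders
  per_resp <- dplyr::summarise(
    dplyr::group_by(responses, .data$respondent_id),
    n_tasks = dplyr::n_distinct(.data$task_id), .groups = "drop"
  )
  min_tasks <- min_tasks %||% max(per_resp$n_tasks)
  keep <- per_resp$respondent_id[per_resp$n_tasks >= min_tasks]
  if (length(keep) < length(per_resp$respondent_id)) {
    rlang::inform(sprintf(
      "Dropping %d respondent(s) with fewer than %d answered tasks.",
      length(per_resp$respondent_id) - length(keep), min_tasks
    ))
  }
  if (length(keep) == 0L) abort("No respondent meets the `min_tasks` threshold.")
  responses <- responses[responses$respondent_id %in% keep, , drop = FALSE]

  responses <- dplyr::arrange(responses, .data$respondent_id, .data$task_id, .data$alt_id)
  coded <- encode_design(responses, space)
  p <- ncol(coded$X)
  prior_df <- config$prior_df %||% (p + 5)

  # contiguous task blocks: first row, n alternatives, chosen offset
  key <- paste(responses$respondent_id, responses$task_id, sep = "\r")
  task_first <- which(!duplicated(key))
  task_len <- diff(c(task_first, nrow(responses) + 1L))
  chosen_row <- which(responses$chosen == 1L)
  task_of_chosen <- findInterval(chosen_row, task_first)
  task_chosen <- integer(length(task_first))
  task_chosen[task_of_chosen] <- chosen_row - task_first[task_of_chosen]
  resp_of_task <- responses$respondent_id[task_first]
  resp_first <- which(!duplicated(resp_of_task))
  resp_count <- diff(c(resp_first, length(task_first) + 1L))
  respondent_ids <- unique(responses$respondent_id)

  raw <- withr::with_seed(config$seed, .hb_mcmc_cpp(
    coded$X, task_first - 1L, task_len, task_chosen,
    resp_first - 1L, resp_count,
    config$n_iterations, config$n_burn_in, config$thinning,
    config$prior_mean_precision, prior_df, config$prior_scale,
    config$proposal_step, config$adapt, 0.23, 0.44
  ))

  structure(
    list(
      alpha = raw$alpha, Sigma = raw$Sigma, beta = raw$beta,
      accept_rate = as.numeric(raw$accept_rate),
      loglik = as.numeric(raw$loglik),
      step = as.numeric(raw$step),
      coded_map = coded$map, attribute_space = space,
      respondent_ids = respondent_ids,
      n_respondents = length(respondent_ids),
      n_tasks = length(task_first),
      config = config, prior_df = prior_df,
      prior_only = FALSE
    ),
    class = "hb_fit"
  )
}

# prior-only limit: no data, draws of alpha from its prior
.fit_prior_only <- function(space, config) {
  coded <- encode_design(.space_level_grid(space), space)
  p <- ncol(coded$X)
  n_save <- (config$n_iterations - config$n_burn_in) %/% config$thinning
  alpha <- withr::with_seed(
    config$seed,
    matrix(rnorm(n_save * p, 0, sqrt(1 / config$prior_mean_precision)), n_save, p)
  )
  structure(
    list(
      alpha = alpha, Sigma = NULL, beta = NULL,
      accept_rate = numeric(0), loglik = numeric(0), step = numeric(0),
      coded_map = coded$map, attribute_space = space,
      respondent_ids = character(0), n_respondents = 0L, n_tasks = 0L,
      config = config, prior_df = config$prior_df %||% (p + 5),
      prior_only = TRUE
    ),
    class = "hb_fit"
  )
}

# one row per attribute level (used to size the coding without data)
.space_level_grid <- function(space) {
  lvls <- space_levels(space)
  out <- tibble::tibble(.rows = max(lengths(lvls)))
  for (a in names(lvls)) out[[a]] <- rep_len(lvls[[a]], nrow(out))
  out
}

# expansion matrix E (total levels x p): utility vector = E %*% beta
.expansion_matrix <- function(map) {
  p <- max(map$column, na.rm = TRUE)
  E <- matrix(0, nrow(map), p)
  for (a in unique(map$attribute)) {
    rows <- which(map$attribute == a)
    cols <- map$column[rows]
    free <- rows[!is.na(cols)]
    for (i in seq_along(free)) E[free[i], cols[!is.na(cols)][i]] <- 1
    E[rows[is.na(cols)], cols[!is.na(cols)]] <- -1
  }
  E
}

#' Extract zero-centered part-worth utilities from a fitted model
#'
#' Posterior means of each respondent's coefficient vector, expanded to the
#' full set of level utilities. Within every respondent and attribute the
#' level utilities sum to zero (effects-coding identification), so positive
#' values indicate increased likelihood of selection.
#'
#' @param fit An `hb_fit`.
#' @return A tibble of class `partworth_set`: `respondent_id`, `attribute`,
#'   `level`, `utility`. The population-mean utilities (from the posterior
#'   mean of `alpha`) are attached as attribute `"population"`, the
#'   attribute space as `"attribute_space"`.
#' @export
extract_partworths <- function(fit) {
  stopifnot(inherits(fit, "hb_fit"))
  if (fit$prior_only || is.null(fit$beta)) abort("Fit contains no respondent draws.")
  beta_mean <- apply(fit$beta, c(1, 2), mean) # respondents x p
  E <- .expansion_matrix(fit$coded_map)
  util <- beta_mean %*% t(E) # respondents x total levels
  out <- tidyr::expand_grid(
    respondent_id = fit$respondent_ids,
    fit$coded_map[c("attribute", "level")]
  )
  out$utility <- as.vector(t(util))
  # exact re-centering within respondent x attribute
  out <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(out, .data$respondent_id, .data$attribute),
    utility = .data$utility - mean(.data$utility)
  ))
  alpha_mean <- colMeans(fit$alpha)
  population <- tibble::tibble(
    attribute = fit$coded_map$attribute,
    level = fit$coded_map$level,
    utility = as.vector(E %*% alpha_mean)
  )
  as_partworth_set(out, fit$attribute_space, population = population)
}

# internal constructor for the tidy part-worth container
as_partworth_set <- function(x, space, population = NULL) {
  structure(
    x,
    attribute_space = space,
    population = population,
    class = unique(c("partworth_set", class(x)))
  )
}

#' @describeIn fit_hb Posterior summaries of the population-mean level
#'   utilities: one row per (attribute, level) with posterior mean,
#'   standard deviation and central credible interval.
#' @param x,object An `hb_fit`.
#' @param conf_level Credible-interval coverage (default 0.95).
#' @param ... Unused.
#' @export
tidy.hb_fit <- function(x, conf_level = 0.95, ...) {
  E <- .expansion_matrix(x$coded_map)
  draws <- x$alpha %*% t(E) # draws x total levels
  a <- (1 - conf_level) / 2
  tibble::tibble(
    attribute = x$coded_map$attribute,
    level = x$coded_map$level,
    estimate = colMeans(draws),
    std.error = apply(draws, 2, sd),
    conf.low = apply(draws, 2, quantile, probs = a),
    conf.high = apply(draws, 2, quantile, probs = 1 - a)
  )
}

#' @describeIn fit_hb One-row model overview: respondents, tasks, retained
#'   draws, mean Metropolis acceptance rate, and mean log-likelihood.
#' @export
glance.hb_fit <- function(x, ...) {
  tibble::tibble(
    n_respondents = x$n_respondents,
    n_tasks = x$n_tasks,
    n_draws = nrow(x$alpha),
    n_iterations = x$config$n_iterations,
    mean_accept_rate = if (length(x$accept_rate)) mean(x$accept_rate) else NA_real_,
    mean_loglik = if (length(x$loglik)) mean(x$loglik) else NA_real_
  )
}

#' @export
print.hb_fit <- function(x, ...) {
  cat("<hb_fit: hierarchical Bayes multinomial logit>\n")
  cat(sprintf(
    "  %d respondents, %d tasks, %d retained draws (%d iterations)\n",
    x$n_respondents, x$n_tasks, nrow(x$alpha), x$config$n_iterations
  ))
  if (length(x$accept_rate)) {
    cat(sprintf("  mean Metropolis acceptance: %.2f\n", mean(x$accept_rate)))
  }
  invisible(x)
}

#' @describeIn fit_hb Population-mean part-worth plot (point estimates with
#'   credible intervals, faceted by attribute).
#' @export
autoplot.hb_fit <- function(object, conf_level = 0.95, ...) {
  td <- tidy(object, conf_level = conf_level)
  ggplot2::ggplot(
    td,
    ggplot2::aes(x = factor(.data$level), y = .data$estimate,
                 ymin = .data$conf.low, ymax = .data$conf.high)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(~attribute, scales = "free_x") +
    ggplot2::labs(
      x = "attribute level", y = "population mean part-worth utility",
      title = "Zero-centered part-worth utilities"
    )
}
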