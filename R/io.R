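#' Validate long-format choice responses
#'
#' Checks the documented long layout (`respondent_id`, `task_id`,
#' `alt_id`, one numeric level column per attribute, `chosen` in 0/1),
#' that every shown level exists in the attribute space, and that exactly
#' one alternative is chosen per respondent-task (one answer per
#' question). Errors name the offending field or rows.
#'
#' @param responses A data frame in the long response layout.
#' @param attribute_space The [attribute_space()] levels are checked
#'   against; defaults to the one attached to `responses`.
#' @return The validated responses as a tibble of class `response_set`
#'   with the attribute space attached.
#' @export
validate_responses <- function(responses, attribute_space = NULL) {
  space <- attribute_space %||% attr(responses, "attribute_space")
  if (is.null(space)) abort("No attribute space supplied or attached to `responses`.")
  check_attribute_space(space)
  need <- c("respondent_id", "task_id", "alt_id", "chosen")
  missing <- setdiff(c(need, space$attribute), names(responses))
  if (length(missing)) {
    abort(sprintf("Responses are missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (!all(responses$chosen %in% c(0, 1))) {
    bad <- which(!responses$chosen %in% c(0, 1))
    abort(sprintf("`chosen` must be 0/1; bad row(s): %s.",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  lvls <- space_levels(space)
  for (a in space$attribute) {
    vals <- responses[[a]]
    bad <- which(!is.na(vals) & !vals %in% lvls[[a]])
    if (length(bad)) {
      abort(sprintf("Unknown level %s for attribute '%s' at row(s) %s.",
                    vals[bad[1]], a, paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  per_task <- dplyr::summarise(
    dplyr::group_by(responses, .data$respondent_id, .data$task_id),
    n_chosen = sum(.data$chosen), .groups = "drop"
  )
  bad <- per_task[per_task$n_chosen != 1L, , drop = FALSE]
  if (nrow(bad)) {
    abort(sprintf(
      "Exactly one alternative must be chosen per task; violated for %s (first: respondent %s, task %s, %d chosen).",
      sprintf("%d task(s)", nrow(bad)), bad$respondent_id[1], bad$task_id[1], bad$n_chosen[1]
    ))
  }
  out <- tibble::as_tibble(responses)
  structure(out, attribute_space = space,
            class = unique(c("response_set", class(out))))
}

#' Read / write long-format choice responses
#'
#' CSV interchange for the long response layout; [read_responses()]
#' validates on load.
#'
#' @param path CSV file path.
#' @param attribute_space The [attribute_space()] of the study.
#' @return `read_responses()`: a validated `response_set` tibble.
#' @export
read_responses <- function(path, attribute_space = build_default_attribute_space()) {
  if (!file.exists(path)) abort(sprintf("Response file not found: %s", path))
  validate_responses(
    tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE)),
    attribute_space
  )
}

#' @rdname read_responses
#' @param responses A `response_set` (or compatible data frame).
#' @return `write_responses()`: the path, invisibly.
#' @export
write_responses <- function(responses, path) {
  write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}

#' Read / write tidy part-worth utilities
#'
#' CSV with columns `respondent_id`, `attribute`, `level`, `utility`.
#'
#' @param path CSV file path.
#' @param attribute_space The [attribute_space()] the utilities refer to.
#' @return `read_partworths()`: a `partworth_set` tibble.
#' @export
read_partworths <- function(path, attribute_space = build_default_attribute_space()) {
  if (!file.exists(path)) abort(sprintf("Part-worth file not found: %s", path))
  x <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("respondent_id", "attribute", "level", "utility")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(sprintf("Part-worth file missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  as_partworth_set(x, attribute_space)
}

#' @rdname read_partworths
#' @param partworths A `partworth_set` (or compatible tidy tibble).
#' @return `write_partworths()`: the path, invisibly.
#' @export
write_partworths <- function(partworths, path) {
  write.csv(
    as.data.frame(partworths)[c("respondent_id", "attribute", "level", "utility")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' Load per-respondent utilities from a supplementary-table export
#'
#' Reads a wide per-respondent utilities sheet (one row per respondent,
#' one column per attribute level) exported to CSV from a supplementary
#' spreadsheet, using a user-supplied column mapping since such sheets
#' have no standard layout. Loaded utilities are re-centered within each
#' respondent and attribute so they satisfy the zero-centering convention.
#'
#' @param path CSV file path (a sheet exported from the workbook).
#' @param mapping A list with `respondent_id` (the respondent column name)
#'   and `columns`, a tibble `attribute` / `level` / `column` mapping each
#'   attribute level to a sheet column.
#' @param attribute_space The study's [attribute_space()].
#' @return A `partworth_set` tibble.
#' @export
read_supplementary_utilities <- function(path, mapping,
                                         attribute_space = build_default_attribute_space()) {
  if (!file.exists(path)) abort(sprintf("Utilities file not found: %s", path))
  x <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE))
  need <- c(mapping$respondent_id, mapping$columns$column)
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(sprintf(
      "Mapped column(s) not found: %s. Columns present: %s.",
      paste(missing, collapse = ", "), paste(names(x), collapse = ", ")
    ))
  }
  long <- purrr::map_dfr(seq_len(nrow(mapping$columns)), function(i) {
    tibble::tibble(
      respondent_id = as.character(x[[mapping$respondent_id]]),
      attribute = mapping$columns$attribute[i],
      level = mapping$columns$level[i],
      utility = as.numeric(x[[mapping$columns$column[i]]])
    )
  })
  long <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(long, .data$respondent_id, .data$attribute),
    utility = .data$utility - mean(.data$utility)
  ))
  as_partworth_set(dplyr::arrange(long, .data$respondent_id), attribute_space)
}

#' Configure an end-to-end pipeline run
#'
#' Bundles the stage configurations for [run_pipeline()]: design shape,
#' synthetic population (or a path to observed responses), MCMC settings,
#' and market-simulation scenarios, under one global seed.
#'
#' @param n_respondents Synthetic respondents to generate (ignored when
#'   `responses_path` is given).
#' @param n_tasks,n_alts Design shape.
#' @param scale Choice-consistency scale for simulated choices.
#' @param responses_path Optional CSV of observed responses; when set, the
#'   synthetic-data stage is skipped.
#' @param mcmc An [mcmc_config()].
#' @param scenarios Named list of product sets (default [gbcm_scenarios()]).
#' @param products Product profiles (default [gbcm_products()]).
#' @param share_method Share method for the simulator stage.
#' @param subgroup_covariate Covariate for the subgroup regression stage
#'   (`NULL` to skip); must be a column of the covariate table.
#' @param seed Global seed; stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_respondents = 50, n_tasks = 15, n_alts = 2,
                            scale = 1, responses_path = NULL,
                            mcmc = mcmc_config(n_iterations = 5000, seed = 1L),
                            scenarios = gbcm_scenarios(),
                            products = gbcm_products(),
                            share_method = "logit",
                            subgroup_covariate = "income_low",
                            seed = 1L) {
  if (!is.null(responses_path) && !file.exists(responses_path)) {
    abort(sprintf("`responses_path` does not exist: %s", responses_path))
  }
  structure(
    list(
      n_respondents = n_respondents, n_tasks = n_tasks, n_alts = n_alts,
      scale = scale, responses_path = responses_path, mcmc = mcmc,
      scenarios = scenarios, products = products,
      share_method = share_method,
      subgroup_covariate = subgroup_covariate,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Design generation, synthetic choice simulation (or reading observed
#' responses), hierarchical Bayes estimation, part-worth extraction,
#' attribute importance with optional subgroup regression, and market
#' simulation — writing every stage's output as CSV into `out_dir`, with
#' a JSON run record (seed, configuration hash, package version) so
#' deterministic stages are byte-reproducible from the same config.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly; the fitted objects are attached as the
#'   attribute `"objects"`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("dce_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  space <- build_default_attribute_space()
  seed <- config$seed

  design <- generate_design(space, config$n_tasks, config$n_alts, seed = seed)
  write.csv(as.data.frame(design), file.path(out_dir, "design.csv"), row.names = FALSE)

  covariates <- NULL
  if (is.null(config$responses_path)) {
    spec <- default_population_spec(n_respondents = config$n_respondents, seed = seed + 1L)
    truth <- sample_population(spec)
    covariates <- truth$covariates
    responses <- simulate_choices(truth, design, scale = config$scale, seed = seed + 2L)
    write_partworths(truth$partworths, file.path(out_dir, "truth_partworths.csv"))
    write.csv(as.data.frame(covariates), file.path(out_dir, "covariates.csv"),
              row.names = FALSE)
  } else {
    responses <- read_responses(config$responses_path, space)
  }
  write_responses(responses, file.path(out_dir, "responses.csv"))

  fit <- fit_hb(responses, space, config$mcmc)
  partworths <- extract_partworths(fit)
  write_partworths(partworths, file.path(out_dir, "utilities.csv"))

  imp <- importance_per_respondent(partworths)
  imp_sum <- summarize_importance(imp)
  write.csv(as.data.frame(imp), file.path(out_dir, "importance.csv"), row.names = FALSE)
  write.csv(as.data.frame(imp_sum), file.path(out_dir, "importance_summary.csv"),
            row.names = FALSE)

  subgroup <- NULL
  if (!is.null(config$subgroup_covariate) && !is.null(covariates) &&
      config$subgroup_covariate %in% names(covariates)) {
    subgroup <- tryCatch(
      subgroup_regression(imp, covariates, config$subgroup_covariate),
      error = function(e) {
        warn(sprintf("Skipping subgroup stage: %s", conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(subgroup)) {
      write.csv(as.data.frame(subgroup), file.path(out_dir, "subgroup.csv"),
                row.names = FALSE)
    }
  }

  shares <- run_scenarios(
    partworths, config$scenarios, config$products,
    method = config$share_method,
    seed = if (config$share_method == "rfc") seed + 3L else NULL
  )
  write.csv(as.data.frame(shares), file.path(out_dir, "shares.csv"), row.names = FALSE)

  run_info <- list(
    package_version = as.character(utils::packageVersion("gbcmdce")),
    seed = seed,
    config_hash = rlang::hash(config),
    n_respondents = length(unique(responses$respondent_id)),
    mcmc_iterations = config$mcmc$n_iterations
  )
  jsonlite::write_json(run_info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(invisible(out_dir),
            objects = list(fit = fit, partworths = partworths,
                           importance = imp, summary = imp_sum,
                           subgroup = subgroup, shares = shares))
}
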