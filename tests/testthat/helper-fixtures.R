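# small spaces and part-worth fixtures shared across test files

one_attr_space <- function(levels = c(0, 1), scale = "linear",
                           direction = "higher_better") {
  attribute_space(attribute_spec("x", levels, direction, scale))
}

# tidy part-worths with two levels per attribute, utilities +-range/2
toy_partworths <- function(ranges, ids = "r1", space = NULL) {
  pw <- purrr::map_dfr(ids, function(id) {
    purrr::imap_dfr(ranges, function(r, a) {
      tibble::tibble(respondent_id = id, attribute = a,
                     level = c(1, 2), utility = c(-r / 2, r / 2))
    })
  })
  if (!is.null(space)) attr(pw, "attribute_space") <- space
  pw
}

quick_cfg <- function(iters = 3000, seed = 1, ...) {
  mcmc_config(n_iterations = iters, seed = seed, ...)
}
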