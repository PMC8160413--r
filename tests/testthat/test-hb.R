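# short-chain fits on small synthetic populations keep these tests fast;
# full-scale recovery is exercised in test-acceptance.R

make_small_study <- function(n = 20, seed = 1, scale = 1) {
  spec <- default_population_spec(n_respondents = n, seed = seed)
  truth <- sample_population(spec)
  design <- generate_design(seed = seed + 1)
  resp <- simulate_choices(truth, design, scale = scale, seed = seed + 2)
  list(spec = spec, truth = truth, design = design, responses = resp)
}

test_that("mcmc_config validates its inputs", {
  cfg <- mcmc_config()
  expect_equal(cfg$n_iterations, 50000L)
  expect_equal(cfg$n_burn_in, 25000L)
  expect_error(mcmc_config(n_iterations = 100, n_burn_in = 100), "n_burn_in")
  expect_error(mcmc_config(thinning = 0), "thinning")
  expect_error(mcmc_config(proposal_step = -1), "positive")
  expect_error(mcmc_config(prior_mean_precision = 0), "positive")
})

test_that("the sampler is deterministic given the seed", {
  st <- make_small_study(n = 8, seed = 3)
  f1 <- fit_hb(st$responses, config = quick_cfg(1500, seed = 9))
  f2 <- fit_hb(st$responses, config = quick_cfg(1500, seed = 9))
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$beta, f2$beta)
  f3 <- fit_hb(st$responses, config = quick_cfg(1500, seed = 10))
  expect_false(identical(f1$alpha, f3$alpha))
})

test_that("retained draw count and acceptance diagnostics are as configured", {
  st <- make_small_study(n = 6, seed = 4)
  cfg <- mcmc_config(n_iterations = 2000, n_burn_in = 800, thinning = 4, seed = 2)
  fit <- fit_hb(st$responses, config = cfg)
  expect_equal(nrow(fit$alpha), (2000 - 800) / 4)
  expect_equal(dim(fit$beta)[3], 300)
  expect_length(fit$accept_rate, 6)
  expect_true(all(fit$accept_rate > 0.05 & fit$accept_rate < 0.8))
  # every retained covariance draw is symmetric positive definite
  for (k in c(1, 150, 300)) {
    S <- fit$Sigma[, , k]
    expect_equal(S, t(S), tolerance = 1e-12)
    expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("extracted part-worths are zero-centered for every respondent and attribute", {
  st <- make_small_study(n = 10, seed = 5)
  fit <- fit_hb(st$responses, config = quick_cfg(1500, seed = 3))
  pw <- extract_partworths(fit)
  sums <- dplyr::summarise(
    dplyr::group_by(pw, respondent_id, attribute),
    s = sum(utility), .groups = "drop"
  )
  expect_true(all(abs(sums$s) < 1e-9))
  pop <- attr(pw, "population")
  expect_true(all(abs(tapply(pop$utility, pop$attribute, sum)) < 1e-9))
})

test_that("prior-only fits center the population mean at the prior mean", {
  fit <- fit_hb(
    tibble::tibble(), build_default_attribute_space(),
    mcmc_config(n_iterations = 1100, n_burn_in = 100, thinning = 1, seed = 6),
    allow_prior_only = TRUE
  )
  expect_true(fit$prior_only)
  # prior sd is 10, so the mean of 1000 draws has se ~0.32 per element
  expect_lt(max(abs(colMeans(fit$alpha))), 2)
  expect_error(fit_hb(tibble::tibble(), build_default_attribute_space()),
               "Empty response set")
})

test_that("a respondent who always prefers higher sensitivity gets monotone part-worths", {
  sp <- attribute_space(
    attribute_spec("sensitivity", c(80, 85, 90, 95), "higher_better", "linear")
  )
  d <- generate_design(sp, n_tasks = 12, n_alts = 2, seed = 7)
  mp <- tibble::tibble(attribute = "sensitivity", level = c(80, 85, 90, 95),
                       utility = c(-3, -1, 1, 3))
  spec <- population_spec(mp, het_sd = c(sensitivity = 0), n_respondents = 5,
                          seed = 8, attribute_space = sp)
  resp <- simulate_choices(sample_population(spec), d, scale = 50, seed = 9)
  fit <- fit_hb(resp, sp, quick_cfg(3000, seed = 10))
  pop <- attr(extract_partworths(fit), "population")
  u <- pop$utility[order(pop$level)]
  expect_true(all(diff(u) > 0))
})

test_that("indifferent respondents yield near-zero utilities", {
  sp <- one_attr_space(c(0, 1))
  d <- generate_design(sp, n_tasks = 15, n_alts = 2, seed = 2)
  mp <- tibble::tibble(attribute = "x", level = c(0, 1), utility = c(0, 0))
  spec <- population_spec(mp, het_sd = c(x = 0), n_respondents = 30, seed = 3,
                          attribute_space = sp)
  resp <- simulate_choices(sample_population(spec), d, seed = 4)
  fit <- fit_hb(resp, sp, quick_cfg(4000, seed = 5))
  pw <- extract_partworths(fit)
  expect_lt(max(abs(pw$utility)), 0.4)
})

test_that("a tight covariance prior shrinks respondents toward the population mean", {
  st <- make_small_study(n = 15, seed = 11)
  loose <- fit_hb(st$responses, config = quick_cfg(3000, seed = 12))
  tight <- fit_hb(st$responses, config = mcmc_config(
    n_iterations = 3000, seed = 12, prior_scale = 0.01, prior_df = 300
  ))
  between_var <- function(fit) {
    bm <- apply(fit$beta, c(1, 2), mean)
    mean(apply(bm, 2, var))
  }
  expect_lt(between_var(tight), between_var(loose))
})

test_that("population-mean recovery error shrinks as respondents increase", {
  errs <- sapply(c(50, 200), function(n) {
    spec <- default_population_spec(n_respondents = n, seed = 21)
    truth <- sample_population(spec)
    d <- generate_design(seed = 22)
    resp <- simulate_choices(truth, d, seed = 23)
    fit <- fit_hb(resp, config = quick_cfg(6000, seed = 24))
    pop <- attr(extract_partworths(fit), "population")
    m <- merge(pop, spec$mean_partworths, by = c("attribute", "level"))
    mean(abs(m$utility.x - m$utility.y))
  })
  expect_lt(errs[2], errs[1])
})

test_that("incomplete responders are dropped under the completeness default", {
  st <- make_small_study(n = 6, seed = 31)
  resp <- st$responses
  drop_id <- unique(resp$respondent_id)[1]
  resp2 <- resp[!(resp$respondent_id == drop_id & resp$task_id > 5), ]
  attr(resp2, "attribute_space") <- attr(resp, "attribute_space")
  expect_message(
    fit <- fit_hb(resp2, config = quick_cfg(800, seed = 1)),
    "Dropping 1 respondent"
  )
  expect_equal(fit$n_respondents, 5)
  # keeping partial responders via min_tasks
  fit2 <- fit_hb(resp2, config = quick_cfg(800, seed = 1), min_tasks = 5)
  expect_equal(fit2$n_respondents, 6)
})

test_that("tidy and glance summarise the fit", {
  st <- make_small_study(n = 6, seed = 41)
  fit <- fit_hb(st$responses, config = quick_cfg(1200, seed = 2))
  td <- tidy(fit)
  expect_named(td, c("attribute", "level", "estimate", "std.error",
                     "conf.low", "conf.high"))
  expect_equal(nrow(td), 20) # 5 attributes x 4 levels
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_respondents, 6)
  expect_equal(gl$n_draws, nrow(fit$alpha))
  expect_s3_class(autoplot(fit), "ggplot")
})
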