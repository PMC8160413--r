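test_that("utility interpolation is exact at levels and midpoints", {
  sp <- attribute_spec("cost", c(25, 50), "lower_better", "linear")
  expect_equal(utility_at_value(sp, c(1, 0), 25), 1)
  expect_equal(utility_at_value(sp, c(1, 0), 50), 0)
  expect_equal(utility_at_value(sp, c(1, 0), 37.5), 0.5)
  # linear extrapolation beyond the level range
  expect_equal(utility_at_value(sp, c(1, 0), 75), -1)
  expect_equal(utility_at_value(sp, c(1, 0), 0), 2)

  lg <- attribute_spec("retention", c(1, 100), "lower_better", "log")
  expect_equal(utility_at_value(lg, c(0.6, -0.6), 10), 0) # midpoint on log10 axis
  expect_equal(utility_at_value(lg, c(0.5, -0.5), 0.1), 1) # one decade below min
  expect_error(utility_at_value(lg, c(0.5, -0.5), 0), "positive")
})

test_that("piecewise interpolation uses adjacent segments", {
  sp <- attribute_spec("mild", c(10, 100, 500, 1000), "lower_better", "log")
  u <- c(0.9, 0.3, -0.4, -0.8)
  # value between levels 2 and 3, interpolated on the log10 axis
  v <- 200
  w <- (log10(v) - log10(100)) / (log10(500) - log10(100))
  expect_equal(utility_at_value(sp, u, v), (1 - w) * 0.3 + w * (-0.4))
})

test_that("product utility sums independent per-attribute interpolations", {
  space <- build_default_attribute_space()
  set.seed(17)
  ids <- c("r1", "r2", "r3")
  pw <- purrr::map_dfr(ids, function(id) {
    purrr::map_dfr(seq_len(nrow(space)), function(i) {
      u <- rnorm(4); u <- u - mean(u)
      tibble::tibble(respondent_id = id, attribute = space$attribute[i],
                     level = space$levels[[i]], utility = u)
    })
  })
  for (k in seq_len(nrow(gbcm_products()))) {
    prod <- gbcm_products()[k, ]
    got <- product_utility(pw, prod, space)
    for (id in ids) {
      want <- sum(sapply(seq_len(nrow(space)), function(i) {
        sub <- pw[pw$respondent_id == id & pw$attribute == space$attribute[i], ]
        utility_at_value(space[i, ], sub$utility[order(sub$level)],
                         prod[[space$attribute[i]]])
      }))
      expect_equal(unname(got[id]), want)
    }
  }
  # all-zero part-worths give zero utility for any product
  pw0 <- dplyr::mutate(pw, utility = 0)
  expect_equal(unname(product_utility(pw0, gbcm_products()[1, ], space)), rep(0, 3))
})

test_that("best and worst products bound any within-range product", {
  space <- build_default_attribute_space()
  spec <- default_population_spec(n_respondents = 5, seed = 2)
  spec$het_sd[] <- 0 # monotone part-worths, so level extremes are utility extremes
  spec$covariates <- list()
  pw <- sample_population(spec)$partworths
  best <- list(sensitivity = 95, cost = 25, retention = 1,
               severe_reaction = 1, mild_reaction = 10)
  worst <- list(sensitivity = 80, cost = 100, retention = 100,
                severe_reaction = 19, mild_reaction = 1000)
  ub <- product_utility(pw, best, space)
  lb <- product_utility(pw, worst, space)
  expect_true(all(ub > lb))
  # product A's values all lie inside the level ranges
  u <- product_utility(pw, gbcm_products()[1, ], space)
  expect_true(all(u <= ub + 1e-9 & u >= lb - 1e-9))
})

test_that("logit shares reproduce closed-form symmetric and 75/25 cases", {
  sp <- one_attr_space(c(0, 1))
  ids <- sprintf("r%d", 1:7)
  pw <- purrr::map_dfr(ids, function(id) {
    tibble::tibble(respondent_id = id, attribute = "x",
                   level = c(0, 1), utility = c(-log(3) / 2, log(3) / 2))
  })
  attr(pw, "attribute_space") <- sp
  prods <- tibble::tibble(product = c("hi", "lo"), x = c(1, 0))
  res <- share_of_preference(pw, prods, sp)
  expect_equal(res$share, c(75, 25))

  same <- tibble::tibble(product = c("p1", "p2"), x = c(1, 1))
  expect_equal(share_of_preference(pw, same, sp)$share, c(50, 50))
})

test_that("shares are normalized per respondent and overall", {
  truth <- sample_population(default_population_spec(n_respondents = 25, seed = 3))
  for (m in c("logit", "first_choice", "rfc")) {
    res <- share_of_preference(truth$partworths, gbcm_products(), method = m,
                               rfc_draws = 200, seed = 9)
    expect_equal(sum(res$share), 100, tolerance = 1e-9)
    rs <- attr(res, "respondent_shares")
    expect_true(all(abs(rowSums(rs) - 100) < 1e-9))
    expect_true(all(rs >= 0))
  }
})

test_that("adding a constant to every product's utility leaves logit shares unchanged", {
  truth <- sample_population(default_population_spec(n_respondents = 10, seed = 4))
  pw <- truth$partworths
  res1 <- share_of_preference(pw, gbcm_products())
  # shift one attribute's utilities by a constant at every level: every
  # product's total utility moves by the same amount per respondent
  pw2 <- dplyr::mutate(pw, utility = utility + 5 * (attribute == "cost"))
  attr(pw2, "attribute_space") <- attr(pw, "attribute_space")
  res2 <- share_of_preference(pw2, gbcm_products())
  expect_equal(res2$share, res1$share)
})

test_that("a strictly dominated product never beats its dominator", {
  spec <- default_population_spec(n_respondents = 8, seed = 6)
  spec$het_sd[] <- 0 # monotone part-worths for every respondent
  spec$covariates <- list()
  pw <- sample_population(spec)$partworths
  prods <- tibble::tibble(
    product = c("good", "dominated", "other"),
    sensitivity = c(92, 88, 85),
    cost = c(40, 60, 80),
    retention = c(5, 20, 50),
    severe_reaction = c(3, 8, 10),
    mild_reaction = c(50, 200, 400)
  )
  res <- share_of_preference(pw, prods)
  expect_lt(res$share[res$product == "dominated"], res$share[res$product == "good"])
  rs <- attr(res, "respondent_shares")
  expect_true(all(rs[, 2] < rs[, 1]))
})

test_that("improving a product on one attribute never lowers its logit share", {
  spec <- default_population_spec(n_respondents = 8, seed = 6)
  spec$het_sd[] <- 0
  spec$covariates <- list()
  pw <- sample_population(spec)$partworths
  base <- gbcm_products()[1:3, ]
  res1 <- share_of_preference(pw, base)
  improved <- base
  improved$sensitivity[1] <- improved$sensitivity[1] + 5
  res2 <- share_of_preference(pw, improved)
  expect_gte(res2$share[1], res1$share[1])
  rs1 <- attr(res1, "respondent_shares"); rs2 <- attr(res2, "respondent_shares")
  expect_true(all(rs2[, 1] >= rs1[, 1] - 1e-12))
})

test_that("scaled-up utilities drive logit shares to the first-choice rule", {
  spec <- default_population_spec(n_respondents = 12, seed = 8)
  spec$het_sd[] <- 0
  spec$covariates <- list()
  pw <- sample_population(spec)$partworths
  fc <- share_of_preference(pw, gbcm_products(), method = "first_choice")
  hot <- dplyr::mutate(pw, utility = utility * 30)
  attr(hot, "attribute_space") <- attr(pw, "attribute_space")
  lg <- share_of_preference(hot, gbcm_products())
  expect_equal(lg$share, fc$share, tolerance = 0.01)
})

test_that("randomized first choice is seeded and approaches first choice as noise shrinks", {
  truth <- sample_population(default_population_spec(n_respondents = 30, seed = 10))
  pw <- truth$partworths
  r1 <- share_of_preference(pw, gbcm_products(), method = "rfc",
                            rfc_draws = 500, rfc_noise = 0.5, seed = 21)
  r2 <- share_of_preference(pw, gbcm_products(), method = "rfc",
                            rfc_draws = 500, rfc_noise = 0.5, seed = 21)
  expect_equal(r1$share, r2$share)
  fc <- share_of_preference(pw, gbcm_products(), method = "first_choice")
  tiny <- share_of_preference(pw, gbcm_products(), method = "rfc",
                              rfc_draws = 2000, rfc_noise = 0.01, seed = 22)
  expect_equal(tiny$share, fc$share, tolerance = 0.02)
})

test_that("share simulation rejects malformed input", {
  truth <- sample_population(default_population_spec(n_respondents = 3, seed = 1))
  pw <- truth$partworths
  expect_error(share_of_preference(pw, gbcm_products()[1, ]), ">= 2 products")
  dup <- gbcm_products()[c(1, 1), ]
  expect_error(share_of_preference(pw, dup), "Duplicate")
  expect_error(
    share_of_preference(pw, gbcm_products(), method = "rfc"),
    "seed"
  )
  empty <- pw[0, ]
  attr(empty, "attribute_space") <- attr(pw, "attribute_space")
  expect_error(share_of_preference(empty, gbcm_products()), "Empty respondent")
})

test_that("scenario runner covers the shipped competitive sets", {
  truth <- sample_population(default_population_spec(n_respondents = 15, seed = 12))
  shares <- run_scenarios(truth$partworths)
  expect_setequal(unique(shares$scenario), names(gbcm_scenarios()))
  sums <- tapply(shares$share, shares$scenario, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_equal(sum(shares$scenario == "scenario_5"), 6)
  expect_error(
    run_scenarios(truth$partworths, scenarios = list(bad = c("A", "Z"))),
    "unknown product"
  )
})
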