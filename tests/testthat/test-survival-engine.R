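test_that("null exposure shows no association and a known effect is recovered", {
  # zero diet effects: log HR of the hPDI within 3 SE of 0
  null_cohort <- analysis_cohort(sim_params(n_participants = 2000), seed = 17)
  idx <- compute_index(null_cohort, "hpdi")
  d <- cbind(null_cohort, index_value = idx$rescaled)
  fit <- fit_cox(d, "index_value", "continuous", covariates = character(0))
  td <- tidy(fit)
  expect_lt(abs(td$estimate[1]), 3 * td$std.error[1])

  # the sole simulated driver used directly as exposure recovers its coefficient
  eff_cohort <- analysis_cohort(protective_scenario_params(), seed = 17)
  fit2 <- fit_cox(cbind(eff_cohort, wg = eff_cohort$whole_grains),
                  "wg", "continuous", covariates = character(0))
  td2 <- tidy(fit2)
  expect_lt(abs(td2$estimate[1] - log(0.35)), 3 * td2$std.error[1])
})

test_that("degenerate inputs error: no events, constant exposure", {
  cohort <- analysis_cohort()
  d <- cbind(cohort, index_value = compute_index(cohort, "pdi")$rescaled)
  d0 <- d
  d0$event <- 0L
  expect_error(fit_cox(d0, "index_value", "continuous"), "events")
  d1 <- d
  d1$index_value <- 54
  expect_error(fit_cox(d1, "index_value", "continuous"), "constant")
})

test_that("per-10-unit HR is the closed-form transform of the per-unit coefficient", {
  cohort <- analysis_cohort()
  d <- cbind(cohort, index_value = compute_index(cohort, "hpdi")$rescaled)
  fit <- fit_cox(d, "index_value", "continuous", stratum = "female")
  b <- tidy(fit)
  b1 <- b$estimate[b$term == "exposure"]
  se1 <- b$std.error[b$term == "exposure"]
  h <- hr_per_10(fit)
  expect_equal(h$hr, exp(10 * b1))
  expect_equal(h$conf.low, exp(10 * b1 - 1.96 * 10 * se1))
  expect_equal(h$conf.high, exp(10 * b1 + 1.96 * 10 * se1))
  # a per-unit log HR of log(0.98) compounds to 0.98^10 per 10 units
  expect_equal(exp(10 * log(0.98)), 0.98^10)
})

test_that("scale equivariance: rescaling the exposure rescales the coefficient", {
  cohort <- analysis_cohort()
  idx <- compute_index(cohort, "pdi", grouping = food_groups()[-10, ])
  d <- cbind(cohort, raw = idx$raw, rescaled = idx$rescaled)
  f_raw <- fit_cox(d, "raw", "continuous", covariates = character(0))
  f_res <- fit_cox(d, "rescaled", "continuous", covariates = character(0))
  b_raw <- tidy(f_raw)$estimate[1]
  b_res <- tidy(f_res)$estimate[1]
  # rescaled = raw * 18/17, so beta transforms by the reciprocal factor
  expect_equal(b_res, b_raw * 17 / 18, tolerance = 1e-6)
})

test_that("decile-indicator fits expose nine contrasts and the extreme contrast", {
  cohort <- analysis_cohort(sim_params(n_participants = 1000), seed = 19)
  idx <- compute_index(cohort, "updi")
  d <- cbind(cohort, index_decile = idx$decile)
  fit <- fit_cox(d, "index_decile", "deciles", covariates = character(0))
  terms <- tidy(fit)$term
  expect_equal(sum(grepl("^exposure", terms)),
               length(unique(idx$decile)) - 1L)
  h <- extreme_decile_hr(fit)
  expect_equal(h$hr, exp(tidy(fit)$estimate[tidy(fit)$term == "exposure10"]))
  # null simulation: extreme-decile HR near 1 (within 3 SE on the log scale)
  expect_lt(abs(h$log_hr), 3 * h$se)
})

test_that("p-for-trend uses the decile medians and rejects a constant term", {
  cohort <- analysis_cohort(sim_params(n_participants = 1000), seed = 19)
  idx <- compute_index(cohort, "hpdi")
  d <- cbind(cohort, decile_median = idx$decile_median)
  p <- p_for_trend(d, covariates = character(0))
  fit <- attr(p, "fit")
  expect_equal(as.numeric(p), tidy(fit)$p.value[tidy(fit)$term == "exposure"])
  d$decile_median <- 50
  expect_error(p_for_trend(d, covariates = character(0)), "constant|inestimable")
})

test_that("fixed-effects meta-analysis matches hand arithmetic and metafor", {
  # identity with a single stratum
  one <- meta_fixed_effects(0.25, 0.1)
  expect_equal(one$beta, 0.25)
  expect_equal(one$se, 0.1)
  # equal strata: same estimate, SE reduced by sqrt(2)
  two <- meta_fixed_effects(c(0.2, 0.2), c(0.1, 0.1))
  expect_equal(two$beta, 0.2)
  expect_equal(two$se, 0.1 / sqrt(2))
  # hand inverse-variance example: (0.1/0.01 + 0.3/0.04) / (1/0.01 + 1/0.04)
  hand <- meta_fixed_effects(c(0.1, 0.3), c(0.1, 0.2))
  expect_equal(hand$beta, (10 + 7.5) / 125)
  expect_equal(hand$beta, 0.14)
  # independent cross-check against the reference meta-analysis fitter
  withr::local_seed(7)
  b <- stats::rnorm(4)
  s <- stats::runif(4, 0.05, 0.3)
  mine <- meta_fixed_effects(b, s)
  ref <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(mine$beta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(mine$se, as.numeric(ref$se), tolerance = 1e-10)
})

test_that("non-convergent fits are flagged rather than silently accepted", {
  # a perfectly separating exposure sends the coefficient to infinity
  d <- tibble::tibble(
    entry_age = rep(50, 40),
    exit_age = 51:90,
    event = rep(c(1L, 0L), each = 20),
    gender = "female",
    x = rep(c(5, 0), each = 20)
  )
  fit <- fit_cox(d, "x", "continuous", covariates = character(0))
  expect_false(fit$converged)
  expect_true(length(fit$warnings) > 0)
})

test_that("female-only covariates enter the female stratum by default", {
  cohort <- analysis_cohort()
  d <- cbind(cohort, index_value = compute_index(cohort, "pdi")$rescaled)
  ff <- fit_cox(d, "index_value", "continuous", stratum = "female")
  fm <- fit_cox(d, "index_value", "continuous", stratum = "male")
  expect_true(any(grepl("hormone_use", tidy(ff)$term)))
  expect_false(any(grepl("hormone_use", tidy(fm)$term)))
  g <- glance(ff)
  expect_equal(g$n, sum(cohort$gender == "female"))
  expect_true(g$converged)
})
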