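# Shared fixtures. Cohorts are cached per (params, seed) so several test
# files can reuse the same simulated data without re-generating it.

.cohort_cache <- new.env(parent = emptyenv())

analysis_cohort <- function(params = sim_params(n_participants = 500),
                            seed = 11) {
  key <- paste(rlang::hash(params), seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(params, seed) |>
      apply_eligibility() |>
      resolve_diet_exposure()
  }
  .cohort_cache[[key]]
}

# Independent quantile-bin oracle: spells out the linear-interpolation
# percentile (h = (n-1)p + 1 on the sorted sample) and the lower-bin tie
# rule by hand, element by element.
oracle_quantile_bins <- function(x, k) {
  n <- length(x)
  xs <- sort(x)
  cuts <- vapply(seq_len(k - 1) / k, function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }, numeric(1))
  vapply(x, function(v) 1L + sum(v > cuts), integer(1))
}

# Rank-based oracle for the balanced distinct-values case (n divisible by k)
oracle_rank_bins <- function(x, k) {
  as.integer(ceiling(k * rank(x) / length(x)))
}

# fast covariate-free survival columns for mechanism-level Cox tests
surv_frame <- function(cohort, exposure) {
  tibble::tibble(
    entry_age = cohort$entry_age,
    exit_age = cohort$exit_age,
    event = cohort$event,
    gender = cohort$gender,
    x = exposure
  )
}

combined_hr10 <- function(data, value_col, covariates = NULL) {
  hs <- lapply(c("female", "male"), function(s) {
    hr_per_10(fit_cox(data, value_col, "continuous",
                      covariates = covariates, stratum = s))
  })
  meta_fixed_effects(vapply(hs, `[[`, 0, "log_hr"),
                     vapply(hs, `[[`, 0, "se"))
}

# force every group's coded score to a given value (positive groups take
# `coded`, reverse groups 6 - coded), for index-bound checks
set_coded_scores <- function(scores, coding, coded) {
  for (g in coding$group) {
    d <- coding$direction[coding$group == g]
    scores[[g]] <- if (d == "positive") coded else 6L - coded
  }
  scores
}

# combined-stratum trend p via fixed-effects meta-analysis of the
# stratum-wise decile-median Wald statistics
combined_trend_p <- function(data, covariates = NULL) {
  est <- lapply(c("female", "male"), function(s) {
    fit <- fit_cox(data, "decile_median", "trend",
                   covariates = covariates, stratum = s)
    td <- tidy(fit)
    td[td$term == "exposure", c("estimate", "std.error")]
  })
  meta_fixed_effects(vapply(est, `[[`, 0, "estimate"),
                     vapply(est, `[[`, 0, "std.error"))$p.value
}
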