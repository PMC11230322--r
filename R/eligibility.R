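#' Eligibility rules for the analytic sample
#'
#' Defaults follow the scoring approach's exclusions: implausible or
#' missing energy intake (below 600 or above 3,500 kcal/day for women;
#' below 800 or above 4,200 kcal/day for men), missing adjustment
#' covariates at baseline, and a prior-disease flag (history of MI,
#' revascularization, stroke/TIA or cancer, collapsed to one boolean).
#'
#' @param energy_bounds `list(female = c(lo, hi), male = c(lo, hi))` in
#'   kcal/day, applied to baseline (capture-1) energy.
#' @param exclude_prior_disease Drop records with `prior_disease == TRUE`.
#' @param require_complete_covariates Drop records with any missing
#'   adjustment covariate (female-only covariates checked in women only).
#' @return A list of class `pdi_eligibility_rules`.
#' @export
eligibility_rules <- function(energy_bounds = list(female = c(600, 3500),
                                                   male = c(800, 4200)),
                              exclude_prior_disease = TRUE,
                              require_complete_covariates = TRUE) {
  structure(
    list(
      energy_bounds = energy_bounds,
      exclude_prior_disease = exclude_prior_disease,
      require_complete_covariates = require_complete_covariates
    ),
    class = "pdi_eligibility_rules"
  )
}

#' Apply eligibility rules to a cohort
#'
#' Filters a cohort to the analytic sample, recording a per-rule exclusion
#' count (rules applied sequentially, so counts sum to the total excluded,
#' as in a cohort flow diagram). The filter is idempotent. An empty result
#' is legal.
#'
#' @param cohort A cohort tibble from [simulate_cohort()] (or with the same
#'   columns).
#' @param rules An [eligibility_rules()] object.
#' @return The retained rows, with the exclusion log in attribute
#'   `"exclusion_log"` (see [exclusion_log()]).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_params(n_participants = 200), seed = 1)
#' eligible <- apply_eligibility(cohort)
#' exclusion_log(eligible)
apply_eligibility <- function(cohort, rules = eligibility_rules()) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop("cohort is empty", call. = FALSE)
  }
  stopifnot(inherits(rules, "pdi_eligibility_rules"))
  log <- list()
  keep <- cohort

  if (isTRUE(rules$exclude_prior_disease) && "prior_disease" %in% names(keep)) {
    drop <- !is.na(keep$prior_disease) & keep$prior_disease
    log[["prior_disease"]] <- sum(drop)
    keep <- keep[!drop, , drop = FALSE]
  }

  eb <- rules$energy_bounds
  lo <- ifelse(keep$gender == "female", eb$female[1], eb$male[1])
  hi <- ifelse(keep$gender == "female", eb$female[2], eb$male[2])
  drop <- is.na(keep$energy_c1) | keep$energy_c1 < lo | keep$energy_c1 > hi
  log[["energy_implausible_or_missing"]] <- sum(drop)
  keep <- keep[!drop, , drop = FALSE]

  if (isTRUE(rules$require_complete_covariates)) {
    shared <- intersect(adjustment_covariates("male"), names(keep))
    shared <- setdiff(shared, "energy")
    female_only <- intersect(c("hormone_use", "past_oc_use"), names(keep))
    incomplete <- rowSums(is.na(keep[shared])) > 0
    if (length(female_only)) {
      fem <- keep$gender == "female"
      incomplete <- incomplete |
        (fem & rowSums(is.na(keep[female_only])) > 0)
    }
    log[["missing_covariate"]] <- sum(incomplete)
    keep <- keep[!incomplete, , drop = FALSE]
  }

  attr(keep, "exclusion_log") <- tibble::tibble(
    rule = names(log),
    n_excluded = as.integer(unlist(log, use.names = FALSE))
  )
  attr(keep, "provenance") <- attr(cohort, "provenance")
  keep
}

#' Exclusion log of an eligibility-filtered cohort
#'
#' @param cohort Output of [apply_eligibility()].
#' @return A tibble with columns `rule` and `n_excluded`.
#' @export
exclusion_log <- function(cohort) {
  log <- attr(cohort, "exclusion_log")
  if (is.null(log)) {
    stop("no exclusion log; was apply_eligibility() run?", call. = FALSE)
  }
  log
}

#' Resolve the two dietary captures to a single exposure
#'
#' Per participant and intake column: the mean of the two captures when
#' capture 2 is present and type-2 diabetes was not diagnosed before it;
#' capture 1 alone when diabetes preceded capture 2 (diet may have changed
#' substantially); capture 1 carried forward when capture 2 is missing.
#' Energy is resolved by the same rule.
#'
#' @param cohort A cohort tibble with `<name>_c1`/`<name>_c2` intake
#'   columns, `energy_c1`/`energy_c2` and `t2d_before_capture2`.
#' @return The cohort with one resolved column `<name>` (and `energy`)
#'   added per intake pair; per-capture columns are retained.
#' @export
resolve_diet_exposure <- function(cohort) {
  stopifnot(is.data.frame(cohort), "t2d_before_capture2" %in% names(cohort))
  c1_cols <- grep("_c1$", names(cohort), value = TRUE)
  if (!length(c1_cols)) stop("no capture-1 intake columns found", call. = FALSE)
  t2d <- cohort$t2d_before_capture2
  out <- cohort
  for (c1 in c1_cols) {
    base <- sub("_c1$", "", c1)
    c2 <- paste0(base, "_c2")
    v2 <- if (c2 %in% names(cohort)) cohort[[c2]] else NA_real_
    out[[base]] <- resolve_pair(cohort[[c1]], v2, t2d)
  }
  attr(out, "provenance") <- attr(cohort, "provenance")
  attr(out, "exclusion_log") <- attr(cohort, "exclusion_log")
  out
}
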