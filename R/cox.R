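#' Fit a Cox proportional-hazards model of incident CHD on a diet index
#'
#' Age is the time scale: entry age is the left-truncation (delayed entry)
#' time and exit age the event/censoring time, so the model is
#' `Surv(entry_age, exit_age, event)`. Ties in event ages use the Efron
#' approximation. The exposure enters either as a continuous index, as
#' decile-bin indicators with bin 1 as reference, or as the decile-median
#' trend variable. Covariates listed in `quintile_covariates` (margarine
#' and energy intake by default) are converted to within-analysis-set
#' quintile factors; character covariates become factors.
#'
#' @param data A tibble with `entry_age`, `exit_age`, `event`, `gender`,
#'   the exposure column and the covariate columns (a resolved cohort
#'   joined with an index, typically).
#' @param exposure Name of the exposure column: the (rescaled) index for
#'   `form = "continuous"`, the `decile` column for `"deciles"`, the
#'   `decile_median` column for `"trend"`.
#' @param form Exposure form.
#' @param covariates Character vector of adjustment covariate columns;
#'   default is the full adjustment set available in `data` for the
#'   stratum (female-only covariates enter the female stratum only).
#' @param stratum `"female"`, `"male"` (filters `gender`) or `"all"`.
#' @param ties Tie handling passed to [survival::coxph()].
#' @param quintile_covariates Numeric covariates recoded to quintile
#'   factors within the analysis set.
#' @return An object of class `pdi_cox`: the fitted model plus metadata
#'   (`stratum`, `form`, `n`, `n_events`, `converged`, collected fitter
#'   warnings). Use [tidy()]/[glance()], [hr_per_10()],
#'   [extreme_decile_hr()].
#' @export
fit_cox <- function(data, exposure, form = c("continuous", "deciles", "trend"),
                    covariates = NULL,
                    stratum = c("all", "female", "male"),
                    ties = "efron",
                    quintile_covariates = c("margarine", "energy")) {
  form <- match.arg(form)
  stratum <- match.arg(stratum)
  stopifnot(exposure %in% names(data))
  need <- c("entry_age", "exit_age", "event")
  if (!all(need %in% names(data))) {
    stop("data must contain ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (stratum != "all") {
    data <- data[data$gender == stratum, , drop = FALSE]
  }
  if (nrow(data) == 0 || sum(data$event) < 1) {
    stop("no events in the analysis set (stratum: ", stratum, ")",
         call. = FALSE)
  }
  if (is.null(covariates)) {
    covariates <- intersect(
      adjustment_covariates(if (stratum == "all") "all" else stratum),
      names(data)
    )
  }
  df <- data[c(need, covariates)]
  for (cv in covariates) {
    if (cv %in% quintile_covariates && is.numeric(df[[cv]])) {
      df[[cv]] <- factor(quantile_score(df[[cv]], k = 5))
    } else if (is.character(df[[cv]]) || is.logical(df[[cv]])) {
      df[[cv]] <- factor(df[[cv]])
    }
  }
  x <- data[[exposure]]
  if (form == "deciles") {
    lev <- sort(unique(x))
    if (length(lev) < 2) stop("fewer than two decile bins present", call. = FALSE)
    df$exposure <- factor(x, levels = lev)
  } else {
    if (!is.numeric(x)) stop("continuous exposure must be numeric", call. = FALSE)
    if (stats::var(x) == 0) {
      stop("exposure is constant; term inestimable", call. = FALSE)
    }
    df$exposure <- x
  }
  fml <- stats::reformulate(
    c("exposure", covariates),
    response = "survival::Surv(entry_age, exit_age, event)"
  )
  warns <- character()
  model <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties, x = FALSE, y = TRUE,
                    model = FALSE),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  bad <- grepl("converge|infinite|out of iterations|beta may be infinite",
               warns, ignore.case = TRUE)
  structure(
    list(
      model = model,
      exposure = exposure,
      form = form,
      stratum = stratum,
      n = nrow(df),
      n_events = sum(df$event),
      converged = !any(bad) && !any(is.na(stats::coef(model)[
        grep("^exposure", names(stats::coef(model)))
      ])),
      warnings = warns
    ),
    class = "pdi_cox"
  )
}

#' @export
print.pdi_cox <- function(x, ...) {
  cat("<pdi_cox> ", x$form, " exposure, stratum = ", x$stratum,
      ", n = ", x$n, ", events = ", x$n_events,
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted Cox model
#'
#' @param x A `pdi_cox` object.
#' @param exponentiate Report hazard ratios instead of log hazard ratios.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`
#'   (Wald 95% limits, 1.96 on the log-HR scale).
#' @export
tidy.pdi_cox <- function(x, exponentiate = FALSE, ...) {
  beta <- stats::coef(x$model)
  se <- sqrt(diag(stats::vcov(x$model)))
  z <- beta / se
  out <- tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z))),
    conf.low = unname(beta - 1.96 * se),
    conf.high = unname(beta + 1.96 * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Model-level summary of a fitted Cox model
#'
#' @param x A `pdi_cox` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_events`, `stratum`, `form`,
#'   `converged`, `logLik`, `concordance`.
#' @export
glance.pdi_cox <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_events = x$n_events,
    stratum = x$stratum,
    form = x$form,
    converged = x$converged,
    logLik = as.numeric(x$model$loglik[length(x$model$loglik)]),
    concordance = unname(x$model$concordance["concordance"])
  )
}

exposure_term <- function(fit, term = "exposure") {
  td <- tidy(fit)
  row <- td[td$term == term, ]
  if (nrow(row) != 1) {
    stop("term `", term, "` not found in fit", call. = FALSE)
  }
  row
}

#' Hazard ratio per 10 index units
#'
#' For a continuous-exposure fit with per-unit log hazard ratio `b`,
#' returns `HR = exp(10 b)` with Wald 95% limits `exp(10 (b +/- 1.96 se))`.
#'
#' @param fit A `pdi_cox` fit with `form = "continuous"` (or `"trend"`).
#' @return One-row tibble: `hr`, `conf.low`, `conf.high`, `p.value`,
#'   `log_hr` (per 10 units) and `se` (per 10 units).
#' @export
hr_per_10 <- function(fit) {
  stopifnot(inherits(fit, "pdi_cox"))
  if (!fit$form %in% c("continuous", "trend")) {
    stop("hr_per_10() needs a continuous exposure fit", call. = FALSE)
  }
  row <- exposure_term(fit)
  b10 <- 10 * row$estimate
  se10 <- 10 * row$std.error
  tibble::tibble(
    hr = exp(b10),
    conf.low = exp(b10 - 1.96 * se10),
    conf.high = exp(b10 + 1.96 * se10),
    p.value = row$p.value,
    log_hr = b10,
    se = se10
  )
}

#' Highest-vs-lowest decile hazard ratio
#'
#' Extracts the bin-10 coefficient of a decile-indicator fit (bin 1 is the
#' reference); the other eight contrasts stay available via [tidy()].
#'
#' @param fit A `pdi_cox` fit with `form = "deciles"`.
#' @return One-row tibble: `hr`, `conf.low`, `conf.high`, `p.value`,
#'   `log_hr`, `se`.
#' @export
extreme_decile_hr <- function(fit) {
  stopifnot(inherits(fit, "pdi_cox"))
  if (fit$form != "deciles") {
    stop("extreme_decile_hr() needs a decile-indicator fit", call. = FALSE)
  }
  xlev <- fit$model$xlevels[["exposure"]]
  if (is.null(xlev) || !("1" %in% xlev) || !("10" %in% xlev)) {
    stop("reference (bin 1) or top (bin 10) decile bin is empty", call. = FALSE)
  }
  row <- exposure_term(fit, "exposure10")
  tibble::tibble(
    hr = exp(row$estimate),
    conf.low = exp(row$conf.low),
    conf.high = exp(row$conf.high),
    p.value = row$p.value,
    log_hr = row$estimate,
    se = row$std.error
  )
}

#' P-for-trend across decile bins
#'
#' Each participant's exposure is replaced by the median index value of
#' their decile bin (the `decile_median` column of [decile_bins()]); the
#' Wald p-value of that single continuous term is the trend test.
#'
#' @param data Cohort joined with an index carrying `decile_median`.
#' @param median_col Name of the decile-median column.
#' @inheritParams fit_cox
#' @return The two-sided Wald p-value, with the underlying `pdi_cox` fit
#'   in attribute `"fit"`.
#' @export
p_for_trend <- function(data, median_col = "decile_median",
                        covariates = NULL, stratum = "all", ...) {
  fit <- fit_cox(data, median_col, form = "trend",
                 covariates = covariates, stratum = stratum, ...)
  p <- exposure_term(fit)$p.value
  attr(p, "fit") <- fit
  p
}

#' Fixed-effects (inverse-variance) meta-analysis of log hazard ratios
#'
#' Combines stratum-specific log hazard ratios with weights `1/se^2`:
#' the combined estimate is the weighted mean and the combined variance
#' `1 / sum(1/se^2)`. With one stratum this is the identity.
#'
#' @param beta Numeric vector of log hazard ratios (one per stratum).
#' @param se Their standard errors (strictly positive).
#' @return One-row tibble: `beta`, `se`, `conf.low`, `conf.high`,
#'   `p.value` (log-HR scale, Wald, 1.96 limits), `hr`, `hr.conf.low`,
#'   `hr.conf.high`, `k` (number of strata).
#' @export
#' @examples
#' meta_fixed_effects(c(0.1, 0.3), c(0.1, 0.2))
meta_fixed_effects <- function(beta, se) {
  stopifnot(length(beta) == length(se), length(beta) >= 1, all(se > 0))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  z <- b / s
  tibble::tibble(
    beta = b,
    se = s,
    conf.low = b - 1.96 * s,
    conf.high = b + 1.96 * s,
    p.value = 2 * stats::pnorm(-abs(z)),
    hr = exp(b),
    hr.conf.low = exp(b - 1.96 * s),
    hr.conf.high = exp(b + 1.96 * s),
    k = length(beta)
  )
}
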