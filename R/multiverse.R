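#' Specification family: potatoes recategorization models
#'
#' The replication configuration plus the five alternative categorizations
#' of the potatoes food group:
#' \describe{
#'   \item{model 1}{exclude the potatoes group entirely (17 groups)}
#'   \item{model 2}{move the intact potatoes group into the healthy-plant
#'     super-category (18 groups; the PDI is unchanged by construction)}
#'   \item{model 3}{merge all potato items into vegetables (17 groups)}
#'   \item{model 4}{white potato becomes its own healthy-plant group; the
#'     remaining potato items stay unhealthy (19 groups)}
#'   \item{model 5}{white potato merges into vegetables; the remaining
#'     potato items stay unhealthy (18 groups)}
#' }
#' Group counts (and hence the 18-90 rescaling) adjust automatically.
#'
#' @param base A [food_groups()] tibble containing a `potatoes` group whose
#'   items are `white_potato`, `french_fries`, `salty_snacks`,
#'   `low_fat_salty_snacks`.
#' @return A `pdi_spec_family` tibble with columns `label`, `family`,
#'   `grouping` (list) and `coding` (list; `NULL` entries mean "derive the
#'   coding from the super-categories for each requested index").
#' @export
recategorization_family <- function(base = food_groups()) {
  validate_grouping(base)
  if (!"potatoes" %in% base$group) {
    stop("base grouping has no `potatoes` group", call. = FALSE)
  }
  rest_items <- setdiff(potato_items(), "white_potato")
  i_pot <- which(base$group == "potatoes")
  i_veg <- which(base$group == "vegetables")

  m1 <- base[-i_pot, ]

  m2 <- base
  m2$super_category[i_pot] <- "healthy_plant"

  m3 <- base
  m3$components[[i_veg]] <- c(m3$components[[i_veg]], m3$components[[i_pot]])
  m3 <- m3[-i_pot, ]

  m4 <- base
  m4$components[[i_pot]] <- rest_items
  m4 <- dplyr::add_row(
    m4, group = "white_potato", super_category = "healthy_plant",
    components = list("white_potato"), .after = i_pot
  )

  m5 <- base
  m5$components[[i_veg]] <- c(m5$components[[i_veg]], "white_potato")
  m5$components[[i_pot]] <- rest_items

  fam <- tibble::tibble(
    label = c("replication", "m1_exclude_potatoes", "m2_potato_group_healthy",
              "m3_potatoes_in_vegetables", "m4_white_potato_healthy",
              "m5_white_potato_in_vegetables"),
    family = "recategorization",
    grouping = list(base, m1, m2, m3, m4, m5),
    coding = vector("list", 6)
  )
  class(fam) <- c("pdi_spec_family", class(fam))
  attr(fam, "base_grouping") <- base
  fam
}

#' Specification family: leave-one-out over the plant food groups
#'
#' One configuration per plant food group, omitting that group from the
#' index (12 members for the default 12 plant groups); animal groups are
#' untouched and each member's index is rescaled back to the 18-90 range.
#'
#' @inheritParams recategorization_family
#' @return A `pdi_spec_family` tibble.
#' @export
leave_one_out_family <- function(base = food_groups()) {
  validate_grouping(base)
  pg <- plant_groups(base)
  members <- lapply(pg, function(g) base[base$group != g, ])
  fam <- tibble::tibble(
    label = paste0("loo_", pg),
    family = "leave_one_out",
    grouping = members,
    coding = vector("list", length(pg))
  )
  class(fam) <- c("pdi_spec_family", class(fam))
  attr(fam, "base_grouping") <- base
  fam
}

#' Specification family: agnostic enumeration of plant-group codings
#'
#' Enumerates every assignment of positive/reverse scoring over the
#' permutable plant groups (2^P coding vectors; 4,096 for the full 12),
#' with animal groups fixed reverse and any non-permuted plant group kept
#' at its hPDI-default direction. Enumeration is deterministic and
#' lexicographic over the configuration's plant-group order; each member's
#' label encodes its direction bit-vector (`1` = positive), so the family
#' is closed under the all-bits complement — which is why the
#' uPDI-oriented enumeration coincides with this hPDI-oriented one as a
#' set.
#'
#' @inheritParams recategorization_family
#' @param permute Plant groups whose direction is enumerated; default all
#'   of them. A subset gives a scaled-down multiverse (2^length(permute)
#'   members).
#' @return A `pdi_spec_family` tibble with explicit `coding` entries and
#'   attributes `permuted_groups` and `base_grouping`.
#' @export
#' @examples
#' nrow(agnostic_family(permute = plant_groups()[1:2]))  # 4
agnostic_family <- function(base = food_groups(), permute = plant_groups(base)) {
  validate_grouping(base)
  pg <- plant_groups(base)
  if (!length(pg)) stop("no plant groups identified in base", call. = FALSE)
  bad <- setdiff(permute, pg)
  if (length(bad)) {
    stop("permute contains non-plant group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  permute <- pg[pg %in% permute]  # enforce configuration order
  P <- length(permute)
  if (P > 16) stop("refusing to enumerate 2^", P, " codings", call. = FALSE)
  hpdi <- index_coding("hpdi", base)
  n_mem <- 2L^P
  bits_mat <- matrix(0L, n_mem, P)
  for (j in seq_len(P)) {
    # lexicographic: first permuted group is the most significant bit
    bits_mat[, j] <- rep(rep(0:1, each = 2L^(P - j)), length.out = n_mem)
  }
  labels <- paste0("agn_", apply(bits_mat, 1, paste, collapse = ""))
  codings <- lapply(seq_len(n_mem), function(i) {
    cd <- hpdi
    dir <- ifelse(bits_mat[i, ] == 1L, "positive", "reverse")
    cd$direction[match(permute, cd$group)] <- dir
    attr(cd, "label") <- "hpdi_oriented"
    attr(cd, "bits") <- bits_mat[i, ]
    cd
  })
  fam <- tibble::tibble(
    label = labels,
    family = "agnostic",
    grouping = rep(list(base), n_mem),
    coding = codings
  )
  class(fam) <- c("pdi_spec_family", class(fam))
  attr(fam, "base_grouping") <- base
  attr(fam, "permuted_groups") <- permute
  fam
}

#' Direction of one group across an agnostic family
#'
#' @param family An [agnostic_family()] tibble.
#' @param group A permuted plant group.
#' @return Named character vector (`"positive"`/`"reverse"`) keyed by
#'   member label.
#' @export
coding_direction <- function(family, group) {
  permuted <- attr(family, "permuted_groups")
  if (is.null(permuted) || !group %in% permuted) {
    stop("`", group, "` is not a permuted group of this family", call. = FALSE)
  }
  j <- match(group, permuted)
  bits <- substr(sub("^agn_", "", family$label), j, j)
  stats::setNames(ifelse(bits == "1", "positive", "reverse"), family$label)
}

flip_label <- function(label, j) {
  bits <- sub("^agn_", "", label)
  flipped <- substr(bits, j, j) == "0"
  substr(bits, j, j) <- ifelse(flipped, "1", "0")
  paste0("agn_", bits)
}

#' Run every specification of a family against a cohort
#'
#' For each member configuration (and, where the member does not fix a
#' coding, each requested named index) the group intakes are re-summed,
#' quintile scores rebuilt, the index rescaled to 18-90, and Cox models
#' fitted per stratum: a continuous per-10-unit model and, when requested,
#' decile-indicator and decile-median trend models. Gender strata are
#' combined by fixed-effects meta-analysis into a `"combined"` row.
#' Positive quintile scores are cached per distinct component set, since a
#' group's scores depend only on its own summed intake distribution.
#' Member-level fitting failures are flagged (`converged = FALSE`, message
#' in `note`), not fatal.
#'
#' @param cohort An eligibility-filtered, exposure-resolved cohort tibble.
#' @param family A `pdi_spec_family` from [recategorization_family()],
#'   [leave_one_out_family()] or [agnostic_family()].
#' @param indices Named indices to build for members without an explicit
#'   coding (ignored for agnostic members, which carry their own).
#' @param forms `"continuous"` and/or `"deciles"` (deciles also yields the
#'   trend p).
#' @param strata Gender strata to fit; `"combined"` rows are added by
#'   meta-analysis whenever two or more strata are fitted.
#' @param covariates Adjustment covariates; default the full available set
#'   per stratum.
#' @param by Stratification column for quantile cutpoints.
#' @param progress Print a line every `progress` members (0 = silent).
#' @return A tibble, one row per member x index x stratum: `label`,
#'   `family`, `index`, `stratum`, `n`, `n_events`, per-10-unit columns
#'   (`hr10`, `hr10_lo`, `hr10_hi`, `hr10_p`), extreme-decile columns
#'   (`hrx`, `hrx_lo`, `hrx_hi`, `hrx_p`), `trend_p`, `converged`, `note`.
#' @export
run_specs <- function(cohort, family,
                      indices = c("pdi", "hpdi", "updi"),
                      forms = c("continuous", "deciles"),
                      strata = c("female", "male"),
                      covariates = NULL, by = "gender", progress = 0) {
  stopifnot(inherits(family, "pdi_spec_family"))
  forms <- match.arg(forms, several.ok = TRUE)
  score_cache <- new.env(parent = emptyenv())
  strata_idx <- lapply(
    stats::setNames(strata, strata),
    function(s) if (s == "all") seq_len(nrow(cohort)) else which(cohort$gender == s)
  )
  base_cols <- intersect(c("entry_age", "exit_age", "event", "gender"),
                         names(cohort))
  covs_for <- function(s) {
    if (!is.null(covariates)) return(intersect(covariates, names(cohort)))
    intersect(adjustment_covariates(if (s == "all") "all" else s),
              names(cohort))
  }
  cov_union <- unique(unlist(lapply(strata, covs_for)))
  frame <- cohort[unique(c(base_cols, cov_union))]

  cached_scores <- function(comps, strat_vec) {
    key <- paste(sort(comps), collapse = "|")
    if (!is.null(score_cache[[key]])) return(score_cache[[key]])
    intake <- rowSums(as.matrix(cohort[comps]))
    sc <- integer(length(intake))
    for (s in unique(strat_vec)) {
      idx <- strat_vec == s
      sc[idx] <- quantile_score(intake[idx], k = 5)
    }
    score_cache[[key]] <- sc
    sc
  }

  strat_vec <- if (is.null(by)) rep("all", nrow(cohort)) else cohort[[by]]
  rows <- list()
  empty_num <- stats::setNames(
    rep(NA_real_, 9),
    c("hr10", "hr10_lo", "hr10_hi", "hr10_p",
      "hrx", "hrx_lo", "hrx_hi", "hrx_p", "trend_p")
  )

  for (m in seq_len(nrow(family))) {
    grouping <- family$grouping[[m]]
    G <- nrow(grouping)
    smat <- vapply(
      grouping$components,
      function(comps) cached_scores(comps, strat_vec),
      numeric(nrow(cohort))
    )
    member_codings <- if (is.null(family$coding[[m]])) {
      lapply(stats::setNames(indices, indices), index_coding,
             grouping = grouping)
    } else {
      cd <- family$coding[[m]]
      stats::setNames(list(cd), attr(cd, "label") %||% "custom")
    }
    for (index_name in names(member_codings)) {
      cd <- member_codings[[index_name]]
      rev <- cd$direction[match(grouping$group, cd$group)] == "reverse"
      # raw = sum of coded scores: positive groups keep s, reverse use 6 - s
      raw <- rowSums(smat)
      if (any(rev)) {
        raw <- raw + rowSums(6 - 2 * smat[, rev, drop = FALSE])
      }
      rescaled <- raw * 18 / G
      if ("deciles" %in% forms) {
        bin <- integer(nrow(cohort))
        med <- numeric(nrow(cohort))
        for (s in unique(strat_vec)) {
          idx <- strat_vec == s
          b <- quantile_score(rescaled[idx], k = 10)
          mm <- tapply(rescaled[idx], b, stats::median)
          bin[idx] <- b
          med[idx] <- unname(mm[as.character(b)])
        }
      }
      stratum_rows <- list()
      for (s in strata) {
        ridx <- strata_idx[[s]]
        covs <- covs_for(s)
        df <- frame[ridx, c(base_cols, covs)]
        res <- c(list(label = family$label[m], family = family$family[m],
                      index = index_name, stratum = s,
                      n = length(ridx), n_events = sum(df$event)),
                 as.list(empty_num),
                 list(converged = TRUE, note = NA_character_))
        fit_one <- function(expr) {
          tryCatch(expr, error = function(e) {
            res$converged <<- FALSE
            res$note <<- conditionMessage(e)
            NULL
          })
        }
        if ("continuous" %in% forms) {
          df$index_value <- rescaled[ridx]
          fit <- fit_one(fit_cox(df, "index_value", "continuous",
                                 covariates = covs, stratum = "all"))
          if (!is.null(fit)) {
            if (!fit$converged) res$converged <- FALSE
            h <- hr_per_10(fit)
            res[c("hr10", "hr10_lo", "hr10_hi", "hr10_p")] <-
              as.list(unname(unlist(h[c("hr", "conf.low", "conf.high", "p.value")])))
          }
        }
        if ("deciles" %in% forms) {
          df$index_decile <- bin[ridx]
          df$index_trend <- med[ridx]
          fit_d <- fit_one(fit_cox(df, "index_decile", "deciles",
                                   covariates = covs, stratum = "all"))
          if (!is.null(fit_d)) {
            if (!fit_d$converged) res$converged <- FALSE
            h <- fit_one(extreme_decile_hr(fit_d))
            if (!is.null(h)) {
              res[c("hrx", "hrx_lo", "hrx_hi", "hrx_p")] <-
                as.list(unname(unlist(h[c("hr", "conf.low", "conf.high", "p.value")])))
            }
          }
          fit_t <- fit_one(fit_cox(df, "index_trend", "trend",
                                   covariates = covs, stratum = "all"))
          if (!is.null(fit_t)) {
            if (!fit_t$converged) res$converged <- FALSE
            res$trend_p <- exposure_term(fit_t)$p.value
            res$trend_beta <- exposure_term(fit_t)$estimate
            res$trend_se <- exposure_term(fit_t)$std.error
          }
        }
        stratum_rows[[s]] <- res
      }
      if (length(strata) >= 2) {
        stratum_rows[["combined"]] <- combine_strata(stratum_rows, family$label[m],
                                                     family$family[m], index_name)
      }
      rows <- c(rows, stratum_rows)
      if (progress > 0 && m %% progress == 0) {
        message("member ", m, "/", nrow(family))
      }
    }
  }
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  keep <- setdiff(names(out), c("trend_beta", "trend_se"))
  out[keep]
}

combine_strata <- function(stratum_rows, label, family, index_name) {
  ok <- Filter(function(r) isTRUE(r$converged), stratum_rows)
  res <- list(label = label, family = family, index = index_name,
              stratum = "combined",
              n = sum(vapply(stratum_rows, `[[`, 0, "n")),
              n_events = sum(vapply(stratum_rows, `[[`, 0, "n_events")),
              hr10 = NA_real_, hr10_lo = NA_real_, hr10_hi = NA_real_,
              hr10_p = NA_real_, hrx = NA_real_, hrx_lo = NA_real_,
              hrx_hi = NA_real_, hrx_p = NA_real_, trend_p = NA_real_,
              converged = length(ok) == length(stratum_rows),
              note = NA_character_)
  grab <- function(field) vapply(ok, `[[`, 0, field)
  if (length(ok) && all(!is.na(grab("hr10")))) {
    # per-10-unit log HR and its SE recovered from the Wald machinery
    b <- log(grab("hr10"))
    se <- (log(grab("hr10_hi")) - log(grab("hr10_lo"))) / (2 * 1.96)
    mfe <- meta_fixed_effects(b, se)
    res[c("hr10", "hr10_lo", "hr10_hi", "hr10_p")] <-
      as.list(unname(unlist(mfe[c("hr", "hr.conf.low", "hr.conf.high", "p.value")])))
  }
  if (length(ok) && all(!is.na(grab("hrx")))) {
    b <- log(grab("hrx"))
    se <- (log(grab("hrx_hi")) - log(grab("hrx_lo"))) / (2 * 1.96)
    mfe <- meta_fixed_effects(b, se)
    res[c("hrx", "hrx_lo", "hrx_hi", "hrx_p")] <-
      as.list(unname(unlist(mfe[c("hr", "hr.conf.low", "hr.conf.high", "p.value")])))
  }
  tb <- vapply(ok, function(r) r$trend_beta %||% NA_real_, 0)
  ts <- vapply(ok, function(r) r$trend_se %||% NA_real_, 0)
  if (length(ok) && all(!is.na(tb)) && all(!is.na(ts))) {
    res$trend_p <- meta_fixed_effects(tb, ts)$p.value
  }
  res
}

#' Compare hazard-ratio distributions between coding directions of a group
#'
#' Splits a complete agnostic family's results by whether `group` was
#' positively or reversely coded and computes, per direction, the
#' geometric-mean hazard ratio `exp(mean(log HR))`, the empirical 95%
#' spread (2.5th and 97.5th HR percentiles), median, min and max; the
#' difference and ratio of the two geometric means
#' (`exp(mean log HR_pos) - exp(mean log HR_rev)` and
#' `exp(mean log HR_pos) / exp(mean log HR_rev)`); and a paired t-test of
#' the log HRs, pairing each model with its counterpart differing only in
#' this group's direction bit (2^(P-1) pairs). Pairs containing a
#' non-converged (or missing-HR) member are dropped together with their
#' partner; the dropped count is reported.
#'
#' @param results A [run_specs()] result for a complete agnostic family.
#' @param family The [agnostic_family()] the results came from.
#' @param group Permuted plant group to compare.
#' @param stratum Stratum to summarise (`"female"`, `"male"`,
#'   `"combined"`).
#' @param measure `"hr10"` (continuous per-10-unit) or `"hrx"`
#'   (highest-vs-lowest decile).
#' @return One-row tibble with the direction summaries, `difference`,
#'   `ratio`, `t_p`, `t_df`, `n_pairs`, `n_pairs_dropped`.
#' @export
summarize_group_direction <- function(results, family, group,
                                      stratum = "combined",
                                      measure = c("hr10", "hrx")) {
  measure <- match.arg(measure)
  permuted <- attr(family, "permuted_groups")
  if (is.null(permuted)) stop("family is not an agnostic family", call. = FALSE)
  j <- match(group, permuted)
  if (is.na(j)) {
    stop("`", group, "` is not a permuted group of this family", call. = FALSE)
  }
  res <- results[results$stratum == stratum & results$label %in% family$label, ]
  missing_labels <- setdiff(family$label, res$label)
  if (length(missing_labels)) {
    stop("incomplete agnostic family in results; missing ",
         length(missing_labels), " member(s), e.g. ",
         paste(utils::head(missing_labels, 3), collapse = ", "),
         call. = FALSE)
  }
  hr <- stats::setNames(res[[measure]], res$label)
  ok <- stats::setNames(res$converged & !is.na(res[[measure]]), res$label)
  pos_labels <- family$label[coding_direction(family, group) == "positive"]
  partner <- stats::setNames(flip_label(pos_labels, j), pos_labels)
  pair_ok <- ok[pos_labels] & ok[partner]
  n_dropped <- sum(!pair_ok)
  pos_l <- pos_labels[pair_ok]
  rev_l <- partner[pair_ok]
  if (!length(pos_l)) stop("no usable pairs", call. = FALSE)
  log_pos <- log(hr[pos_l])
  log_rev <- log(hr[rev_l])
  dir_stats <- function(l) {
    q <- stats::quantile(exp(l), c(0.025, 0.975), type = 7, names = FALSE)
    tibble::tibble(
      mean_hr = exp(mean(l)), spread_lo = q[1], spread_hi = q[2],
      median_hr = stats::median(exp(l)), min_hr = min(exp(l)),
      max_hr = max(exp(l))
    )
  }
  sp <- dir_stats(log_pos)
  sr <- dir_stats(log_rev)
  diffs <- log_pos - log_rev
  # constant differences (degenerate synthetic result sets) have no t
  # statistic; report p = 1 at zero shift, p = 0 at a nonzero exact shift
  tt <- tryCatch(stats::t.test(diffs), error = function(e) NULL)
  if (is.null(tt)) {
    tt <- list(p.value = if (isTRUE(all.equal(mean(diffs), 0))) 1 else 0,
               parameter = c(df = length(diffs) - 1))
  }
  tibble::tibble(
    group = group, stratum = stratum, measure = measure,
    mean_hr_positive = sp$mean_hr, spread_lo_positive = sp$spread_lo,
    spread_hi_positive = sp$spread_hi, median_hr_positive = sp$median_hr,
    min_hr_positive = sp$min_hr, max_hr_positive = sp$max_hr,
    mean_hr_reverse = sr$mean_hr, spread_lo_reverse = sr$spread_lo,
    spread_hi_reverse = sr$spread_hi, median_hr_reverse = sr$median_hr,
    min_hr_reverse = sr$min_hr, max_hr_reverse = sr$max_hr,
    difference = sp$mean_hr - sr$mean_hr,
    ratio = sp$mean_hr / sr$mean_hr,
    mean_log_diff = mean(diffs),
    t_p = tt$p.value,
    t_df = unname(tt$parameter),
    n_pairs = length(diffs),
    n_pairs_dropped = n_dropped
  )
}

#' Direction summaries for several groups and strata
#'
#' @inheritParams summarize_group_direction
#' @param groups Permuted groups to summarise (default all).
#' @param strata Strata to summarise.
#' @return A tibble, one row per group x stratum (see
#'   [summarize_group_direction()]).
#' @export
summarize_directions <- function(results, family,
                                 groups = attr(family, "permuted_groups"),
                                 strata = "combined",
                                 measure = "hr10") {
  grid <- tidyr::expand_grid(group = groups, stratum = strata)
  purrr::pmap(grid, function(group, stratum) {
    summarize_group_direction(results, family, group, stratum, measure)
  }) |> dplyr::bind_rows()
}
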