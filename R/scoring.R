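#' Quantile scores with a deterministic tie rule
#'
#' Scores a vector into `k` quantile bins, 1 (lowest) to `k` (highest).
#' Cutpoints are empirical percentiles with linear interpolation
#' (`stats::quantile()` type 7). A value equal to a cutpoint goes to the
#' lower bin; duplicated cutpoints (e.g. under heavy ties at zero) collapse
#' bins, and affected values take the lowest applicable score — so a
#' constant vector scores 1 everywhere.
#'
#' @param x Numeric vector.
#' @param k Number of bins (5 for quintiles, 10 for deciles).
#' @return Integer scores in `1..k`.
#' @export
quantile_score <- function(x, k = 5) {
  stopifnot(k >= 2, is.numeric(x))
  cuts <- stats::quantile(x, probs = seq_len(k - 1) / k, type = 7, names = FALSE)
  out <- rep(1L, length(x))
  for (cut in cuts) out <- out + (x > cut)
  as.integer(out)
}

#' Quintile scores for food-group intakes
#'
#' Within each stratum (gender by default, mirroring the sex-specific
#' source cohorts of the scoring approach) and each food group, summed
#' group intakes are divided by quintiles and scored 1-5. Positive
#' direction: higher intake, higher score; reverse direction: 6 minus the
#' positive score. With `coding = NULL` all groups are scored positively,
#' the form consumed by [build_index()].
#'
#' @param data Resolved cohort tibble (see [resolve_diet_exposure()])
#'   containing every component column of `grouping`.
#' @param grouping A [food_groups()] tibble (possibly a recategorization
#'   variant); group intake is the row sum of its `components` columns.
#' @param coding Optional coding tibble from [index_coding()]; `NULL`
#'   scores every group positively.
#' @param by Stratification column for the quantile cutpoints, or `NULL`
#'   for whole-cohort quantiles.
#' @param min_stratum Minimum stratum size; smaller strata are an error
#'   (quantile cutpoints would be meaningless).
#' @return A tibble with `id`, the stratification column, and one integer
#'   score column per group; attributes `"grouping"` and `"coding"`.
#' @export
score_quintiles <- function(data, grouping = food_groups(), coding = NULL,
                            by = "gender", min_stratum = 10) {
  validate_grouping(grouping)
  if (!is.null(coding)) validate_coding(coding, grouping)
  comp_cols <- unique(unlist(grouping$components))
  missing_cols <- setdiff(comp_cols, names(data))
  if (length(missing_cols)) {
    stop("data lacks intake column(s): ", paste(missing_cols, collapse = ", "),
         " (did you run resolve_diet_exposure()?)", call. = FALSE)
  }
  strata <- if (is.null(by)) rep("all", nrow(data)) else data[[by]]
  tab <- table(strata)
  if (any(tab < min_stratum)) {
    stop("stratum smaller than min_stratum (", min_stratum, "): ",
         paste(names(tab)[tab < min_stratum], collapse = ", "), call. = FALSE)
  }
  neg <- vapply(comp_cols, function(cl) any(data[[cl]] < 0, na.rm = TRUE),
                logical(1))
  if (any(neg)) {
    stop("negative intakes in: ", paste(comp_cols[neg], collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(id = data$id)
  if (!is.null(by)) out[[by]] <- data[[by]]
  for (i in seq_len(nrow(grouping))) {
    g <- grouping$group[i]
    comps <- grouping$components[[i]]
    intake <- rowSums(as.matrix(data[comps]))
    score <- integer(nrow(data))
    for (s in unique(strata)) {
      idx <- strata == s
      score[idx] <- quantile_score(intake[idx], k = 5)
    }
    if (!is.null(coding) &&
        coding$direction[match(g, coding$group)] == "reverse") {
      score <- 6L - score
    }
    out[[g]] <- as.integer(score)
  }
  attr(out, "grouping") <- grouping
  attr(out, "coding") <- coding
  out
}

#' Build a diet index from quintile scores
#'
#' Applies a coding vector to positively scored quintiles (reverse groups
#' become 6 minus the score), sums the group scores into the raw index, and
#' linearly rescales so that `G` active groups map `[G, 5G]` onto
#' `[18, 90]` (with the full 18 groups the rescaled index equals the raw
#' index; index variants with fewer or more groups are rescaled back to
#' the original scale).
#'
#' @param scores Positive-direction score tibble from [score_quintiles()]
#'   (`coding = NULL`).
#' @param coding A coding tibble from [index_coding()] or an agnostic
#'   variant; must cover the scored groups exactly.
#' @return A tibble with `id`, the stratification column if present,
#'   `raw` and `rescaled`; attribute `"n_groups"`.
#' @export
build_index <- function(scores, coding) {
  grouping <- attr(scores, "grouping")
  if (is.null(grouping)) stop("scores lack a grouping attribute", call. = FALSE)
  if (!is.null(attr(scores, "coding"))) {
    stop("scores were already direction-coded; rebuild with coding = NULL",
         call. = FALSE)
  }
  validate_coding(coding, grouping)
  G <- nrow(grouping)
  meta_cols <- intersect(c("id", "gender"), names(scores))
  mat <- as.matrix(scores[grouping$group])
  rev <- coding$direction[match(grouping$group, coding$group)] == "reverse"
  mat[, rev] <- 6L - mat[, rev]
  raw <- rowSums(mat)
  out <- scores[meta_cols]
  out$raw <- raw
  out$rescaled <- raw * 18 / G
  attr(out, "n_groups") <- G
  attr(out, "index_label") <- attr(coding, "label")
  out
}

#' Decile bins and bin medians of an index
#'
#' Within each stratum, participants are partitioned into 10 bins by index
#' deciles (same interpolation and tie rule as [quantile_score()]: bin 1
#' from below decile 1, bin 10 from above decile 9; duplicated cutpoints
#' collapse bins). Each bin's median index value is attached for the
#' trend analysis.
#'
#' @param index Output of [build_index()].
#' @param by Stratification column, or `NULL` for whole-cohort deciles.
#' @param value Column to bin (default the rescaled index).
#' @return `index` with integer `decile` and numeric `decile_median`
#'   columns added.
#' @export
decile_bins <- function(index, by = "gender", value = "rescaled") {
  stopifnot(value %in% names(index))
  strata <- if (is.null(by)) rep("all", nrow(index)) else index[[by]]
  v <- index[[value]]
  bin <- integer(length(v))
  med <- numeric(length(v))
  for (s in unique(strata)) {
    idx <- strata == s
    b <- quantile_score(v[idx], k = 10)
    m <- tapply(v[idx], b, stats::median)
    bin[idx] <- b
    med[idx] <- unname(m[as.character(b)])
  }
  index$decile <- bin
  index$decile_median <- med
  index
}

#' Compute a diet index for a resolved cohort
#'
#' Convenience chain: quintile-score the group intakes, apply the coding,
#' rescale, and attach decile bins.
#'
#' @param data Resolved cohort tibble.
#' @param index Index name (`"pdi"`, `"hpdi"`, `"updi"`) or a coding tibble.
#' @param grouping A [food_groups()] tibble.
#' @param by Stratification column for quantiles and deciles.
#' @inheritParams score_quintiles
#' @return A tibble with `id`, stratum, `raw`, `rescaled`, `decile`,
#'   `decile_median`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_params(n_participants = 300), seed = 2)
#' cohort |>
#'   resolve_diet_exposure() |>
#'   compute_index("hpdi") |>
#'   head()
compute_index <- function(data, index = "hpdi", grouping = food_groups(),
                          by = "gender", min_stratum = 10) {
  coding <- if (is.character(index)) index_coding(index, grouping) else index
  scores <- score_quintiles(data, grouping, coding = NULL, by = by,
                            min_stratum = min_stratum)
  build_index(scores, coding) |> decile_bins(by = by)
}
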