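test_that("item-to-group mapping sums members and logs unmatched items", {
  im <- tibble::tibble(
    item = c("broccoli", "carrots", "oatmeal"),
    group = c("vegetables", "vegetables", "whole_grains")
  )
  cfg <- food_groups(item_map = im)
  items <- tibble::tibble(
    id = c("p1", "p1", "p1", "p1", "p2"),
    item = c("broccoli", "carrots", "gravy", "oatmeal", "broccoli"),
    servings = c(0.5, 0.3, 1.0, 0.7, 0.2)
  )
  out <- map_items_to_groups(items, cfg)
  expect_equal(out$vegetables[out$id == "p1"], 0.8)
  expect_equal(out$whole_grains[out$id == "p1"], 0.7)  # single-item identity
  expect_equal(out$vegetables[out$id == "p2"], 0.2)
  un <- attr(out, "unmatched")
  expect_equal(un$item, "gravy")
  expect_equal(un$n_rows, 1L)
  expect_error(map_items_to_groups(items[0, ], cfg), "empty")
  expect_error(map_items_to_groups(items, food_groups()), "item_map")
})

test_that("quintile scoring matches rank logic on distinct values and flips under reverse coding", {
  withr::local_seed(21)
  x <- sample(seq(0.1, 10, length.out = 100))
  s <- quantile_score(x, 5)
  expect_equal(as.integer(table(s)), rep(20L, 5))
  expect_equal(s, oracle_rank_bins(x, 5))
  expect_equal(6L - s, 6L - oracle_rank_bins(x, 5))
  # monotone: sorting by intake sorts the scores
  expect_true(all(diff(s[order(x)]) >= 0))
  # degenerate ties: constant vector collapses to the lowest score
  expect_equal(quantile_score(rep(2, 50), 5), rep(1L, 50))
})

test_that("quintile and decile scores agree with the hand-built interpolation oracle under heavy ties", {
  for (seed in 1:3) {
    withr::local_seed(seed)
    n <- sample(200:1000, 1)
    # zero-inflated, duplicated values: the regime that collapses cutpoints
    x <- ifelse(stats::runif(n) < 0.4, 0,
                round(stats::rlnorm(n, 0, 0.8), 1))
    for (k in c(5, 10)) {
      expect_equal(quantile_score(x, k), oracle_quantile_bins(x, k))
    }
  }
})

test_that("within-gender scoring is the default and small strata error", {
  cohort <- analysis_cohort()
  sc <- score_quintiles(cohort)
  for (g in c("whole_grains", "meat")) {
    for (s in c("female", "male")) {
      idx <- cohort$gender == s
      expect_equal(sc[[g]][idx], quantile_score(cohort[[g]][idx], 5))
    }
  }
  expect_error(score_quintiles(cohort[1:5, ], min_stratum = 10), "stratum")
})

test_that("index bounds and rescaling follow the 18-90 linear map", {
  cohort <- analysis_cohort()
  scores <- score_quintiles(cohort)
  coding <- index_coding("pdi")
  # all-minimum coded scores: positive groups at 1, reverse groups at 5
  set_coded <- function(scores, coding, coded) {
    for (g in coding$group) {
      d <- coding$direction[coding$group == g]
      scores[[g]] <- if (d == "positive") coded else 6L - coded
    }
    scores
  }
  lo <- build_index(set_coded(scores, coding, 1L), coding)
  expect_true(all(lo$raw == 18) && all(lo$rescaled == 18))
  hi <- build_index(set_coded(scores, coding, 5L), coding)
  expect_true(all(hi$raw == 90) && all(hi$rescaled == 90))

  # 17 active groups: raw 85 rescales to 90, raw 17 to 18
  g17 <- food_groups()[-10, ]
  s17 <- score_quintiles(cohort, g17)
  cd17 <- index_coding("pdi", g17)
  expect_true(all(build_index(set_coded(s17, cd17, 5L), cd17)$rescaled == 90))
  expect_equal(18 * 85 / 17, 90)
  expect_true(all(build_index(set_coded(s17, cd17, 1L), cd17)$rescaled == 18))
})

test_that("flipping one group's direction shifts the raw index by 6 - 2s", {
  cohort <- analysis_cohort()
  scores <- score_quintiles(cohort)
  cd <- index_coding("pdi")
  base <- build_index(scores, cd)
  cd2 <- cd
  cd2$direction[cd2$group == "nuts"] <- "reverse"
  flipped <- build_index(scores, cd2)
  expect_equal(flipped$raw - base$raw, 6 - 2 * scores$nuts)
})

test_that("uPDI is hPDI with every plant direction flipped; animal groups reverse in both", {
  h <- index_coding("hpdi")
  u <- index_coding("updi")
  plants <- plant_groups()
  animals <- setdiff(h$group, plants)
  expect_true(all(h$direction[h$group %in% animals] == "reverse"))
  expect_true(all(u$direction[u$group %in% animals] == "reverse"))
  hp <- h$direction[match(plants, h$group)]
  up <- u$direction[match(plants, u$group)]
  expect_true(all(hp != up))
})

test_that("decile bins balance on distinct values with nondecreasing medians", {
  withr::local_seed(33)
  idx <- tibble::tibble(
    id = as.character(1:100),
    gender = rep("female", 100),
    raw = sample(seq(18, 90, length.out = 100)),
    rescaled = NA_real_
  )
  idx$rescaled <- idx$raw
  out <- decile_bins(idx)
  expect_equal(as.integer(table(out$decile)), rep(10L, 10))
  med <- tapply(out$decile_median, out$decile, unique)
  expect_true(all(diff(med) >= 0))
  expect_equal(unname(med["1"]), stats::median(out$rescaled[out$decile == 1]))
})

test_that("tied index values partition exhaustively and match the oracle", {
  x <- c(rep(40, 60), rep(50, 25), seq(51, 70, length.out = 15))
  idx <- tibble::tibble(id = as.character(seq_along(x)),
                        gender = "male", raw = x, rescaled = x)
  out <- decile_bins(idx)
  expect_equal(out$decile, oracle_quantile_bins(x, 10))
  expect_true(all(out$decile >= 1 & out$decile <= 10))
  expect_false(any(is.na(out$decile)))
  # bin medians still nondecreasing over the occupied bins
  med <- tapply(out$rescaled, out$decile, stats::median)
  expect_true(all(diff(med) >= 0))
})
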