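test_that("specification families have the exact prescribed sizes", {
  recat <- recategorization_family()
  expect_equal(nrow(recat), 6L)
  expect_equal(recat$label[1], "replication")
  loo <- leave_one_out_family()
  expect_equal(nrow(loo), 12L)
  expect_true(all(vapply(loo$grouping, nrow, 0L) == 17L))
  # animal groups untouched in every leave-one-out member
  for (g in loo$grouping) {
    expect_equal(sum(g$super_category == "animal"), 6L)
  }
  full <- agnostic_family()
  expect_equal(nrow(full), 4096L)
  expect_false(anyDuplicated(full$label) > 0)
  # every plant group positive in exactly half the codings
  for (g in plant_groups()) {
    expect_equal(sum(coding_direction(full, g) == "positive"), 2048L)
  }
  small <- agnostic_family(permute = plant_groups()[1:2])
  expect_equal(nrow(small), 4L)
  expect_error(recategorization_family(food_groups()[-10, ]), "potatoes")
})

test_that("the agnostic family is closed under the all-plant complement", {
  fam <- agnostic_family()
  bits <- sub("^agn_", "", fam$label)
  flipped <- chartr("01", "10", bits)
  expect_setequal(paste0("agn_", flipped), fam$label)
  # hence the hPDI-oriented and uPDI-oriented enumerations coincide as sets
})

test_that("recategorization group counts and potato splits are as designed", {
  recat <- recategorization_family()
  G <- vapply(recat$grouping, nrow, 0L)
  expect_equal(G, c(18L, 17L, 18L, 17L, 19L, 18L))
  m4 <- recat$grouping[[5]]
  expect_true("white_potato" %in% m4$group)
  expect_equal(m4$super_category[m4$group == "white_potato"], "healthy_plant")
  expect_setequal(m4$components[[which(m4$group == "potatoes")]],
                  setdiff(potato_items(), "white_potato"))
  m3 <- recat$grouping[[4]]
  expect_true("potatoes" %in% m3$components[[which(m3$group == "vegetables")]])
  m2 <- recat$grouping[[3]]
  expect_equal(m2$super_category[m2$group == "potatoes"], "healthy_plant")
})

test_that("model 1 equals leave-out-potatoes and model-2 PDI equals replication PDI participantwise", {
  cohort <- analysis_cohort(sim_params(n_participants = 500), seed = 23)
  recat <- recategorization_family()
  loo <- leave_one_out_family()
  g_m1 <- recat$grouping[[2]]
  g_loo <- loo$grouping[[which(loo$label == "loo_potatoes")]]
  for (index in c("pdi", "hpdi", "updi")) {
    i1 <- compute_index(cohort, index, grouping = g_m1)
    i2 <- compute_index(cohort, index, grouping = g_loo)
    expect_identical(i1$raw, i2$raw)
    expect_identical(i1$rescaled, i2$rescaled)
  }
  pdi_rep <- compute_index(cohort, "pdi", grouping = recat$grouping[[1]])
  pdi_m2 <- compute_index(cohort, "pdi", grouping = recat$grouping[[3]])
  expect_identical(pdi_rep$raw, pdi_m2$raw)
  # hPDI does change under model 2 (potatoes now positively scored)
  h_rep <- compute_index(cohort, "hpdi", grouping = recat$grouping[[1]])
  h_m2 <- compute_index(cohort, "hpdi", grouping = recat$grouping[[3]])
  expect_false(identical(h_rep$raw, h_m2$raw))
})

test_that("omitting a group removes exactly its score from the raw index", {
  cohort <- analysis_cohort(sim_params(n_participants = 500), seed = 23)
  scores <- score_quintiles(cohort)
  full_idx <- build_index(scores, index_coding("pdi"))
  g_loo <- food_groups()[food_groups()$group != "nuts", ]
  loo_idx <- compute_index(cohort, "pdi", grouping = g_loo)
  expect_equal(full_idx$raw - loo_idx$raw, as.numeric(scores$nuts))
  expect_true(all(loo_idx$rescaled >= 18 & loo_idx$rescaled <= 90))
})

test_that("run_specs on a replication-only family matches direct survival fits", {
  cohort <- analysis_cohort(sim_params(n_participants = 800), seed = 29)
  fam <- recategorization_family()[1, ]
  res <- run_specs(cohort, fam, indices = "hpdi", forms = "continuous")
  expect_equal(nrow(res), 3L)  # female, male, combined
  idx <- compute_index(cohort, "hpdi")
  d <- cbind(cohort, index_value = idx$rescaled)
  direct <- hr_per_10(fit_cox(d, "index_value", "continuous", stratum = "female"))
  got <- res[res$stratum == "female", ]
  expect_equal(got$hr10, direct$hr)
  expect_equal(got$hr10_p, direct$p.value)
  combined <- meta_fixed_effects(
    c(direct$log_hr,
      hr_per_10(fit_cox(d, "index_value", "continuous", stratum = "male"))$log_hr),
    c(direct$se,
      hr_per_10(fit_cox(d, "index_value", "continuous", stratum = "male"))$se)
  )
  expect_equal(res$hr10[res$stratum == "combined"], combined$hr,
               tolerance = 1e-9)
})

test_that("a toy agnostic run yields one row per coding, stratum and index", {
  cohort <- analysis_cohort(sim_params(n_participants = 300), seed = 31)
  fam <- agnostic_family(permute = plant_groups()[1:2])
  res <- run_specs(cohort, fam, forms = "continuous")
  expect_equal(nrow(res), 4L * 3L)
  expect_setequal(unique(res$stratum), c("female", "male", "combined"))
  expect_true(all(res$index == "hpdi_oriented"))
  # deterministic given identical inputs
  res2 <- run_specs(cohort, fam, forms = "continuous")
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("direction summaries obey the footnote formulas on constructed results", {
  fam <- agnostic_family(permute = plant_groups()[1:2])
  # flipping group 1's bit multiplies the HR by k: ratio must equal 1/k
  k <- 1.25
  base_hr <- c(1.00, 1.10)  # indexed by group-2 bit
  hr <- vapply(fam$label, function(l) {
    bits <- sub("^agn_", "", l)
    h <- base_hr[as.integer(substr(bits, 2, 2)) + 1]
    if (substr(bits, 1, 1) == "0") h * k else h
  }, numeric(1))
  res <- tibble::tibble(
    label = fam$label, family = "agnostic", index = "hpdi_oriented",
    stratum = "combined", n = 100, n_events = 20,
    hr10 = unname(hr), hr10_lo = NA_real_, hr10_hi = NA_real_,
    hr10_p = NA_real_, converged = TRUE, note = NA_character_
  )
  s <- summarize_group_direction(res, fam, plant_groups()[1], "combined")
  expect_equal(s$ratio, 1 / k, tolerance = 1e-12)
  expect_equal(s$difference,
               s$mean_hr_positive - s$mean_hr_reverse, tolerance = 1e-12)
  # footnote identity: ratio * exp(mean log HR_reverse) = exp(mean log HR_positive)
  expect_equal(s$ratio * s$mean_hr_reverse, s$mean_hr_positive,
               tolerance = 1e-12)
  expect_equal(s$n_pairs, 2L)
  expect_equal(s$t_df, 1)

  # degenerate distribution: all HRs identical
  res0 <- res
  res0$hr10 <- 1.07
  s0 <- summarize_group_direction(res0, fam, plant_groups()[1], "combined")
  expect_equal(s0$difference, 0)
  expect_equal(s0$ratio, 1)

  # incomplete family errors naming the missing member
  expect_error(
    summarize_group_direction(res[-1, ], fam, plant_groups()[1], "combined"),
    "missing"
  )

  # a non-converged member drops its pair from the comparison
  res_nc <- res
  res_nc$converged[1] <- FALSE
  s_nc <- summarize_group_direction(res_nc, fam, plant_groups()[1], "combined")
  expect_equal(s_nc$n_pairs, 1L)
  expect_equal(s_nc$n_pairs_dropped, 1L)
})

test_that("paired degrees of freedom equal half the family size minus one", {
  fam <- agnostic_family(permute = plant_groups()[1:3])
  withr::local_seed(41)
  res <- tibble::tibble(
    label = fam$label, family = "agnostic", index = "hpdi_oriented",
    stratum = "combined", n = 100, n_events = 20,
    hr10 = exp(stats::rnorm(8, 0, 0.1)), hr10_lo = NA_real_,
    hr10_hi = NA_real_, hr10_p = NA_real_, converged = TRUE,
    note = NA_character_
  )
  s <- summarize_group_direction(res, fam, plant_groups()[2], "combined")
  expect_equal(s$t_df, 2^(3 - 1) - 1)
  expect_equal(s$n_pairs, 4L)
})
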