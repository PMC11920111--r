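test_that("generated cohort honours the configured arm and site counts", {
  cohort <- generate_cohort(cohort_config(seed = 5))
  expect_equal(sum(cohort$arm == "imaging"), 403)
  expect_equal(sum(cohort$arm == "soc"), 399)
  counts <- table(cohort$site, cohort$arm)
  expect_equal(unname(counts["Ulm", "imaging"]), 107)
  expect_equal(unname(counts["Coimbra", "soc"]), 75)
  expect_false(any(duplicated(cohort$patient_id)))
})

test_that("cT1 missingness follows the configured rate and mechanism", {
  none <- generate_cohort(tiny_config(n = 20, missing_ct1_rate = 0))
  expect_equal(sum(is.na(none$ct1[none$arm == "imaging"])), 0)

  cohort <- generate_cohort(cohort_config(seed = 2))
  img <- cohort[cohort$arm == "imaging", ]
  n_missing <- sum(is.na(img$ct1))
  rate <- 21 / 403
  se <- sqrt(rate * (1 - rate) * nrow(img))
  expect_lt(abs(n_missing - rate * nrow(img)), 3 * se + 1)
  # standard of care never has mpMRI readings
  expect_true(all(is.na(cohort$ct1[cohort$arm == "soc"])))

  fat <- generate_cohort(cohort_config(seed = 2,
                                       missing_mechanism = "fat_dependent"))
  img_fat <- fat[fat$arm == "imaging", ]
  expect_gt(mean(img_fat$pdff[is.na(img_fat$ct1)]),
            mean(img_fat$pdff[!is.na(img_fat$ct1)]))
})

test_that("patient records satisfy their invariants", {
  cohort <- generate_cohort(cohort_config(seed = 9))
  expect_true(all(is.na(cohort$mas[!cohort$biopsied])))
  expect_true(all(is.na(cohort$fibrosis[!cohort$biopsied])))
  expect_true(all(!is.na(cohort$mas[cohort$biopsied])))
  expect_true(all(cohort$ct1 > 0, na.rm = TRUE))
  expect_true(all(cohort$pdff >= 0 & cohort$pdff <= 100, na.rm = TRUE))
  expect_true(all(cohort$age >= 18 & cohort$age <= 75))
})

test_that("invalid configuration errors name the offending field", {
  expect_error(cohort_config(missing_ct1_rate = 1.2), "missing_ct1_rate")
  expect_error(cohort_config(dx_rate_by_arm = c(imaging = 0.5, soc = -0.1)),
               "dx_rate_by_arm")
  bp <- default_biomarker_params()
  bp$sd[3] <- -1
  expect_error(cohort_config(biomarker_params = bp), "biomarker_params")
  hr <- default_hcru_rates()
  hr$category[1] <- "acupuncture"
  expect_error(cohort_config(hcru_rates = hr), "acupuncture")
  bad_hist <- default_histology_model()
  bad_hist$imaging_joint <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(cohort_config(histology_model = bad_hist), "histology_model")
})

test_that("configured diagnosis rates are recovered at large n", {
  cfg <- one_site_config(10000L, 10000L, seed = 31)
  cohort <- generate_cohort(cfg)
  for (arm in trial_arms) {
    p <- cfg$dx_rate_by_arm[[arm]]
    obs <- mean(cohort$has_final_dx[cohort$arm == arm])
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(obs - p), 3 * se)
  }
})

test_that("identical seed and config give identical output, byte for byte", {
  cfg <- tiny_config(n = 10, seed = 17)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  e1 <- generate_hcru_events(c1, cfg)
  e2 <- generate_hcru_events(c2, cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(e1, f1, row.names = FALSE)
  write.csv(e2, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("event generation matches its Poisson calibration", {
  rates0 <- default_hcru_rates()
  rates0$imaging <- 0; rates0$soc <- 0
  quiet <- tiny_config(n = 5, hcru_rates = rates0,
                       biopsy_referral_rate = c(imaging = 0, soc = 0))
  ev0 <- generate_hcru_events(generate_cohort(quiet), quiet)
  expect_equal(nrow(ev0), 0)

  cfg <- cohort_config(seed = 23)
  cohort <- generate_cohort(cfg)
  events <- generate_hcru_events(cohort, cfg)
  expect_true(all(events$patient_id %in% cohort$patient_id))
  expect_true(all(events$window %in% hcru_windows))
  expect_true(all(events$category %in% hcru_categories))
  expect_true(all(events$count >= 1))
  arm <- cohort$arm[match(events$patient_id, cohort$patient_id)]
  gp_soc <- sum(events$count[events$category == "gp" & arm == "soc"])
  expect_lt(abs(gp_soc - 768), 3 * sqrt(768))
  # biopsy events exist exactly for referred patients
  biopsied <- cohort$patient_id[cohort$biopsied]
  expect_setequal(unique(events$patient_id[events$category == "biopsy"]),
                  biopsied)
})

test_that("biopsy fixture reproduces the published subgroup structure", {
  fx <- make_biopsy_fixture()
  expect_equal(nrow(fx), 21)
  expect_equal(sum(fx$excluded), 3)
  analyzable <- fx[!fx$excluded, ]
  expect_equal(nrow(analyzable), 18)

  no_fib <- !mash_with_fibrosis(analyzable$mas, analyzable$fibrosis)
  expect_equal(sum(no_fib), 10)
  expect_equal(sum(no_fib & analyzable$ct1 <= 875), 9)
  expect_equal(sum(!no_fib & analyzable$ct1 <= 875), 3)
  expect_equal(sum(!no_fib & analyzable$ct1 > 875), 5)
  # the published low-risk case appears verbatim
  expect_true(any(analyzable$mas == 2 & analyzable$fibrosis == 0 &
                    analyzable$ct1 == 795 & analyzable$pdff == 5.2))
  # all other analyzable records are high risk
  risk <- classify_risk(analyzable$ct1, analyzable$pdff)
  expect_equal(sum(risk == "low"), 1)
  expect_equal(sum(risk == "high"), 17)
})

test_that("the fixture's condition-negative split is the unique one matching
           the published operating characteristics", {
  # brute force over every split of the 8 condition-negative records
  matches <- integer(0)
  for (s in 0:8) {
    m <- diagnostic_metrics(
      contingency_table(tp = 9, fp = s, fn = 1, tn = 8 - s)
    )
    ok <- round_half_up(m$sensitivity, 2) == 0.90 &&
      round_half_up(m$specificity, 2) == 0.63 &&
      round_half_up(m$ppv, 2) == 0.75 &&
      round_half_up(m$npv, 2) == 0.83
    if (ok) matches <- c(matches, s)
  }
  expect_equal(matches, 3L)
})
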