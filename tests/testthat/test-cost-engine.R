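test_that("inflation is index-ratio arithmetic", {
  expect_equal(inflate_nominal(100, 100, 110), 110)
  expect_equal(inflate_nominal(50, 125, 100), 40)
  for (x in c(0, 4.51, 301, 1e6)) {
    expect_equal(inflate_nominal(x, 103.7, 103.7), x)
  }
  expect_error(inflate_nominal(100, 0, 110), "positive")
  expect_error(inflate_nominal(100, 100, -1), "positive")
})

test_that("currency conversion multiplies GBP and passes EUR through", {
  expect_equal(convert_currency(0, "GBP", 1.5), 0)
  expect_equal(convert_currency(258, "GBP", 301 / 258), 301)
  expect_equal(convert_currency(100, "GBP", 1), 100)
  expect_equal(convert_currency(42.5, "EUR"), 42.5)
  expect_error(convert_currency(10, "GBP"), "rate")
  expect_error(convert_currency(10, "GBP", -2), "rate")
})

test_that("inflation and conversion commute for constant rates", {
  for (x in c(3.7, 258, 1000)) {
    a <- convert_currency(inflate_nominal(x, 97, 104), "GBP", 1.167)
    b <- inflate_nominal(convert_currency(x, "GBP", 1.167), 97, 104)
    expect_equal(a, b)
  }
})

test_that("event costing multiplies frequency by the real euro unit cost", {
  prices <- default_unit_costs()
  cohort <- simple_cohort("p1", site = "Coimbra")
  lines <- cost_events(simple_events("p1", "gp", 1), cohort, prices)
  expect_equal(lines$total, 4.51)

  expect_equal(nrow(cost_events(simple_events(character(0), character(0),
                                              integer(0)),
                                cohort, prices)), 0)

  tab <- flat_cost_table(unit = 59.45)
  lines2 <- cost_events(simple_events("p1", "gp", 209),
                        simple_cohort("p1", site = "Ulm"), tab)
  expect_equal(lines2$total, 12425.05)

  # window rows are pooled into one line per patient and category
  ev <- rbind(simple_events("p1", "gp", 2, window = 2L),
              simple_events("p1", "gp", 3, window = 12L))
  pooled <- cost_events(ev, simple_cohort("p1", site = "Ulm"), tab)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$events, 5)
})

test_that("an unpriced country-category pair errors naming both", {
  tab <- flat_cost_table(unit = 10)
  tab$countries$Ulm$costs$biopsy <- NULL
  err <- expect_error(
    cost_events(simple_events("p1", "biopsy", 1),
                simple_cohort("p1", site = "Ulm"), tab)
  )
  expect_match(conditionMessage(err), "Ulm")
  expect_match(conditionMessage(err), "biopsy")
})

test_that("summaries satisfy additivity and currency homogeneity", {
  cfg <- tiny_config(n = 6, seed = 41)
  cohort <- generate_cohort(cfg)
  events <- flag_events(generate_hcru_events(cohort, cfg))
  prices <- default_unit_costs()
  lines <- cost_events(events, cohort, prices)

  by_arm <- summarize_costs(lines, cohort, "arm")
  by_arm_site <- summarize_costs(lines, cohort, c("arm", "site"))
  for (arm in trial_arms) {
    expect_equal(
      sum(by_arm_site$grand_total[by_arm_site$arm == arm]),
      by_arm$grand_total[by_arm$arm == arm]
    )
  }
  # grand total is the sum of its component groups
  expect_equal(by_arm$practitioner_visits + by_arm$patient_assessments +
                 by_arm$mri + by_arm$mpmri,
               by_arm$grand_total)
  # liver-related subtotal never exceeds the all-cause total
  expect_true(all(by_arm$total_liver_related <= by_arm$grand_total + 1e-9))

  # scaling every unit cost by k scales every summary by k
  scaled <- prices
  for (ctry in names(scaled$countries)) {
    scaled$countries[[ctry]]$costs <-
      lapply(scaled$countries[[ctry]]$costs, function(v) v * 3)
  }
  by_arm_scaled <- summarize_costs(cost_events(events, cohort, scaled),
                                   cohort, "arm")
  expect_equal(by_arm_scaled$grand_total, 3 * by_arm$grand_total)
})

test_that("per-patient means use all randomized patients as denominator", {
  cohort <- simple_cohort(c("p1", "p2"), site = "Ulm")
  lines <- cost_events(simple_events("p1", "gp", 1), cohort,
                       flat_cost_table(unit = 10))
  s <- summarize_costs(lines, cohort, "arm")
  expect_equal(s$grand_total, 10)
  expect_equal(s$n_patients, 2)
  expect_equal(s$per_patient_mean, 5)

  # single patient, single line of 10
  solo <- simple_cohort("p1", site = "Ulm")
  s1 <- summarize_costs(cost_events(simple_events("p1", "gp", 1), solo,
                                    flat_cost_table(unit = 10)),
                        solo, "arm")
  expect_equal(s1$per_patient_mean, 10)
})

test_that("a group with no cost lines gets zero totals, not an error", {
  cohort <- rbind(simple_cohort("p1", arm = "imaging"),
                  simple_cohort("p2", arm = "soc"))
  lines <- cost_events(simple_events("p1", "gp", 1), cohort,
                       flat_cost_table(unit = 10))
  s <- summarize_costs(lines, cohort, "arm")
  soc_row <- s[s$arm == "soc", ]
  expect_equal(soc_row$grand_total, 0)
  expect_true(soc_row$mean_defined)  # patients exist, mean is 0
  expect_equal(soc_row$per_patient_mean, 0)
})

test_that("the packaged unit-cost table loads and validates", {
  prices <- default_unit_costs()
  expect_s3_class(prices, "unit_cost_table")
  expect_setequal(names(prices$countries), trial_sites)
  expect_equal(real_unit_cost(prices, "Ulm", "mpmri"), 301)
  # UK tariffs are GBP and convert on pricing
  expect_equal(real_unit_cost(prices, "UK", "mpmri"), 258 * 1.167)
  expect_error(real_unit_cost(prices, "Oslo", "gp"), "Oslo")
})
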