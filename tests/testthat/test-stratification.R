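test_that("risk classification follows the dual-threshold rule", {
  expect_equal(classify_risk(795, 5.2), "low")
  expect_equal(classify_risk(800, 0), "high")     # inclusive boundary
  expect_equal(classify_risk(0.1, 10), "high")
  expect_equal(classify_risk(NA, 9.9), "unclassified")
  expect_equal(classify_risk(NA, 10), "high")     # decisive PDFF alone
  expect_equal(classify_risk(799, NA), "unclassified")
  expect_equal(classify_risk(900, NA), "high")
  expect_equal(classify_risk(NA, NA), "unclassified")
})

test_that("risk classes partition any cohort and respond monotonically to
           thresholds", {
  cohort <- generate_cohort(cohort_config(seed = 13))
  img <- cohort[cohort$arm == "imaging", ]
  risk <- classify_risk(img$ct1, img$pdff)
  expect_equal(sum(risk == "high") + sum(risk == "low") +
                 sum(risk == "unclassified"), nrow(img))

  for (th2 in list(risk_thresholds(ct1_high = 750),
                   risk_thresholds(pdff_high = 5))) {
    risk2 <- classify_risk(img$ct1, img$pdff, th2)
    expect_gte(sum(risk2 == "high"), sum(risk == "high"))
  }
})

test_that("MASH-with-fibrosis criteria are conjunctive with inclusive
           boundaries", {
  expect_false(mash_with_fibrosis(2, 0))
  expect_true(mash_with_fibrosis(4, 2))
  expect_false(mash_with_fibrosis(5, 1))
  expect_false(mash_with_fibrosis(3, 4))
  expect_error(mash_with_fibrosis(NA, 2), "missing")
})

test_that("the avoidable-biopsy rule needs both clauses", {
  expect_true(avoidable_biopsy(2, 0, 795))
  expect_false(avoidable_biopsy(5, 3, 700))   # condition-positive, never
  expect_false(avoidable_biopsy(2, 0, 900))   # cT1 too high
  expect_true(avoidable_biopsy(2, 0, 875))    # inclusive by default
  expect_false(avoidable_biopsy(2, 0, 875, strict = TRUE))
  expect_error(avoidable_biopsy(2, 0, NA), "ct1")

  fx <- make_biopsy_fixture()
  analyzable <- fx[!fx$excluded, ]
  expect_equal(sum(avoidable_biopsy(analyzable$mas, analyzable$fibrosis,
                                    analyzable$ct1)), 9)
})

test_that("contingency construction counts every record exactly once", {
  fx <- make_biopsy_fixture()
  analyzable <- fx[!fx$excluded, ]
  tab <- build_contingency(
    analyzable,
    flag_rule = function(d) d$ct1 <= 875,
    condition_rule = function(d) !mash_with_fibrosis(d$mas, d$fibrosis)
  )
  expect_equal(tab$tp, 9)
  expect_equal(tab$fp, 3)
  expect_equal(tab$fn, 1)
  expect_equal(tab$tn, 5)
  expect_equal(attr(tab, "n"), 18)

  # swapping flag polarity swaps tp<->fn and fp<->tn
  swapped <- build_contingency(
    analyzable,
    flag_rule = function(d) d$ct1 > 875,
    condition_rule = function(d) !mash_with_fibrosis(d$mas, d$fibrosis)
  )
  expect_equal(swapped$tp, tab$fn)
  expect_equal(swapped$fn, tab$tp)
  expect_equal(swapped$fp, tab$tn)
  expect_equal(swapped$tn, tab$fp)

  all_pos <- build_contingency(
    analyzable,
    flag_rule = function(d) rep(TRUE, nrow(d)),
    condition_rule = function(d) rep(TRUE, nrow(d))
  )
  expect_equal(c(all_pos$fp, all_pos$fn, all_pos$tn), c(0, 0, 0))

  expect_error(build_contingency(analyzable[0, ],
                                 function(d) TRUE, function(d) TRUE),
               "nonempty")
})

test_that("diagnostic metrics follow their defining ratios", {
  m <- diagnostic_metrics(contingency_table(9, 3, 1, 5))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.625)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 5 / 6)

  perfect <- diagnostic_metrics(contingency_table(1, 0, 0, 1))
  expect_true(all(unlist(perfect) == 1))

  undef <- diagnostic_metrics(contingency_table(0, 3, 0, 5))
  expect_true(is.na(undef$sensitivity))  # no condition-positives
  expect_true(is.na(undef$npv) || undef$npv == 5 / 5)
})

test_that("PPV obeys the Bayes identity on random tables", {
  set.seed(99)
  for (i in 1:50) {
    counts <- rmultinom(1, sample(4:200, 1), prob = runif(4, 0.05, 1))
    t <- contingency_table(counts[1], counts[2], counts[3], counts[4])
    m <- diagnostic_metrics(t)
    prev <- (t$tp + t$fn) / attr(t, "n")
    if (anyNA(unlist(m))) next
    expect_equal(
      m$ppv,
      m$sensitivity * prev /
        (m$sensitivity * prev + (1 - m$specificity) * (1 - prev))
    )
  }
})

test_that("contingency counting agrees with exhaustive recount on small
           cohorts", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(1:12, 1)
    records <- data.frame(
      ct1 = sample(700:1000, n, replace = TRUE),
      mas = sample(0:8, n, replace = TRUE),
      fibrosis = sample(0:4, n, replace = TRUE)
    )
    flag <- function(d) d$ct1 <= 875
    cond <- function(d) !mash_with_fibrosis(d$mas, d$fibrosis)
    tab <- build_contingency(records, flag, cond)
    # brute-force recount by direct filtering, record by record
    tp <- fp <- fn <- tn <- 0L
    for (j in seq_len(n)) {
      f <- records$ct1[j] <= 875
      c_ <- !(records$mas[j] >= 4 && records$fibrosis[j] >= 2)
      if (f && c_) tp <- tp + 1L
      if (f && !c_) fp <- fp + 1L
      if (!f && c_) fn <- fn + 1L
      if (!f && !c_) tn <- tn + 1L
    }
    expect_equal(c(tab$tp, tab$fp, tab$fn, tab$tn), c(tp, fp, fn, tn))
    expect_equal(attr(tab, "n"), n)
  }
})
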