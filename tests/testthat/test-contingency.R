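test_that("RR, OR, PR, POR reproduce their closed forms on the 132-patient table", {
  t2 <- breast_fixture()

  rr <- relative_risk(t2)
  expect_equal(rr$estimate, (26 / 34) / (38 / 98), tolerance = 1e-12)
  expect_equal(rr$log_se, sqrt(1 / 26 - 1 / 34 + 1 / 38 - 1 / 98),
               tolerance = 1e-12)
  expect_equal(round(rr$estimate, 2), 1.97)
  expect_equal(round(c(rr$ci_lower, rr$ci_upper), 2), c(1.45, 2.69))

  or <- odds_ratio(t2)
  expect_equal(or$estimate, (26 * 60) / (8 * 38), tolerance = 1e-12)
  expect_equal(or$log_se, sqrt(1 / 26 + 1 / 8 + 1 / 38 + 1 / 60),
               tolerance = 1e-12)
  expect_equal(round(or$log_se, 4), 0.4544)
  expect_equal(round(or$estimate, 2), 5.13)
  expect_equal(round(c(or$ci_lower, or$ci_upper), 2), c(2.11, 12.50))

  # PR/POR: same arithmetic, truthful labels
  pr <- prevalence_ratio(t2)
  expect_equal(pr$estimate, rr$estimate)
  expect_identical(pr$measure, "PR")
  expect_equal(prevalence_odds_ratio(t2)$estimate, or$estimate)
  expect_equal(prevalence_ratio(contingency_2x2(1, 99, 2, 98))$estimate, 0.5)
  expect_equal(prevalence_ratio(contingency_2x2(5, 95, 5, 95))$estimate, 1)

  # symmetric table: both measures null
  expect_equal(relative_risk(contingency_2x2(10, 10, 10, 10))$estimate, 1)
  expect_equal(odds_ratio(contingency_2x2(10, 10, 10, 10))$estimate, 1)
})

test_that("confidence level and interval geometry behave", {
  t2 <- breast_fixture()
  rr95 <- relative_risk(t2, 0.95)
  rr99 <- relative_risk(t2, 0.99)
  expect_lt(rr95$ci_lower, rr95$estimate)
  expect_gt(rr95$ci_upper, rr95$estimate)
  expect_lt(rr99$ci_lower, rr95$ci_lower)
  expect_gt(rr99$ci_upper, rr95$ci_upper)
  # bounds are exp(log est -/+ z se) with the exact normal quantile
  z <- qnorm(0.975)
  expect_equal(rr95$ci_lower, exp(log(rr95$estimate) - z * rr95$log_se))
  expect_equal(rr95$ci_upper, exp(log(rr95$estimate) + z * rr95$log_se))
})

test_that("zero cells error naming the cell unless continuity correction is requested", {
  expect_error(relative_risk(contingency_2x2(0, 10, 5, 5)), "cell 'a'")
  expect_error(relative_risk(contingency_2x2(5, 10, 0, 5)), "cell 'c'")
  expect_error(odds_ratio(contingency_2x2(5, 0, 5, 5)), "cell 'b'")
  corrected <- relative_risk(contingency_2x2(0, 10, 5, 5), correction = TRUE)
  expect_true(corrected$corrected)
  expect_equal(corrected$estimate, (0.5 / 11) / (5.5 / 11), tolerance = 1e-12)
  # no correction applied when none is needed
  expect_false(relative_risk(breast_fixture(), correction = TRUE)$corrected)
  # malformed tables rejected at construction
  expect_error(contingency_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(contingency_2x2(0, 0, 3, 4), "exposed margin")
})

test_that("OR = inflation factor x RR exactly, and OR is reciprocal where RR is not", {
  t2 <- breast_fixture()
  expect_equal(or_rr_inflation_factor(t2), (60 / 98) / (8 / 34),
               tolerance = 1e-12)
  expect_equal(round(or_rr_inflation_factor(t2), 3), 2.602)

  set.seed(42)
  for (i in 1:100) {
    tab <- random_table()
    expect_equal(or_rr_inflation_factor(tab) * relative_risk(tab)$estimate,
                 odds_ratio(tab)$estimate, tolerance = 1e-12)
    # OR reciprocity under outcome relabelling, to machine precision
    expect_equal(odds_ratio(swap_outcome(tab))$estimate *
                   odds_ratio(tab)$estimate, 1, tolerance = 1e-12)
  }
  expect_error(or_rr_inflation_factor(contingency_2x2(5, 0, 3, 7)),
               "division by zero")

  # RR non-reciprocity witness on the fixture
  rr <- relative_risk(t2)$estimate
  rr_swap <- relative_risk(swap_outcome(t2))$estimate
  expect_equal(rr_swap, (8 / 34) / (60 / 98), tolerance = 1e-12)
  expect_equal(round(rr_swap, 4), 0.3843)
  expect_gt(abs(rr * rr_swap - 1), 0.1)
  # swap is an involution and null tables stay null
  expect_equal(swap_outcome(swap_outcome(t2)), t2)
  t_null <- contingency_2x2(10, 10, 10, 10)
  expect_equal(relative_risk(swap_outcome(t_null))$estimate, 1)
})

test_that("OR approximates RR only for rare outcomes", {
  # both arms at risk <= 1%: relative gap below 1.5%
  rare <- list(contingency_2x2(2, 398, 1, 399),
               contingency_2x2(5, 995, 4, 996),
               contingency_2x2(1, 199, 2, 398))
  for (tab in rare) {
    or <- odds_ratio(tab)$estimate
    rr <- relative_risk(tab)$estimate
    expect_lt(abs(or - rr) / rr, 0.015)
  }
})

test_that("rr_from_or is exact for crude tables and respects its limits", {
  t2 <- breast_fixture()
  expect_equal(rr_from_or(odds_ratio(t2)$estimate, 38 / 98),
               relative_risk(t2)$estimate, tolerance = 1e-12)
  expect_equal(round(rr_from_or(5.1316, 38 / 98), 4), 1.9721)
  set.seed(11)
  for (i in 1:50) {
    tab <- random_table()
    expect_equal(rr_from_or(odds_ratio(tab)$estimate,
                            tab$c / (tab$c + tab$d)),
                 relative_risk(tab)$estimate, tolerance = 1e-12)
  }
  expect_equal(rr_from_or(1, 0.3), 1)           # null maps to null
  expect_equal(rr_from_or(4, 1e-9), 4, tolerance = 1e-6)  # rare-outcome limit
  expect_error(rr_from_or(2, 0), "p0")
  expect_error(rr_from_or(2, 1), "p0")
  expect_error(rr_from_or(-1, 0.5), "positive")
})

test_that("Mantel-Haenszel pooled RR collapses to the crude RR for one stratum and matches hand computation", {
  t2 <- breast_fixture()
  mh1 <- mantel_haenszel_rr(t2)
  crude <- relative_risk(t2)
  expect_equal(mh1$estimate, crude$estimate, tolerance = 1e-12)
  expect_equal(mh1$log_se, crude$log_se, tolerance = 1e-12)  # GR variance, K = 1
  expect_identical(mh1$measure, "MH-RR")

  # homogeneity: duplicated strata leave the point estimate unchanged
  mh2 <- mantel_haenszel_rr(stratified_2x2(t2, t2))
  expect_equal(mh2$estimate, crude$estimate, tolerance = 1e-12)
  expect_lt(mh2$log_se, crude$log_se)  # twice the information

  # hand-evaluated two-stratum pooled estimate:
  # stratum 1 (10,10,5,15): a(c+d)/n = 5,    c(a+b)/n = 2.5
  # stratum 2 (8,2,12,8):   a(c+d)/n = 16/3, c(a+b)/n = 4
  mh <- mantel_haenszel_rr(stratified_2x2(contingency_2x2(10, 10, 5, 15),
                                          contingency_2x2(8, 2, 12, 8)))
  expect_equal(mh$estimate, (5 + 16 / 3) / (2.5 + 4), tolerance = 1e-12)

  expect_error(
    mantel_haenszel_rr(stratified_2x2(contingency_2x2(0, 10, 0, 10))),
    "no information")
})
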