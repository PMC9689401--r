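fixture_design <- function() {
  cohort <- breast_fixture_cohort()
  list(x = cbind("(Intercept)" = 1, mixed = cohort$mixed),
       y = cohort$death)
}

test_that("saturated one-predictor fits reproduce the crude measures exactly", {
  d <- fixture_design()

  logi <- irls_fit(d$x, d$y, link = "logit", family = "bernoulli")
  expect_true(logi$converged)
  # saturated logistic: slope is the log cross-product ratio
  expect_equal(logi$coefficients[["mixed"]], log((26 * 60) / (8 * 38)),
               tolerance = 1e-10)
  expect_equal(logi$coefficients[["(Intercept)"]], log(38 / 60),
               tolerance = 1e-10)
  expect_equal(round(logi$coefficients[["mixed"]], 2), 1.64)
  expect_equal(round(exp(logi$coefficients[["mixed"]]), 2), 5.13)

  pois <- irls_fit(d$x, d$y, link = "log", family = "poisson")
  expect_true(pois$converged)
  expect_equal(pois$coefficients[["mixed"]], log((26 / 34) / (38 / 98)),
               tolerance = 1e-10)
  expect_equal(pois$coefficients[["(Intercept)"]], log(38 / 98),
               tolerance = 1e-10)
  expect_equal(round(pois$coefficients[["mixed"]], 2), 0.68)
  expect_equal(round(exp(pois$coefficients[["mixed"]]), 2), 1.97)

  # intercept-only log-Poisson: exp(B0) is the outcome mean
  null_fit <- irls_fit(matrix(1, 132, 1), d$y, "log", "poisson")
  expect_equal(exp(null_fit$coefficients[[1]]), mean(d$y), tolerance = 1e-10)
})

test_that("sandwich covariance matches the closed-form robust SE and collapses to the model SE when saturated", {
  d <- fixture_design()
  pois <- irls_fit(d$x, d$y, "log", "poisson")
  expect_equal(sqrt(pois$robust_cov["mixed", "mixed"]),
               sqrt(1 / 26 - 1 / 34 + 1 / 38 - 1 / 98), tolerance = 1e-10)

  # saturated Bernoulli fit: squared residuals average to mu(1-mu) within
  # each covariate pattern, so HC0 equals the model-based covariance
  logi <- irls_fit(d$x, d$y, "logit", "bernoulli")
  expect_equal(logi$robust_cov, logi$model_cov, tolerance = 1e-10)
  expect_equal(sqrt(logi$robust_cov["mixed", "mixed"]),
               sqrt(1 / 26 + 1 / 8 + 1 / 38 + 1 / 60), tolerance = 1e-10)

  # HC1 applies the n/(n-p) factor
  hc1 <- sandwich_covariance(pois, type = "HC1")
  expect_equal(hc1, pois$robust_cov * 132 / 130, tolerance = 1e-12)

  # zero residuals: every duplicated row carries the event, so the Poisson
  # working model fits mu = 1 exactly at finite coefficients and the meat
  # matrix vanishes
  x0 <- cbind("(Intercept)" = 1, g = rep(c(0, 1), each = 6))
  y0 <- rep(1L, 12)
  f0 <- irls_fit(x0, y0, "log", "poisson")
  expect_true(f0$converged)
  expect_equal(max(abs(f0$fitted - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(sandwich_covariance(f0))), 0, tolerance = 1e-12)
})

test_that("frequency-weighted grouped fits equal expanded fits exactly", {
  xg <- cbind("(Intercept)" = 1, e = c(1, 1, 0, 0))
  yg <- c(1, 0, 1, 0)
  wg <- c(26, 8, 38, 60)
  d <- fixture_design()
  for (mod in list(c("logit", "bernoulli"), c("log", "poisson"))) {
    grouped <- irls_fit(xg, yg, mod[1], mod[2], weights = wg)
    expanded <- irls_fit(d$x, d$y, mod[1], mod[2])
    expect_equal(unname(grouped$coefficients), unname(expanded$coefficients),
                 tolerance = 1e-10)
    expect_equal(unname(grouped$robust_cov), unname(expanded$robust_cov),
                 tolerance = 1e-10)
    expect_equal(unname(grouped$model_cov), unname(expanded$model_cov),
                 tolerance = 1e-10)
    expect_equal(grouped$n_obs, 132)
  }
})

test_that("outcome complement negates logistic coefficients but not log-link risk ratios", {
  d <- fixture_design()
  yc <- relabel_outcome(d$y)
  expect_identical(relabel_outcome(yc), as.integer(d$y))  # involution

  logi <- irls_fit(d$x, d$y, "logit", "bernoulli")
  logi_c <- irls_fit(d$x, yc, "logit", "bernoulli")
  expect_equal(logi_c$coefficients, -logi$coefficients, tolerance = 1e-8)
  tt <- term_table(logi, robust = FALSE)
  tt_c <- term_table(logi_c, robust = FALSE)
  expect_equal(tt_c$ratio * tt$ratio, 1, tolerance = 1e-8)
  expect_equal(tt_c$p_value, tt$p_value, tolerance = 1e-8)

  pois_c <- irls_fit(d$x, yc, "log", "poisson")
  rr_death <- exp(irls_fit(d$x, d$y, "log", "poisson")$coefficients[["mixed"]])
  rr_surv <- exp(pois_c$coefficients[["mixed"]])
  expect_equal(rr_surv, (8 / 34) / (60 / 98), tolerance = 1e-10)  # 0.3843
  expect_equal(round(rr_surv, 3), 0.384)
  expect_equal(round(1 / rr_death, 3), 0.507)
  expect_gt(abs(rr_surv - 1 / rr_death), 0.1)

  # property over random datasets: logistic reciprocity is structural
  set.seed(9)
  for (i in 1:10) {
    dat <- random_regression_data()
    f1 <- irls_fit(dat$x, dat$y, "logit", "bernoulli")
    f2 <- irls_fit(dat$x, 1L - dat$y, "logit", "bernoulli")
    expect_equal(f2$coefficients, -f1$coefficients, tolerance = 1e-8)
  }
})

test_that("coefficients and robust SEs agree with the reference GLM implementation", {
  skip_if_not_installed("sandwich")
  set.seed(12)
  for (i in 1:10) {
    dat <- random_regression_data()
    df <- as.data.frame(dat$x[, -1, drop = FALSE])
    df$y <- dat$y
    for (mod in list(list("logit", "bernoulli", binomial()),
                     list("log", "poisson", poisson()))) {
      mine <- irls_fit(dat$x, dat$y, mod[[1]], mod[[2]])
      ref <- glm(y ~ ., data = df, family = mod[[3]],
                 control = glm.control(epsilon = 1e-12))
      expect_true(mine$converged)
      expect_equal(unname(mine$coefficients), unname(coef(ref)),
                   tolerance = 1e-6)
      expect_equal(unname(sqrt(diag(mine$robust_cov))),
                   unname(sqrt(diag(sandwich::vcovHC(ref, type = "HC0")))),
                   tolerance = 1e-6)
    }
  }
})

test_that("log-binomial fits respect the probability boundary and report failure honestly", {
  # saturated case converges to the crude risks
  d <- fixture_design()
  lb <- irls_fit(d$x, d$y, "log", "bernoulli")
  expect_true(lb$converged)
  expect_equal(exp(lb$coefficients[["mixed"]]), (26 / 34) / (38 / 98),
               tolerance = 1e-8)
  expect_lte(lb$max_fitted_prob, 1)

  # high incidence + strong continuous covariate: boundary failure, flagged
  set.seed(4)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(2 + 2.5 * x))
  hard <- irls_fit(cbind(1, x), y, "log", "bernoulli")
  expect_false(hard$converged)
  expect_error(sandwich_covariance(hard), "non-converged")

  # modified Poisson may fit mu > 1 and must surface it
  pois <- irls_fit(cbind(1, x), y, "log", "poisson")
  expect_true(pois$converged)
  expect_gt(pois$max_fitted_prob, 1)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- fixture_design()
  x_bad <- cbind(d$x, twin = d$x[, "mixed"])
  expect_error(irls_fit(x_bad, d$y, "logit", "bernoulli"),
               "singular design.*twin")
  expect_error(irls_fit(d$x[1:2, ], d$y[1:2], "logit", "bernoulli"),
               "too few")
  expect_error(irls_fit(d$x, c(d$y[-1], 2), "logit", "bernoulli"), "binary")
})

test_that("term_table builds Wald inference on the requested scale", {
  d <- fixture_design()
  pois <- irls_fit(d$x, d$y, "log", "poisson")
  tt95 <- term_table(pois, robust = TRUE, conf_level = 0.95)
  tt99 <- term_table(pois, robust = TRUE, conf_level = 0.99)
  expect_equal(tt95$ratio, exp(tt95$coefficient))
  expect_lt(tt99$ci_lower, tt95$ci_lower)
  expect_gt(tt99$ci_upper, tt95$ci_upper)
  expect_equal(tt95$ci_lower, exp(tt95$coefficient -
                                    qnorm(0.975) * tt95$log_se))
  expect_identical(attr(tt95, "ratio_label"), "RR")
  expect_identical(attr(term_table(irls_fit(d$x, d$y, "logit", "bernoulli")),
                        "ratio_label"), "OR")
  with_int <- term_table(pois, include_intercept = TRUE)
  expect_identical(with_int$term[1], "(Intercept)")
  expect_equal(nrow(term_table(pois)), 1L)
})
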