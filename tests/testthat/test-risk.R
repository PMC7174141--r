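test_that("response selection follows the strict 75% detection rule", {
  expect_equal(choose_response(1.00), "concentration")
  expect_equal(choose_response(0.16), "detection")
  expect_equal(choose_response(0.75), "concentration")  # boundary stays
  expect_equal(choose_response(0.7499), "detection")
  expect_error(choose_response(1.2), "fraction")
})

test_that("predictor preparation centres, scales and windows precipitation", {
  met <- data.frame(date = seq(as.Date("2015-04-01"),
                               as.Date("2015-06-30"), by = "day"))
  met$precip_mm <- 0
  met$precip_mm[met$date == as.Date("2015-05-10")] <- 12
  met$precip_mm[met$date == as.Date("2015-04-20")] <- 5

  cov <- data.frame(date = as.Date(c("2015-05-12", "2015-05-12",
                                     "2015-05-12", "2015-05-12")),
                    wealth = c(55.8, 45.8, 35.8, 45.8),
                    temp = c(18, 20, 22, 21.6))
  out <- prepare_predictors(cov, met, scale = list(wealth = 10))

  # wealth 55.8 with mean 45.8 and unit 10 -> +1.0 scaled units
  expect_equal(out$wealth[1], 1.0, tolerance = 1e-12)
  # SD-standardized column has mean 0, SD 1
  expect_equal(mean(out$temp), 0, tolerance = 1e-12)
  expect_equal(sd(out$temp), 1, tolerance = 1e-12)
  # precipitation windows: 12 mm two days before; 5 mm 22 days before
  expect_equal(out$precip_7d[1], 12)
  expect_equal(out$precip_30d[1], 17)
  expect_equal(out$rain_days_7d[1], 1)
  expect_equal(out$rain_days_30d[1], 2)

  # zero-rain window
  met0 <- met; met0$precip_mm <- 0
  out0 <- prepare_predictors(cov, met0)
  expect_equal(out0$precip_7d, rep(0, 4))

  # missing meteorology history names the date
  expect_error(prepare_predictors(
    data.frame(date = as.Date("2015-04-05"), wealth = 50), met),
    "2015-04-05")
})

test_that("censored linear slope matches OLS in the uncensored case", {
  set.seed(101)
  n <- 100
  x <- rnorm(n)
  y <- 4 + 0.5 * x + rnorm(n, 0, 0.8)
  obs <- censored_obs(y)
  est <- fit_censored_linear(obs, x, config = fast_mcmc(seed = 101))
  ols <- unname(coef(lm(y ~ x))[2])
  expect_equal(est$mean, ols, tolerance = 0.05)
  expect_equal(est$scale, "log10 change")
})

test_that("censored linear recovers a known slope under 30% censoring", {
  sim <- simulate_censored_response(n = 80, beta = 1, censor_frac = 0.3,
                                    seed = 7)
  est <- fit_censored_linear(sim$obs, sim$x, config = fast_mcmc(seed = 7))
  expect_lt(abs(est$mean - 1), 0.4)
  expect_true(est$q2.5 < 1 && 1 < est$q97.5)
  expect_true(est$excludes_null)  # beta = 1 is far from zero here
  expect_error(fit_censored_linear(sim$obs, rep(1, 80)), "constant")
})

test_that("compound intercepts are honoured in grouped fits", {
  sim <- simulate_censored_response(n = 90, beta = 0.8, censor_frac = 0.25,
                                    n_groups = 18, group_sd = 0.8,
                                    seed = 15)
  est <- fit_censored_linear(sim$obs, sim$x, group = sim$group,
                             config = fast_mcmc(seed = 15))
  expect_lt(abs(est$mean - 0.8), 0.45)
})

test_that("logistic fit reports odds ratios with credible intervals", {
  sim <- simulate_detection(n = 200, or = 4, seed = 33)
  est <- fit_logistic(sim$y, sim$x, config = fast_mcmc(seed = 33))
  expect_equal(est$scale, "odds ratio")
  expect_true(est$q2.5 < 4 && 4 < est$q97.5)
  expect_true(est$excludes_null)  # OR = 4 with n = 200 excludes unity
  expect_error(fit_logistic(rep(1, 20), rnorm(20)), "single class")
})

test_that("quasi-separated binary tables yield finite flagged estimates", {
  # 18 of 33 positive in the exposed group, 1 of 16 in the unexposed
  y <- c(rep(1, 18), rep(0, 15), rep(1, 1), rep(0, 15))
  x <- c(rep(1, 33), rep(0, 16))
  est <- fit_logistic(y, x, config = fast_mcmc(seed = 3))
  expect_true(is.finite(est$mean))
  expect_gt(est$mean, 1)
  expect_true(est$warning)
})

test_that("rescaling a predictor inversely rescales the slope", {
  set.seed(55)
  n <- 150
  x <- rnorm(n)
  y <- 1 + 0.6 * x + rnorm(n, 0, 0.5)
  obs <- censored_obs(y)
  e1 <- fit_censored_linear(obs, x, config = fast_mcmc(seed = 55))
  e2 <- fit_censored_linear(obs, x / 2, config = fast_mcmc(seed = 55))
  expect_equal(e2$mean / e1$mean, 2, tolerance = 0.1)
})

test_that("summarize_effects collates, sorts and marks null exclusion", {
  e1 <- data.frame(response = "soil", predictor = "wetness",
                   scale = "log10 change", mean = 1.2, q2.5 = 0.1,
                   q97.5 = 2.2, excludes_null = TRUE, warning = FALSE,
                   rhat = 1.0)
  e2 <- data.frame(response = "soil", predictor = "wealth",
                   scale = "log10 change", mean = 0.3, q2.5 = -0.2,
                   q97.5 = 0.9, excludes_null = FALSE, warning = FALSE,
                   rhat = 1.0)
  tab <- summarize_effects(list(e1, e2),
                           family = c("sample characteristics",
                                      "demographics"))
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "n_models"), 2)
  expect_equal(tab$predictor, c("wealth", "wetness"))  # family then name
  expect_identical(tab$excludes_null, c(FALSE, TRUE))
  expect_error(summarize_effects(list()), "no estimates")

  single <- summarize_effects(list(e1))
  expect_equal(nrow(single), 1)
})
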