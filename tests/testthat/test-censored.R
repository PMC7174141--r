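test_that("with no censoring the fit reduces to the closed-form normal MLE", {
  set.seed(3)
  y <- rnorm(40, 4.2, 0.8)
  fit <- fit_censored_normal(censored_obs(y))
  expect_equal(fit$mean, mean(y), tolerance = 1e-4)
  expect_equal(fit$sd, sd(y) * sqrt(39 / 40), tolerance = 1e-3)
  expect_equal(fit$n_censored, 0)
})

test_that("censored MLE agrees with the fitdistrplus reference", {
  set.seed(8)
  y <- rnorm(200, 4.26, 0.83)
  lim <- 3.36
  cens <- y < lim
  obs <- censored_obs(value = ifelse(cens, NA, y),
                      censoring = ifelse(cens, "left", "observed"),
                      limit = ifelse(cens, lim, NA))
  fit <- fit_censored_normal(obs)

  ref_tab <- data.frame(left = ifelse(cens, NA, y),
                        right = ifelse(cens, lim, y))
  ref <- fitdistrplus::fitdistcens(ref_tab, "norm")
  expect_equal(fit$mean, unname(ref$estimate["mean"]), tolerance = 1e-4)
  expect_equal(fit$sd, unname(ref$estimate["sd"]), tolerance = 1e-4)
  expect_equal(fit$se_mean, unname(ref$sd["mean"]), tolerance = 1e-3)
  expect_equal(fit$se_sd, unname(ref$sd["sd"]), tolerance = 1e-3)
})

test_that("symmetric censoring of symmetric data keeps the mean centred", {
  set.seed(5)
  mu <- 2
  y <- mu + c(rnorm(300), -rnorm(300))  # exactly symmetric sample
  cens_l <- y < mu - 1
  cens_r <- y > mu + 1
  obs <- censored_obs(
    value = ifelse(cens_l | cens_r, NA, y),
    censoring = ifelse(cens_l, "left", ifelse(cens_r, "right",
                                              "observed")),
    limit = ifelse(cens_l, mu - 1, ifelse(cens_r, mu + 1, NA)))
  fit <- fit_censored_normal(obs)
  expect_equal(fit$mean, mu, tolerance = 1e-2)
})

test_that("the returned optimum beats random perturbations", {
  set.seed(13)
  y <- rnorm(80, 4, 1)
  cens <- y < 3.4
  obs <- censored_obs(ifelse(cens, NA, y),
                      ifelse(cens, "left", "observed"),
                      ifelse(cens, 3.4, NA))
  fit <- fit_censored_normal(obs)
  nll_hat <- mstquant:::censnorm_nll(c(fit$mean, log(fit$sd)), obs)
  for (k in 1:50) {
    pert <- c(fit$mean, log(fit$sd)) + rnorm(2, 0, 0.3)
    expect_gte(mstquant:::censnorm_nll(pert, obs), nll_hat - 1e-8)
  }
})

test_that("degenerate inputs raise identifiability errors", {
  all_cens <- censored_obs(value = rep(NA_real_, 5),
                           censoring = rep("left", 5),
                           limit = rep(3, 5))
  expect_error(fit_censored_normal(all_cens), "identifiable")
  expect_error(fit_censored_normal(censored_obs(c(1, 2))), "3 observations")
  expect_error(censored_obs(NA_real_, "left", NA_real_), "limit")
  expect_error(censored_obs(NA_real_, "observed"), "value")
})

test_that("truncated-normal expectations match closed forms and quadrature", {
  # standard normal, left-censored at 0: E[X | X < 0] = -sqrt(2/pi)
  expect_equal(impute_censored(0, "left", 0, 1), -sqrt(2 / pi),
               tolerance = 1e-9)
  expect_equal(impute_censored(0, "right", 0, 1), sqrt(2 / pi),
               tolerance = 1e-9)

  # mu = 5, sigma = 2, left at 1 (alpha = -2), against quadrature
  quad <- integrate(function(x) x * dnorm(x, 5, 2), -Inf, 1)$value /
    pnorm(1, 5, 2)
  got <- impute_censored(1, "left", 5, 2)
  expect_equal(got, quad, tolerance = 1e-6)
  expect_equal(got, 5 - 2 * dnorm(-2) / pnorm(-2), tolerance = 1e-12)

  # extreme limits stay finite (asymptotic-safe Mills ratio)
  far <- impute_censored(-40, "left", 0, 1)
  expect_true(is.finite(far))
  expect_lt(far, -40)
  expect_gt(impute_censored(40, "right", 0, 1), 40)
})

test_that("imputed values always fall on the censored side of the limit", {
  set.seed(23)
  for (k in 1:50) {
    mu <- rnorm(1, 0, 3)
    sigma <- runif(1, 0.2, 3)
    lim <- rnorm(1, mu, 2 * sigma)
    expect_lt(impute_censored(lim, "left", mu, sigma), lim)
    expect_gt(impute_censored(lim, "right", mu, sigma), lim)
  }
  expect_error(impute_censored(0, "left", 0, 0), "sd")
})

test_that("censored_summary groups, fits and imputes per stratum", {
  set.seed(29)
  y1 <- rnorm(60, 4, 1); y2 <- rnorm(60, 2, 0.5)
  lim <- 3
  mk <- function(y, g) {
    cens <- y < lim
    data.frame(value = ifelse(cens, NA, y),
               censoring = ifelse(cens, "left", "observed"),
               limit = ifelse(cens, lim, NA), group = g)
  }
  dat <- rbind(mk(y1, "soil"), mk(y2, "water"))
  out <- censored_summary(dat[, 1:3], dat$group)
  expect_equal(nrow(out$summary), 2)
  expect_equal(out$summary$n, c(60, 60))
  soil_mu <- out$summary$mean[out$summary$group == "soil"]
  water_mu <- out$summary$mean[out$summary$group == "water"]
  expect_gt(soil_mu, water_mu)
  # imputations preserved order and censored side
  cen_idx <- which(dat$censoring == "left")
  expect_true(all(out$imputed$value[cen_idx] < lim))
  obs_idx <- which(dat$censoring == "observed")
  expect_equal(out$imputed$value[obs_idx], dat$value[obs_idx])
})
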