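test_that("near-noiseless standards recover slope, intercept and efficiency", {
  truth <- sim_truth(beta0 = 38, beta1 = -3.3219, sigma = 0.02,
                     tau_run = c(0, 0), tau_batch = c(0, 0))
  std <- simulate_standards(truth, n_runs = 2, n_batches = 2,
                            levels = 5:1, reps = 3, seed = 12)
  post <- suppressWarnings(
    fit_calibration(std, fast_mcmc(seed = 12)))
  b1 <- mean(post$draws[, "b1"])
  expect_equal(mean(post$draws[, "b0"]), 38, tolerance = 0.01)
  expect_equal(b1, -3.3219, tolerance = 0.01)
  # amplification efficiency 10^(-1/slope) - 1 at the true slope is 100%
  expect_equal(10^(-1 / b1) - 1, 1, tolerance = 0.02)
})

test_that("single run and batch posterior matches the OLS fit", {
  truth <- sim_truth(tau_run = c(0, 0), tau_batch = c(0, 0), sigma = 0.3)
  std <- simulate_standards(truth, n_runs = 1, n_batches = 1,
                            levels = 5:1, reps = 6, seed = 2)
  post <- suppressWarnings(fit_calibration(std, fast_mcmc(seed = 2)))
  ols <- coef(lm(cq ~ log10_copies, data = std))
  # with one run and one batch the population intercept is confounded with
  # the group offsets; the identified quantity is the effective curve
  eff <- curve_draws(post, run = "run01", batch = "batch01")
  mcse_b0 <- sd(eff$intercept) / sqrt(200)  # conservative ESS
  mcse_b1 <- sd(eff$slope) / sqrt(200)
  expect_lt(abs(mean(eff$intercept) - ols[1]), 2 * mcse_b0 + 0.05)
  expect_lt(abs(mean(eff$slope) - ols[2]), 2 * mcse_b1 + 0.02)
})

test_that("fit_calibration validates its design", {
  std <- simulate_standards(seed = 1)
  flat <- std[std$log10_copies == 3, ]
  expect_error(fit_calibration(flat, fast_mcmc()), "rank deficient")
  expect_error(
    fit_calibration(std[, setdiff(names(std), "cq")], fast_mcmc()),
    "missing columns")
})

test_that("invert_cq is the inverse of the calibration prediction", {
  std <- simulate_standards(seed = 41)
  post <- suppressWarnings(
    fit_calibration(std, fast_mcmc(seed = 41, warmup = 300,
                                   sampling = 300)))
  for (x in c(1, 2.5, 5)) {
    ab <- curve_draws(post, run = "run02", batch = "batch01")
    cq_pred <- ab$intercept + ab$slope * x
    ok <- ab$slope < 0
    back <- (cq_pred[ok] - ab$intercept[ok]) / ab$slope[ok]
    expect_equal(back, rep(x, sum(ok)), tolerance = 1e-10)
  }
})

test_that("invert_cq arithmetic on a degenerate posterior", {
  post <- point_posterior(b0 = 38, b1 = -3.5)
  expect_equal(unique(invert_cq(31, post)$draws), 2.0)
  # Cq at the intercept -> zero log10 copies
  expect_equal(unique(invert_cq(38, post)$draws), 0)
  # nonnegative-slope draws are excluded with a count
  mixed <- point_posterior(b0 = 38, b1 = c(rep(-3.5, 40), rep(0.1, 10)),
                           n_draws = 50)
  out <- invert_cq(31, mixed)
  expect_equal(out$n_dropped, 10)
  expect_length(out$draws, 40)
  allbad <- point_posterior(b1 = 2)
  expect_error(invert_cq(31, allbad), "negative slope")
})

test_that("sample_concentration normalizes by effort and pools replicates", {
  post <- point_posterior(b0 = 38, b1 = -3.5)
  # x-hat fixed at 2.0; reaction = 1/20 of a 100 mL filtration
  est <- sample_concentration(31, effort = 0.05, post)
  expect_equal(est$mean, 2 + log10(20), tolerance = 1e-12)  # 3.301
  expect_equal(est$sd, 0)
  expect_true(est$detected)

  # five-fold diluted template: effort / 5, concentration + log10(5)
  est5 <- sample_concentration(31, effort = 0.01, post)
  expect_equal(est5$mean - est$mean, log10(5), tolerance = 1e-12)

  # two replicates with identical Cq give the same summary as one
  est2 <- sample_concentration(c(31, 31), effort = 0.05, post)
  expect_equal(est2$mean, est$mean)
  expect_equal(est2$sd, est$sd)
  expect_equal(est2$n_amplifying, 2L)
})

test_that("pooled posterior SD does not increase with identical replicates", {
  set.seed(77)
  post <- point_posterior(b0 = rnorm(400, 38, 0.5),
                          b1 = -3.4 + rnorm(400, 0, 0.08), n_draws = 400)
  one <- sample_concentration(30, effort = 0.05, post)
  two <- sample_concentration(c(30, 30), effort = 0.05, post)
  expect_lte(two$sd, one$sd + 1e-12)
})

test_that("all-nondetect samples come back left-censored at the LLoD", {
  post <- point_posterior(b0 = 38, b1 = -3.5)
  est <- sample_concentration(c(NA, NA), effort = 0.05, post, cutoff = 39)
  expect_false(est$detected)
  expect_equal(est$censoring, "left")
  expect_equal(est$limit, (39 - 38) / (-3.5) + log10(20),
               tolerance = 1e-12)
  expect_error(sample_concentration(c(NA, NA), 0.05, post), "cutoff")
})

test_that("recovered concentrations track the simulated truth", {
  # noiseless chain: degenerate posterior + exact Cq reproduces truth
  post <- point_posterior(b0 = 38, b1 = -3.4)
  true_conc <- 4.2
  effort <- 0.05
  cq <- 38 - 3.4 * (true_conc + log10(effort))
  est <- sample_concentration(cq, effort, post)
  expect_equal(est$mean, true_conc, tolerance = 1e-10)
})

test_that("inhibition flagging uses a strict 3-Cq margin over controls", {
  expect_true(flag_inhibition(28.5, c(25.0, 25.0))$inhibited)
  expect_false(flag_inhibition(28.0, c(25.0, 25.0))$inhibited)
  expect_false(flag_inhibition(27.9, c(24, 26))$inhibited)
  expect_true(flag_inhibition(28.1, c(24, 26))$inhibited)
  nd <- flag_inhibition(NA, c(24, 26))
  expect_true(nd$inhibited)
  expect_equal(nd$reason, "spc_nondetect")
  expect_error(flag_inhibition(30, NA_real_), "control")
})
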