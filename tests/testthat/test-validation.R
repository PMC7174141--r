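test_that("reaction classification is strict at the cutoff boundary", {
  expect_true(classify_reaction(37.1, 39))
  expect_false(classify_reaction(39.0, 39))
  expect_false(classify_reaction(NA_real_, 39))
  expect_equal(classify_reaction(c(38.9, 39, NA, 10), 39),
               c(TRUE, FALSE, FALSE, TRUE))
  expect_error(classify_reaction(30, 0), "cutoff")
})

test_that("sample detection is the OR of reaction flags", {
  expect_true(sample_detection(c(FALSE, TRUE)))
  expect_false(sample_detection(rep(FALSE, 4)))
  expect_true(sample_detection(rep(TRUE, 4)))
  expect_error(sample_detection(logical(0)), "no reactions")
})

test_that("roc_sweep matches exhaustive per-cutoff counting", {
  # six hand-built reactions
  cq <- c(22.3, 35.0, NA, 28.1, 36.2, NA)
  is_target <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  got <- roc_sweep(cq, is_target, 10, 40)
  want <- roc_oracle(cq, is_target, 10, 40)
  expect_equal(got$sensitivity, want$sensitivity)
  expect_equal(got$specificity, want$specificity)
  expect_equal(got$J, want$J)

  # monotone in the cutoff
  expect_true(all(diff(got$sensitivity) >= 0))
  expect_true(all(diff(got$specificity) <= 0))

  expect_error(roc_sweep(cq, rep(TRUE, 6)), "non-target")
  expect_error(roc_sweep(cq, is_target, min_cq = 9), "min_cq")
})

test_that("J = sensitivity + specificity - 1 and perfect separation gives J = 1", {
  cq <- c(runif(10, 20, 29), rep(NA_real_, 10))
  is_target <- rep(c(TRUE, FALSE), each = 10)
  sweep <- roc_sweep(cq, is_target, 10, 45)
  expect_equal(sweep$J, sweep$sensitivity + sweep$specificity - 1)
  above <- sweep$cutoff > 29
  expect_true(all(sweep$J[above] == 1))
})

test_that("select_cutoff takes the highest cutoff among Youden ties", {
  sweep <- data.frame(cutoff = 36:41,
                      J = c(0.2, 0.8, 0.8, 0.8, 0.5, 0.4))
  expect_equal(select_cutoff(sweep), 39)
  sweep$J <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.9)
  expect_equal(select_cutoff(sweep), 41)
  expect_error(select_cutoff(sweep[0, ]), "empty")
})

test_that("select_cutoff agrees with argmax-by-enumeration on random panels", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(6:50, 1)
    is_target <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(is_target)) is_target[1] <- TRUE
    if (all(is_target)) is_target[1] <- FALSE
    cq <- ifelse(runif(n) < 0.75, runif(n, 12, 44), NA_real_)
    max_cq <- sample(40:45, 1)
    sweep <- roc_sweep(cq, is_target, 10, max_cq)
    oracle <- roc_oracle(cq, is_target, 10, max_cq)
    best <- max(oracle$cutoff[oracle$J == max(oracle$J)])
    expect_equal(select_cutoff(sweep), best)

    # permutation invariance
    perm <- sample(n)
    expect_equal(select_cutoff(roc_sweep(cq[perm], is_target[perm], 10,
                                         max_cq)),
                 best)
  }
})

test_that("sample-level diagnostics match direct counting", {
  # 14 target samples, 11 positive; 27 non-target, 25 negative
  set.seed(7)
  mk <- function(n, n_pos, prefix, target) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      pos <- i <= n_pos
      # two reactions per sample; positives amplify in at least one
      cq <- if (pos) c(runif(1, 20, 30), NA) else c(NA_real_, NA_real_)
      data.frame(sample_id = paste0(prefix, i), is_target = target,
                 cq = cq)
    }))
  }
  dat <- rbind(mk(14, 11, "T", TRUE), mk(27, 2, "N", FALSE))
  got <- diagnostic_summary(dat$cq, dat$sample_id, dat$is_target,
                            cutoff = 44)
  expect_equal(got$n, 41)
  expect_equal(round(got$sensitivity, 2), 0.79)
  expect_equal(round(got$specificity, 2), 0.93)
  expect_equal(round(got$accuracy, 2), 0.88)
  expect_equal(got$J, got$sensitivity + got$specificity - 1)

  # general assays: no non-target samples -> specificity undefined
  gen <- mk(14, 14, "T", TRUE)
  gsum <- diagnostic_summary(gen$cq, gen$sample_id, gen$is_target, 44)
  expect_equal(gsum$sensitivity, 1)
  expect_true(is.na(gsum$specificity))

  none <- mk(5, 0, "T", TRUE)
  expect_equal(diagnostic_summary(none$cq, none$sample_id,
                                  none$is_target, 44)$sensitivity, 0)
})

test_that("validate_assay uses blanks in the sweep but not in sample counts", {
  set.seed(30)
  pan <- simulate_validation_panel(n_target = 12, n_nontarget = 18,
                                   sensitivity = 0.9, cross_rate = 0.05,
                                   seed = 30)
  res <- validate_assay(pan$cq, pan$sample_id, pan$is_target,
                        max_cq = 45, blank_cq = rep(NA_real_, 6))
  expect_equal(res$summary$n, 30)
  expect_true(res$cutoff >= 10 && res$cutoff <= 45)
  expect_equal(res$cutoff, select_cutoff(res$sweep))
})

test_that("recovered diagnostics converge to panel truth at large n", {
  pan <- simulate_validation_panel(n_target = 400, n_nontarget = 400,
                                   sensitivity = 0.8, cross_rate = 0.1,
                                   reps = 1, cq_mean = 28, cq_sd = 2,
                                   nontarget_cq_mean = 33, seed = 55)
  got <- diagnostic_summary(pan$cq, pan$sample_id, pan$is_target,
                            cutoff = 45)
  # binomial 99.9% half-widths at n = 400
  expect_lt(abs(got$sensitivity - 0.8), 3.3 * sqrt(0.8 * 0.2 / 400))
  expect_lt(abs(got$specificity - 0.9), 3.3 * sqrt(0.9 * 0.1 / 400))
})
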