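# Shared test fixtures and reduced MCMC settings.

fast_mcmc <- function(seed = 1L, chains = 2L, warmup = 500L,
                      sampling = 500L) {
  mcmc_config(chains, warmup, sampling, seed = seed)
}

# calibration posterior with known, possibly degenerate, draws -- used for
# arithmetic checks that need exact curve parameters
point_posterior <- function(b0 = 38, b1 = -3.5, n_draws = 50L,
                            runs = "run01", batches = "batch01",
                            r0 = 0, r1 = 0, e0 = 0, e1 = 0, sigma = 0.3) {
  cols <- c("b0", "b1",
            sprintf("r0[%d]", seq_along(runs)),
            sprintf("r1[%d]", seq_along(runs)),
            sprintf("e0[%d]", seq_along(batches)),
            sprintf("e1[%d]", seq_along(batches)),
            "sigma")
  draws <- matrix(0, n_draws, length(cols), dimnames = list(NULL, cols))
  draws[, "b0"] <- b0
  draws[, "b1"] <- b1
  draws[, "sigma"] <- sigma
  for (i in seq_along(runs)) {
    draws[, sprintf("r0[%d]", i)] <- rep_len(r0, n_draws)
    draws[, sprintf("r1[%d]", i)] <- rep_len(r1, n_draws)
  }
  for (i in seq_along(batches)) {
    draws[, sprintf("e0[%d]", i)] <- rep_len(e0, n_draws)
    draws[, sprintf("e1[%d]", i)] <- rep_len(e1, n_draws)
  }
  structure(list(draws = draws, runs = runs, batches = batches,
                 rhat = NULL, ess = NULL, n_standards = NA_integer_,
                 n_dropped = 0L, convergence_warning = FALSE,
                 config = NULL),
            class = "calibration_posterior")
}

# independent brute-force ROC oracle: per-cutoff counting loops
roc_oracle <- function(cq, is_target, min_cq, max_cq) {
  res <- NULL
  for (cc in min_cq:max_cq) {
    tp <- 0; fn <- 0; tn <- 0; fp <- 0
    for (i in seq_along(cq)) {
      pos <- !is.na(cq[i]) && cq[i] < cc
      if (is_target[i]) {
        if (pos) tp <- tp + 1 else fn <- fn + 1
      } else {
        if (pos) fp <- fp + 1 else tn <- tn + 1
      }
    }
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    res <- rbind(res, data.frame(cutoff = cc, sensitivity = sens,
                                 specificity = spec, J = sens + spec - 1))
  }
  res
}
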