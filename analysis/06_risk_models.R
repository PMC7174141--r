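#!/usr/bin/env Rscript
# Stage 6: univariable Bayesian risk-factor models. For each target x
# matrix stratum, the response is the (censored) log10 concentration when
# the target was detected in >= 75% of samples, and binary detection
# otherwise; compound intercepts are included for household-level sample
# types (several samples per compound).

suppressPackageStartupMessages(library(mstquant))

mol <- read.csv("results/quantification/molecular_concentrations.csv",
                stringsAsFactors = FALSE)
env <- simulate_environment(sim_truth(), n_compounds = 20,
                            households_per_compound = 2, seed = 1L)
cov <- prepare_predictors(env$covariates, env$meteorology,
                          scale = list(wealth = 10))

household_level <- c("stored_water", "food_surface", "household_soil")
cfg <- mcmc_config(4L, 1500L, 1000L, seed = 1L)
predictors <- c("hazard", "wealth", "precip_7d", "rain_days_7d")
families <- c("hazards", "demographics", "meteorology", "meteorology")

estimates <- list()
fams <- character(0)
for (t in unique(mol$target)) {
  for (mx in unique(mol$matrix)) {
    idx <- which(mol$target == t & mol$matrix == mx)
    ci <- match(mol$sample_id[idx], cov$sample_id)
    frac <- mean(mol$detected[idx])
    kind <- choose_response(frac)
    group <- if (mx %in% household_level) cov$compound_id[ci] else NULL
    cat(sprintf("%s in %s: detected %.0f%% -> %s response%s\n", t, mx,
                100 * frac, kind,
                if (is.null(group)) "" else " (compound intercepts)"))
    for (pred in predictors) {
      x <- cov[[pred]][ci]
      if (sd(x) == 0) next
      est <- if (kind == "concentration") {
        obs <- censored_obs(
          value = ifelse(mol$censoring[idx] == "observed",
                         mol$mean[idx], NA),
          censoring = mol$censoring[idx],
          limit = ifelse(mol$censoring[idx] == "observed", NA,
                         mol$limit[idx]))
        fit_censored_linear(obs, x, group = group, config = cfg,
                            response = paste(t, mx, sep = ":"),
                            predictor = pred)
      } else {
        if (length(unique(mol$detected[idx])) < 2L) next
        fit_logistic(mol$detected[idx], x, group = group, config = cfg,
                     response = paste(t, mx, sep = ":"),
                     predictor = pred)
      }
      estimates[[paste(t, mx, pred)]] <- est
      fams <- c(fams, families[match(pred, predictors)])
    }
  }
}

tab <- summarize_effects(estimates, family = fams)
cat(sprintf("\n%d univariable models fitted (no multiplicity adjustment)\n",
            attr(tab, "n_models")))
cat(sprintf("%d estimates exclude the null\n", sum(tab$excludes_null)))
cat("(simulation truth: all covariate effects are zero, so null\n",
    "exclusions near the 5% rate per model are expected false positives)\n\n")
print(tab[, c("response", "predictor", "scale", "mean", "q2.5", "q97.5",
              "excludes_null")], digits = 2)

write_results(list(effect_estimates = tab), "results/risk", seed = 1L)
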