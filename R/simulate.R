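# Synthetic data with known ground truth, emulating the structure of a
# household fecal-contamination survey: plasmid standard dilution series
# with run/batch-level curve variation, host-labeled validation panels,
# and environmental samples with plates, reactions, covariates and
# meteorology clustered within compounds.

#' Ground-truth parameters for the synthetic data generator
#'
#' Defaults describe a typical probe-based qPCR assay (intercept 38 Cq,
#' slope -3.4 Cq per log10 copy, i.e. ~97% amplification efficiency,
#' residual SD 0.3 Cq) with modest between-run and between-batch curve
#' variation, and matrix-level mean log10 concentrations in the range
#' observed for E. coli markers in heavily contaminated domestic
#' environments (around 4 log10 per 100 mL of stored water and 6.5 log10
#' per dry g of soil).
#'
#' @param beta0 population calibration intercept (Cq).
#' @param beta1 population calibration slope (Cq per log10 copy); < 0.
#' @param sigma residual Cq SD; >= 0.
#' @param tau_run,tau_batch length-2 vectors: SDs of the run- and
#'   batch-level intercept and slope offsets (Cq, Cq per log10 copy).
#' @param conc_mean,conc_sd named numeric vectors of true log10
#'   concentration mean/SD per matrix.
#' @param effect named list of covariate effect sizes: \code{linear} (log10
#'   concentration change per unit) and \code{logodds}.
#' @param targets named numeric vector of per-target shifts (log10) added
#'   to the matrix concentration means; the first entry is the general
#'   indicator quantified by both culture and qPCR, later entries are
#'   qPCR-only (e.g. a host-associated marker several logs lower).
#' @param compound_sd SD of compound-level intercepts on the log10
#'   concentration scale.
#' @param max_cycles assay cycle ceiling; reactions whose realized Cq
#'   exceeds it are nondetects.
#' @return object of class \code{sim_truth}.
#' @export
sim_truth <- function(beta0 = 38, beta1 = -3.4, sigma = 0.3,
                      tau_run = c(0.5, 0.1), tau_batch = c(0.5, 0.1),
                      conc_mean = c(source_water = 2.5, stored_water = 4.3,
                                    food_surface = 4.7, latrine_soil = 6.5,
                                    household_soil = 6.7),
                      conc_sd = c(source_water = 1.0, stored_water = 0.85,
                                  food_surface = 0.9, latrine_soil = 1.1,
                                  household_soil = 0.9),
                      effect = list(linear = 0, logodds = 0),
                      targets = c(general = 0, human = -3),
                      compound_sd = 0.5, max_cycles = 40) {
  if (beta1 >= 0) stop("sim_truth: slope must be negative", call. = FALSE)
  if (sigma < 0 || any(tau_run < 0) || any(tau_batch < 0) ||
      compound_sd < 0) {
    stop("sim_truth: SDs must be >= 0", call. = FALSE)
  }
  structure(list(beta0 = beta0, beta1 = beta1, sigma = sigma,
                 tau_run = tau_run, tau_batch = tau_batch,
                 conc_mean = conc_mean, conc_sd = conc_sd,
                 effect = effect, targets = targets,
                 compound_sd = compound_sd, max_cycles = max_cycles),
            class = "sim_truth")
}

# run/batch offsets drawn once per group
draw_offsets <- function(n, tau) {
  cbind(intercept = stats::rnorm(n, 0, tau[1]),
        slope = stats::rnorm(n, 0, tau[2]))
}

#' Simulate plasmid standard dilution series
#'
#' Generates standard reactions across instrument runs and extraction
#' batches: Cq = (beta0 + b0) + (beta1 + b1) * x + Normal(0, sigma), with
#' group offsets drawn once per run and batch. The realized offsets are
#' attached for recovery tests.
#'
#' @param truth a \code{\link{sim_truth}}.
#' @param n_runs,n_batches number of instrument runs / extraction batches.
#' @param levels log10 copy numbers of the dilution series (default
#'   10^5..10^1, the environmental-analysis series; validation runs used
#'   10^7..10^1).
#' @param reps replicate reactions per run x batch x level (default
#'   triplicates).
#' @param seed RNG seed.
#' @return data.frame of standard reactions (\code{assay}, \code{run_id},
#'   \code{batch_id}, \code{log10_copies}, \code{cq}); the truth and group
#'   offsets are attached as attributes \code{truth}, \code{run_offsets},
#'   \code{batch_offsets}.
#' @export
simulate_standards <- function(truth = sim_truth(), n_runs = 4L,
                               n_batches = 3L, levels = 5:1, reps = 3L,
                               seed = 1L) {
  if (length(levels) == 0L) {
    stop("simulate_standards: levels must be non-empty", call. = FALSE)
  }
  if (reps < 1L) stop("simulate_standards: reps must be >= 1",
                      call. = FALSE)
  set.seed(seed)
  run_off <- draw_offsets(n_runs, truth$tau_run)
  bat_off <- draw_offsets(n_batches, truth$tau_batch)
  grid <- expand.grid(run = seq_len(n_runs), batch = seq_len(n_batches),
                      log10_copies = levels, rep = seq_len(reps))
  mu <- (truth$beta0 + run_off[grid$run, 1] + bat_off[grid$batch, 1]) +
    (truth$beta1 + run_off[grid$run, 2] + bat_off[grid$batch, 2]) *
    grid$log10_copies
  out <- data.frame(assay = "target1",
                    run_id = sprintf("run%02d", grid$run),
                    batch_id = sprintf("batch%02d", grid$batch),
                    log10_copies = grid$log10_copies,
                    cq = mu + stats::rnorm(nrow(grid), 0, truth$sigma),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- truth
  attr(out, "run_offsets") <- run_off
  attr(out, "batch_offsets") <- bat_off
  out
}

#' Simulate a host-labeled assay validation panel
#'
#' Generates reaction-level Cq data for fecal samples of known host origin.
#' Reactions from target hosts amplify with probability \code{sensitivity}
#' and non-target reactions with the cross-reaction rate; amplifying
#' reactions draw Cq from Normal(\code{cq_mean}, \code{cq_sd}) truncated at
#' \code{max_cycles}, and non-amplifying reactions are nondetects.
#'
#' @param n_target,n_nontarget numbers of samples per class.
#' @param sensitivity per-reaction amplification probability for target
#'   hosts, in [0, 1].
#' @param cross_rate per-reaction amplification probability for non-target
#'   hosts, in [0, 1].
#' @param reps reactions per sample (dilution x replicate wells).
#' @param cq_mean,cq_sd Cq distribution of true amplifications.
#' @param nontarget_cq_mean Cq distribution center of cross-reactions
#'   (typically later than true positives).
#' @param max_cycles assay cycle ceiling.
#' @param seed RNG seed.
#' @return data.frame with \code{sample_id}, \code{host} (\code{"target"} /
#'   \code{"nontarget"}), \code{is_target}, \code{cq} (NA = nondetect).
#' @export
simulate_validation_panel <- function(n_target = 14L, n_nontarget = 27L,
                                      sensitivity = 0.8, cross_rate = 0.1,
                                      reps = 4L, cq_mean = 30, cq_sd = 3,
                                      nontarget_cq_mean = 36,
                                      max_cycles = 45, seed = 1L) {
  if (sensitivity < 0 || sensitivity > 1 || cross_rate < 0 ||
      cross_rate > 1) {
    stop("simulate_validation_panel: rates must lie in [0, 1]",
         call. = FALSE)
  }
  set.seed(seed)
  one_class <- function(n, prefix, p, mean_cq, target) {
    if (n == 0L) return(NULL)
    grid <- expand.grid(sample = seq_len(n), rep = seq_len(reps))
    amplifies <- stats::runif(nrow(grid)) < p
    cq <- rep(NA_real_, nrow(grid))
    if (any(amplifies)) {
      raw <- stats::rnorm(sum(amplifies), mean_cq, cq_sd)
      raw[raw >= max_cycles] <- NA_real_  # beyond the ceiling: no signal
      cq[amplifies] <- raw
    }
    data.frame(sample_id = sprintf("%s%03d", prefix, grid$sample),
               host = if (target) "target" else "nontarget",
               is_target = target, cq = cq, stringsAsFactors = FALSE)
  }
  out <- rbind(one_class(n_target, "T", sensitivity, cq_mean, TRUE),
               one_class(n_nontarget, "N", cross_rate, nontarget_cq_mean,
                         FALSE))
  rownames(out) <- NULL
  out
}

#' Simulate an environmental sampling campaign
#'
#' Generates compounds with households, one sample per matrix type
#' (source water and latrine soil at compound level; stored water, food
#' surface and household soil at household level), together with the
#' laboratory data the pipeline consumes: qPCR reactions generated through
#' the inverse calibration relation Cq = a + b * (log10 C + log10 effort),
#' culture plates with Poisson colony counts and TNTC flags at the 400-cfu
#' ceiling, soil moisture, a binary hazard covariate, a 0-100 wealth-like
#' index, and a daily meteorology table.
#'
#' True log10 concentration of each sample is
#' matrix mean + compound intercept + linear effect * covariate +
#' Normal(0, matrix SD); detection covariate effects act on the same latent
#' concentration, so \code{effect$logodds} shifts it via the hazard flag as
#' well when supplied.
#'
#' @param truth a \code{\link{sim_truth}}.
#' @param n_compounds number of compounds.
#' @param households_per_compound households per compound.
#' @param n_runs,n_batches instrument runs and extraction batches the field
#'   reactions are spread over.
#' @param qpcr_reps replicate qPCR reactions per sample.
#' @param start_date first sampling date.
#' @param seed RNG seed.
#' @return list with data.frames \code{samples}, \code{reactions} (all
#'   targets), \code{plates}, \code{covariates}, \code{meteorology},
#'   \code{truth_conc} (per-sample per-target true log10 concentration),
#'   the realized \code{run_offsets} / \code{batch_offsets}, and
#'   \code{truth}.
#' @export
simulate_environment <- function(truth = sim_truth(), n_compounds = 20L,
                                 households_per_compound = 2L,
                                 n_runs = 4L, n_batches = 3L,
                                 qpcr_reps = 2L,
                                 start_date = as.Date("2015-05-01"),
                                 seed = 1L) {
  if (n_compounds < 1L || households_per_compound < 1L) {
    stop("simulate_environment: design counts must be >= 1", call. = FALSE)
  }
  set.seed(seed)
  run_off <- draw_offsets(n_runs, truth$tau_run)
  bat_off <- draw_offsets(n_batches, truth$tau_batch)
  comp_int <- stats::rnorm(n_compounds, 0, truth$compound_sd)

  # sampling frame: compound-level and household-level sample types
  rows <- list()
  for (ci in seq_len(n_compounds)) {
    cid <- sprintf("C%03d", ci)
    rows[[length(rows) + 1L]] <- data.frame(
      compound_id = cid, household_id = NA_character_,
      matrix = c("source_water", "latrine_soil"), stringsAsFactors = FALSE)
    for (hi in seq_len(households_per_compound)) {
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = cid, household_id = sprintf("%s-H%d", cid, hi),
        matrix = c("stored_water", "food_surface", "household_soil"),
        stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, rows)
  samples$sample_id <- sprintf("S%04d", seq_len(nrow(samples)))
  n <- nrow(samples)
  samples$compound_idx <- match(samples$compound_id,
                                sprintf("C%03d", seq_len(n_compounds)))
  samples$date <- start_date + (samples$compound_idx - 1L) %% 27L
  samples$run_id <- sprintf("run%02d", 1L + (seq_len(n) - 1L) %% n_runs)
  samples$batch_id <- sprintf("batch%02d",
                              1L + (seq_len(n) - 1L) %% n_batches)

  # covariates: binary hazard flag, wealth index, moisture for soils
  hazard <- stats::rbinom(n, 1L, 0.5)
  wealth <- pmin(pmax(stats::rnorm(n, 46, 12), 0), 100)
  is_soil <- grepl("soil", samples$matrix)
  moisture <- ifelse(is_soil,
                     pmin(pmax(stats::rnorm(n, 0.084 + 0.04 * hazard,
                                            0.03), 0.005), 0.6),
                     NA_real_)
  samples$moisture <- moisture
  samples$hazard <- hazard
  samples$wealth <- wealth
  samples$sun_exposure <- ifelse(is_soil,
                                 sample(c("full", "partial", "shade"), n,
                                        TRUE, prob = c(.25, .6, .15)), NA)
  samples$surface_wet <- ifelse(is_soil, hazard == 1L, NA)

  # true log10 concentration in matrix units, per target
  tnames <- names(truth$targets)
  base <- truth$conc_mean[samples$matrix] +
    comp_int[samples$compound_idx] + truth$effect$linear * hazard
  conc <- sapply(tnames, function(t) {
    base + truth$targets[[t]] +
      stats::rnorm(n, 0, truth$conc_sd[samples$matrix])
  })
  samples$true_log10_conc <- conc[, 1]  # general indicator (plated target)
  truth_conc <- data.frame(
    sample_id = rep(samples$sample_id, length(tnames)),
    target = rep(tnames, each = n),
    true_log10_conc = as.vector(conc), stringsAsFactors = FALSE)

  # plate volumes: initial pair plus the protocol re-filter volume used
  # when the smallest plate saturates (1 mL water, 0.01 mL eluate)
  cls <- matrix_class(samples$matrix)
  vol_big <- ifelse(cls == "water", 100, 1)
  vol_small <- ifelse(cls == "water", 10, 0.1)
  vol_refilter <- ifelse(cls == "water", 1, 0.01)
  molec_vol <- ifelse(cls == "water", 300, ifelse(cls == "surface", 12, 30))

  # culture plates: Poisson(conc x effort), TNTC above the 400-cfu ceiling
  plates <- do.call(rbind, lapply(seq_len(n), function(i) {
    vols <- c(vol_big[i], vol_small[i])
    eff <- sampling_effort(samples$matrix[i], vols, samples$moisture[i])
    lam <- 10^samples$true_log10_conc[i] * eff
    cnt <- stats::rpois(2L, pmin(lam, 1e7))
    tn <- cnt > PLATE_ULOQ_CFU
    if (tn[which.min(vols)]) {
      # smallest initial plate saturated: re-filter at the protocol volume
      eff3 <- sampling_effort(samples$matrix[i], vol_refilter[i],
                              samples$moisture[i])
      cnt3 <- stats::rpois(1L, min(10^samples$true_log10_conc[i] * eff3,
                                   1e7))
      vols <- c(vols, vol_refilter[i])
      tn <- c(tn, cnt3 > PLATE_ULOQ_CFU)
      cnt <- c(cnt, cnt3)
    }
    data.frame(sample_id = samples$sample_id[i], volume_ml = vols,
               count = ifelse(tn, NA_real_, cnt), tntc = tn,
               stringsAsFactors = FALSE)
  }))

  # qPCR reactions through the inverse calibration relation, per target
  run_idx <- match(samples$run_id, sprintf("run%02d", seq_len(n_runs)))
  bat_idx <- match(samples$batch_id,
                   sprintf("batch%02d", seq_len(n_batches)))
  eff_rxn <- sampling_effort(samples$matrix, molec_vol, samples$moisture,
                             reaction_fraction = REACTION_FRACTION)
  reactions <- do.call(rbind, lapply(seq_len(n), function(i) {
    a <- truth$beta0 + run_off[run_idx[i], 1] + bat_off[bat_idx[i], 1]
    b <- truth$beta1 + run_off[run_idx[i], 2] + bat_off[bat_idx[i], 2]
    do.call(rbind, lapply(seq_along(tnames), function(ti) {
      x <- conc[i, ti] + log10(eff_rxn[i])  # log10 gc per reaction
      cq <- a + b * x + stats::rnorm(qpcr_reps, 0, truth$sigma)
      cq[cq > truth$max_cycles] <- NA_real_
      data.frame(sample_id = samples$sample_id[i], assay = tnames[ti],
                 run_id = samples$run_id[i],
                 batch_id = samples$batch_id[i],
                 dilution = 1, replicate = seq_len(qpcr_reps), cq = cq,
                 effort = eff_rxn[i], stringsAsFactors = FALSE)
    }))
  }))

  dates <- seq(start_date - 31, max(samples$date), by = "day")

  rain <- stats::rbinom(length(dates), 1L, 0.12) *
    stats::rgamma(length(dates), 1.5, 0.2)
  meteorology <- data.frame(date = dates, precip_mm = round(rain, 1),
                            temp_c = round(stats::rnorm(length(dates),
                                                        20.4, 1.7), 1),
                            wind_kn = round(pmax(stats::rnorm(
                              length(dates), 7.7, 2.5), 0), 1))

  covariates <- samples[, c("sample_id", "compound_id", "household_id",
                            "matrix", "date", "hazard", "wealth",
                            "sun_exposure", "surface_wet")]
  list(samples = samples, reactions = reactions, plates = plates,
       covariates = covariates, meteorology = meteorology,
       truth_conc = truth_conc, run_offsets = run_off,
       batch_offsets = bat_off, truth = truth)
}

#' Simulate a censored concentration response for risk-model studies
#'
#' Draws a linear response y = alpha + beta * x (+ compound intercepts) +
#' Normal(0, sigma) and left-censors the lowest \code{censor_frac} fraction
#' at a common limit (the corresponding sample quantile), mimicking
#' concentrations below a process LLoD.
#'
#' @param n samples.
#' @param beta true slope (log10 concentration change per unit predictor).
#' @param alpha intercept.
#' @param sigma residual SD.
#' @param censor_frac target fraction of left-censored records.
#' @param n_groups number of compounds (0 = no grouping).
#' @param group_sd compound-intercept SD.
#' @param seed RNG seed.
#' @return list with \code{obs} (a \code{\link{censored_obs}} table),
#'   \code{x}, \code{group} (NULL when ungrouped) and \code{beta}.
#' @export
simulate_censored_response <- function(n = 60L, beta = 1, alpha = 4,
                                       sigma = 1, censor_frac = 0.3,
                                       n_groups = 0L, group_sd = 0.5,
                                       seed = 1L) {
  set.seed(seed)
  x <- stats::rnorm(n)
  group <- NULL
  u <- 0
  if (n_groups > 0L) {
    group <- sample(sprintf("C%03d", seq_len(n_groups)), n, replace = TRUE)
    u <- stats::rnorm(n_groups, 0, group_sd)[match(group, sort(unique(group)))]
    u[is.na(u)] <- 0
  }
  y <- alpha + beta * x + u + stats::rnorm(n, 0, sigma)
  lim <- stats::quantile(y, censor_frac, names = FALSE)
  cens <- y < lim
  obs <- censored_obs(value = ifelse(cens, NA, y),
                      censoring = ifelse(cens, "left", "observed"),
                      limit = ifelse(cens, lim, NA))
  list(obs = obs, x = x, group = group, beta = beta)
}

#' Simulate binary detection data for risk-model studies
#'
#' Draws detection flags from logit P(detect) = alpha + log(OR) * x
#' (+ compound intercepts).
#'
#' @param n samples.
#' @param or true odds ratio per unit predictor.
#' @param alpha intercept on the log-odds scale.
#' @param n_groups,group_sd compound clustering (0 = none).
#' @param binary_x use a balanced binary predictor instead of a standard
#'   normal one.
#' @param seed RNG seed.
#' @return list with \code{y}, \code{x}, \code{group}, \code{or}.
#' @export
simulate_detection <- function(n = 120L, or = 4, alpha = 0, n_groups = 0L,
                               group_sd = 0.5, binary_x = FALSE,
                               seed = 1L) {
  set.seed(seed)
  x <- if (binary_x) rep_len(c(0, 1), n) else stats::rnorm(n)
  group <- NULL
  u <- 0
  if (n_groups > 0L) {
    group <- sample(sprintf("C%03d", seq_len(n_groups)), n, replace = TRUE)
    u <- stats::rnorm(n_groups, 0, group_sd)[match(group, sort(unique(group)))]
    u[is.na(u)] <- 0
  }
  p <- stats::plogis(alpha + log(or) * x + u)
  list(y = stats::rbinom(n, 1L, p), x = x, group = group, or = or)
}
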