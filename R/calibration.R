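# Multilevel Bayesian calibration curves relating Cq to log10 copy number,
# with slopes and intercepts varying by instrument run and extraction batch,
# and posterior propagation into per-sample concentration estimates.

# JAGS model: Cq_i ~ Normal((b0 + r0[run] + e0[batch]) +
#                           (b1 + r1[run] + e1[batch]) * x_i, sigma).
# Population coefficients get effectively-flat Normal(0, 1000) priors.
# Group SDs and the residual SD get weakly informative half-Student-t(3, 0,
# scale) priors with scales on the natural units of each parameter:
# 2.5 Cq for intercept offsets and residual noise (run-to-run shifts of a
# functioning assay are within a couple of Cq), 0.5 Cq per log10 copy for
# slope offsets (slopes of a usable curve vary by well under half a unit).
calibration_model <- function(prec_int = 1 / 2.5^2,
                              prec_slope = 1 / 0.5^2,
                              prec_sigma = 1 / 2.5^2) {
  sprintf("model {
for (i in 1:N) {
  mu[i] <- (b0 + r0[run[i]] + e0[bat[i]]) + (b1 + r1[run[i]] + e1[bat[i]]) * x[i]
  cq[i] ~ dnorm(mu[i], tau)
}
for (j in 1:R) { r0[j] ~ dnorm(0, tau_r0); r1[j] ~ dnorm(0, tau_r1) }
for (j in 1:B) { e0[j] ~ dnorm(0, tau_b0); e1[j] ~ dnorm(0, tau_b1) }
b0 ~ dnorm(0, 1.0E-6)
b1 ~ dnorm(0, 1.0E-6)
sd_r0 ~ dt(0, %g, 3) T(0,); tau_r0 <- pow(sd_r0, -2)
sd_r1 ~ dt(0, %g, 3) T(0,); tau_r1 <- pow(sd_r1, -2)
sd_b0 ~ dt(0, %g, 3) T(0,); tau_b0 <- pow(sd_b0, -2)
sd_b1 ~ dt(0, %g, 3) T(0,); tau_b1 <- pow(sd_b1, -2)
sigma ~ dt(0, %g, 3) T(0,); tau <- pow(sigma, -2)
}", prec_int, prec_slope, prec_int, prec_slope, prec_sigma)
}

#' Fit a multilevel Bayesian calibration curve
#'
#' Regresses reaction Cq on known log10 copy number for extracted plasmid
#' standards, allowing both slope and intercept to vary by instrument run
#' and by extraction batch. Population-level coefficients get effectively
#' flat priors; group-level and residual SDs get weakly informative
#' half-Student-t priors scaled to each parameter's natural units (2.5 Cq
#' for intercept offsets and residual noise, 0.5 Cq per log10 copy for
#' slope offsets). Population coefficients are
#' initialized at the pooled ordinary least squares fit, which starts all
#' chains near the ridge along which the intercept trades off against group
#' offsets.
#'
#' @param standards data.frame with columns \code{cq} (numeric),
#'   \code{log10_copies}, \code{run_id}, \code{batch_id}. Nondetect (NA) Cq
#'   rows are dropped with a count retained in the result.
#' @param config an \code{\link{mcmc_config}}; the default matches the
#'   production settings (4 chains, 2000 warmup, 2000 sampling).
#' @return object of class \code{calibration_posterior}: draws of
#'   \code{b0}, \code{b1}, per-run and per-batch offsets, group SDs and
#'   residual \code{sigma}; run/batch label maps; split-Rhat and effective
#'   sample sizes; \code{convergence_warning} flag.
#' @export
fit_calibration <- function(standards, config = mcmc_config()) {
  stopifnot(is.data.frame(standards))
  need <- c("cq", "log10_copies", "run_id", "batch_id")
  missing_cols <- setdiff(need, names(standards))
  if (length(missing_cols)) {
    stop("fit_calibration: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_dropped <- sum(is.na(standards$cq))
  standards <- standards[!is.na(standards$cq), , drop = FALSE]
  if (length(unique(standards$log10_copies)) < 2L) {
    stop("fit_calibration: need >= 2 distinct standard concentrations ",
         "(design is rank deficient)", call. = FALSE)
  }
  runs <- sort(unique(as.character(standards$run_id)))
  bats <- sort(unique(as.character(standards$batch_id)))
  run_idx <- match(as.character(standards$run_id), runs)
  bat_idx <- match(as.character(standards$batch_id), bats)
  ols <- stats::coef(stats::lm(cq ~ log10_copies, data = standards))
  fit <- run_jags(
    calibration_model(),
    data = list(N = nrow(standards), R = length(runs), B = length(bats),
                cq = standards$cq, x = standards$log10_copies,
                run = run_idx, bat = bat_idx),
    monitor = c("b0", "b1", "r0", "r1", "e0", "e1",
                "sd_r0", "sd_r1", "sd_b0", "sd_b1", "sigma"),
    config = config,
    inits_fn = function(k) list(b0 = unname(ols[1]), b1 = unname(ols[2])))
  # coda drops the [1] suffix for single-element group vectors
  for (nm in c("r0", "r1", "e0", "e1")) {
    hit <- colnames(fit$draws) == nm
    if (any(hit)) colnames(fit$draws)[hit] <- sprintf("%s[1]", nm)
    hitr <- names(fit$rhat) == nm
    if (any(hitr)) names(fit$rhat)[hitr] <- sprintf("%s[1]", nm)
  }
  core <- c("b0", "b1", "sigma")
  warn <- convergence_flag(fit$rhat[core], fit$ess[core])
  if (warn) {
    warning("fit_calibration: convergence diagnostics failed the gate ",
            "(split-Rhat > 1.01 or bulk ESS < 400) for a population ",
            "parameter; inspect $rhat", call. = FALSE)
  }
  structure(list(draws = fit$draws, runs = runs, batches = bats,
                 rhat = fit$rhat, ess = fit$ess,
                 n_standards = nrow(standards), n_dropped = n_dropped,
                 convergence_warning = warn, config = config),
            class = "calibration_posterior")
}

#' @export
print.calibration_posterior <- function(x, ...) {
  b0 <- x$draws[, "b0"]; b1 <- x$draws[, "b1"]
  eff <- 10^(-1 / mean(b1)) - 1
  cat("Multilevel calibration curve posterior\n")
  cat(sprintf("  standards: %d (%d nondetect dropped), runs: %d, batches: %d\n",
              x$n_standards, x$n_dropped, length(x$runs), length(x$batches)))
  cat(sprintf("  intercept: %.2f (%.2f, %.2f) Cq\n", mean(b0),
              stats::quantile(b0, 0.025), stats::quantile(b0, 0.975)))
  cat(sprintf("  slope:     %.3f (%.3f, %.3f) Cq per log10 copy\n", mean(b1),
              stats::quantile(b1, 0.025), stats::quantile(b1, 0.975)))
  cat(sprintf("  amplification efficiency at posterior-mean slope: %.1f%%\n",
              100 * eff))
  if (x$convergence_warning) cat("  WARNING: convergence gate failed\n")
  invisible(x)
}

#' Group-specific intercept and slope draws
#'
#' Returns the per-draw effective intercept and slope for a given instrument
#' run and extraction batch (population values plus the group offsets), or
#' the population-level curve when \code{run}/\code{batch} are NULL. Groups
#' not present in the calibration data fall back to the population curve
#' (offset zero), with a warning.
#'
#' @param posterior a \code{calibration_posterior}.
#' @param run,batch group labels or NULL.
#' @return list with numeric vectors \code{intercept} and \code{slope},
#'   one entry per posterior draw.
#' @export
curve_draws <- function(posterior, run = NULL, batch = NULL) {
  stopifnot(inherits(posterior, "calibration_posterior"))
  d <- posterior$draws
  a <- d[, "b0"]
  b <- d[, "b1"]
  pick <- function(label, labels, prefix) {
    i <- match(as.character(label), labels)
    if (is.na(i)) {
      warning("curve_draws: unknown group '", label,
              "'; using population curve", call. = FALSE)
      return(NULL)
    }
    i
  }
  if (!is.null(run)) {
    i <- pick(run, posterior$runs)
    if (!is.null(i)) {
      a <- a + d[, sprintf("r0[%d]", i)]
      b <- b + d[, sprintf("r1[%d]", i)]
    }
  }
  if (!is.null(batch)) {
    i <- pick(batch, posterior$batches)
    if (!is.null(i)) {
      a <- a + d[, sprintf("e0[%d]", i)]
      b <- b + d[, sprintf("e1[%d]", i)]
    }
  }
  list(intercept = unname(a), slope = unname(b))
}

#' Invert observed Cq to log10 gene copies per reaction
#'
#' For each posterior draw, the reaction's log10 copy number is
#' (Cq - a_d) / b_d with a_d, b_d the draw's run/batch-specific intercept and
#' slope. Draws with nonnegative slope cannot be inverted and are excluded
#' (their count is reported).
#'
#' @param cq observed quantification cycle.
#' @param posterior a \code{calibration_posterior}.
#' @param run,batch group labels (optional).
#' @return list with \code{draws} (log10 gc per reaction, one per retained
#'   posterior draw) and \code{n_dropped}.
#' @export
invert_cq <- function(cq, posterior, run = NULL, batch = NULL) {
  ab <- curve_draws(posterior, run = run, batch = batch)
  ok <- ab$slope < 0
  if (!any(ok)) {
    stop("invert_cq: no draws with negative slope; calibration unusable",
         call. = FALSE)
  }
  list(draws = (cq - ab$intercept[ok]) / ab$slope[ok],
       n_dropped = sum(!ok))
}

#' Posterior concentration of one sample from its replicate reactions
#'
#' Converts each amplifying replicate reaction's Cq into log10 gene copies
#' per reaction (per posterior draw, with run/batch-specific curve
#' parameters), normalizes by the effort the reaction represents, and pools
#' the transformed draws across replicates into a single posterior for the
#' sample's log10 concentration. Nondetect replicates are excluded from
#' quantification (detection uses any-positive separately). If no replicate
#' amplifies, a left-censored estimate at the sample LLoD is returned
#' (requires \code{cutoff}).
#'
#' @param cqs numeric Cq of the sample's replicate reactions (NA =
#'   nondetect).
#' @param effort effort in matrix units represented by one reaction
#'   (see \code{\link{sampling_effort}}); > 0.
#' @param posterior a \code{calibration_posterior}.
#' @param run,batch group labels per replicate (scalar or vector).
#' @param cutoff integer detection cutoff, used for the censoring limit when
#'   no replicate amplifies.
#' @param combine \code{"pool"} (concatenate per-replicate draw vectors; the
#'   default) or \code{"average"} (per-draw mean across replicates).
#' @return a one-row data.frame (class \code{concentration_estimate}):
#'   \code{mean}, \code{sd}, \code{q2.5}, \code{q97.5} of log10
#'   concentration, \code{detected}, \code{censoring}, \code{limit},
#'   \code{n_reactions}, \code{n_amplifying}.
#' @export
sample_concentration <- function(cqs, effort, posterior, run = NULL,
                                 batch = NULL, cutoff = NULL,
                                 combine = c("pool", "average")) {
  combine <- match.arg(combine)
  if (length(cqs) < 1L) {
    stop("sample_concentration: need >= 1 reaction", call. = FALSE)
  }
  if (effort <= 0) {
    stop("sample_concentration: effort must be > 0", call. = FALSE)
  }
  runs <- rep_len(if (is.null(run)) list(NULL) else as.list(run),
                  length(cqs))
  bats <- rep_len(if (is.null(batch)) list(NULL) else as.list(batch),
                  length(cqs))
  amp <- which(!is.na(cqs))
  if (length(amp) == 0L) {
    if (is.null(cutoff)) {
      stop("sample_concentration: no amplifying reactions and no cutoff ",
           "to set the censoring limit", call. = FALSE)
    }
    lim <- molecular_llod(cutoff, effort, posterior,
                          run = runs[[1]], batch = bats[[1]])
    out <- data.frame(mean = NA_real_, sd = NA_real_, q2.5 = NA_real_,
                      q97.5 = NA_real_, detected = FALSE,
                      censoring = "left", limit = lim$mean,
                      n_reactions = length(cqs), n_amplifying = 0L)
    class(out) <- c("concentration_estimate", "data.frame")
    return(out)
  }
  per_rep <- lapply(amp, function(i) {
    invert_cq(cqs[i], posterior, run = runs[[i]],
              batch = bats[[i]])$draws - log10(effort)
  })
  pooled <- if (combine == "pool") {
    unlist(per_rep, use.names = FALSE)
  } else {
    lens <- lengths(per_rep)
    rowMeans(do.call(cbind, lapply(per_rep, `[`, seq_len(min(lens)))))
  }
  q <- stats::quantile(pooled, c(0.025, 0.975), names = FALSE)
  out <- data.frame(mean = mean(pooled), sd = stats::sd(pooled),
                    q2.5 = q[1], q97.5 = q[2], detected = TRUE,
                    censoring = "observed", limit = NA_real_,
                    n_reactions = length(cqs),
                    n_amplifying = length(amp))
  class(out) <- c("concentration_estimate", "data.frame")
  out
}

#' Flag PCR inhibition from the specimen processing control
#'
#' A sample is inhibited when its SPC (exogenous salmon-testes DNA, Sketa22
#' assay) Cq exceeds the mean SPC Cq of the associated extraction controls
#' by strictly more than 3 cycles, or when the SPC fails to amplify at all.
#'
#' @param sample_cq SPC Cq of the sample (NA = nondetect).
#' @param control_cqs numeric SPC Cq values of the extraction controls
#'   (NEC and PC) from the sample's batch.
#' @return list with logical \code{inhibited} and a \code{reason} code
#'   (\code{"ok"}, \code{"delayed_spc"} or \code{"spc_nondetect"}).
#' @export
flag_inhibition <- function(sample_cq, control_cqs) {
  control_cqs <- control_cqs[!is.na(control_cqs)]
  if (length(control_cqs) == 0L) {
    stop("flag_inhibition: need >= 1 control SPC Cq", call. = FALSE)
  }
  if (is.na(sample_cq)) {
    return(list(inhibited = TRUE, reason = "spc_nondetect"))
  }
  if (sample_cq > mean(control_cqs) + 3) {
    list(inhibited = TRUE, reason = "delayed_spc")
  } else {
    list(inhibited = FALSE, reason = "ok")
  }
}
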