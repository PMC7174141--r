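# Univariable Bayesian risk-factor models: censored linear regression for
# concentration responses, logistic regression for detection responses,
# both optionally with compound-varying intercepts.

#' Choose the response type for a target x sample-type combination
#'
#' Normalized log10 concentration is the response unless the target was
#' detected in fewer than \code{threshold} (default 75%) of samples of the
#' type, in which case binary detection status is used. The comparison is
#' strict: a detection fraction exactly at the threshold keeps the
#' concentration response.
#'
#' @param detection_fraction fraction of samples positive, in [0, 1].
#' @param threshold detection-fraction threshold in (0, 1].
#' @return \code{"concentration"} or \code{"detection"}.
#' @export
choose_response <- function(detection_fraction, threshold = 0.75) {
  if (any(detection_fraction < 0 | detection_fraction > 1)) {
    stop("choose_response: detection_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  ifelse(detection_fraction < threshold, "detection", "concentration")
}

#' Prepare predictor columns for the risk models
#'
#' Centers and scales continuous covariates and derives precipitation-window
#' variables. Continuous predictors other than cumulative precipitation are
#' mean-centered and either standardized by their SD (\code{scale = "sd"})
#' or scaled by a stated unit (\code{scale = unit value}; e.g. 10 for a
#' wealth index on a 0-100 scale so one unit is a 10-point increase).
#' From the daily meteorology table, cumulative precipitation sums and
#' rain-day counts over the 7 and 30 days preceding each sampling date are
#' computed (cumulative precipitation is left uncentered).
#'
#' @param covariates data.frame of sample-level covariates including a
#'   \code{date} column (Date).
#' @param meteorology data.frame with columns \code{date},
#'   \code{precip_mm}, and any other daily variables; must cover every
#'   sampling date minus 30 days.
#' @param scale named list mapping continuous covariate names to either
#'   \code{"sd"} or a numeric scaling unit; unlisted numeric columns are
#'   standardized by SD.
#' @return the covariate table with transformed continuous columns and the
#'   added columns \code{precip_7d}, \code{precip_30d}, \code{rain_days_7d},
#'   \code{rain_days_30d}.
#' @export
prepare_predictors <- function(covariates, meteorology, scale = list()) {
  stopifnot(is.data.frame(covariates), is.data.frame(meteorology))
  if (!"date" %in% names(covariates)) {
    stop("prepare_predictors: covariates need a 'date' column",
         call. = FALSE)
  }
  met_dates <- as.Date(meteorology$date)
  for (d in unique(as.Date(covariates$date))) {
    window <- seq(as.Date(d, origin = "1970-01-01") - 30,
                  as.Date(d, origin = "1970-01-01") - 1, by = "day")
    if (!all(window %in% met_dates)) {
      stop("prepare_predictors: meteorology does not cover the 30 days ",
           "before ", format(as.Date(d, origin = "1970-01-01")),
           call. = FALSE)
    }
  }
  win_sum <- function(d, days, f) {
    idx <- met_dates >= (d - days) & met_dates <= (d - 1)
    f(meteorology$precip_mm[idx])
  }
  dates <- as.Date(covariates$date)
  covariates$precip_7d <- vapply(dates, win_sum, numeric(1), days = 7,
                                 f = sum)
  covariates$precip_30d <- vapply(dates, win_sum, numeric(1), days = 30,
                                  f = sum)
  covariates$rain_days_7d <- vapply(dates, win_sum, numeric(1), days = 7,
                                    f = function(p) sum(p > 0))
  covariates$rain_days_30d <- vapply(dates, win_sum, numeric(1), days = 30,
                                     f = function(p) sum(p > 0))
  no_center <- c("precip_7d", "precip_30d")
  for (nm in names(covariates)) {
    if (nm %in% c("date", no_center)) next
    x <- covariates[[nm]]
    if (!is.numeric(x) || length(unique(x)) <= 2L) next
    unit <- scale[[nm]]
    if (is.null(unit)) unit <- "sd"
    denom <- if (identical(unit, "sd")) stats::sd(x) else as.numeric(unit)
    covariates[[nm]] <- (x - mean(x)) / denom
  }
  covariates
}

# JAGS censored linear model. Observed responses use the normal density
# directly; left/right censored ones a dinterval likelihood with a latent
# response. Priors: Normal(0, 10) intercept, Normal(0, 2) slope, and
# half-Student-t(3, 0, 2.5) for the residual and compound-intercept SDs.
censored_linear_model <- function(grouped) {
  group_lines <- if (grouped) {
    c("  + u[g_obs[i]]", "  + u[g_cen[i]]",
      "for (j in 1:G) { u[j] ~ dnorm(0, tau_u) }",
      "sd_u ~ dt(0, 0.16, 3) T(0,)\ntau_u <- pow(sd_u, -2)")
  } else c("", "", "", "")
  sprintf("model {
for (i in 1:Nobs) {
  y_obs[i] ~ dnorm(alpha + beta * x_obs[i]%s, tau)
}
for (i in 1:Ncen) {
  is_right[i] ~ dinterval(y_cen[i], lim[i])
  y_cen[i] ~ dnorm(alpha + beta * x_cen[i]%s, tau)
}
%s
alpha ~ dnorm(0, 0.01)
beta ~ dnorm(0, 0.25)
sigma ~ dt(0, 0.16, 3) T(0,)
tau <- pow(sigma, -2)
%s
}", group_lines[1], group_lines[2], group_lines[3], group_lines[4])
}

effect_estimate <- function(response, predictor, scale, draws, null_value,
                            warning_flag, rhat) {
  est <- if (scale == "odds ratio") exp(draws) else draws
  q <- stats::quantile(est, c(0.025, 0.975), names = FALSE)
  data.frame(response = response, predictor = predictor, scale = scale,
             mean = mean(est), q2.5 = q[1], q97.5 = q[2],
             excludes_null = (q[1] > null_value) | (q[2] < null_value),
             warning = warning_flag, rhat = rhat,
             stringsAsFactors = FALSE)
}

#' Bayesian censored linear regression for one risk factor
#'
#' Regresses a (possibly censored) log10 concentration response on a single
#' predictor, with the censored-normal likelihood of
#' \code{\link{fit_censored_normal}} and, when \code{group} is supplied, an
#' intercept varying by compound. Priors are weakly regularizing normals:
#' SD 10 for the intercept and SD 2 for the predictor; half-Student-t(3, 0,
#' 2.5) for the residual and group SDs. Defaults follow the production MCMC
#' settings (4 chains, 1500 warmup, 1000 sampling).
#'
#' @param obs \code{\link{censored_obs}} response table, one row per sample.
#' @param x numeric predictor, one value per sample; must be non-constant.
#' @param group optional compound labels for the varying intercept.
#' @param config an \code{\link{mcmc_config}}.
#' @param response name used in the output table.
#' @param predictor predictor name for the output table.
#' @return one-row \code{data.frame} effect estimate: posterior mean and 95%
#'   credible interval of the slope (log10 concentration change per unit
#'   predictor), \code{excludes_null}, convergence \code{warning} flag.
#' @export
fit_censored_linear <- function(obs, x, group = NULL,
                                config = mcmc_config(4L, 1500L, 1000L),
                                response = "log10_concentration",
                                predictor = "x") {
  obs <- as.data.frame(obs)
  n <- nrow(obs)
  if (length(x) != n) {
    stop("fit_censored_linear: predictor length mismatch", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("fit_censored_linear: constant predictor", call. = FALSE)
  }
  is_obs <- obs$censoring == "observed"
  cen <- which(!is_obs)
  grouped <- !is.null(group)
  data <- list(Nobs = sum(is_obs), Ncen = length(cen),
               y_obs = obs$value[is_obs], x_obs = x[is_obs],
               x_cen = x[cen], lim = obs$limit[cen],
               is_right = as.integer(obs$censoring[cen] == "right"))
  # latent censored responses need inits on the correct side of the limit
  y_cen_init <- ifelse(obs$censoring[cen] == "right",
                       obs$limit[cen] + 0.5, obs$limit[cen] - 0.5)
  if (grouped) {
    glab <- sort(unique(as.character(group)))
    data$G <- length(glab)
    data$g_obs <- match(as.character(group)[is_obs], glab)
    data$g_cen <- match(as.character(group)[cen], glab)
  }
  model <- censored_linear_model(grouped)
  if (data$Ncen == 0L) {
    # JAGS rejects zero-length loops; drop the censored block entirely

    model <- sub("(?s)for \\(i in 1:Ncen\\) \\{.*?\\}\n", "", model,
                 perl = TRUE)
    data$Ncen <- NULL; data$x_cen <- NULL; data$lim <- NULL
    data$is_right <- NULL
    if (grouped) data$g_cen <- NULL
  }
  inits_fn <- function(k) {
    ini <- list(alpha = mean(obs$value[is_obs]), beta = 0)
    if (length(cen) > 0L) ini$y_cen <- y_cen_init
    ini
  }
  fit <- run_jags(model, data, monitor = c("alpha", "beta", "sigma"),
                  config = config, inits_fn = inits_fn)
  warn <- convergence_flag(fit$rhat[c("alpha", "beta")],
                           fit$ess[c("alpha", "beta")])
  effect_estimate(response, predictor, "log10 change", fit$draws[, "beta"],
                  null_value = 0, warning_flag = warn,
                  rhat = max(fit$rhat[c("alpha", "beta")], na.rm = TRUE))
}

logistic_model <- function(grouped) {
  group_lines <- if (grouped) {
    c(" + u[g[i]]",
      "for (j in 1:G) { u[j] ~ dnorm(0, tau_u) }",
      "sd_u ~ dt(0, 0.16, 3) T(0,)\ntau_u <- pow(sd_u, -2)")
  } else c("", "", "")
  sprintf("model {
for (i in 1:N) {
  y[i] ~ dbern(p[i])
  logit(p[i]) <- alpha + beta * x[i]%s
}
%s
alpha ~ dt(0, 0.01, 5)
beta ~ dt(0, 0.16, 5)
%s
}", group_lines[1], group_lines[2], group_lines[3])
}

#' Bayesian logistic regression for one risk factor
#'
#' Models binary target detection with a single predictor and, optionally,
#' a compound-varying intercept. Weakly regularizing Student-t priors with 5
#' degrees of freedom are used for population parameters: scale 10 for the
#' intercept and scale 2.5 for the predictor. The effect is reported as an
#' odds ratio (posterior mean and 95% CrI of exp(beta)). Under complete or
#' quasi-separation the regularizing prior keeps the estimate finite, but
#' the estimate is flagged: for a binary predictor when any outcome x
#' predictor cell holds at most one observation, and in general when the
#' posterior-mean |beta| exceeds 5 (OR beyond about 150).
#'
#' @param y logical or 0/1 detection flags.
#' @param x numeric predictor.
#' @param group optional compound labels.
#' @param config an \code{\link{mcmc_config}}.
#' @param response,predictor names for the output table.
#' @return one-row effect-estimate data.frame on the odds-ratio scale.
#' @export
fit_logistic <- function(y, x, group = NULL,
                         config = mcmc_config(4L, 1500L, 1000L),
                         response = "detection", predictor = "x") {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("fit_logistic: outcome has a single class", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("fit_logistic: predictor length mismatch", call. = FALSE)
  }
  grouped <- !is.null(group)
  data <- list(N = length(y), y = y, x = x)
  if (grouped) {
    glab <- sort(unique(as.character(group)))
    data$G <- length(glab)
    data$g <- match(as.character(group), glab)
  }
  fit <- run_jags(logistic_model(grouped), data,
                  monitor = c("alpha", "beta"), config = config)
  beta <- fit$draws[, "beta"]
  separation <- abs(mean(beta)) > 5
  if (length(unique(x)) == 2L) {
    separation <- separation || min(table(x, y)) <= 1L
  }
  warn <- convergence_flag(fit$rhat[c("alpha", "beta")],
                           fit$ess[c("alpha", "beta")]) || separation
  effect_estimate(response, predictor, "odds ratio", beta, null_value = 1,
                  warning_flag = warn,
                  rhat = max(fit$rhat[c("alpha", "beta")], na.rm = TRUE))
}

#' Collate effect estimates into a forest-style table
#'
#' Binds univariable effect estimates, groups them by response and predictor
#' family, sorts within groups, and marks null exclusion. The number of
#' models fitted is attached as an attribute since no multiplicity
#' adjustment is applied.
#'
#' @param estimates list of one-row effect-estimate data.frames (from
#'   \code{\link{fit_censored_linear}} / \code{\link{fit_logistic}}).
#' @param family optional character vector (recycled) assigning each
#'   estimate to a predictor family (hazards, amenities, demographics,
#'   meteorology, sample characteristics).
#' @return data.frame sorted by response, family, predictor.
#' @export
summarize_effects <- function(estimates, family = "unspecified") {
  if (length(estimates) == 0L) {
    stop("summarize_effects: no estimates", call. = FALSE)
  }
  tab <- do.call(rbind, estimates)
  tab$family <- rep_len(family, nrow(tab))
  tab <- tab[order(tab$response, tab$family, tab$predictor), ,
             drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_models") <- nrow(tab)
  tab
}
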