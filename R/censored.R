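# Censored-normal maximum likelihood and truncated-normal imputation for
# log10 concentration data with nondetects (left-censored at the sample
# process LLoD) and saturated plates (right-censored at the ULoQ).

#' Construct a table of possibly censored observations
#'
#' @param value numeric log10 concentration for observed records; ignored
#'   (may be NA) for censored records.
#' @param censoring character vector with entries \code{"observed"},
#'   \code{"left"} or \code{"right"}.
#' @param limit numeric censoring limit (log10 scale) for censored records;
#'   ignored for observed records.
#' @return a data.frame of class \code{censored_obs}.
#' @export
censored_obs <- function(value, censoring = rep("observed", length(value)),
                         limit = rep(NA_real_, length(value))) {
  censoring <- match.arg(censoring, c("observed", "left", "right"),
                         several.ok = TRUE)
  n <- max(length(value), length(censoring), length(limit))
  value <- rep_len(as.numeric(value), n)
  censoring <- rep_len(censoring, n)
  limit <- rep_len(as.numeric(limit), n)
  if (any(censoring != "observed" & !is.finite(limit))) {
    stop("censored records must carry a finite limit", call. = FALSE)
  }
  if (any(censoring == "observed" & !is.finite(value))) {
    stop("observed records must carry a finite value", call. = FALSE)
  }
  structure(data.frame(value = value, censoring = censoring, limit = limit,
                       stringsAsFactors = FALSE),
            class = c("censored_obs", "data.frame"))
}

# Negative log-likelihood of the censored normal model at (mu, log sigma).
censnorm_nll <- function(par, obs) {
  mu <- par[1]
  sigma <- exp(par[2])
  ll <- 0
  is_obs <- obs$censoring == "observed"
  if (any(is_obs)) {
    ll <- ll + sum(stats::dnorm(obs$value[is_obs], mu, sigma, log = TRUE))
  }
  is_l <- obs$censoring == "left"
  if (any(is_l)) {
    ll <- ll + sum(stats::pnorm(obs$limit[is_l], mu, sigma, log.p = TRUE))
  }
  is_r <- obs$censoring == "right"
  if (any(is_r)) {
    ll <- ll + sum(stats::pnorm(obs$limit[is_r], mu, sigma,
                                lower.tail = FALSE, log.p = TRUE))
  }
  -ll
}

#' Censored-normal maximum likelihood estimation
#'
#' Fits a normal distribution to log10 concentrations in which nondetects are
#' known only to lie below their sample-specific lower limit of detection and
#' saturated observations above their upper limit of quantification. The
#' likelihood uses the normal density for observed values, the normal CDF at
#' the limit for left-censored values, and the survival function for
#' right-censored values. Standard errors come from the observed information
#' matrix at the optimum.
#'
#' Heterogeneous (per-record) limits are supported; optimization is a
#' bounded quasi-Newton search on (mu, log sigma) initialized at the naive
#' estimates obtained by treating censored records as observed at their
#' limits.
#'
#' @param obs a \code{\link{censored_obs}} table (or data.frame with columns
#'   \code{value}, \code{censoring}, \code{limit}).
#' @return list with elements \code{mean}, \code{sd}, \code{se_mean},
#'   \code{se_sd}, \code{loglik}, \code{n}, \code{n_censored},
#'   \code{convergence}.
#' @export
fit_censored_normal <- function(obs) {
  obs <- as.data.frame(obs)
  stopifnot(all(c("value", "censoring", "limit") %in% names(obs)))
  if (nrow(obs) < 3L) {
    stop("fit_censored_normal: need at least 3 observations", call. = FALSE)
  }
  if (!any(obs$censoring == "observed")) {
    stop("fit_censored_normal: all observations censored; mean and SD are not identifiable",
         call. = FALSE)
  }
  # naive start: censored records at their limits
  y0 <- ifelse(obs$censoring == "observed", obs$value, obs$limit)
  mu0 <- mean(y0)
  s0 <- stats::sd(y0) * sqrt((length(y0) - 1) / length(y0))
  if (!is.finite(s0) || s0 <= 0) s0 <- 0.5
  fit <- stats::optim(c(mu0, log(s0)), censnorm_nll, obs = obs,
                      method = "L-BFGS-B",
                      lower = c(-1e6, log(1e-6)), upper = c(1e6, log(1e6)),
                      control = list(factr = 1e5))
  mu <- fit$par[1]
  sigma <- exp(fit$par[2])
  if (sigma < 1e-5) {
    stop("fit_censored_normal: degenerate fit (sigma -> 0)", call. = FALSE)
  }
  # observed information on the (mu, sigma) scale
  hess <- stats::optimHess(c(mu, sigma), function(p) {
    censnorm_nll(c(p[1], log(p[2])), obs)
  })
  ses <- c(NA_real_, NA_real_)
  cov <- tryCatch(solve(hess), error = function(e) NULL)
  if (!is.null(cov)) {
    d <- diag(cov)
    ses <- ifelse(d > 0, sqrt(d), NA_real_)
  }
  list(mean = mu, sd = sigma, se_mean = ses[1], se_sd = ses[2],
       loglik = -fit$value, n = nrow(obs),
       n_censored = sum(obs$censoring != "observed"),
       convergence = fit$convergence)
}

#' Expected value of a truncated normal distribution
#'
#' Imputes a censored log10 concentration as the conditional expectation of
#' a Normal(mu, sigma) given that it lies below (left) or above (right) the
#' censoring limit. With alpha = (limit - mu)/sigma, the left-censored
#' expectation is mu - sigma * phi(alpha)/Phi(alpha) and the right-censored
#' one mu + sigma * phi(alpha)/(1 - Phi(alpha)). The Mills ratio is evaluated
#' on the log scale so extreme limits never produce NaN.
#'
#' @param limit censoring limit (log10 scale); vectorized.
#' @param side \code{"left"} (value known to lie below the limit) or
#'   \code{"right"} (above).
#' @param mean,sd parameters of the untruncated normal; \code{sd > 0}.
#' @return expected value(s), strictly below the limit for left censoring and
#'   strictly above it for right censoring.
#' @export
impute_censored <- function(limit, side = c("left", "right"), mean = 0,
                            sd = 1) {
  side <- match.arg(side)
  if (any(sd <= 0)) stop("impute_censored: sd must be > 0", call. = FALSE)
  alpha <- (limit - mean) / sd
  if (side == "left") {
    # phi(a)/Phi(a), computed in log space (safe as alpha -> -Inf)
    mills <- exp(stats::dnorm(alpha, log = TRUE) -
                   stats::pnorm(alpha, log.p = TRUE))
    mean - sd * mills
  } else {
    mills <- exp(stats::dnorm(alpha, log = TRUE) -
                   stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
    mean + sd * mills
  }
}

#' Summarize censored concentration data by group
#'
#' Applies \code{\link{fit_censored_normal}} within each group (typically
#' target x sample type) and returns a summary table of the MLE mean and SD
#' with their standard errors, plus truncated-normal imputations for the
#' censored records.
#'
#' @param obs \code{\link{censored_obs}} table.
#' @param group factor-like vector, one entry per observation.
#' @return list with \code{summary} (one row per group) and \code{imputed}
#'   (per-record values: observed values untouched, censored ones replaced by
#'   their truncated-normal expectation).
#' @export
censored_summary <- function(obs, group = rep("all", nrow(obs))) {
  obs <- as.data.frame(obs)
  group <- as.character(group)
  out <- lapply(split(seq_len(nrow(obs)), group), function(idx) {
    sub <- obs[idx, , drop = FALSE]
    fit <- fit_censored_normal(sub)
    imp <- sub$value
    for (k in seq_len(nrow(sub))) {
      if (sub$censoring[k] != "observed") {
        imp[k] <- impute_censored(sub$limit[k], sub$censoring[k],
                                  fit$mean, fit$sd)
      }
    }
    list(row = data.frame(group = group[idx][1], n = fit$n,
                          n_censored = fit$n_censored,
                          mean = fit$mean, se_mean = fit$se_mean,
                          sd = fit$sd, se_sd = fit$se_sd,
                          stringsAsFactors = FALSE),
         imputed = data.frame(index = idx, value = imp,
                              stringsAsFactors = FALSE))
  })
  summary <- do.call(rbind, lapply(out, `[[`, "row"))
  rownames(summary) <- NULL
  imputed <- do.call(rbind, lapply(out, `[[`, "imputed"))
  imputed <- imputed[order(imputed$index), , drop = FALSE]
  rownames(imputed) <- NULL
  list(summary = summary, imputed = imputed)
}
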