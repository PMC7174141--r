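# Shared JAGS plumbing: model compilation, seeded chains, convergence checks.

#' MCMC sampler settings
#'
#' Container for the Markov chain Monte Carlo settings shared by all Bayesian
#' models in the pipeline. Calibration-curve fits default to four chains with
#' 2000 warmup and 2000 sampling iterations; risk-factor regressions use four
#' chains with 1500 warmup and 1000 sampling iterations (see
#' \code{\link{fit_censored_linear}}). Reduced settings are appropriate for
#' simulation studies.
#'
#' @param chains number of chains (>= 2).
#' @param warmup adaptation + burn-in iterations per chain (>= 1).
#' @param sampling retained iterations per chain (>= 1).
#' @param seed integer seed from which per-chain RNG seeds are derived.
#' @return an object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(chains = 4L, warmup = 2000L, sampling = 2000L,
                        seed = 1L) {
  chains <- as.integer(chains)
  warmup <- as.integer(warmup)
  sampling <- as.integer(sampling)
  if (chains < 2L) stop("mcmc_config: chains must be >= 2", call. = FALSE)
  if (warmup < 1L || sampling < 1L) {
    stop("mcmc_config: warmup and sampling must be >= 1", call. = FALSE)
  }
  structure(list(chains = chains, warmup = warmup, sampling = sampling,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# Split-Rhat (potential scale reduction on half-chains) for one parameter.
# x: iterations x chains matrix of draws.
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  halves <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(halves)
  nn <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  B <- nn * stats::var(means)
  W <- mean(vars)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# The glm module provides block updating for linear-model structures; the
# default single-site samplers mix very slowly along the ridge between a
# population intercept and its group offsets.
ensure_glm_module <- local({
  loaded <- FALSE
  function() {
    if (!loaded) {
      try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
      loaded <<- TRUE
    }
    invisible(NULL)
  }
})

# Run a JAGS model and return combined draws plus diagnostics.
# monitor: character vector of node names.
# inits_fn: function(chain_index) -> list of initial values (may be NULL).
run_jags <- function(model_string, data, monitor, config,
                     inits_fn = NULL) {
  stopifnot(inherits(config, "mcmc_config"))
  ensure_glm_module()
  inits <- lapply(seq_len(config$chains), function(k) {
    ini <- if (is.null(inits_fn)) list() else inits_fn(k)
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- (config$seed * 1000L + k) %% .Machine$integer.max
    ini
  })
  adapt <- max(100L, floor(config$warmup / 2))
  burn <- config$warmup - adapt
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = config$chains,
                             n.adapt = adapt, quiet = TRUE)
  if (burn > 0L) stats::update(model, burn, progress.bar = "none")
  samp <- rjags::coda.samples(model, variable.names = monitor,
                              n.iter = config$sampling,
                              progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  pars <- colnames(draws)
  rhat <- vapply(pars, function(p) {
    split_rhat(sapply(samp, function(ch) as.matrix(ch)[, p]))
  }, numeric(1))
  ess <- tryCatch(coda::effectiveSize(samp), error = function(e) NULL)
  list(draws = draws, rhat = rhat, ess = ess, mcmc = samp)
}

# TRUE when any monitored parameter fails the convergence gate
# (split-Rhat > 1.01 or bulk ESS < 400); used to attach warnings, never to
# discard a fit.
convergence_flag <- function(rhat, ess, rhat_max = 1.01, ess_min = 400) {
  bad_rhat <- any(is.finite(rhat) & rhat > rhat_max)
  bad_ess <- !is.null(ess) && any(is.finite(ess) & ess < ess_min)
  isTRUE(bad_rhat || bad_ess)
}
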