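# Sampling efforts, soil moisture, and process detection limits.
#
# A sampling "effort" is the quantity of original matrix a plate or qPCR
# reaction represents, in the unit the concentrations are reported in:
# 100 mL of water, 100 cm^2 of food preparation surface, or gram of dry soil.
# Conversion constants: each mL of eluate filtered represents 0.01 g wet soil
# or 8.33 cm^2 of swabbed surface, and each qPCR reaction carries 5 uL of the
# 100 uL DNA eluate, i.e. 1/20 of the filtered volume.

SURFACE_CM2_PER_ML <- 8.33
SOIL_WET_G_PER_ML <- 0.01
REACTION_FRACTION <- 1 / 20
PLATE_LLOD_CFU <- 1
PLATE_ULOQ_CFU <- 400

MATRIX_LEVELS <- c("source_water", "stored_water", "food_surface",
                   "latrine_soil", "household_soil")

# water / surface / soil class of a matrix label
matrix_class <- function(matrix) {
  matrix <- match.arg(matrix, MATRIX_LEVELS, several.ok = TRUE)
  out <- character(length(matrix))
  out[grepl("water", matrix)] <- "water"
  out[matrix == "food_surface"] <- "surface"
  out[grepl("soil", matrix)] <- "soil"
  out
}

#' Concentration unit implied by a sample matrix
#'
#' @param matrix one of \code{"source_water"}, \code{"stored_water"},
#'   \code{"food_surface"}, \code{"latrine_soil"}, \code{"household_soil"}.
#' @return \code{"per 100 mL"}, \code{"per 100 cm2"} or \code{"per dry g"}.
#' @export
matrix_unit <- function(matrix) {
  c(water = "per 100 mL", surface = "per 100 cm2",
    soil = "per dry g")[matrix_class(matrix)]
}

#' Gravimetric soil moisture fraction
#'
#' Moisture is the mass lost on drying divided by the initial wet mass.
#'
#' @param wet_g initial wet mass (g).
#' @param dry_g final dry mass (g); must satisfy 0 < dry_g <= wet_g.
#' @return moisture fraction in [0, 1).
#' @export
soil_moisture <- function(wet_g, dry_g) {
  if (any(dry_g <= 0) || any(wet_g <= 0)) {
    stop("soil_moisture: masses must be positive", call. = FALSE)
  }
  if (any(dry_g > wet_g)) {
    stop("soil_moisture: dry mass exceeds wet mass (measurement error)",
         call. = FALSE)
  }
  (wet_g - dry_g) / wet_g
}

#' Sampling effort of a plate or reaction
#'
#' Converts a processed volume into the amount of original matrix it
#' represents. Water volumes are normalized per 100 mL; surface eluate is
#' converted at 8.33 cm^2 per mL and normalized per 100 cm^2; soil eluate is
#' converted at 0.01 g wet soil per mL and then to dry mass via the moisture
#' fraction. A qPCR reaction represents 1/20 of the filtered volume
#' (\code{reaction_fraction = 1/20}); a culture plate represents the full
#' volume (\code{reaction_fraction = 1}). Five-fold template dilution of an
#' inhibited sample divides the effort by 5.
#'
#' @param matrix sample matrix (see \code{\link{matrix_unit}}).
#' @param volume_ml volume of water or eluate processed (mL), > 0.
#' @param moisture soil moisture fraction in [0, 1); required for soils.
#' @param reaction_fraction fraction of the filtered volume in the assayed
#'   unit: 1/20 for a qPCR reaction, 1 for a plate.
#' @param template_dilution fold-dilution of the DNA template (1 = undiluted,
#'   5 = inhibited sample diluted five-fold).
#' @return effort in matrix units (100 mL, 100 cm^2 or dry g).
#' @export
sampling_effort <- function(matrix, volume_ml, moisture = NA_real_,
                            reaction_fraction = 1,
                            template_dilution = 1) {
  if (any(volume_ml <= 0)) {
    stop("sampling_effort: volume must be positive", call. = FALSE)
  }
  if (any(template_dilution < 1)) {
    stop("sampling_effort: template_dilution must be >= 1", call. = FALSE)
  }
  cls <- matrix_class(matrix)
  n <- max(length(cls), length(volume_ml), length(moisture))
  cls <- rep_len(cls, n)
  volume_ml <- rep_len(volume_ml, n)
  moisture <- rep_len(moisture, n)
  soil <- cls == "soil"
  if (any(soil & !is.finite(moisture))) {
    stop("sampling_effort: soil effort requires a moisture fraction ",
         "(impute it first)", call. = FALSE)
  }
  if (any(soil & (moisture < 0 | moisture >= 1))) {
    stop("sampling_effort: moisture must lie in [0, 1)", call. = FALSE)
  }
  base <- numeric(n)
  base[cls == "water"] <- volume_ml[cls == "water"] / 100
  base[cls == "surface"] <- volume_ml[cls == "surface"] *
    SURFACE_CM2_PER_ML / 100
  base[soil] <- volume_ml[soil] * SOIL_WET_G_PER_ML * (1 - moisture[soil])
  base * reaction_fraction / template_dilution
}

# Default re-filter volume used when every initial plate is TNTC:
# 1 mL for water samples, 0.01 mL for surface and soil eluates.
refilter_volume <- function(matrix) {
  ifelse(matrix_class(matrix) == "water", 1, 0.01)
}

#' Process detection limits for culturable E. coli
#'
#' The plate-level limits are 1 cfu (detection) and 400 cfu (quantification,
#' the too-numerous-to-count ceiling). The process LLoD uses the largest
#' volume filtered (the scenario of a sample with no growth on any plate) and
#' the process ULoQ the smallest volume, including the re-filter volume used
#' when all initial plates are saturated (1 mL water, 0.01 mL eluate).
#'
#' @param matrix sample matrix.
#' @param volumes_ml volumes filtered across the sample's plates (mL).
#' @param moisture soil moisture fraction (soils only).
#' @param refilter_ml smallest achievable re-filter volume; defaults to the
#'   standard protocol volume for the matrix.
#' @return list with \code{llod} and \code{uloq} (natural concentration
#'   units), their log10 counterparts \code{log10_llod}, \code{log10_uloq},
#'   and \code{unit}.
#' @export
culture_limits <- function(matrix, volumes_ml, moisture = NA_real_,
                           refilter_ml = refilter_volume(matrix)) {
  if (length(volumes_ml) < 1L) {
    stop("culture_limits: need at least one plate volume", call. = FALSE)
  }
  eff_max <- sampling_effort(matrix, max(volumes_ml), moisture)
  eff_min <- sampling_effort(matrix, min(c(volumes_ml, refilter_ml)),
                             moisture)
  llod <- PLATE_LLOD_CFU / eff_max
  uloq <- PLATE_ULOQ_CFU / eff_min
  list(llod = llod, uloq = uloq,
       log10_llod = log10(llod), log10_uloq = log10(uloq),
       unit = unname(matrix_unit(matrix)))
}

#' Sample-specific molecular limit of detection
#'
#' The process LLoD of a qPCR target in a given sample is the log10
#' concentration whose expected Cq equals the ROC-derived detection cutoff,
#' computed per calibration posterior draw with the draw's run/batch-specific
#' intercept and slope and normalized by the sample's effort:
#' LLoD_d = (cutoff - a_d) / b_d - log10(effort).
#'
#' @param cutoff integer detection cutoff (Cq).
#' @param effort sampling effort of one reaction in matrix units (> 0).
#' @param posterior a \code{\link{fit_calibration}} result.
#' @param run,batch optional run / batch labels selecting group-specific
#'   curve parameters; population-level curve when omitted.
#' @return list with \code{mean} and \code{sd} over posterior draws,
#'   \code{draws}, and \code{n_dropped} nonnegative-slope draws excluded.
#' @export
molecular_llod <- function(cutoff, effort, posterior, run = NULL,
                           batch = NULL) {
  if (effort <= 0) stop("molecular_llod: effort must be > 0", call. = FALSE)
  ab <- curve_draws(posterior, run = run, batch = batch)
  ok <- ab$slope < 0
  x <- (cutoff - ab$intercept[ok]) / ab$slope[ok] - log10(effort)
  list(mean = mean(x), sd = stats::sd(x), draws = x,
       n_dropped = sum(!ok))
}

#' Chained-equations imputation of missing soil moisture
#'
#' Fills missing moisture fractions from auxiliary covariates (sun exposure,
#' surface wetness, meteorology) by multiple imputation with predictive mean
#' matching: each imputation regresses moisture on the auxiliaries over
#' complete records, perturbs the coefficients with a draw from their
#' sampling distribution (Bayesian linear regression with flat priors), and
#' replaces each missing value with an observed donor value whose prediction
#' is among the \code{donors} nearest. With moisture as the only incomplete
#' variable the chained-equations cycle reduces to this single imputation
#' model, so no between-variable iteration is needed; the auxiliaries must be
#' complete. The point value returned per record is the mean over
#' imputations, constrained to [0, 0.99].
#'
#' @param moisture numeric vector with NAs to impute.
#' @param covariates data.frame of complete auxiliary variables (numeric or
#'   factor-like), same number of rows.
#' @param m number of imputations (default 10).
#' @param donors donor pool size for predictive mean matching.
#' @param seed RNG seed.
#' @return list with \code{completed} (point values), \code{imputations}
#'   (n_missing x m matrix), and \code{missing} (indices imputed).
#' @export
impute_moisture <- function(moisture, covariates, m = 10L, donors = 5L,
                            seed = 1L) {
  n <- length(moisture)
  miss <- which(is.na(moisture))
  if (length(miss) == 0L) {
    return(list(completed = moisture, imputations = NULL,
                missing = integer(0)))
  }
  if (sum(!is.na(moisture)) < 5L) {
    stop("impute_moisture: need at least 5 complete moisture records",
         call. = FALSE)
  }
  covariates <- as.data.frame(covariates)
  if (anyNA(covariates)) {
    stop("impute_moisture: auxiliary covariates must be complete",
         call. = FALSE)
  }
  X <- stats::model.matrix(~ ., data = covariates)
  if (nrow(X) != n) {
    stop("impute_moisture: covariate rows must match moisture records",
         call. = FALSE)
  }
  obs <- setdiff(seq_len(n), miss)
  fit <- stats::lm.fit(X[obs, , drop = FALSE], moisture[obs])
  keep <- !is.na(fit$coefficients)
  beta <- fit$coefficients[keep]
  Xk <- X[, keep, drop = FALSE]
  dfres <- max(length(obs) - sum(keep), 1L)
  s2 <- sum(fit$residuals^2) / dfres
  XtXinv <- tryCatch(solve(crossprod(Xk[obs, , drop = FALSE])),
                     error = function(e) NULL)
  pred_obs <- as.numeric(Xk[obs, , drop = FALSE] %*% beta)
  set.seed(seed)
  imps <- matrix(NA_real_, length(miss), m)
  for (im in seq_len(m)) {
    bstar <- beta
    if (!is.null(XtXinv)) {
      sig2 <- dfres * s2 / stats::rchisq(1, dfres)
      ev <- eigen(sig2 * XtXinv, symmetric = TRUE)
      hl <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
      bstar <- beta + as.numeric(hl %*% stats::rnorm(length(beta)))
    }
    pred_miss <- as.numeric(Xk[miss, , drop = FALSE] %*% bstar)
    for (j in seq_along(miss)) {
      d <- abs(pred_obs - pred_miss[j])
      pool <- order(d)[seq_len(min(donors, length(obs)))]
      imps[j, im] <- moisture[obs][sample(pool, 1L)]
    }
  }
  completed <- moisture
  completed[miss] <- pmin(pmax(rowMeans(imps), 0), 0.99)
  list(completed = completed, imputations = imps, missing = miss)
}
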