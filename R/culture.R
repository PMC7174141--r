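# Plate-count arithmetic for culturable E. coli with censoring at the
# sample-specific process limits.

#' Culturable E. coli concentration from membrane-filtration plates
#'
#' Sums colony counts and efforts over all countable plates of a sample:
#' concentration = sum(cfu) / sum(effort). Plates flagged too numerous to
#' count (TNTC), or with numeric counts above the 400-cfu quantification
#' ceiling, are excluded from the sums. Zero-count plates are countable and
#' contribute their volume. A sample with zero colonies on every plate is
#' left-censored at its process LLoD; a sample with every plate TNTC is
#' right-censored at its process ULoQ.
#'
#' @param counts numeric cfu per plate; NA for TNTC plates.
#' @param volumes_ml volume filtered per plate (mL), parallel to
#'   \code{counts}.
#' @param matrix sample matrix (see \code{\link{matrix_unit}}).
#' @param moisture soil moisture fraction (soils only).
#' @param tntc optional logical TNTC flags; defaults to \code{is.na(counts)}.
#' @return one-row data.frame (class \code{concentration_estimate}) with
#'   \code{value} and \code{log10_value} (concentration in matrix units, NA
#'   when censored), \code{censoring}, \code{limit} (log10 scale),
#'   \code{detected}, and plate bookkeeping columns.
#' @export
cec_concentration <- function(counts, volumes_ml, matrix,
                              moisture = NA_real_, tntc = is.na(counts)) {
  if (length(counts) == 0L) {
    stop("cec_concentration: need >= 1 plate", call. = FALSE)
  }
  if (length(counts) != length(volumes_ml)) {
    stop("cec_concentration: counts and volumes lengths differ",
         call. = FALSE)
  }
  if (any(!is.na(counts) & counts < 0)) {
    stop("cec_concentration: negative colony count", call. = FALSE)
  }
  # numeric counts above the quantification ceiling are treated as TNTC
  tntc <- tntc | (!is.na(counts) & counts > PLATE_ULOQ_CFU)
  lims <- culture_limits(matrix, volumes_ml, moisture)
  countable <- which(!tntc)
  if (length(countable) == 0L) {
    out <- data.frame(value = NA_real_, log10_value = NA_real_,
                      censoring = "right", limit = lims$log10_uloq,
                      detected = TRUE, n_plates = length(counts),
                      n_countable = 0L, total_cfu = NA_real_)
  } else {
    total <- sum(counts[countable])
    eff <- sum(sampling_effort(matrix, volumes_ml[countable], moisture))
    if (total == 0 && any(tntc)) {
      # zero colonies alongside a saturated plate is contradictory; trust
      # the saturation signal and right-censor
      out <- data.frame(value = NA_real_, log10_value = NA_real_,
                        censoring = "right", limit = lims$log10_uloq,
                        detected = TRUE, n_plates = length(counts),
                        n_countable = length(countable), total_cfu = 0)
    } else if (total == 0) {
      out <- data.frame(value = NA_real_, log10_value = NA_real_,
                        censoring = "left", limit = lims$log10_llod,
                        detected = FALSE, n_plates = length(counts),
                        n_countable = length(countable), total_cfu = 0)
    } else {
      conc <- total / eff
      out <- data.frame(value = conc, log10_value = log10(conc),
                        censoring = "observed", limit = NA_real_,
                        detected = conc > 0, n_plates = length(counts),
                        n_countable = length(countable), total_cfu = total)
    }
  }
  class(out) <- c("concentration_estimate", "data.frame")
  out
}
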