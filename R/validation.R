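# Assay validation: detection cutoffs by ROC sweep with the Youden index,
# and host-level diagnostic performance.

#' Classify a qPCR reaction at a detection cutoff
#'
#' A reaction detects its target when it produced a numeric Cq strictly below
#' the assay's cutoff cycle; nondetects and Cq at or above the cutoff are
#' negative.
#'
#' @param cq numeric Cq values; NA encodes a non-amplifying reaction.
#' @param cutoff integer cutoff cycle (>= 1).
#' @return logical detection flags.
#' @export
classify_reaction <- function(cq, cutoff) {
  if (any(cutoff < 1)) stop("classify_reaction: cutoff must be >= 1",
                            call. = FALSE)
  !is.na(cq) & cq < cutoff
}

#' Sample-level detection from reaction-level flags
#'
#' A sample is positive for a target if the target was detected in any
#' reaction containing the sample's DNA template (any dilution, any
#' replicate).
#'
#' @param flags logical reaction-level detection flags for one sample.
#' @return single logical.
#' @export
sample_detection <- function(flags) {
  if (length(flags) == 0L) {
    stop("sample_detection: no reactions for sample", call. = FALSE)
  }
  any(flags)
}

#' ROC sweep over integer Cq cutoffs
#'
#' Sweeps detection cutoffs in one-Cq increments from \code{min_cq} to
#' \code{max_cq} (the assay's maximum cycle count), classifying every labeled
#' reaction (extraction blanks included, as non-targets) at each cutoff.
#' Sensitivity is the fraction of target reactions classified positive,
#' specificity the fraction of non-target reactions classified negative, and
#' J = sensitivity + specificity - 1 the Youden index.
#'
#' @param cq numeric Cq per reaction (NA = nondetect).
#' @param is_target logical; TRUE for reactions from target-host samples.
#' @param min_cq,max_cq inclusive integer sweep bounds; \code{10 <= min_cq <
#'   max_cq}.
#' @return data.frame with one row per cutoff: \code{cutoff},
#'   \code{sensitivity}, \code{specificity}, \code{accuracy}, \code{J}.
#' @export
roc_sweep <- function(cq, is_target, min_cq = 10L, max_cq = 45L) {
  if (length(cq) != length(is_target)) {
    stop("roc_sweep: cq and is_target lengths differ", call. = FALSE)
  }
  if (min_cq < 10L || min_cq >= max_cq) {
    stop("roc_sweep: need 10 <= min_cq < max_cq", call. = FALSE)
  }
  n_t <- sum(is_target)
  n_n <- sum(!is_target)
  if (n_t == 0L || n_n == 0L) {
    stop("roc_sweep: need both target and non-target reactions",
         call. = FALSE)
  }
  cutoffs <- seq.int(min_cq, max_cq)
  rows <- lapply(cutoffs, function(cc) {
    pos <- classify_reaction(cq, cc)
    sens <- sum(pos & is_target) / n_t
    spec <- sum(!pos & !is_target) / n_n
    data.frame(cutoff = cc, sensitivity = sens, specificity = spec,
               accuracy = (sum(pos & is_target) + sum(!pos & !is_target)) /
                 length(cq),
               J = sens + spec - 1)
  })
  do.call(rbind, rows)
}

#' Select the optimal detection cutoff
#'
#' Returns the highest whole Cq value that maximizes the Youden index over
#' the sweep.
#'
#' @param sweep result of \code{\link{roc_sweep}}.
#' @return integer cutoff.
#' @export
select_cutoff <- function(sweep) {
  if (nrow(sweep) == 0L) stop("select_cutoff: empty sweep", call. = FALSE)
  jmax <- max(sweep$J)
  max(sweep$cutoff[sweep$J >= jmax - 1e-12])
}

#' Sample-level diagnostic performance at a cutoff
#'
#' Aggregates reactions to sample-level detections (any positive reaction)
#' and reports sensitivity, specificity and accuracy over samples. Extraction
#' blanks contribute to the reaction-level ROC sweep but not to these
#' sample-level counts, which cover labeled fecal samples only. For assays
#' with no non-target samples (general fecal assays), specificity and
#' accuracy are undefined and reported as NA.
#'
#' @param cq numeric reaction Cq values (NA = nondetect).
#' @param sample_id sample identifier per reaction.
#' @param is_target logical per reaction (constant within sample).
#' @param cutoff integer cutoff cycle.
#' @return one-row data.frame: \code{cutoff}, \code{n}, \code{n_target},
#'   \code{n_nontarget}, \code{sensitivity}, \code{specificity},
#'   \code{accuracy}, \code{J}.
#' @export
diagnostic_summary <- function(cq, sample_id, is_target, cutoff) {
  flags <- classify_reaction(cq, cutoff)
  det <- tapply(flags, sample_id, sample_detection)
  lab <- tapply(is_target, sample_id, function(x) {
    u <- unique(x)
    if (length(u) != 1L) {
      stop("diagnostic_summary: sample with conflicting target labels",
           call. = FALSE)
    }
    u
  })
  lab <- lab[names(det)]
  tp <- sum(det & lab)
  tn <- sum(!det & !lab)
  n_t <- sum(lab)
  n_n <- sum(!lab)
  sens <- if (n_t > 0L) tp / n_t else NA_real_
  spec <- if (n_n > 0L) tn / n_n else NA_real_
  acc <- if (n_n > 0L && n_t > 0L) (tp + tn) / (n_t + n_n) else NA_real_
  data.frame(cutoff = cutoff, n = n_t + n_n, n_target = n_t,
             n_nontarget = n_n, sensitivity = sens, specificity = spec,
             accuracy = acc, J = sens + spec - 1)
}

#' Validate one assay end to end
#'
#' Runs the reaction-level ROC sweep, selects the Youden-optimal cutoff, and
#' reports sample-level diagnostics at that cutoff. Blank reactions (non-
#' target, no sample label) may be supplied via \code{blank_cq}; they enter
#' the sweep only.
#'
#' @param cq,sample_id,is_target labeled fecal-sample reactions as in
#'   \code{\link{diagnostic_summary}}.
#' @param max_cq assay maximum cycle count.
#' @param blank_cq optional numeric Cq of extraction blanks (NA = nondetect).
#' @param min_cq sweep lower bound.
#' @return list with \code{sweep}, \code{cutoff} and \code{summary}.
#' @export
validate_assay <- function(cq, sample_id, is_target, max_cq = 45L,
                           blank_cq = numeric(0), min_cq = 10L) {
  sweep <- roc_sweep(c(cq, blank_cq),
                     c(is_target, rep(FALSE, length(blank_cq))),
                     min_cq = min_cq, max_cq = max_cq)
  cutoff <- select_cutoff(sweep)
  list(sweep = sweep, cutoff = cutoff,
       summary = diagnostic_summary(cq, sample_id, is_target, cutoff))
}
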