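#' Per-sample signal quality assessment
#'
#' Computes the per-sample LRR standard deviation and the fitted GC-wave
#' slope (OLS of LRR on centered GC fraction), and flags the sample as
#' passing when the LRR SD does not exceed the cutoff. The 0.30 default is
#' the community-standard noise cutoff for array LRR.
#'
#' @param signal sample signal (`sample_id`, `lrr`, `baf`).
#' @param map probe map aligned to the signal.
#' @param lrr_sd_max pass threshold on the LRR standard deviation.
#' @return one-row data.frame: `sample_id`, `lrr_sd`, `gc_wave_coeff`,
#'   `passed`.
#' @export
assess_sample <- function(signal, map, lrr_sd_max = 0.30) {
  stopifnot(length(signal$lrr) == nrow(map))
  lrr <- signal$lrr
  if (all(is.na(lrr))) stop("all-missing LRR for sample ", signal$sample_id)
  lrr_sd <- sd(lrr, na.rm = TRUE)
  if (is.na(lrr_sd)) lrr_sd <- 0            # single non-missing probe
  gc <- map$gc_frac
  coeff <- NA_real_
  if (!all(is.na(gc)) && sd(gc, na.rm = TRUE) > 0) {
    gcc <- gc - mean(gc, na.rm = TRUE)
    fit <- lm(lrr ~ gcc, na.action = stats::na.exclude)
    coeff <- unname(coef(fit)[2])
  }
  data.frame(sample_id = signal$sample_id, lrr_sd = lrr_sd,
             gc_wave_coeff = coeff, passed = lrr_sd <= lrr_sd_max,
             stringsAsFactors = FALSE)
}

#' QC a whole cohort of signals
#'
#' @param signals list of sample signals.
#' @param map probe map.
#' @param lrr_sd_max pass threshold, as in [assess_sample()].
#' @return data.frame with one QC row per sample.
#' @export
assess_cohort <- function(signals, map, lrr_sd_max = 0.30) {
  do.call(rbind, lapply(signals, assess_sample, map = map,
                        lrr_sd_max = lrr_sd_max))
}

#' GC-wave correction of a sample's LRR
#'
#' Ordinary least squares of LRR on centered GC fraction; the corrected LRR
#' is the residual plus the original mean (so the sample mean is preserved
#' and the corrected signal is orthogonal to GC). BAF is untouched. With
#' zero GC variance the correction is skipped with a warning.
#'
#' @param signal sample signal.
#' @param map probe map with `gc_frac`.
#' @return the signal with corrected `lrr`.
#' @export
gc_correct <- function(signal, map) {
  gc <- map$gc_frac
  stopifnot(length(signal$lrr) == nrow(map))
  if (all(is.na(gc)) || sd(gc, na.rm = TRUE) == 0) {
    warning("zero GC variance; correction skipped for sample ",
            signal$sample_id)
    return(signal)
  }
  gcc <- gc - mean(gc, na.rm = TRUE)
  fit <- lm(signal$lrr ~ gcc, na.action = stats::na.exclude)
  res <- stats::residuals(fit)
  corrected <- as.numeric(res) + mean(signal$lrr, na.rm = TRUE)
  signal$lrr <- unname(corrected)
  signal
}

#' Remove implausibly long CNV calls
#'
#' Calls longer than the cutoff (default 8 Mb) are split off; such events
#' are treated as likely pathological rather than segregating variation.
#' The partition is exhaustive and disjoint; the boundary is inclusive
#' (a call of exactly the cutoff length is kept).
#'
#' @param calls `cnv_calls` data.frame.
#' @param max_len_bp length cutoff in bp.
#' @return list `kept`, `removed`.
#' @export
filter_long_calls <- function(calls, max_len_bp = 8e6) {
  len <- calls$end_bp - calls$start_bp + 1
  keep <- len <= max_len_bp
  list(kept = calls[keep, , drop = FALSE],
       removed = calls[!keep, , drop = FALSE])
}
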