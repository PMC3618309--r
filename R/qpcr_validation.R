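#' Copy number from qPCR Ct triplicates by the delta-delta-Ct method
#'
#' dCt = mean(target Ct) - mean(reference Ct) per assay; ddCt = dCt(sample)
#' - dCt(calibrator), with the calibrator assumed diploid; CN = 2 *
#' base^(-ddCt) with amplification base 2 (perfect doubling per cycle).
#' A target censored at the no-amplification ceiling in all replicates
#' yields CN = 0. The estimate is left continuous; rounding to integer
#' states is the caller's choice.
#'
#' @param assay one assay row (`ct_target_1..3`, `ct_reference_1..3`).
#' @param calibrator_assay the calibrator sample's assay for the same
#'   region.
#' @param amp_base amplification factor per cycle (2 = perfect
#'   efficiency).
#' @param ct_ceiling censoring ceiling in cycles.
#' @return estimated copy number (non-negative real).
#' @export
delta_delta_ct <- function(assay, calibrator_assay, amp_base = 2,
                           ct_ceiling = 55) {
  tgt <- as.numeric(assay[c("ct_target_1", "ct_target_2", "ct_target_3")])
  ref <- as.numeric(assay[c("ct_reference_1", "ct_reference_2",
                            "ct_reference_3")])
  tgt <- tgt[!is.na(tgt)]; ref <- ref[!is.na(ref)]
  if (length(tgt) < 3 || length(ref) < 3)
    warning("fewer than 3 replicates in assay")
  if (all(tgt >= ct_ceiling)) return(0)
  ct <- as.numeric(calibrator_assay[c("ct_target_1", "ct_target_2",
                                      "ct_target_3")])
  cr <- as.numeric(calibrator_assay[c("ct_reference_1", "ct_reference_2",
                                      "ct_reference_3")])
  dct <- mean(tgt) - mean(ref)
  dct_cal <- mean(ct, na.rm = TRUE) - mean(cr, na.rm = TRUE)
  ddct <- dct - dct_cal
  2 * amp_base^(-ddct)
}

#' Estimate copy numbers for a table of assays
#'
#' Applies [delta_delta_ct()] to every assay against its region's
#' calibrator assay.
#'
#' @param assays assay data.frame as produced by [simulate_qpcr()] or read
#'   from the qPCR TSV.
#' @param amp_base,ct_ceiling see [delta_delta_ct()].
#' @return the assays with a `qpcr_cn` column appended.
#' @export
estimate_qpcr_cn <- function(assays, amp_base = 2, ct_ceiling = 55) {
  assays$qpcr_cn <- vapply(seq_len(nrow(assays)), function(i) {
    cal <- assays[assays$sample_id == assays$calibrator_sample_id[i] &
                    assays$region_id == assays$region_id[i], , drop = FALSE]
    if (!nrow(cal)) stop("no calibrator assay for region ",
                         assays$region_id[i])
    delta_delta_ct(assays[i, ], cal[1, ], amp_base, ct_ceiling)
  }, 0)
  assays
}

#' Regress qPCR copy number on array copy number
#'
#' Ordinary least squares qpcr_cn ~ array_cn over assayed pairs, the
#' validation analysis relating continuous qPCR estimates to integer array
#' states. Reports the slope with its standard error, two-sided t-test
#' p-value, adjusted R^2 and the pair count.
#'
#' @param pairs data.frame with columns `array_cn` (integer) and `qpcr_cn`
#'   (real).
#' @return one-row data.frame: `slope`, `slope_se`, `adj_r2`, `p_value`,
#'   `n`.
#' @export
regress_validation <- function(pairs) {
  if (nrow(pairs) < 3) stop("need at least 3 assayed pairs")
  if (sd(pairs$array_cn) == 0) stop("degenerate regressor: array_cn constant")
  if (sd(pairs$qpcr_cn) == 0) {
    return(data.frame(slope = 0, slope_se = 0, adj_r2 = 0, p_value = 1,
                      n = nrow(pairs)))
  }
  fit <- lm(qpcr_cn ~ array_cn, data = pairs)
  sm <- summary(fit)
  data.frame(slope = unname(coef(fit)[2]),
             slope_se = sm$coefficients[2, 2],
             adj_r2 = sm$adj.r.squared,
             p_value = sm$coefficients[2, 4],
             n = nrow(pairs))
}

#' Write / read the qPCR assay TSV
#'
#' @param assays assay data.frame.
#' @param path file path.
#' @return `path` invisibly (writer); assay data.frame (reader).
#' @export
write_qpcr_table <- function(assays, path) {
  utils::write.table(assays, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_table
#' @export
read_qpcr_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
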