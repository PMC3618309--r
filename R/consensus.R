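#' Merge two caller tracks into a consensus call set
#'
#' Where the two tracks call overlapping events in the same sample on the
#' same chromosome with the same sign (both gains or both losses), the call
#' with the higher Bayes factor is kept and the other dropped (ties keep
#' the A-track call). Non-overlapping calls from either track pass through
#' (union semantics), and a gain never merges with a loss. All output calls
#' carry `source = "consensus"`.
#'
#' @param callsA,callsB `cnv_calls` from tracks A and B.
#' @return `cnv_calls` with `source = "consensus"`.
#' @export
merge_dual_calls <- function(callsA, callsB) {
  callsA <- as.data.frame(callsA); callsB <- as.data.frame(callsB)
  keepA <- rep(TRUE, nrow(callsA)); keepB <- rep(TRUE, nrow(callsB))
  if (nrow(callsA) && nrow(callsB)) {
    signA <- ifelse(callsA$cn > 2, "gain", "loss")
    signB <- ifelse(callsB$cn > 2, "gain", "loss")
    gA <- paste(callsA$sample_id, callsA$chrom, signA)
    gB <- paste(callsB$sample_id, callsB$chrom, signB)
    for (g in intersect(unique(gA), unique(gB))) {
      ia <- which(gA == g); ib <- which(gB == g)
      ra <- IRanges::IRanges(as.integer(callsA$start_bp[ia]),
                             as.integer(callsA$end_bp[ia]))
      rb <- IRanges::IRanges(as.integer(callsB$start_bp[ib]),
                             as.integer(callsB$end_bp[ib]))
      hits <- IRanges::findOverlaps(ra, rb, minoverlap = 1L)
      for (h in seq_along(hits)) {
        a <- ia[S4Vectors::queryHits(hits)[h]]
        b <- ib[S4Vectors::subjectHits(hits)[h]]
        if (callsA$bf[a] >= callsB$bf[b]) keepB[b] <- FALSE
        else keepA[a] <- FALSE
      }
    }
  }
  out <- rbind(callsA[keepA, , drop = FALSE], callsB[keepB, , drop = FALSE])
  if (nrow(out)) out$source <- "consensus"
  ord <- order(out$chrom, out$start_bp, out$end_bp, out$sample_id)
  validate_cnv_calls(out[ord, , drop = FALSE])
}

#' Apply the Bayes-factor confidence threshold
#'
#' Inclusive comparison: a call with bf exactly at the threshold is
#' retained. The pipeline default of 15 is the value at which the
#' qPCR-calibrated false-positive rate flattens.
#'
#' @param calls `cnv_calls`.
#' @param bf_min threshold (log10 scale).
#' @return filtered `cnv_calls`.
#' @export
apply_bf_threshold <- function(calls, bf_min = 15) {
  calls[!is.na(calls$bf) & calls$bf >= bf_min | is.na(calls$bf) & bf_min <= 0,
        , drop = FALSE]
}

#' Collapse redundant calls to unique CNVs
#'
#' Unique key is the exact (chrom, start, end, cn) tuple; the
#' representative per key is the member with the highest Bayes factor and
#' the multiplicity is the carrier count.
#'
#' @param calls `cnv_calls`.
#' @return list `unique_calls` (`cnv_calls` with a `multiplicity` column)
#'   and `multiplicity` (named integer vector keyed by
#'   "chrom:start-end:cn").
#' @export
deduplicate <- function(calls) {
  if (!nrow(calls))
    return(list(unique_calls = calls, multiplicity = integer()))
  key <- sprintf("%d:%.0f-%.0f:%d", calls$chrom, calls$start_bp,
                 calls$end_bp, calls$cn)
  ord <- order(calls$chrom, calls$start_bp, calls$end_bp, calls$cn,
               -ifelse(is.na(calls$bf), -Inf, calls$bf))
  first <- !duplicated(key[ord])
  uniq <- calls[ord, , drop = FALSE][first, , drop = FALSE]
  mult <- table(key)
  uniq$multiplicity <- as.integer(mult[sprintf(
    "%d:%.0f-%.0f:%d", uniq$chrom, uniq$start_bp, uniq$end_bp, uniq$cn)])
  rownames(uniq) <- NULL
  list(unique_calls = uniq,
       multiplicity = setNames(as.integer(mult), names(mult)))
}

#' Bayes-factor threshold sweep against qPCR copy numbers
#'
#' At each threshold the surviving calls define an array copy number for
#' every assayed (sample, region) pair — the cn of the highest-bf
#' surviving call overlapping the region for that sample, else the diploid
#' 2 — and qPCR CN is regressed on array CN by OLS. The adjusted R^2
#' (1 - (1 - R^2)(n - 1)/(n - 2)) tracks the false-positive rate: spurious
#' low-bf calls depress it.
#'
#' @param calls consensus `cnv_calls` (pre-threshold).
#' @param assays data.frame `sample_id`, `region_id`, `qpcr_cn`.
#' @param regions data.frame `region_id`, `chrom`, `start_bp`, `end_bp`.
#' @param thresholds Bayes-factor thresholds to sweep.
#' @return data.frame of class `bf_sweep`: `threshold`, `n_calls`,
#'   `n_unique`, `adj_r2`.
#' @export
bf_sweep <- function(calls, assays, regions,
                     thresholds = c(10, 15, 20, 30)) {
  if (nrow(assays) < 3) stop("fewer than 3 assayed pairs")
  stopifnot(all(assays$region_id %in% regions$region_id))
  res <- lapply(thresholds, function(t) {
    surv <- apply_bf_threshold(calls, t)
    array_cn <- vapply(seq_len(nrow(assays)), function(i) {
      reg <- regions[regions$region_id == assays$region_id[i], ][1, ]
      hit <- surv[surv$sample_id == assays$sample_id[i] &
                    surv$chrom == reg$chrom &
                    surv$start_bp <= reg$end_bp &
                    surv$end_bp >= reg$start_bp, , drop = FALSE]
      if (nrow(hit)) hit$cn[which.max(hit$bf)] else 2L
    }, 0L)
    adj <- adjusted_r2(assays$qpcr_cn, array_cn)
    data.frame(threshold = t, n_calls = nrow(surv),
               n_unique = nrow(deduplicate(surv)$unique_calls),
               adj_r2 = adj)
  })
  out <- do.call(rbind, res)
  class(out) <- c("bf_sweep", class(out))
  out
}

# adjusted R^2 of y ~ x with p = 1 regressor; degenerate x (no variance)
# yields R^2 = 0, reported as computed (can be negative after adjustment)
adjusted_r2 <- function(y, x) {
  n <- length(y)
  r2 <- if (sd(x) == 0 || sd(y) == 0) 0 else {
    fit <- lm(y ~ x)
    summary(fit)$r.squared
  }
  1 - (1 - r2) * (n - 1) / (n - 2)
}
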