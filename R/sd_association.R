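#' Fraction of intervals intersecting a segmental-duplication track
#'
#' An interval counts as intersecting when it shares >= 1 bp with any SD
#' interval on the same chromosome.
#'
#' @param intervals data.frame with `chrom`, `start_bp`, `end_bp` (unique
#'   CNVs, post-deduplication, by default usage).
#' @param sd_track `feature_intervals` with `kind = "SD"`.
#' @return overlap fraction in \[0, 1\].
#' @export
overlap_fraction <- function(intervals, sd_track) {
  if (!nrow(intervals)) stop("empty interval list")
  mean(overlaps_any(intervals$chrom, intervals$start_bp, intervals$end_bp,
                    sd_track$chrom, sd_track$start_bp, sd_track$end_bp))
}

# Sorted-start / running-max-end overlap predicate, vectorized over query
# segments; used inside the permutation loop for speed. Equivalent to an
# any-overlap test against the SD track (cross-checked against IRanges in
# the test suite).
sd_index <- function(sd_track, n_chrom) {
  lapply(seq_len(n_chrom), function(ch) {
    idx <- which(sd_track$chrom == ch)
    if (!length(idx)) return(NULL)
    o <- order(sd_track$start_bp[idx])
    list(start = sd_track$start_bp[idx][o],
         max_end = cummax(sd_track$end_bp[idx][o]))
  })
}

seg_overlaps_sd <- function(chrom, start, end, index) {
  out <- logical(length(chrom))
  for (ch in unique(chrom)) {
    ix <- index[[ch]]
    sel <- chrom == ch
    if (is.null(ix)) next
    k <- findInterval(end[sel], ix$start)     # SDs with start <= end
    hit <- k > 0
    hit[hit] <- ix$max_end[k[hit]] >= start[sel][hit]
    out[sel] <- hit
  }
  out
}

#' Permutation test for CNV / segmental-duplication colocalization
#'
#' Each permutation draws as many segments as there are observed CNVs:
#' lengths sampled with replacement from the observed CNV length
#' distribution, chromosome chosen with probability proportional to its
#' placeable span, start uniform so the segment fits. The add-one
#' empirical p-value (1 + #\{null >= observed\}) / (n_perm + 1) never
#' reaches zero; 1000 permutations give a resolution floor of ~0.001.
#' Permuted segments may overlap one another.
#'
#' @param cnv_lengths observed CNV lengths in bp.
#' @param sd_track SD `feature_intervals`.
#' @param chrom_lengths autosome lengths in bp.
#' @param observed observed overlap fraction (from [overlap_fraction()]).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list of class `permutation_result`: `observed_overlap_fraction`,
#'   `null_fractions`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(cnv_lengths, sd_track, chrom_lengths,
                             observed, n_perm = 1000L, seed = 1L) {
  stopifnot(length(cnv_lengths) > 0, n_perm >= 1)
  if (any(cnv_lengths > max(chrom_lengths)))
    stop("a CNV length exceeds every chromosome")
  set.seed(seed)
  n_seg <- length(cnv_lengths)
  total <- n_perm * n_seg
  index <- sd_index(sd_track, length(chrom_lengths))

  len <- cnv_lengths[sample.int(length(cnv_lengths), total, replace = TRUE)]
  # chromosome ~ placeable span (depends on each segment's length)
  W <- outer(len, chrom_lengths, function(l, L) pmax(0, L - l + 1))
  if (any(rowSums(W) == 0)) stop("a sampled length fits no chromosome")
  cw <- W / rowSums(W)
  if (ncol(cw) > 1) for (j in 2:ncol(cw)) cw[, j] <- cw[, j - 1] + cw[, j]
  u <- runif(total)
  chrom <- rowSums(cw < u) + 1L
  span <- chrom_lengths[chrom] - len + 1
  start <- floor(runif(total, 1, span + 1))
  end <- start + len - 1

  hit <- seg_overlaps_sd(chrom, start, end, index)
  null_fractions <- colMeans(matrix(hit, nrow = n_seg))
  p <- (1 + sum(null_fractions >= observed)) / (n_perm + 1)
  structure(list(observed_overlap_fraction = observed,
                 null_fractions = null_fractions, p_value = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permutation_result")
}

#' Run the full SD association analysis on a call set
#'
#' Computes the observed overlap fraction of the (deduplicated) CNVs with
#' the SD track and its permutation p-value.
#'
#' @param calls `cnv_calls` (deduplicated to unique CNVs unless
#'   `unique_only = FALSE`).
#' @param sd_track SD `feature_intervals`.
#' @param chrom_lengths autosome lengths.
#' @param n_perm,seed see [permutation_test()].
#' @param unique_only test unique CNVs (default) or all redundant calls.
#' @return `permutation_result`.
#' @export
sd_association <- function(calls, sd_track, chrom_lengths, n_perm = 1000L,
                           seed = 1L, unique_only = TRUE) {
  if (unique_only) calls <- deduplicate(calls)$unique_calls
  obs <- overlap_fraction(calls, sd_track)
  permutation_test(calls$end_bp - calls$start_bp + 1, sd_track,
                   chrom_lengths, obs, n_perm = n_perm, seed = seed)
}
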