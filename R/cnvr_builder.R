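#' Aggregate CNV calls into CNV regions (CNVRs)
#'
#' CNVRs are the connected components of the interval-overlap graph (>= 1
#' bp overlap on the same chromosome, transitive closure), the union-CNVR
#' construction standard in the array-CNV literature. Each region's
#' envelope is the min start / max end of its members; regions are
#' numbered deterministically by (chrom, start).
#'
#' @param calls `cnv_calls` passing QC and the confidence threshold.
#' @param cohort_n post-QC cohort size (frequency denominator).
#' @return data.frame of regions: `region_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_calls`, `n_samples`, `frequency`, `category`
#'   (gain/loss/both), `n_gain`, `n_loss`, and a `member_ids` list column
#'   of member row indices into `calls`.
#' @export
build_cnvrs <- function(calls, cohort_n) {
  if (!nrow(calls)) {
    out <- data.frame(region_id = character(), chrom = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_calls = integer(), n_samples = integer(),
                      frequency = numeric(), category = character(),
                      n_gain = integer(), n_loss = integer(),
                      stringsAsFactors = FALSE)
    out$member_ids <- list()
    return(out)
  }
  rows <- list()
  for (ch in sort(unique(calls$chrom))) {
    idx <- which(calls$chrom == ch)
    ir <- IRanges::IRanges(as.integer(calls$start_bp[idx]),
                           as.integer(calls$end_bp[idx]))
    # min.gapwidth = 0: merge only on >= 1 bp overlap, not mere adjacency
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hits <- IRanges::findOverlaps(ir, red)
    comp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
    for (k in seq_along(red)) {
      members <- idx[comp == k]
      cns <- calls$cn[members]
      rows[[length(rows) + 1]] <- list(
        chrom = ch, start_bp = min(calls$start_bp[members]),
        end_bp = max(calls$end_bp[members]),
        n_calls = length(members),
        n_samples = length(unique(calls$sample_id[members])),
        category = if (all(cns > 2)) "gain" else if (all(cns < 2)) "loss"
                   else "both",
        n_gain = sum(cns > 2), n_loss = sum(cns < 2),
        member_ids = members)
    }
  }
  out <- data.frame(
    chrom = vapply(rows, `[[`, 0, "chrom"),
    start_bp = vapply(rows, `[[`, 0, "start_bp"),
    end_bp = vapply(rows, `[[`, 0, "end_bp"),
    n_calls = vapply(rows, `[[`, 0L, "n_calls"),
    n_samples = vapply(rows, `[[`, 0L, "n_samples"),
    category = vapply(rows, `[[`, "", "category"),
    n_gain = vapply(rows, function(r) as.integer(r$n_gain), 0L),
    n_loss = vapply(rows, function(r) as.integer(r$n_loss), 0L),
    stringsAsFactors = FALSE)
  if (cohort_n < max(out$n_samples))
    stop("cohort_n smaller than a region's sample count")
  ord <- order(out$chrom, out$start_bp, out$end_bp)
  out <- out[ord, , drop = FALSE]
  out$frequency <- out$n_samples / cohort_n
  out$region_id <- sprintf("CNVR%04d", seq_len(nrow(out)))
  out$member_ids <- lapply(rows, `[[`, "member_ids")[ord]
  rownames(out) <- NULL
  out[, c("region_id", "chrom", "start_bp", "end_bp", "n_calls",
          "n_samples", "frequency", "category", "n_gain", "n_loss",
          "member_ids")]
}

#' Count CNVRs above population-frequency thresholds
#'
#' Strict inequality: a region at exactly a threshold frequency is not
#' counted in that class.
#'
#' @param regions CNVR data.frame with a `frequency` column.
#' @param thresholds frequency cutoffs.
#' @return named integer vector of counts per threshold.
#' @export
frequency_classes <- function(regions, thresholds = c(0.01, 0.02, 0.05)) {
  vapply(thresholds, function(t) sum(regions$frequency > t), 0L) |>
    setNames(paste0(">", thresholds * 100, "%"))
}

#' Genome coverage of the CNVR set
#'
#' Length of the union of region envelopes (overlaps never double-count)
#' and its fraction of the summed autosome lengths.
#'
#' @param regions CNVR data.frame.
#' @param chrom_lengths autosome lengths in bp (autosome i at index i).
#' @return list `covered_bp`, `fraction`.
#' @export
genome_coverage <- function(regions, chrom_lengths) {
  if (!nrow(regions)) return(list(covered_bp = 0, fraction = 0))
  if (any(regions$end_bp > chrom_lengths[regions$chrom]))
    stop("region extends beyond chromosome end")
  covered <- 0
  for (ch in unique(regions$chrom)) {
    idx <- regions$chrom == ch
    ir <- IRanges::IRanges(as.integer(regions$start_bp[idx]),
                           as.integer(regions$end_bp[idx]))
    covered <- covered + sum(IRanges::width(IRanges::reduce(ir)))
  }
  list(covered_bp = covered, fraction = covered / sum(chrom_lengths))
}
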