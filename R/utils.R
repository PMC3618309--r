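#' Round half away from zero
#'
#' Fixed-decimal rounding with halves going up in absolute value, the
#' convention used for all printed percentages and ratios in the cohort
#' tables (base R `round()` uses banker's rounding).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  trunc(abs(x) * p + 0.5) * sign(x) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a CNV call table
#'
#' Standard per-call container used throughout the pipeline: one row per
#' called variant with 1-based inclusive coordinates, an integer copy number
#' in \{0, 1, 3, 4\} (2 is the diploid null and never a call), the number of
#' supporting probes, a non-negative log10-scale Bayes factor and the track
#' of origin.
#'
#' @param sample_id character vector.
#' @param chrom integer chromosome (autosome) numbers.
#' @param start_bp,end_bp 1-based inclusive interval bounds, start <= end.
#' @param cn integer copy numbers in \{0, 1, 3, 4\}.
#' @param n_probes supporting probe counts (>= 1).
#' @param bf non-negative Bayes factors (log10 scale); NA allowed for truth
#'   sets that carry no confidence score.
#' @param source one of "A", "B", "consensus", "truth".
#' @return data.frame of class `cnv_calls`.
#' @export
cnv_calls <- function(sample_id = character(), chrom = integer(),
                      start_bp = integer(), end_bp = integer(),
                      cn = integer(), n_probes = integer(),
                      bf = numeric(), source = character()) {
  df <- data.frame(
    sample_id = as.character(sample_id), chrom = as.integer(chrom),
    start_bp = as.numeric(start_bp), end_bp = as.numeric(end_bp),
    cn = as.integer(cn), n_probes = as.integer(n_probes),
    bf = as.numeric(bf), source = as.character(source),
    stringsAsFactors = FALSE
  )
  validate_cnv_calls(df)
}

validate_cnv_calls <- function(df) {
  if (nrow(df)) {
    if (any(df$cn == 2L, na.rm = TRUE))
      stop("cn = 2 is the diploid null and cannot be a CNV call")
    if (!all(df$cn %in% c(0L, 1L, 3L, 4L)))
      stop("cn must be in {0, 1, 3, 4}")
    if (any(df$end_bp < df$start_bp))
      stop("end_bp must be >= start_bp")
    if (any(df$n_probes < 1L, na.rm = TRUE))
      stop("n_probes must be >= 1")
    if (any(df$bf < 0, na.rm = TRUE))
      stop("bf must be non-negative")
  }
  class(df) <- unique(c("cnv_calls", class(df)))
  df
}

#' Construct a genomic feature table (SDs or genes)
#'
#' @param chrom integer chromosome numbers.
#' @param start_bp,end_bp 1-based inclusive bounds.
#' @param kind "SD" or "gene".
#' @param gene_id optional gene identifiers (genes only).
#' @param biotype optional biotypes (genes only).
#' @return data.frame of class `feature_intervals`.
#' @export
feature_intervals <- function(chrom = integer(), start_bp = integer(),
                              end_bp = integer(), kind = character(),
                              gene_id = NA_character_,
                              biotype = NA_character_) {
  n <- max(length(chrom), length(start_bp), length(end_bp))
  if (!length(chrom)) n <- 0L
  df <- data.frame(
    chrom = rep_len(as.integer(chrom), n),
    start_bp = rep_len(as.numeric(start_bp), n),
    end_bp = rep_len(as.numeric(end_bp), n),
    kind = rep_len(as.character(kind), n),
    gene_id = rep_len(as.character(gene_id), n),
    biotype = rep_len(as.character(biotype), n),
    stringsAsFactors = FALSE
  )
  if (n && any(df$end_bp < df$start_bp))
    stop("feature end_bp must be >= start_bp")
  class(df) <- unique(c("feature_intervals", class(df)))
  df
}

# IRanges helper: list of per-chromosome IRanges keyed by chromosome
split_iranges <- function(chrom, start, end) {
  idx <- split(seq_along(chrom), chrom)
  lapply(idx, function(i) {
    ir <- IRanges::IRanges(start = as.integer(start[i]),
                           end = as.integer(end[i]))
    S4Vectors::mcols(ir)$row <- i
    ir
  })
}

# Does each query interval overlap (>= 1 bp) any subject interval?
# Both sides given as parallel vectors with integer chromosome ids.
overlaps_any <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  out <- logical(length(q_chrom))
  if (!length(q_chrom) || !length(s_chrom)) return(out)
  s_by <- split(seq_along(s_chrom), s_chrom)
  q_by <- split(seq_along(q_chrom), q_chrom)
  for (ch in names(q_by)) {
    qi <- q_by[[ch]]
    si <- s_by[[ch]]
    if (is.null(si)) next
    qr <- IRanges::IRanges(as.integer(q_start[qi]), as.integer(q_end[qi]))
    sr <- IRanges::IRanges(as.integer(s_start[si]), as.integer(s_end[si]))
    out[qi] <- IRanges::countOverlaps(qr, sr, minoverlap = 1L) > 0L
  }
  out
}
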