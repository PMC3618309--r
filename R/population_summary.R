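#' Genotype-class table for a call set
#'
#' Counts and percentages of calls per copy-number class (homozygous
#' deletion 0, heterozygous deletion 1, three-copy 3, four-copy 4),
#' gain/loss totals and their ratio. Percentages are half-up rounded to 2
#' decimals and always recompute from the counts.
#'
#' @param calls `cnv_calls`, or a named integer vector of counts per class
#'   (names "0","1","3","4") for direct tabulations.
#' @return list of class `class_table`: `counts`, `total`, `percent`,
#'   `n_gain`, `n_loss`, `loss_gain_ratio` (NA when no gains).
#' @export
genotype_class_table <- function(calls) {
  counts <- if (is.data.frame(calls)) {
    vapply(c("0", "1", "3", "4"), function(s)
      sum(calls$cn == as.integer(s)), 0L)
  } else {
    stopifnot(identical(sort(names(calls)), c("0", "1", "3", "4")))
    as.integer(calls[c("0", "1", "3", "4")]) |>
      setNames(c("0", "1", "3", "4"))
  }
  total <- sum(counts)
  percent <- if (total > 0) round_half_up(100 * counts / total, 2)
             else setNames(rep(NA_real_, 4), names(counts))
  n_gain <- unname(counts["3"] + counts["4"])
  n_loss <- unname(counts["0"] + counts["1"])
  ratio <- if (n_gain > 0) round_half_up(n_loss / n_gain, 2) else NA_real_
  structure(list(counts = counts, total = total, percent = percent,
                 n_gain = n_gain, n_loss = n_loss,
                 loss_gain_ratio = ratio), class = "class_table")
}

#' Loss/gain ratio over CNV regions
#'
#' Ratio of loss-bearing regions (>= 1 loss member; categories loss and
#' both) to gain-bearing regions (categories gain and both), half-up
#' rounded to 2 decimals. A region of category "both" counts in numerator
#' and denominator.
#'
#' @param regions CNVR data.frame with a `category` column.
#' @return ratio, or NA when no region bears a gain.
#' @export
region_class_ratio <- function(regions) {
  loss_bearing <- sum(regions$category %in% c("loss", "both"))
  gain_bearing <- sum(regions$category %in% c("gain", "both"))
  if (gain_bearing == 0) return(NA_real_)
  round_half_up(loss_bearing / gain_bearing, 2)
}

#' Mean CNV count per autosome
#'
#' Total call count divided by the autosome count, half-up rounded to the
#' nearest integer for display; the raw mean is attached as attribute
#' `"raw"`.
#'
#' @param calls `cnv_calls`, or a single total count.
#' @param n_autosomes number of autosomes.
#' @return rounded mean with attribute `raw`.
#' @export
per_chromosome_mean <- function(calls, n_autosomes = 29L) {
  n <- if (is.data.frame(calls)) nrow(calls) else as.numeric(calls)
  raw <- n / n_autosomes
  structure(round_half_up(raw, 0), raw = raw)
}

recurrence_bins <- c("1", "2", "3", "4-5", "6-10", "10-25", ">25")

bin_recurrence <- function(mult) {
  cut(mult, breaks = c(0.5, 1.5, 2.5, 3.5, 5.5, 9.5, 25.5, Inf),
      labels = recurrence_bins)
}

#' Per-breed cohort summaries
#'
#' For each breed: sample and call counts, per-sample rate, unique CNVs
#' (distinct chrom/start/end/cn keys), breed-specific CNVs (keys absent
#' from every other breed), gain/loss counts, CNVR count, the recurrence
#' spectrum over unique CNVs (carriers-per-CNV bins 1 / 2 / 3 / 4-5 /
#' 6-10 / 10-25 / >25, the overlapping printed bins disambiguated as 6-9
#' and 10-25), per-chromosome call percentages (1 decimal) and CNV length
#' statistics. Rates and spectrum percentages are half-up rounded to 2
#' decimals.
#'
#' @param calls `cnv_calls` for the whole cohort.
#' @param samples sample table (`sample_id`, `breed`) incl. CNV-free
#'   samples.
#' @param chroms autosome numbers the per-chromosome percentages cover.
#' @return list of per-breed summary lists, named by breed.
#' @export
breed_summaries <- function(calls, samples, chroms = 1:29) {
  if (nrow(calls) && !all(calls$sample_id %in% samples$sample_id))
    stop("call from a sample missing in the breed table")
  key <- sprintf("%d:%.0f-%.0f:%d", calls$chrom, calls$start_bp,
                 calls$end_bp, calls$cn)
  breed_of <- samples$breed[match(calls$sample_id, samples$sample_id)]
  out <- lapply(unique(samples$breed), function(b) {
    idx <- which(breed_of == b)
    bc <- calls[idx, , drop = FALSE]
    n_samples <- sum(samples$breed == b)
    dd <- deduplicate(bc)
    uniq <- dd$unique_calls
    other_keys <- unique(key[breed_of != b])
    spec_n <- sum(!(sprintf("%d:%.0f-%.0f:%d", uniq$chrom, uniq$start_bp,
                            uniq$end_bp, uniq$cn) %in% other_keys))
    spectrum <- table(bin_recurrence(uniq$multiplicity))
    spectrum <- as.integer(spectrum[recurrence_bins]) |>
      setNames(recurrence_bins)
    spectrum[is.na(spectrum)] <- 0L
    spectrum_pct <- if (nrow(uniq))
      round_half_up(100 * spectrum / nrow(uniq), 2) else spectrum * NA_real_
    per_chrom <- vapply(chroms, function(ch) sum(bc$chrom == ch), 0L) |>
      setNames(paste0("BTA", chroms))
    per_chrom_pct <- if (nrow(bc))
      round_half_up(100 * per_chrom / nrow(bc), 1) else per_chrom * NA_real_
    lens <- bc$end_bp - bc$start_bp + 1
    list(breed = b, n_samples = n_samples, cnv_count = nrow(bc),
         cnv_per_sample = round_half_up(nrow(bc) / n_samples, 2),
         unique_count = nrow(uniq), specific_count = spec_n,
         gain_count = sum(bc$cn > 2), loss_count = sum(bc$cn < 2),
         cnvr_count = nrow(build_cnvrs(bc, n_samples)),
         spectrum = spectrum, spectrum_pct = spectrum_pct,
         per_chrom_count = per_chrom, per_chrom_percent = per_chrom_pct,
         length_mean = if (nrow(bc)) mean(lens) else NA_real_,
         length_median = if (nrow(bc)) median(lens) else NA_real_,
         length_min = if (nrow(bc)) min(lens) else NA_real_,
         length_max = if (nrow(bc)) max(lens) else NA_real_)
  })
  names(out) <- unique(samples$breed)
  out
}

#' Recurrence-spectrum percentages from counts
#'
#' Direct arithmetic used by the breed tables: percentages of unique CNVs
#' per carriers-per-CNV bin, half-up rounded to 2 decimals.
#'
#' @param counts integer vector of bin counts.
#' @return percentages summing to ~100.
#' @export
spectrum_percent <- function(counts) {
  round_half_up(100 * counts / sum(counts), 2)
}

#' Pairwise Wilcoxon rank-sum comparisons between breeds
#'
#' Two-sided Wilcoxon-Mann-Whitney test for every breed pair: exact null
#' distribution when min(n, m) <= 8 and there are no ties, normal
#' approximation with continuity and tie correction otherwise. Pairs where
#' both groups are a single constant value get p = 1.
#'
#' @param values_by_breed named list: numeric vector per breed.
#' @return symmetric matrix of p-values (diagonal NA).
#' @export
compare_breeds <- function(values_by_breed) {
  breeds <- names(values_by_breed)
  stopifnot(length(breeds) >= 2,
            all(lengths(values_by_breed) >= 1))
  P <- matrix(NA_real_, length(breeds), length(breeds),
              dimnames = list(breeds, breeds))
  for (i in seq_along(breeds)) for (j in seq_along(breeds)) {
    if (j <= i) next
    x <- values_by_breed[[i]]; y <- values_by_breed[[j]]
    ties <- anyDuplicated(c(x, y)) > 0
    p <- if (sd(c(x, y)) == 0) 1 else {
      use_exact <- min(length(x), length(y)) <= 8 && !ties
      suppressWarnings(
        wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
    }
    if (is.nan(p)) p <- 1
    P[i, j] <- P[j, i] <- p
  }
  P
}
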