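#' Assign genes to CNV/CNVR intervals
#'
#' A gene is assigned to an interval when the gene body shares >= 1 bp
#' with it; a gene may appear under many intervals. Gene lists per
#' interval are ordered by genomic coordinate.
#'
#' @param intervals data.frame with `chrom`, `start_bp`, `end_bp`.
#' @param genes gene `feature_intervals` (with `gene_id`, `biotype`).
#' @return list parallel to `intervals` rows; each element a character
#'   vector of gene ids.
#' @export
annotate_intervals <- function(intervals, genes) {
  out <- rep(list(character()), nrow(intervals))
  if (!nrow(intervals) || !nrow(genes)) return(out)
  ord <- order(genes$chrom, genes$start_bp, genes$end_bp)
  genes <- genes[ord, , drop = FALSE]
  for (ch in unique(intervals$chrom)) {
    qi <- which(intervals$chrom == ch)
    si <- which(genes$chrom == ch)
    if (!length(si)) next
    qr <- IRanges::IRanges(as.integer(intervals$start_bp[qi]),
                           as.integer(intervals$end_bp[qi]))
    sr <- IRanges::IRanges(as.integer(genes$start_bp[si]),
                           as.integer(genes$end_bp[si]))
    hits <- IRanges::findOverlaps(qr, sr, minoverlap = 1L)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    for (k in unique(q))
      out[[qi[k]]] <- genes$gene_id[si][sort(s[q == k])]
  }
  out
}

#' Tally biotypes over the union of assigned genes
#'
#' Counts and fractions are over the deduplicated union of all assigned
#' genes: a gene hit by several CNVs counts once.
#'
#' @param annotation list of gene-id vectors from [annotate_intervals()].
#' @param genes gene `feature_intervals` supplying biotypes.
#' @return data.frame `biotype`, `count`, `fraction` (fractions of the
#'   union size, summing to 1 when any gene is assigned).
#' @export
biotype_tally <- function(annotation, genes) {
  ids <- unique(unlist(annotation))
  if (!length(ids))
    return(data.frame(biotype = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  bt <- genes$biotype[match(ids, genes$gene_id)]
  tab <- table(bt)
  data.frame(biotype = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / length(ids),
             stringsAsFactors = FALSE, row.names = NULL)
}
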