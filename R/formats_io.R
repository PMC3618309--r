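#' Read a per-probe signal table
#'
#' Reads an Illumina final-report-like TSV with columns `Sample ID`,
#' `SNP Name`, `Chr`, `Position`, `Log R Ratio`, `B Allele Freq` (long
#' format: one row per sample x probe). Only autosomes 1-29 are retained;
#' records on other chromosomes are skipped and counted. All samples must
#' share one probe set.
#'
#' @param path path to the TSV file.
#' @return list with elements `map` (probe map data.frame: `probe_id`,
#'   `chrom`, `pos_bp`, `gc_frac` — GC is NA when the file carries none),
#'   `samples` (list of sample signals: `sample_id`, `breed`, `lrr`, `baf`),
#'   and attribute-like element `n_skipped` (non-autosomal record count).
#' @export
read_signal_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("Sample ID", "SNP Name", "Chr", "Position",
            "Log R Ratio", "B Allele Freq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("signal table is missing columns: ", paste(miss, collapse = ", "))

  pos <- suppressWarnings(as.numeric(df$Position))
  lrr <- suppressWarnings(as.numeric(df$`Log R Ratio`))
  baf <- suppressWarnings(as.numeric(df$`B Allele Freq`))
  bad <- which(is.na(pos) | (is.na(lrr) & df$`Log R Ratio` != "") |
                 df$`SNP Name` == "" | df$`Sample ID` == "")
  if (length(bad))
    stop("malformed signal row at line ", bad[1] + 1L,
         " (1 header line counted)")

  autosomal <- df$Chr %in% as.character(1:29)
  n_skipped <- sum(!autosomal)
  if (n_skipped)
    message("read_signal_table: skipped ", n_skipped,
            " non-autosomal probe record(s)")
  df <- df[autosomal, , drop = FALSE]
  pos <- pos[autosomal]; lrr <- lrr[autosomal]; baf <- baf[autosomal]
  if (!nrow(df)) stop("no autosomal records in ", path)

  sample_ids <- unique(df$`Sample ID`)            # first-appearance order
  first <- df$`Sample ID` == sample_ids[1]
  ord <- order(as.integer(df$Chr[first]), pos[first])
  map <- data.frame(
    probe_id = df$`SNP Name`[first][ord],
    chrom = as.integer(df$Chr[first])[ord],
    pos_bp = pos[first][ord],
    gc_frac = if ("GC" %in% names(df))
      suppressWarnings(as.numeric(df$GC[first][ord])) else NA_real_,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(map$probe_id))
    stop("duplicate probe_id in signal table: ",
         map$probe_id[duplicated(map$probe_id)][1])

  samples <- lapply(sample_ids, function(sid) {
    rows <- which(df$`Sample ID` == sid)
    key <- match(map$probe_id, df$`SNP Name`[rows])
    if (anyNA(key) || length(rows) != nrow(map)) {
      divergent <- if (anyNA(key)) map$probe_id[which(is.na(key))[1]] else
        setdiff(df$`SNP Name`[rows], map$probe_id)[1]
      stop("inconsistent probe sets across samples; first divergent probe: ",
           divergent)
    }
    list(sample_id = sid,
         breed = if ("Breed" %in% names(df)) df$Breed[rows][key][1]
                 else NA_character_,
         lrr = lrr[rows][key],
         baf = baf[rows][key])
  })
  list(map = map, samples = samples, n_skipped = n_skipped)
}

#' Write a per-probe signal table
#'
#' Inverse of [read_signal_table()]; LRR/BAF printed to 6 decimals.
#'
#' @param map probe map data.frame.
#' @param samples list of sample signals.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(map, samples, path) {
  rows <- lapply(samples, function(s) {
    data.frame(`Sample ID` = s$sample_id, `SNP Name` = map$probe_id,
               Chr = map$chrom, Position = map$pos_bp,
               `Log R Ratio` = sprintf("%.6f", s$lrr),
               `B Allele Freq` = ifelse(is.na(s$baf), "",
                                        sprintf("%.6f", s$baf)),
               Breed = s$breed %||% NA_character_,
               GC = if (all(is.na(map$gc_frac))) "" else
                 sprintf("%.6f", map$gc_frac),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample CNV calls in a caller's text dialect
#'
#' Two dialects are supported. `penncnv`: whitespace-separated lines of the
#' form `chr1:1000-2000 numsnp=10 length=1,001 state2,cn=1 <sample>
#' startsnp=rs1 endsnp=rs2 conf=20.5`. `quantisnp`: a tab table whose header
#' includes sample, chromosome, start, end, copy number, probe count and log
#' Bayes factor columns. Confidence/log BF is mapped onto the common `bf`
#' field; the source track is "A" for penncnv-style and "B" for
#' quantisnp-style input.
#'
#' @param path input file.
#' @param dialect "penncnv" or "quantisnp".
#' @return `cnv_calls` data.frame.
#' @export
read_caller_calls <- function(path, dialect = c("penncnv", "quantisnp")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "penncnv") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(cnv_calls())
    pat <- paste0("^chr([0-9XYM]+):([0-9]+)-([0-9]+)\\s+numsnp=([0-9]+)\\s+",
                  "length=([0-9,]+)\\s+state([0-9]+),cn=([0-9]+)\\s+(\\S+)\\s+",
                  "startsnp=(\\S+)\\s+endsnp=(\\S+)(?:\\s+conf=(-?[0-9.]+))?")
    m <- regmatches(lines, regexec(pat, lines))
    ok <- lengths(m) > 0
    if (any(!ok)) stop("malformed penncnv line ", which(!ok)[1])
    f <- function(i) vapply(m, `[`, "", i + 1L)
    chrom <- f(1); cn <- as.integer(f(7)); conf <- as.numeric(f(11))
    conf[is.na(conf)] <- 0
    if (any(conf < 0)) stop("negative conf in penncnv input")
    keep <- chrom %in% as.character(1:29)
    if (any(!keep))
      message("read_caller_calls: skipped ", sum(!keep),
              " non-autosomal call(s)")
    cn2 <- cn == 2L & keep
    if (any(cn2)) {
      warning(sum(cn2), " record(s) with cn=2 rejected")
      keep <- keep & cn != 2L
    }
    cnv_calls(sample_id = f(8)[keep], chrom = as.integer(chrom[keep]),
              start_bp = as.numeric(f(2))[keep],
              end_bp = as.numeric(f(3))[keep], cn = cn[keep],
              n_probes = as.integer(f(4))[keep], bf = conf[keep],
              source = "A")
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!nrow(df)) return(cnv_calls())
    ln <- tolower(names(df))
    pick <- function(pat) {
      i <- grep(pat, ln)[1]
      if (is.na(i)) stop("quantisnp table lacks a column matching '",
                         pat, "'")
      df[[i]]
    }
    samp <- as.character(pick("sample"))
    chrom <- as.character(pick("chromosome|^chr"))
    start <- as.numeric(pick("start"))
    end <- as.numeric(pick("end"))
    cn <- as.integer(pick("copy"))
    np <- as.integer(pick("probe|snp"))
    bf <- as.numeric(pick("bayes|bf|conf"))
    if (any(bf < 0, na.rm = TRUE)) stop("negative log Bayes factor")
    keep <- chrom %in% as.character(1:29)
    if (any(!keep))
      message("read_caller_calls: skipped ", sum(!keep),
              " non-autosomal call(s)")
    cn2 <- cn == 2L & keep
    if (any(cn2)) {
      warning(sum(cn2), " record(s) with cn=2 rejected")
      keep <- keep & cn != 2L
    }
    cnv_calls(sample_id = samp[keep], chrom = as.integer(chrom[keep]),
              start_bp = start[keep], end_bp = end[keep], cn = cn[keep],
              n_probes = np[keep], bf = bf[keep], source = "B")
  }
}

#' Write CNV calls in a caller text dialect
#'
#' Emits files [read_caller_calls()] can re-read; used to exercise the
#' dialect round trip and to archive per-track calls.
#'
#' @param calls `cnv_calls` data.frame.
#' @param path output file.
#' @param dialect "penncnv" or "quantisnp".
#' @return `path`, invisibly.
#' @export
write_caller_calls <- function(calls, path,
                               dialect = c("penncnv", "quantisnp")) {
  dialect <- match.arg(dialect)
  if (dialect == "penncnv") {
    state <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)[as.character(calls$cn)]
    lines <- sprintf(
      "chr%d:%.0f-%.0f numsnp=%d length=%.0f state%d,cn=%d %s startsnp=p%d endsnp=p%d conf=%.3f",
      calls$chrom, calls$start_bp, calls$end_bp, calls$n_probes,
      calls$end_bp - calls$start_bp + 1, state, calls$cn, calls$sample_id,
      seq_len(nrow(calls)), seq_len(nrow(calls)), calls$bf)
    writeLines(lines, path)
  } else {
    df <- data.frame(`Sample Name` = calls$sample_id,
                     Chromosome = calls$chrom,
                     `Start Position (bp)` = calls$start_bp,
                     `End Position (bp)` = calls$end_bp,
                     `Copy Number` = calls$cn, `No. Probes` = calls$n_probes,
                     `Log Bayes Factor` = calls$bf,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read genomic features (SD or gene tracks)
#'
#' BED input (0-based half-open) is normalized to the pipeline's 1-based
#' inclusive convention (`start + 1`); GFF3 is already 1-based inclusive.
#' Gene identifiers come from BED column 4 or GFF3 `ID=`/`gene_id=`
#' attributes; biotype from a `biotype=`/`gene_biotype=` attribute
#' (defaulting to "other" for gene features that carry none).
#'
#' @param path input file.
#' @param format "bed" or "gff3".
#' @param kind "SD" or "gene".
#' @return `feature_intervals` data.frame. Duplicate lines are retained.
#' @export
read_features <- function(path, format = c("bed", "gff3"),
                          kind = c("SD", "gene")) {
  format <- match.arg(format); kind <- match.arg(kind)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines))
    return(feature_intervals(kind = character()))
  parts <- strsplit(lines, "\t")
  if (format == "bed") {
    chrom <- vapply(parts, `[`, "", 1)
    start <- as.numeric(vapply(parts, `[`, "", 2)) + 1  # 0-based -> 1-based
    end <- as.numeric(vapply(parts, `[`, "", 3))
    gene_id <- vapply(parts, function(p) if (length(p) >= 4) p[4]
                      else NA_character_, "")
    biotype <- rep(if (kind == "gene") "other" else NA_character_,
                   length(chrom))
  } else {
    if (any(lengths(parts) < 9))
      stop("malformed GFF3 line ", which(lengths(parts) < 9)[1])
    chrom <- vapply(parts, `[`, "", 1)
    start <- as.numeric(vapply(parts, `[`, "", 4))
    end <- as.numeric(vapply(parts, `[`, "", 5))
    attr9 <- vapply(parts, `[`, "", 9)
    get_attr <- function(a, keys) {
      for (k in keys) {
        m <- regmatches(a, regexec(paste0("(?:^|;)", k, "=([^;]+)"), a))[[1]]
        if (length(m)) return(m[2])
      }
      NA_character_
    }
    gene_id <- vapply(attr9, get_attr, "", keys = c("ID", "gene_id"),
                      USE.NAMES = FALSE)
    biotype <- vapply(attr9, get_attr, "",
                      keys = c("biotype", "gene_biotype"), USE.NAMES = FALSE)
    if (kind == "gene") biotype[is.na(biotype)] <- "other"
  }
  chrom <- sub("^chr", "", chrom)
  bad <- which(end < start)
  if (length(bad))
    stop("feature end < start after normalization at line ", bad[1])
  keep <- chrom %in% as.character(1:29)
  if (any(!keep))
    message("read_features: skipped ", sum(!keep),
            " non-autosomal feature(s)")
  feature_intervals(chrom = as.integer(chrom[keep]),
                    start_bp = start[keep], end_bp = end[keep],
                    kind = kind, gene_id = gene_id[keep],
                    biotype = if (kind == "gene") biotype[keep]
                              else NA_character_)
}

#' Write / read the per-CNV output table
#'
#' Deterministic TSV sorted by (chrom, start); field-for-field re-readable.
#'
#' @param calls `cnv_calls` data.frame.
#' @param path output path.
#' @return `path` invisibly (writer); `cnv_calls` (reader).
#' @export
write_cnv_table <- function(calls, path) {
  ord <- order(calls$chrom, calls$start_bp, calls$end_bp, calls$sample_id)
  df <- as.data.frame(calls)[ord, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cnv_table
#' @export
read_cnv_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) return(cnv_calls())
  cnv_calls(sample_id = df$sample_id, chrom = df$chrom,
            start_bp = df$start_bp, end_bp = df$end_bp, cn = df$cn,
            n_probes = df$n_probes, bf = df$bf, source = df$source)
}

#' Write / read the per-CNVR output table
#'
#' @param regions CNVR data.frame from [build_cnvrs()].
#' @param path output path.
#' @return `path` invisibly (writer); CNVR data.frame (reader, without the
#'   member list column).
#' @export
write_cnvr_table <- function(regions, path) {
  df <- as.data.frame(regions[, setdiff(names(regions), "member_ids")])
  if (!is.null(regions$member_ids))
    df$member_ids <- vapply(regions$member_ids, paste, "", collapse = ",")
  ord <- order(df$chrom, df$start_bp)
  utils::write.table(df[ord, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cnvr_table
#' @export
read_cnvr_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
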