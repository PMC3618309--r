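#' Cohort specification for the synthetic-data generator
#'
#' Defaults encode the study conditions the downstream analyses assume at
#' desk scale: a 30-bull cohort split across the five breeds in the same
#' proportions as the real panel, two 50 Mb autosomes genotyped at 49 kb
#' mean probe spacing, CNV lengths log-normal with median 700 kb and sigma
#' chosen so the mean/median ratio is 930/700, copy-number class weights
#' 92:5259:1592:550 (CN 0/1/3/4), and a mostly-rare frequency spectrum with
#' 90% singleton mass and rare-locus carrier frequencies drawn Beta(1, 19).
#'
#' @param breeds named integer vector: samples per breed.
#' @param chrom_lengths_bp autosome lengths in bp (autosome i has length
#'   `chrom_lengths_bp[i]`).
#' @param mean_probe_spacing_bp mean inter-probe gap (exponential gaps).
#' @param n_cnvr_loci number of CNV loci to place.
#' @param singleton_mass probability a locus is carried by exactly one
#'   sample.
#' @param common_freq_shape Beta shape parameters for non-singleton carrier
#'   frequency.
#' @param length_median_bp median CNV length.
#' @param length_sigma log-normal sigma of CNV length.
#' @param cn_class_weights weights for CN classes 0/1/3/4 (normalized
#'   internally).
#' @param seed integer RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(breeds = c("Italian Friesian" = 10L,
                                   "Italian Brown" = 8L,
                                   "Italian Simmental" = 5L,
                                   "Piedmontese" = 4L,
                                   "Marchigiana" = 3L),
                        chrom_lengths_bp = c(50e6, 50e6),
                        mean_probe_spacing_bp = 49000,
                        n_cnvr_loci = 40L,
                        singleton_mass = 0.9,
                        common_freq_shape = c(1, 19),
                        length_median_bp = 700e3,
                        length_sigma = sqrt(2 * log(930 / 700)),
                        cn_class_weights = c(`0` = 92, `1` = 5259,
                                             `3` = 1592, `4` = 550),
                        seed = 1L) {
  stopifnot(all(chrom_lengths_bp > 0), mean_probe_spacing_bp > 0,
            length_median_bp > 0, length_sigma > 0,
            all(cn_class_weights >= 0), sum(cn_class_weights) > 0,
            singleton_mass >= 0, singleton_mass <= 1)
  w <- cn_class_weights / sum(cn_class_weights)
  if (!identical(names(w), c("0", "1", "3", "4")))
    stop("cn_class_weights must be named '0','1','3','4'")
  structure(list(breeds = breeds, chrom_lengths_bp = chrom_lengths_bp,
                 mean_probe_spacing_bp = mean_probe_spacing_bp,
                 n_cnvr_loci = as.integer(n_cnvr_loci),
                 singleton_mass = singleton_mass,
                 common_freq_shape = common_freq_shape,
                 length_median_bp = length_median_bp,
                 length_sigma = length_sigma,
                 cn_class_weights = w, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Noise specification for signal simulation
#'
#' LRR per-state emission means follow the de-facto SNP-array convention
#' (-3.0 / -0.66 / 0 / +0.40 / +0.68 for CN 0..4); per-probe LRR noise,
#' BAF cluster noise and an optional GC wave are configurable.
#'
#' @param lrr_sd per-probe LRR standard deviation.
#' @param baf_sd BAF cluster standard deviation.
#' @param gc_wave_amplitude slope of LRR on centered GC fraction.
#' @param lrr_mean_by_cn named numeric, LRR means for CN 0..4
#'   (non-decreasing).
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(lrr_sd = 0.15, baf_sd = 0.03, gc_wave_amplitude = 0,
                       lrr_mean_by_cn = c(`0` = -3.0, `1` = -0.66, `2` = 0,
                                          `3` = 0.40, `4` = 0.68)) {
  stopifnot(lrr_sd >= 0, baf_sd >= 0, gc_wave_amplitude >= 0,
            !is.unsorted(lrr_mean_by_cn))
  structure(list(lrr_sd = lrr_sd, baf_sd = baf_sd,
                 gc_wave_amplitude = gc_wave_amplitude,
                 lrr_mean_by_cn = lrr_mean_by_cn), class = "noise_spec")
}

#' Simulate a probe map
#'
#' Inter-probe gaps are i.i.d. exponential with the configured mean, giving
#' Poisson-level variation around the expected probe count; the GC fraction
#' is a smooth AR(1) track mapped into \[0.3, 0.7\].
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return probe map data.frame: `probe_id`, `chrom`, `pos_bp`, `gc_frac`,
#'   sorted and strictly increasing within chromosome.
#' @export
make_probe_map <- function(spec, seed = spec$seed) {
  if (any(spec$chrom_lengths_bp <= spec$mean_probe_spacing_bp))
    stop("probe spacing exceeds a chromosome length")
  set.seed(seed)
  maps <- lapply(seq_along(spec$chrom_lengths_bp), function(ch) {
    len <- spec$chrom_lengths_bp[ch]
    n_guess <- ceiling(len / spec$mean_probe_spacing_bp * 1.6) + 20
    pos <- cumsum(ceiling(rexp(n_guess, 1 / spec$mean_probe_spacing_bp)))
    while (pos[length(pos)] < len) {
      pos <- c(pos, pos[length(pos)] +
                 cumsum(ceiling(rexp(n_guess, 1 / spec$mean_probe_spacing_bp))))
    }
    pos <- pos[pos <= len]
    n <- length(pos)
    phi <- 0.98
    z <- as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - phi^2)), phi,
                                  method = "recursive"))
    gc <- 0.5 + 0.2 * (2 * pnorm(z) - 1)
    data.frame(probe_id = sprintf("bta%d_p%06d", ch, seq_len(n)),
               chrom = ch, pos_bp = pos, gc_frac = gc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  out
}

#' Sample table implied by a cohort spec
#'
#' @param spec a [cohort_spec()].
#' @return data.frame `sample_id`, `breed`.
#' @export
cohort_samples <- function(spec) {
  breed <- rep(names(spec$breeds), spec$breeds)
  data.frame(sample_id = sprintf("S%03d", seq_along(breed)), breed = breed,
             stringsAsFactors = FALSE)
}

#' Simulate a truth set of CNVs
#'
#' Places `n_cnvr_loci` CNV loci uniformly on the genome (chromosome chosen
#' proportional to placeable span), draws per-locus carrier sets from the
#' singleton/rare mixture, and per-carrier copy-number classes from the
#' class weights. Homozygous deletions are kept at very low frequency: for
#' loci with more than two carriers, CN 0 draws are redrawn from the
#' remaining classes. Every truth call covers at least 3 probes (loci are
#' resampled up to a retry cap otherwise).
#'
#' @param spec a [cohort_spec()].
#' @param map probe map from [make_probe_map()].
#' @param seed RNG seed (default `spec$seed + 1`).
#' @return `cnv_calls` with `source = "truth"`, plus a `locus` column
#'   (integer locus index shared by carriers of the same event).
#' @export
make_truth_set <- function(spec, map, seed = spec$seed + 1L) {
  set.seed(seed)
  samples <- cohort_samples(spec)
  n_samp <- nrow(samples)
  classes <- c(0L, 1L, 3L, 4L)
  chrom_len <- spec$chrom_lengths_bp

  place_locus <- function() {
    for (try in 1:200) {
      len <- ceiling(rlnorm(1, meanlog = log(spec$length_median_bp),
                            sdlog = spec$length_sigma))
      span <- pmax(0, chrom_len - len + 1)
      if (all(span == 0)) next
      ch <- sample.int(length(chrom_len), 1, prob = span)
      start <- floor(runif(1, 1, span[ch] + 1))
      end <- start + len - 1
      n_probes <- sum(map$chrom == ch & map$pos_bp >= start &
                        map$pos_bp <= end)
      if (n_probes >= 3) return(list(chrom = ch, start = start, end = end,
                                     n_probes = n_probes))
    }
    stop("could not place a CNV locus covering >= 3 probes")
  }

  out <- vector("list", spec$n_cnvr_loci)
  for (j in seq_len(spec$n_cnvr_loci)) {
    loc <- place_locus()
    if (runif(1) < spec$singleton_mass) {
      n_carriers <- 1L
    } else {
      f <- rbeta(1, spec$common_freq_shape[1], spec$common_freq_shape[2])
      n_carriers <- max(2L, rbinom(1, n_samp, f))
    }
    carriers <- sample(samples$sample_id, n_carriers)
    cn <- sample(classes, n_carriers, replace = TRUE,
                 prob = spec$cn_class_weights)
    if (n_carriers > 2L && any(cn == 0L)) {
      w <- spec$cn_class_weights[-1] / sum(spec$cn_class_weights[-1])
      cn[cn == 0L] <- sample(classes[-1], sum(cn == 0L), replace = TRUE,
                             prob = w)
    }
    out[[j]] <- data.frame(sample_id = carriers, chrom = loc$chrom,
                           start_bp = loc$start, end_bp = loc$end, cn = cn,
                           n_probes = loc$n_probes, bf = NA_real_,
                           source = "truth", locus = j,
                           stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, out)
  rownames(truth) <- NULL
  validate_cnv_calls(truth)
}

#' Simulate LRR/BAF signals for a cohort
#'
#' Per probe i in state s: LRR ~ Normal(mean_by_cn\[s\] + wave_i, lrr_sd)
#' where wave_i = gc_wave_amplitude * (gc_i - mean gc). BAF is drawn from
#' the state's genotype clusters (CN2: \{0, 1/2, 1\}; CN1: \{0, 1\}; CN0:
#' uniform noise; CN3: \{0, 1/3, 2/3, 1\}; CN4: \{0, 1/4, 1/2, 3/4, 1\}),
#' cluster perturbed Normal(0, baf_sd) and clipped to \[0, 1\].
#'
#' @param truth truth calls from [make_truth_set()].
#' @param map probe map.
#' @param samples sample table (`sample_id`, `breed`); defaults to the
#'   carriers present in `truth`.
#' @param noise a [noise_spec()].
#' @param seed RNG seed.
#' @return list of sample signals (`sample_id`, `breed`, `lrr`, `baf`).
#' @export
simulate_signals <- function(truth, map, samples, noise = noise_spec(),
                             seed = 1L) {
  set.seed(seed)
  n <- nrow(map)
  gc_centered <- if (all(is.na(map$gc_frac))) rep(0, n)
                 else map$gc_frac - mean(map$gc_frac)
  wave <- noise$gc_wave_amplitude * gc_centered
  clusters <- list(`0` = NULL, `1` = c(0, 1), `2` = c(0, 0.5, 1),
                   `3` = c(0, 1/3, 2/3, 1), `4` = c(0, 0.25, 0.5, 0.75, 1))
  lapply(seq_len(nrow(samples)), function(i) {
    sid <- samples$sample_id[i]
    state <- rep(2L, n)
    tr <- truth[truth$sample_id == sid, , drop = FALSE]
    if (nrow(tr)) for (k in seq_len(nrow(tr))) {
      idx <- map$chrom == tr$chrom[k] & map$pos_bp >= tr$start_bp[k] &
        map$pos_bp <= tr$end_bp[k]
      state[idx] <- tr$cn[k]
    }
    lrr <- noise$lrr_mean_by_cn[as.character(state)] + wave +
      rnorm(n, sd = noise$lrr_sd)
    baf <- numeric(n)
    for (s in c("0", "1", "2", "3", "4")) {
      idx <- which(state == as.integer(s))
      if (!length(idx)) next
      if (s == "0") {
        baf[idx] <- runif(length(idx))
      } else {
        mu <- sample(clusters[[s]], length(idx), replace = TRUE)
        baf[idx] <- pmin(1, pmax(0, mu + rnorm(length(idx),
                                               sd = noise$baf_sd)))
      }
    }
    list(sample_id = sid, breed = samples$breed[i], lrr = unname(lrr),
         baf = baf)
  })
}

#' Simulate a segmental-duplication track
#'
#' A fraction (1 - 1/enrichment) of SD intervals is placed overlapping
#' randomly chosen truth loci; the remainder uniformly on the genome.
#' SD lengths are log-normal with median 50 kb.
#'
#' @param truth truth calls (one row per carrier; loci deduplicated
#'   internally).
#' @param chrom_lengths_bp autosome lengths.
#' @param enrichment >= 1; 1 means fully uniform placement.
#' @param n_sd number of SD intervals.
#' @param seed RNG seed.
#' @param sd_length_median_bp,sd_length_sigma SD length distribution.
#' @return `feature_intervals` with `kind = "SD"`.
#' @export
simulate_sd_track <- function(truth, chrom_lengths_bp, enrichment = 1,
                              n_sd = 60L, seed = 1L,
                              sd_length_median_bp = 5e4,
                              sd_length_sigma = 0.5) {
  stopifnot(enrichment >= 1)
  set.seed(seed)
  loci <- unique(truth[, c("chrom", "start_bp", "end_bp")])
  lens <- pmin(ceiling(rlnorm(n_sd, log(sd_length_median_bp),
                              sd_length_sigma)),
               max(chrom_lengths_bp))
  targeted <- runif(n_sd) < (1 - 1 / enrichment) & nrow(loci) > 0
  chrom <- integer(n_sd); start <- numeric(n_sd)
  for (i in seq_len(n_sd)) {
    if (targeted[i]) {
      j <- sample.int(nrow(loci), 1)
      chrom[i] <- loci$chrom[j]
      lo <- max(1, loci$start_bp[j] - lens[i] + 1)
      hi <- min(loci$end_bp[j], chrom_lengths_bp[chrom[i]] - lens[i] + 1)
      if (hi < lo) hi <- lo
      start[i] <- floor(runif(1, lo, hi + 1))
    } else {
      span <- pmax(1, chrom_lengths_bp - lens[i] + 1)
      chrom[i] <- sample.int(length(chrom_lengths_bp), 1, prob = span)
      start[i] <- floor(runif(1, 1, span[chrom[i]] + 1))
    }
  }
  end <- pmin(start + lens - 1, chrom_lengths_bp[chrom])
  feature_intervals(chrom = chrom, start_bp = start, end_bp = end,
                    kind = "SD")
}

#' Simulate a gene track
#'
#' Uniformly placed gene bodies with a biotype mix that mirrors an
#' annotated mammalian autosome set (87% protein coding, 12% non-coding
#' RNA, 1% pseudogene).
#'
#' @param chrom_lengths_bp autosome lengths.
#' @param n_genes number of genes.
#' @param seed RNG seed.
#' @return `feature_intervals` with `kind = "gene"`.
#' @export
simulate_gene_track <- function(chrom_lengths_bp, n_genes = 400L, seed = 1L) {
  set.seed(seed)
  lens <- ceiling(rlnorm(n_genes, log(3e4), 0.8))
  span <- outer(chrom_lengths_bp, lens, function(L, l) pmax(1, L - l + 1))
  chrom <- vapply(seq_len(n_genes), function(i)
    sample.int(length(chrom_lengths_bp), 1, prob = span[, i]), 1L)
  start <- floor(runif(n_genes, 1, pmax(1, chrom_lengths_bp[chrom] -
                                          lens + 1) + 1))
  biotypes <- sample(c("protein_coding", "miRNA", "rRNA", "snRNA", "snoRNA",
                       "misc_RNA", "pseudogene"), n_genes, replace = TRUE,
                     prob = c(0.87, 0.035, 0.012, 0.033, 0.02, 0.01, 0.02))
  feature_intervals(chrom = chrom, start_bp = start,
                    end_bp = pmin(start + lens - 1, chrom_lengths_bp[chrom]),
                    kind = "gene",
                    gene_id = sprintf("GENE%04d", seq_len(n_genes)),
                    biotype = biotypes)
}

#' Simulate qPCR Ct triplicates for assayed (sample, region) pairs
#'
#' Target Ct = base - log2(CN_true / 2) + Normal(0, ct_sd) per replicate;
#' reference Ct = base + Normal(0, ct_sd). A true CN of 0 yields no
#' amplification: target Ct is set to the censoring ceiling (55 cycles).
#' Each region's calibrator is a sample with true CN 2.
#'
#' @param truth truth calls.
#' @param assayed_pairs data.frame `sample_id`, `region_id`, `chrom`,
#'   `start_bp`, `end_bp` naming the assayed intervals.
#' @param ct_sd replicate Ct standard deviation (cycles).
#' @param seed RNG seed.
#' @param base_ct baseline cycle threshold.
#' @param ct_ceiling no-amplification ceiling (cycles).
#' @param calibrators named character: calibrator sample per region_id.
#' @return data.frame of assays: `sample_id`, `region_id`, `ct_target_1..3`,
#'   `ct_reference_1..3`, `calibrator_sample_id`, `true_cn`. Calibrator rows
#'   are included.
#' @export
simulate_qpcr <- function(truth, assayed_pairs, ct_sd = 0.1, seed = 1L,
                          base_ct = 25, ct_ceiling = 55,
                          calibrators = NULL) {
  set.seed(seed)
  cn_of <- function(sid, ch, s, e) {
    tr <- truth[truth$sample_id == sid & truth$chrom == ch &
                  truth$start_bp <= e & truth$end_bp >= s, , drop = FALSE]
    if (nrow(tr)) tr$cn[1] else 2L
  }
  regions <- unique(assayed_pairs[, c("region_id", "chrom", "start_bp",
                                      "end_bp")])
  if (is.null(calibrators)) {
    all_samples <- unique(c(assayed_pairs$sample_id, truth$sample_id))
    calibrators <- vapply(seq_len(nrow(regions)), function(i) {
      ok <- all_samples[vapply(all_samples, function(sid)
        cn_of(sid, regions$chrom[i], regions$start_bp[i],
              regions$end_bp[i]) == 2L, TRUE)]
      if (!length(ok)) stop("no diploid calibrator available for region ",
                            regions$region_id[i])
      ok[1]
    }, "")
    names(calibrators) <- regions$region_id
  }
  pairs <- assayed_pairs
  # append calibrator self-assays not already listed
  for (i in seq_len(nrow(regions))) {
    cal <- calibrators[[regions$region_id[i]]]
    if (!any(pairs$sample_id == cal &
               pairs$region_id == regions$region_id[i]))
      pairs <- rbind(pairs, data.frame(sample_id = cal,
                                       region_id = regions$region_id[i],
                                       chrom = regions$chrom[i],
                                       start_bp = regions$start_bp[i],
                                       end_bp = regions$end_bp[i],
                                       stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    cn <- cn_of(pairs$sample_id[i], pairs$chrom[i], pairs$start_bp[i],
                pairs$end_bp[i])
    if (cn == 0L) {
      tgt <- rep(ct_ceiling, 3)
    } else {
      tgt <- base_ct - log2(cn / 2) + rnorm(3, sd = ct_sd)
    }
    ref <- base_ct + rnorm(3, sd = ct_sd)
    data.frame(sample_id = pairs$sample_id[i],
               region_id = pairs$region_id[i],
               ct_target_1 = tgt[1], ct_target_2 = tgt[2],
               ct_target_3 = tgt[3],
               ct_reference_1 = ref[1], ct_reference_2 = ref[2],
               ct_reference_3 = ref[3],
               calibrator_sample_id = calibrators[[pairs$region_id[i]]],
               true_cn = cn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simulate a full cohort
#'
#' Convenience wrapper: probe map, truth set, signals, SD track and gene
#' track from one spec and seed.
#'
#' @param spec a [cohort_spec()].
#' @param noise a [noise_spec()].
#' @param sd_enrichment SD/CNV colocalization enrichment (>= 1).
#' @param n_sd,n_genes track sizes.
#' @return list: `spec`, `map`, `samples`, `truth`, `signals`, `sd_track`,
#'   `gene_track`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), noise = noise_spec(),
                            sd_enrichment = 1, n_sd = 60L,
                            n_genes = 400L) {
  map <- make_probe_map(spec)
  samples <- cohort_samples(spec)
  truth <- make_truth_set(spec, map)
  signals <- simulate_signals(truth, map, samples, noise,
                              seed = spec$seed + 2L)
  sd_track <- simulate_sd_track(truth, spec$chrom_lengths_bp,
                                enrichment = sd_enrichment, n_sd = n_sd,
                                seed = spec$seed + 3L)
  gene_track <- simulate_gene_track(spec$chrom_lengths_bp, n_genes,
                                    seed = spec$seed + 4L)
  list(spec = spec, map = map, samples = samples, truth = truth,
       signals = signals, sd_track = sd_track, gene_track = gene_track)
}
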