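test_that("probe map has the configured density, determinism and bounds", {
  spec <- cohort_spec(breeds = c(A = 2L), chrom_lengths_bp = 4.9e6,
                      mean_probe_spacing_bp = 49000, n_cnvr_loci = 1L,
                      seed = 3L)
  map <- make_probe_map(spec)
  # ~100 expected probes with Poisson-level variation
  expect_gt(nrow(map), 60)
  expect_lt(nrow(map), 140)
  expect_true(all(diff(map$pos_bp) > 0))
  expect_true(all(map$gc_frac >= 0.3 & map$gc_frac <= 0.7))
  expect_identical(map, make_probe_map(spec))  # same seed, same map

  bad <- cohort_spec(breeds = c(A = 2L), chrom_lengths_bp = 1e4,
                     n_cnvr_loci = 1L)
  expect_error(make_probe_map(bad), "spacing")
})

test_that("truth sets respect the class weights and carrier rules", {
  # degenerate spec: all mass on cn=3
  spec3 <- tiny_spec(cn_class_weights = c(`0` = 0, `1` = 0, `3` = 1,
                                          `4` = 0))
  map <- make_probe_map(spec3)
  truth <- make_truth_set(spec3, map)
  expect_true(all(truth$cn == 3L))
  expect_true(all(truth$n_probes >= 3))

  # single common locus: freq ~1 via singleton_mass = 0 and extreme Beta
  spec1 <- tiny_spec(n_cnvr_loci = 1L, singleton_mass = 0,
                     common_freq_shape = c(1000, 1e-3),
                     cn_class_weights = c(`0` = 0, `1` = 1, `3` = 0,
                                          `4` = 0))
  t1 <- make_truth_set(spec1, make_probe_map(spec1))
  expect_equal(sort(unique(t1$sample_id)),
               sort(cohort_samples(spec1)$sample_id))
  expect_equal(length(unique(t1$start_bp)), 1)

  # class fractions over many singleton calls match the multinomial weights
  specN <- cohort_spec(breeds = c(A = 30L), chrom_lengths_bp = rep(50e6, 2),
                       n_cnvr_loci = 5000L, seed = 5L)
  tN <- make_truth_set(specN, make_probe_map(specN))
  frac <- table(factor(tN$cn, levels = c(0, 1, 3, 4))) / nrow(tN)
  w <- specN$cn_class_weights
  for (k in seq_along(w)) {
    se <- sqrt(w[k] * (1 - w[k]) / nrow(tN))
    expect_lt(abs(frac[k] - w[k]), 3 * se + 1e-9)
  }
  # homozygous deletions never exceed 2 carriers per locus
  hom <- tN[tN$cn == 0L, ]
  if (nrow(hom)) expect_true(all(table(hom$locus) <= 2))
})

test_that("truth length distribution tracks the configured median", {
  spec <- cohort_spec(breeds = c(A = 10L), chrom_lengths_bp = rep(50e6, 2),
                      n_cnvr_loci = 1200L, seed = 8L)
  truth <- make_truth_set(spec, make_probe_map(spec))
  loci <- truth[!duplicated(truth$locus), ]
  med <- median(loci$end_bp - loci$start_bp + 1)
  expect_lt(abs(med - spec$length_median_bp) / spec$length_median_bp, 0.10)
})

test_that("signal emissions follow the copy-number state", {
  map <- flat_map(100)
  samples <- data.frame(sample_id = "S1", breed = "A")
  # noiseless diploid baseline
  quiet <- noise_spec(lrr_sd = 0, baf_sd = 0)
  sig <- simulate_signals(cnv_calls(), map, samples, quiet, seed = 2)[[1]]
  expect_equal(sig$lrr, rep(0, 100), tolerance = 1e-9)

  # implanted cn=1 segment: lrr -0.66, baf in {0,1}
  truth <- cnv_calls("S1", 1L, map$pos_bp[40], map$pos_bp[60], 1L, 21L,
                     NA_real_, "truth")
  sig1 <- simulate_signals(truth, map, samples, quiet, seed = 2)[[1]]
  inside <- 40:60
  expect_equal(sig1$lrr[inside], rep(-0.66, 21), tolerance = 1e-9)
  expect_true(all(sig1$baf[inside] %in% c(0, 1)))
  expect_equal(sig1$lrr[-inside], rep(0, 79), tolerance = 1e-9)

  # a GC wave induces positive lrr-gc correlation
  spec <- tiny_spec()
  mapgc <- make_probe_map(spec)
  wav <- noise_spec(lrr_sd = 0.05, gc_wave_amplitude = 2)
  sigw <- simulate_signals(cnv_calls(), mapgc,
                           data.frame(sample_id = "S1", breed = "A"),
                           wav, seed = 3)[[1]]
  expect_gt(cor(sigw$lrr, mapgc$gc_frac), 0.3)
})

test_that("SD track placement responds to the enrichment parameter", {
  spec <- tiny_spec(seed = 21L)
  map <- make_probe_map(spec)
  truth <- make_truth_set(spec, map)
  # enrichment -> infinity: every SD overlaps a truth locus
  sd_inf <- simulate_sd_track(truth, spec$chrom_lengths_bp,
                              enrichment = 1e9, n_sd = 40L, seed = 4)
  hits <- vapply(seq_len(nrow(sd_inf)), function(i)
    any(truth$chrom == sd_inf$chrom[i] &
          truth$start_bp <= sd_inf$end_bp[i] &
          truth$end_bp >= sd_inf$start_bp[i]), TRUE)
  expect_true(all(hits))
  # enrichment = 4 separates observed overlap from the null in most cohorts
  wins <- vapply(1:50, function(r) {
    sp <- tiny_spec(seed = 100L + r, n_cnvr_loci = 20L)
    m <- make_probe_map(sp)
    tr <- make_truth_set(sp, m)
    uq <- deduplicate(tr)$unique_calls
    sd4 <- simulate_sd_track(tr, sp$chrom_lengths_bp, enrichment = 4,
                             n_sd = 40L, seed = 200 + r)
    obs <- overlap_fraction(uq, sd4)
    null <- permutation_test(uq$end_bp - uq$start_bp + 1, sd4,
                             sp$chrom_lengths_bp, obs, n_perm = 100L,
                             seed = 300 + r)$null_fractions
    obs > quantile(null, 0.95)
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("qPCR simulation encodes copy number in cycle thresholds", {
  map <- flat_map(20)
  truth <- cnv_calls(c("S1", "S2", "S4"), 1L, 1e5, 5e5, c(1L, 4L, 0L),
                     5L, NA_real_, "truth")
  pairs <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                      region_id = "R1", chrom = 1L, start_bp = 1e5,
                      end_bp = 5e5)
  assays <- simulate_qpcr(truth, pairs, ct_sd = 0, seed = 1)
  est <- estimate_qpcr_cn(assays)
  get <- function(s) est$qpcr_cn[est$sample_id == s][1]
  expect_equal(get("S3"), 2)         # diploid: ddCt = 0
  expect_equal(get("S1"), 1)         # one extra cycle
  expect_equal(get("S2"), 4)         # one cycle early
  expect_equal(get("S4"), 0)         # censored: no amplification
  # CN=1 target Ct is one cycle above the calibrator's
  t1 <- assays$ct_target_1[assays$sample_id == "S1"]
  tc <- assays$ct_target_1[assays$sample_id == "S3"]
  expect_equal(t1 - tc, 1)
})

test_that("cohort simulation is reproducible under a fixed seed", {
  a <- simulate_cohort(tiny_spec(seed = 9L))
  b <- simulate_cohort(tiny_spec(seed = 9L))
  expect_identical(a$map, b$map)
  expect_identical(a$truth, b$truth)
  expect_identical(a$signals[[3]]$lrr, b$signals[[3]]$lrr)
  expect_identical(a$sd_track, b$sd_track)
})
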