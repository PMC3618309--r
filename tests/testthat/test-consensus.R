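mk <- function(sample, chrom, s, e, cn, bf, src) {
  cnv_calls(sample, chrom, s, e, cn, n_probes = 3L, bf = bf, source = src)
}

test_that("dual-track merge keeps the higher-confidence overlapping call", {
  a <- mk("S1", 1L, 100, 200, 1L, 20, "A")
  b <- mk("S1", 1L, 150, 300, 1L, 12, "B")
  m <- merge_dual_calls(a, b)
  expect_equal(nrow(m), 1)
  expect_equal(m$start_bp, 100)    # A's coordinates survive
  expect_equal(m$bf, 20)
  expect_identical(m$source, "consensus")

  # idempotence on identical tracks (ties keep A)
  m2 <- merge_dual_calls(a, a)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$start_bp, a$start_bp)

  # opposite signs never merge
  gain <- mk("S1", 1L, 100, 200, 3L, 20, "A")
  loss <- mk("S1", 1L, 150, 300, 1L, 25, "B")
  expect_equal(nrow(merge_dual_calls(gain, loss)), 2)

  # different samples never merge; non-overlapping calls pass through
  other <- mk("S2", 1L, 100, 200, 1L, 5, "B")
  far <- mk("S1", 1L, 5000, 6000, 1L, 5, "B")
  m3 <- merge_dual_calls(a, rbind(other, far))
  expect_equal(nrow(m3), 3)

  # merge is commutative in kept coordinates (up to the tie rule)
  m_ab <- merge_dual_calls(a, b)
  m_ba <- merge_dual_calls(b, a)
  expect_equal(m_ab[, c("chrom", "start_bp", "end_bp", "cn", "bf")],
               m_ba[, c("chrom", "start_bp", "end_bp", "cn", "bf")])
})

test_that("Bayes-factor thresholding is inclusive and monotone", {
  calls <- mk(rep("S1", 4), 1L, c(1, 300, 600, 900) * 10,
              c(2, 400, 700, 950) * 10, 1L, c(10, 15, 20, 30), "A")
  expect_equal(nrow(apply_bf_threshold(calls, 15)), 3)  # 15.0 retained
  expect_equal(nrow(apply_bf_threshold(calls, 0)), 4)   # identity
  counts <- vapply(c(10, 15, 20, 30), function(t)
    nrow(apply_bf_threshold(calls, t)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("deduplication keys on exact coordinates and conserves carriers", {
  same <- mk(c("S1", "S2", "S3"), 1L, 100, 200, 1L, c(10, 30, 20), "A")
  shifted <- mk("S4", 1L, 101, 200, 1L, 5, "A")
  dd <- deduplicate(rbind(same, shifted))
  expect_equal(nrow(dd$unique_calls), 2)
  u1 <- dd$unique_calls[dd$unique_calls$start_bp == 100, ]
  expect_equal(u1$multiplicity, 3)
  expect_equal(u1$bf, 30)           # representative is the top-bf carrier
  expect_equal(sum(dd$multiplicity), 4)  # conservation
})

test_that("the qPCR-anchored sweep penalizes low-confidence false calls", {
  # 12 assayed samples, 3 regions; true CNs known
  regions <- data.frame(region_id = c("R1", "R2", "R3"), chrom = 1L,
                        start_bp = c(1e6, 5e6, 9e6),
                        end_bp = c(2e6, 6e6, 10e6))
  set.seed(42)
  assays <- expand.grid(sample_id = sprintf("S%02d", 1:12),
                        region_id = regions$region_id,
                        stringsAsFactors = FALSE)
  true_cn <- sample(c(1L, 2L, 2L, 3L), nrow(assays), replace = TRUE)
  assays$qpcr_cn <- as.numeric(true_cn)
  # true calls with high bf where cn != 2
  idx <- which(true_cn != 2L)
  good <- mk(assays$sample_id[idx], 1L,
             regions$start_bp[match(assays$region_id[idx],
                                    regions$region_id)],
             regions$end_bp[match(assays$region_id[idx],
                                  regions$region_id)],
             true_cn[idx], bf = 25, src = "consensus")
  # spurious low-bf calls on truly diploid pairs
  dip <- which(true_cn == 2L)[1:8]
  fake <- mk(assays$sample_id[dip], 1L,
             regions$start_bp[match(assays$region_id[dip],
                                    regions$region_id)],
             regions$end_bp[match(assays$region_id[dip],
                                  regions$region_id)],
             sample(c(1L, 3L), 8, replace = TRUE), bf = 5,
             src = "consensus")
  sweep <- bf_sweep(rbind(good, fake), assays, regions,
                    thresholds = c(0, 15))
  expect_true(all(diff(sweep$n_calls) <= 0))
  expect_gt(sweep$adj_r2[sweep$threshold == 15],
            sweep$adj_r2[sweep$threshold == 0])
  expect_equal(sweep$adj_r2[sweep$threshold == 15], 1)  # concordant at 15

  # degenerate: nothing survives, array CN constant, qPCR varies
  deg <- bf_sweep(good, assays, regions, thresholds = c(50))
  expect_lte(deg$adj_r2, 0)
  expect_error(bf_sweep(good, assays[1:2, ], regions, 15), "fewer than 3")
})
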