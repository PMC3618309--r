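#!/usr/bin/env Rscript
# Stage 9: qPCR validation of called CNVs.
# Assays a sample of called regions by simulated Ct triplicates (replicate
# noise 0.1 cycles), estimates copy number by delta-delta-Ct against a
# diploid calibrator, and regresses qPCR CN on array CN. Also runs the BF
# threshold sweep anchored to the qPCR copy numbers.

suppressPackageStartupMessages(library(cnvpopscan))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cons <- read_cnv_table("results/cnv_calls.tsv")
truth <- read_cnv_table("results/cohort/truth_cnvs.tsv")

# assay up to 11 called regions across carriers and non-carriers
set.seed(seed)
uniq <- deduplicate(cons)$unique_calls
picked <- uniq[sample.int(nrow(uniq), min(11L, nrow(uniq))), ]
regions <- data.frame(region_id = sprintf("V%02d", seq_len(nrow(picked))),
                      chrom = picked$chrom, start_bp = picked$start_bp,
                      end_bp = picked$end_bp)
carriers <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
  hit <- cons[cons$chrom == regions$chrom[i] &
                cons$start_bp <= regions$end_bp[i] &
                cons$end_bp >= regions$start_bp[i], ]
  data.frame(sample_id = unique(hit$sample_id),
             region_id = regions$region_id[i], chrom = regions$chrom[i],
             start_bp = regions$start_bp[i], end_bp = regions$end_bp[i])
}))
assays <- estimate_qpcr_cn(simulate_qpcr(truth, carriers, ct_sd = 0.1,
                                         seed = seed + 1L))

# array CN for each assayed pair (diploid 2 where no call overlaps)
array_cn <- vapply(seq_len(nrow(assays)), function(i) {
  reg <- regions[regions$region_id == assays$region_id[i], ][1, ]
  hit <- cons[cons$sample_id == assays$sample_id[i] &
                cons$chrom == reg$chrom & cons$start_bp <= reg$end_bp &
                cons$end_bp >= reg$start_bp, ]
  if (nrow(hit)) hit$cn[which.max(hit$bf)] else 2L
}, 0L)
fit <- regress_validation(data.frame(array_cn = array_cn,
                                     qpcr_cn = assays$qpcr_cn))
write.table(fit, "results/validation_fit.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("validation: n = %d pairs, slope %.2f (SE %.2f), adj R^2 %.2f, p = %.3g\n",
            fit$n, fit$slope, fit$slope_se, fit$adj_r2, fit$p_value))

sweep <- bf_sweep(cons, assays[, c("sample_id", "region_id", "qpcr_cn")],
                  regions, thresholds = c(10, 15, 20, 30))
write.table(sweep, "results/bf_sweep.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("BF sweep (threshold / calls / unique / adj R^2):\n")
print(sweep, row.names = FALSE)
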