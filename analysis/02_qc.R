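#!/usr/bin/env Rscript
# Stage 2: per-sample QC and GC-wave correction.
# Samples with LRR SD above 0.30 are dropped; the remaining signals are
# regressed against centered GC to remove the wave, and the corrected
# signal table is written for the callers.

suppressPackageStartupMessages(library(cnvpopscan))

cohort <- read_signal_table("results/cohort/signals.tsv")
qc <- assess_cohort(cohort$samples, cohort$map)
write.table(qc, "results/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

passed <- cohort$samples[qc$passed]
corrected <- lapply(passed, gc_correct, map = cohort$map)
write_signal_table(cohort$map, corrected, "results/signals_corrected.tsv")

cat(sprintf("QC: %d/%d samples passed (LRR SD <= 0.30)\n", sum(qc$passed),
            nrow(qc)))
cat(sprintf("median LRR SD %.3f, median |GC slope| %.3f\n",
            median(qc$lrr_sd), median(abs(qc$gc_wave_coeff))))
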