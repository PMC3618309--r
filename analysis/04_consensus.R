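#!/usr/bin/env Rscript
# Stage 4: dual-caller consensus, long-call filter, BF threshold.
# Overlapping same-sign calls keep the higher Bayes factor; calls longer
# than 8 Mb are removed; the confidence threshold bf >= 15 is applied and
# the threshold sweep over {10, 15, 20, 30} is recorded.

suppressPackageStartupMessages(library(cnvpopscan))

callsA <- read_caller_calls("results/calls_A.rawcnv", "penncnv")
callsB <- read_caller_calls("results/calls_B.tsv", "quantisnp")

merged <- merge_dual_calls(callsA, callsB)
flt <- filter_long_calls(merged)
cons <- apply_bf_threshold(flt$kept, 15)
write_cnv_table(cons, "results/cnv_calls.tsv")

dd <- deduplicate(cons)
write_cnv_table(dd$unique_calls, "results/cnv_calls_unique.tsv")

counts <- vapply(c(10, 15, 20, 30), function(t)
  nrow(apply_bf_threshold(flt$kept, t)), 0L)
write.table(data.frame(threshold = c(10, 15, 20, 30), n_calls = counts),
            "results/bf_threshold_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("consensus: %d merged, %d removed as >8 Mb, %d at bf>=15 (%d unique)\n",
            nrow(merged), nrow(flt$removed), nrow(cons),
            nrow(dd$unique_calls)))
cat(sprintf("calls at bf thresholds 10/15/20/30: %s (non-increasing)\n",
            paste(counts, collapse = "/")))
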