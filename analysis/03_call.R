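#!/usr/bin/env Rscript
# Stage 3: HMM CNV calling, twice.
# The one engine runs under two parameterizations (presets A and B) to
# produce two independent call tracks, archived in the respective caller
# text dialects so stage 4 can re-read them exactly as external calls.

suppressPackageStartupMessages(library(cnvpopscan))

cohort <- read_signal_table("results/signals_corrected.tsv")
callsA <- call_cohort(cohort$samples, cohort$map, hmm_params("A"))
callsB <- call_cohort(cohort$samples, cohort$map, hmm_params("B"))

write_caller_calls(callsA, "results/calls_A.rawcnv", "penncnv")
write_caller_calls(callsB, "results/calls_B.tsv", "quantisnp")

cat(sprintf("track A: %d calls (median bf %.1f); track B: %d calls (median bf %.1f)\n",
            nrow(callsA), median(callsA$bf), nrow(callsB),
            median(callsB$bf)))
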