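#!/usr/bin/env Rscript
# Stage 6: segmental-duplication colocalization.
# Observed: fraction of unique CNVs sharing >= 1 bp with an SD. Null: 1000
# random placements of length-matched segments; add-one empirical p.

suppressPackageStartupMessages(library(cnvpopscan))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cons <- read_cnv_table("results/cnv_calls.tsv")
sd_track <- read_features("results/cohort/sd_track.bed", "bed", "SD")
chrom_len <- read.delim("results/cohort/chrom_lengths.tsv")$length_bp

res <- sd_association(cons, sd_track, chrom_len, n_perm = 1000L,
                      seed = seed)
write.table(data.frame(null_fraction = res$null_fractions),
            "results/sd_null_distribution.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(observed = res$observed_overlap_fraction,
                       p_value = res$p_value, n_perm = res$n_perm),
            "results/sd_test.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%.1f%% of unique CNVs intersect an SD (null mean %.1f%%), p = %.4g\n",
            100 * res$observed_overlap_fraction,
            100 * mean(res$null_fractions), res$p_value))
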