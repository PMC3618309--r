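#!/usr/bin/env Rscript
# Stage 5: CNV-region construction.
# Consensus calls are aggregated into CNVRs (connected components of
# >= 1 bp overlap), classified gain/loss/both, and summarized by
# population frequency class and genome coverage.

suppressPackageStartupMessages(library(cnvpopscan))

cons <- read_cnv_table("results/cnv_calls.tsv")
qc <- read.delim("results/qc_report.tsv")
chrom_len <- read.delim("results/cohort/chrom_lengths.tsv")$length_bp

regions <- build_cnvrs(cons, cohort_n = sum(qc$passed))
write_cnvr_table(regions, "results/cnvr.tsv")

fc <- frequency_classes(regions)
cov <- genome_coverage(regions, chrom_len)

cat(sprintf("%d CNVRs (%s); loss/gain region ratio %.2f\n", nrow(regions),
            paste(names(table(regions$category)), table(regions$category),
                  sep = "=", collapse = " "),
            region_class_ratio(regions)))
cat(sprintf("frequency classes: %s\n",
            paste(names(fc), fc, sep = " ", collapse = ", ")))
cat(sprintf("genome coverage: %.1f Mb (%.1f%% of the autosomes)\n",
            cov$covered_bp / 1e6, 100 * cov$fraction))
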