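#!/usr/bin/env Rscript
# Stage 1: generate the study cohort.
# A 30-bull cohort over five breeds, two 50 Mb autosomes genotyped at 49 kb
# mean probe spacing, 40 CNV loci with a mostly-rare frequency spectrum, an
# SD track colocalized with the CNV loci (enrichment 4) and a gene track.
# Everything downstream reads the files written here.

suppressPackageStartupMessages(library(cnvpopscan))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)

spec <- cohort_spec(seed = seed)
co <- simulate_cohort(spec, sd_enrichment = 4)

write_signal_table(co$map, co$signals, "results/cohort/signals.tsv")
write_cnv_table(co$truth, "results/cohort/truth_cnvs.tsv")
writeLines(sprintf("%d\t%0.f\t%0.f", co$sd_track$chrom,
                   co$sd_track$start_bp - 1, co$sd_track$end_bp),
           "results/cohort/sd_track.bed")
writeLines(sprintf("%d\tsim\tgene\t%.0f\t%.0f\t.\t+\t.\tID=%s;biotype=%s",
                   co$gene_track$chrom, co$gene_track$start_bp,
                   co$gene_track$end_bp, co$gene_track$gene_id,
                   co$gene_track$biotype),
           "results/cohort/genes.gff3")
write.table(data.frame(chrom = seq_along(spec$chrom_lengths_bp),
                       length_bp = spec$chrom_lengths_bp),
            "results/cohort/chrom_lengths.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("cohort: %d samples, %d probes, %d truth calls at %d loci\n",
            length(co$signals), nrow(co$map), nrow(co$truth),
            length(unique(co$truth$locus))))
cat(sprintf("truth class mix: %s\n",
            paste(names(table(co$truth$cn)), table(co$truth$cn),
                  sep = "=", collapse = " ")))
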