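#!/usr/bin/env Rscript
# Stage 7: gene content of the CNV regions.
# Genes overlapping a CNVR by >= 1 bp are assigned to it; biotypes are
# tallied over the deduplicated gene union.

suppressPackageStartupMessages(library(cnvpopscan))

regions <- read_cnvr_table("results/cnvr.tsv")
genes <- read_features("results/cohort/genes.gff3", "gff3", "gene")

ann <- annotate_intervals(regions, genes)
per_region <- data.frame(region_id = regions$region_id,
                         n_genes = lengths(ann),
                         gene_ids = vapply(ann, paste, "", collapse = ","))
write.table(per_region, "results/cnvr_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tally <- biotype_tally(ann, genes)
write.table(tally, "results/gene_biotypes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d distinct genes overlap the %d CNVRs\n",
            length(unique(unlist(ann))), nrow(regions)))
print(tally, row.names = FALSE)
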