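#!/usr/bin/env Rscript
# Stage 8: population and breed summaries.
# Genotype-class table, loss/gain ratios, per-breed counts, rates,
# recurrence spectra and pairwise Wilcoxon comparisons of per-sample CNV
# counts between breeds.

suppressPackageStartupMessages(library(cnvpopscan))

cons <- read_cnv_table("results/cnv_calls.tsv")
cohort <- read_signal_table("results/cohort/signals.tsv")
samples <- data.frame(
  sample_id = vapply(cohort$samples, `[[`, "", "sample_id"),
  breed = vapply(cohort$samples, `[[`, "", "breed"))
chroms <- sort(unique(cohort$map$chrom))

ct <- genotype_class_table(cons)
cat(sprintf("classes 0/1/3/4: %s -> %s%%; loss/gain ratio %.2f\n",
            paste(ct$counts, collapse = "/"),
            paste(ct$percent, collapse = "/"), ct$loss_gain_ratio))

bs <- breed_summaries(cons, samples, chroms = chroms)
tab <- do.call(rbind, lapply(bs, function(b)
  data.frame(breed = b$breed, n_samples = b$n_samples,
             cnv_count = b$cnv_count, per_sample = b$cnv_per_sample,
             unique = b$unique_count, specific = b$specific_count,
             gain = b$gain_count, loss = b$loss_count,
             cnvr = b$cnvr_count,
             singleton_pct = unname(b$spectrum_pct["1"]))))
write.table(tab, "results/breed_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab, row.names = FALSE)

# per-sample CNV counts per breed -> pairwise rank-sum p-values
counts_by_sample <- table(factor(cons$sample_id,
                                 levels = samples$sample_id))
by_breed <- split(as.numeric(counts_by_sample), samples$breed)
P <- compare_breeds(by_breed)
write.table(round(P, 4), "results/breed_wilcoxon_p.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
cat("pairwise Wilcoxon p-values written (per-sample CNV counts)\n")
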