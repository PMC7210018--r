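#!/usr/bin/env Rscript
# Per-peak survival association on promoter peaks: Cox proportional
# hazards on the continuous intensity (Breslow ties, Wald tests, BH across
# peaks, prognostic = q < 0.05), chromosome-wise direction summary, and a
# median-split Kaplan-Meier comparison for the strongest protective peak.

suppressMessages(library(chromaccess))

bundle <- read_fixture_bundle("results/fixtures")
norm_tab <- read_result_tsv("results/normalized_matrix.tsv")
norm <- as.matrix(norm_tab[, -1])
rownames(norm) <- norm_tab$peak_id

peaks <- bundle$loci
peaks$category <- assign_category(peaks$annotation)
peaks <- assign_promoter_peaks(peaks, bundle$genes)
prom <- peaks$peak_id[peaks$category == "promoter"]

rec <- cox_per_peak(norm[prom, ], bundle$clinical, alpha = 0.05)
rec$gene <- peaks$nearest_gene[match(rec$peak_id, peaks$peak_id)]
rec$dist_to_tss <- peaks$dist_to_tss[match(rec$peak_id, peaks$peak_id)]
write_result_tsv(rec, "results/survival.tsv", "survive", list(alpha = 0.05))

by_chrom <- prognostic_landscape(rec, peaks)
by_chrom <- by_chrom[order(-by_chrom$n_prognostic), ]
write_result_tsv(by_chrom, "results/prognostic_by_chrom.tsv", "survive",
                 list(alpha = 0.05))

n_used <- sum(!is.na(bundle$clinical$os_time) & bundle$clinical$os_time > 0 &
                !is.na(bundle$clinical$os_event))
cat(sprintf("survival analysis on %d samples, %d promoter peaks\n",
            n_used, nrow(rec)))
cat(sprintf("%d prognostic peaks (q < 0.05): %d with HR > 1, %d with HR < 1\n",
            sum(rec$prognostic),
            sum(rec$prognostic & rec$direction == "positive"),
            sum(rec$prognostic & rec$direction == "negative")))
top_chrom <- by_chrom[1, ]
cat(sprintf("most prognostic chromosome: %s (%d peaks, %.1f%% positive)\n",
            top_chrom$chrom, top_chrom$n_prognostic,
            top_chrom$pct_positive))

# Kaplan-Meier median split for the strongest protective (HR < 1) peak
prot <- rec[rec$prognostic & rec$direction == "negative", ]
if (nrow(prot) > 0) {
  best <- prot$peak_id[which.min(prot$q)]
  km <- km_median_split(norm[best, ], bundle$clinical)
  write_result_tsv(km$curves, "results/km_best_protective.tsv", "survive",
                   list(peak = best))
  row <- rec[rec$peak_id == best, ]
  cat(sprintf(
    "best protective peak %s (gene %s): HR = %.3f (95%% CI %.3f-%.3f, q = %.3g)\n",
    best, ifelse(is.na(row$gene), "-", row$gene), row$hr, row$ci_low,
    row$ci_high, row$q))
  cat(sprintf("  KM median split: %d high vs %d low, log-rank p = %.3g\n",
              km$n_high, km$n_low, km$logrank_p))
}
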