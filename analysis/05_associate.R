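#!/usr/bin/env Rscript
# Differential promoter accessibility between clinical groups: sex, age
# (median split), stage (III/IV vs I/II) at FDR < 0.01 and |log2FC| > 0.3;
# LUAD vs LUSC and basal vs non-basal BRCA at FDR < 0.01 and fold change
# >= 2. Mann-Whitney tests with Benjamini-Hochberg correction, restricted
# to promoter peaks.

suppressMessages(library(chromaccess))

bundle <- read_fixture_bundle("results/fixtures")
norm_tab <- read_result_tsv("results/normalized_matrix.tsv")
norm <- as.matrix(norm_tab[, -1])
rownames(norm) <- norm_tab$peak_id

peaks <- bundle$loci
peaks$category <- assign_category(peaks$annotation)
peaks <- assign_promoter_peaks(peaks, bundle$genes)
prom <- peaks$peak_id[peaks$category == "promoter"]
truth <- bundle$truth

for (ct in c("sex", "age", "stage", "histology_lung", "brca_basal")) {
  contrast <- clinical_contrast(bundle$clinical, ct)
  rec <- mann_whitney_bh(norm[prom, ], contrast)
  rec$gene <- peaks$nearest_gene[match(rec$peak_id, peaks$peak_id)]
  rec$dist_to_tss <- peaks$dist_to_tss[match(rec$peak_id, peaks$peak_id)]
  write_result_tsv(rec, sprintf("results/assoc_%s.tsv", ct),
                   paste0("associate:", ct),
                   list(fdr = contrast$fdr_threshold,
                        lfc = contrast$lfc_threshold))
  sel <- select_differential(rec, contrast)
  planted <- truth$peak_id[truth$contrast == ct]
  called <- c(sel$up_in_a, sel$up_in_b)
  cat(sprintf(
    "%-14s (%d vs %d): %3d significant (%d up in A, %d up in B); %d/%d planted recovered\n",
    ct, length(contrast$group_a), length(contrast$group_b),
    sel$n_up_in_a + sel$n_up_in_b, sel$n_up_in_a, sel$n_up_in_b,
    sum(planted %in% called), length(planted)))
}
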