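#!/usr/bin/env Rscript
# Normalize the raw peak-by-replicate count matrix into the peak-by-sample
# log2 intensity matrix: prior count of 5, CPM, log2, quantile
# normalization, then averaging of technical replicates.

suppressMessages(library(chromaccess))

bundle <- read_fixture_bundle("results/fixtures")
norm <- normalize_counts(bundle$counts, bundle$replicate_map, prior = 5)

out <- data.frame(peak_id = rownames(norm),
                  as.data.frame(unclass(norm), check.names = FALSE),
                  check.names = FALSE)
write_result_tsv(out, "results/normalized_matrix.tsv", "normalize",
                 list(prior = 5))

cat(sprintf("normalized %d peaks x %d replicates into %d samples\n",
            nrow(bundle$counts), ncol(bundle$counts), ncol(norm)))
cat(sprintf("intensity range: [%.2f, %.2f] log2 units\n",
            min(norm), max(norm)))
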