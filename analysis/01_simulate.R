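#!/usr/bin/env Rscript
# Generate the synthetic pan-cancer cohort used by every downstream step:
# a 23-cancer-type, 404-sample cohort on a 1/100-scale GRCh38 genome with
# planted sex, histology, subtype and survival effects, written as a
# plain-text fixture bundle under results/fixtures/.

suppressMessages(library(chromaccess))

seed <- 20260101
cfg <- sim_config(seed = seed)
sim <- simulate_cohort(cfg)

dir.create("results", showWarnings = FALSE)
write_fixture_bundle(sim, "results/fixtures")

comp <- cohort_composition(sim$clinical)
write_result_tsv(comp, "results/cohort_composition.tsv", "simulate",
                 list(seed = seed))

cat(sprintf("cohort: %d samples, %d cancer types, %d replicate columns\n",
            nrow(sim$clinical), length(unique(sim$clinical$cancer_type)),
            ncol(sim$counts)))
cat(sprintf("largest type: %s (%d samples, %.1f%%); smallest: %s (%d, %.1f%%)\n",
            comp$cancer_type[1], comp$n[1], comp$percent[1],
            comp$cancer_type[nrow(comp)], comp$n[nrow(comp)],
            comp$percent[nrow(comp)]))
cat(sprintf("planted effects: %d (see results/fixtures/truth.tsv)\n",
            nrow(sim$truth)))
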