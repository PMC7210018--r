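test_that("interval lengths follow the 1-based inclusive convention", {
  expect_equal(interval_length(151689921, 151690150), 230)
  expect_equal(interval_length(151690401, 151690650), 250)
  expect_equal(interval_length(42, 42), 1)
  expect_error(interval_length(10, 9), "invalid interval")
  # translation invariance
  for (k in c(-1000, 1, 7, 1e6)) {
    expect_equal(interval_length(100 + k, 399 + k), interval_length(100, 399))
  }
})

test_that("promoter windows are transcription-oriented and clipped", {
  w <- promoter_window(151690496, "+")
  expect_equal(c(w$start, w$end), c(151689496, 151690596))
  expect_equal(interval_length(w$start, w$end), 1101)
  # minus strand mirrors the window in genomic coordinates
  wm <- promoter_window(5000, "-")
  expect_equal(c(wm$start, wm$end), c(4900, 6000))
  # clipping at chromosome edges
  wc <- promoter_window(1000, "+")
  expect_equal(wc$start, 1)
  we <- promoter_window(990, "-", chromosome_length = 1500)
  expect_equal(c(we$start, we$end), c(890, 1500))
  expect_error(promoter_window(100, "*"), "strand")
})

test_that("summit-based promoter assignment picks the closest gene", {
  genome <- tiny_genome()
  genes <- gene_annotation(data.frame(
    gene_id = c("GA", "GB"), symbol = c("A", "B"), chrom = "chr1",
    tss = c(20000, 20600), strand = c("+", "+")), genome)
  # summit 247 bp upstream of GA's TSS and inside its window only
  p <- data.frame(chrom = "chr1", summit = 20000 - 247)
  res <- assign_promoter_peaks(p, genes)
  expect_equal(res$nearest_gene, "GA")
  expect_equal(res$dist_to_tss, -247)
  # summit exactly at the TSS
  res0 <- assign_promoter_peaks(data.frame(chrom = "chr1", summit = 20600), genes)
  expect_equal(res0$dist_to_tss, 0)
  expect_equal(res0$nearest_gene, "GB")
  # 1001 bp upstream is just outside the window
  resna <- assign_promoter_peaks(data.frame(chrom = "chr1", summit = 20000 - 1001),
                                 genes[genes$gene_id == "GA", ])
  expect_true(is.na(resna$nearest_gene) && is.na(resna$dist_to_tss))
  # tie: summit in both windows, closer to GB wins; equidistant -> gene_id order
  restie <- assign_promoter_peaks(data.frame(chrom = "chr1", summit = 20500), genes)
  expect_equal(restie$nearest_gene, "GB")
  expect_equal(restie$dist_to_tss, -100)
  # exact-distance tie between a plus- and a minus-strand gene falls back
  # to lexicographic gene_id
  genes2 <- gene_annotation(data.frame(
    gene_id = c("GA", "GB"), symbol = c("A", "B"), chrom = "chr1",
    tss = c(20000, 19500), strand = c("+", "-")), genome)
  eq <- assign_promoter_peaks(data.frame(chrom = "chr1", summit = 19750),
                              genes2)
  expect_equal(eq$nearest_gene, "GA")  # both at distance -250; GA < GB
  expect_equal(eq$dist_to_tss, -250)
})

test_that("promoter assignment is consistent with window membership", {
  set.seed(11)
  genome <- tiny_genome()
  genes <- gene_annotation(data.frame(
    gene_id = sprintf("G%02d", 1:15), symbol = sprintf("S%02d", 1:15),
    chrom = sample(c("chr1", "chr2"), 15, replace = TRUE),
    tss = sample(2000:70000, 15),
    strand = sample(c("+", "-"), 15, replace = TRUE)), genome)
  peaks <- data.frame(chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
                      summit = sample(1000:75000, 300))
  res <- assign_promoter_peaks(peaks, genes)
  win <- promoter_window(genes$tss, genes$strand)
  in_any <- vapply(seq_len(nrow(peaks)), function(i) {
    any(genes$chrom == peaks$chrom[i] &
          win$start <= peaks$summit[i] & win$end >= peaks$summit[i])
  }, logical(1))
  expect_equal(!is.na(res$nearest_gene), in_any)
  hit <- which(!is.na(res$nearest_gene))
  expect_true(all(abs(res$dist_to_tss[hit]) <= 1000))
})

test_that("annotation labels collapse to the four categories", {
  expect_equal(assign_category(c("distal", "5'UTR", "promoter", "intron",
                                 "exon", "3'UTR", "enhancer")),
               c("enhancer", "other", "promoter", "intron", "other", "other",
                 "enhancer"))
  expect_error(assign_category("flank"), "accepted")
  expect_equal(assign_category("distal", distal_as_enhancer = FALSE), "other")
})

test_that("cohort composition reproduces printed percentages and ordering", {
  counts <- tcga_cohort_table()
  clin <- data.frame(sample_id = seq_len(sum(counts$n)),
                     cancer_type = rep(counts$cancer_type, counts$n))
  comp <- cohort_composition(clin)
  expect_equal(comp$percent[comp$cancer_type == "BRCA"], 18.3)
  expect_equal(comp$percent[comp$cancer_type == "CESC"], 0.5)
  expect_equal(comp$cancer_type[1], "BRCA")  # sorted descending by percent
  expect_equal(sum(comp$n), 404)
  expect_lt(abs(sum(comp$percent) - 100), 0.1 * nrow(comp))
  one <- cohort_composition(data.frame(sample_id = 1:5, cancer_type = "ACC"))
  expect_equal(one$percent, 100.0)
  expect_error(cohort_composition(clin[0, ]), "empty")
})

test_that("genome model and annotation validate their invariants", {
  expect_error(genome_model(data.frame(chrom = c("chr1", "chr1"),
                                       length = c(10, 20))), "duplicated")
  expect_error(genome_model(data.frame(chrom = "chr1", length = 0)),
               "positive")
  expect_error(genome_model(data.frame(chrom = "chr1", length = 100),
                            data.frame(chrom = "chr1", start = 50, end = 200)),
               "bounds")
  g <- tiny_genome()
  expect_error(gene_annotation(data.frame(gene_id = c("A", "A"),
                                          symbol = "s", chrom = "chr1",
                                          tss = 10, strand = "+"), g),
               "duplicated")
})
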