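test_that("summit extension yields fixed-width peaks and drops edge windows", {
  g <- tiny_genome(c(chr1 = 1e5))
  calls <- data.frame(chrom = "chr1", summit = c(10000, 251, 250, 99750, 99751),
                      score = 1:5)
  p <- extend_summits(calls, g, width = 501)
  expect_equal(nrow(p), 3)  # summits 250 and 99751 would cross an edge
  expect_true(all(p$end - p$start + 1 == 501))
  expect_equal(c(p$start[1], p$end[1]), c(9750, 10250))
  expect_equal(c(p$start[2], p$end[2]), c(1, 501))
  expect_error(extend_summits(calls, g, width = 500), "odd")
})

test_that("iterative overlap removal keeps the most significant peaks", {
  peaks <- data.frame(chrom = "chr1",
                      start = c(100, 400, 800), end = c(600, 900, 1300),
                      score = c(10, 8, 5), stringsAsFactors = FALSE)
  kept <- iterative_overlap_removal(peaks)
  expect_equal(kept$start, c(100, 800))  # B overlaps A; C clears A
  # tie between identical intervals: exactly one kept
  ties <- data.frame(chrom = "chr1", start = c(10, 10), end = c(50, 50),
                     score = c(5, 5))
  expect_equal(nrow(iterative_overlap_removal(ties)), 1)
  # non-overlapping input is unchanged (idempotence on clean input)
  clean <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(1, 100, 1), end = c(50, 150, 50),
                      score = c(1, 2, 3))
  expect_equal(iterative_overlap_removal(clean)$start, clean$start)
})

test_that("greedy removal matches the literal reference on random instances", {
  set.seed(2024)
  for (trial in 1:200) {
    peaks <- random_peaks(sample.int(12, 1))
    ours <- iterative_overlap_removal(peaks)
    ref <- greedy_reference(peaks)
    expect_equal(ours[, c("chrom", "start", "end", "score")],
                 ref[, c("chrom", "start", "end", "score")])
    expect_false(has_overlap(ours))
    # idempotence and order invariance
    expect_equal(iterative_overlap_removal(ours), ours)
    shuffled <- peaks[sample.int(nrow(peaks)), , drop = FALSE]
    expect_equal(iterative_overlap_removal(shuffled)$start, ours$start)
  }
})

test_that("sample score normalization scales totals to one million", {
  p <- data.frame(chrom = "chr1", start = c(1, 1000, 2000),
                  end = c(500, 1500, 2500), score = c(2, 3, 5))
  n <- normalize_sample_scores(p)
  expect_equal(n$score, c(2e5, 3e5, 5e5))
  expect_equal(sum(n$score), 1e6, tolerance = 1e-6)
  # symmetry and single-peak cases
  eq <- p; eq$score <- rep(7, 3)
  expect_equal(normalize_sample_scores(eq)$score, rep(1e6 / 3, 3))
  single <- p[1, ]; single$score <- 123.4
  expect_equal(normalize_sample_scores(single)$score, 1e6)
  # scale invariance
  scaled <- p; scaled$score <- p$score * 17.3
  expect_equal(normalize_sample_scores(scaled)$score, n$score)
  zero <- p; zero$score <- 0
  expect_error(normalize_sample_scores(zero), "positive score")
})

test_that("peak filters drop singletons, chrY and N-spanning peaks", {
  nm <- data.frame(chrom = "chr1", start = 5000, end = 5100)
  g <- tiny_genome(c(chr1 = 1e5, chrY = 5e4), n_masked = nm)
  peaks <- data.frame(
    chrom = c("chr1", "chrY", "chr1", "chr1", "chr1"),
    start = c(1000, 1000, 4900, 4399, 20000),
    end = c(1500, 1500, 5000, 4999, 20500),
    score = 1, stringsAsFactors = FALSE)
  support <- c(1, 10, 3, 3, 5)
  kept <- filter_peaks(peaks, support, g)
  # row 1 singleton, row 2 chrY, row 3 touches the N mask by 1 bp;
  # row 4 ends 1 bp clear of the mask and stays
  expect_equal(kept$start, c(4399, 20000))
})

test_that("pan-cancer construction merges shared peaks across samples", {
  g <- tiny_genome(c(chr1 = 1e5))
  # two samples share an overlapping peak at slightly shifted positions;
  # each also has a private anchor peak so normalization keeps score order
  s1 <- data.frame(chrom = "chr1", start = c(1000, 50000), end = c(1500, 50500),
                   summit = c(1250, 50250), score = c(9, 3))
  s2 <- data.frame(chrom = "chr1", start = c(1100, 50000), end = c(1600, 50500),
                   summit = c(1350, 50250), score = c(4, 8))
  pan <- build_pan_cancer_set(list(TYPE = list(A = s1, B = s2)), g)
  expect_equal(nrow(pan), 2)
  # at the shared locus the higher-share peak (sample A's, 9/12 of its mass)
  # wins the overlap
  expect_equal(pan$start[1], 1000)
  expect_false(has_overlap(pan))
  expect_identical(attr(pan, "provenance"), "pan_cancer")
  expect_error(build_pan_cancer_set(list(), g), "at least one")
})

test_that("pan-cancer output satisfies its postconditions on simulated calls", {
  sim <- simulate_cohort(sim_config(
    seed = 5, cohort_scale = 0.05, n_peaks = 600, n_genes = 150,
    sex_effect = list(n_female_up = 10, n_male_up = 2, lfc_range = c(0.5, 2)),
    subtype_effect = list(n_each = 5, lfc_range = c(1, 2)),
    survival_effect = list(n_positive = 3, n_negative = 3,
                           beta_range = c(0.3, 0.5), chrom = NULL)))
  per_sample <- lapply(sim$summit_calls, function(ss)
    lapply(ss, extend_summits, genome = sim$genome))
  pan <- build_pan_cancer_set(per_sample, sim$genome)
  expect_true(all(pan$end - pan$start + 1 == 501))
  expect_false(any(pan$chrom == "chrY"))
  expect_false(has_overlap(pan))
  # support >= 2 for every retained peak
  flat <- unlist(per_sample, recursive = FALSE)
  expect_true(all(peak_sample_support(pan, flat) >= 2))
  # no retained peak touches an N-masked interval
  nm <- sim$genome$n_masked
  touches <- vapply(seq_len(nrow(pan)), function(i) {
    any(nm$chrom == pan$chrom[i] & nm$start <= pan$end[i] & nm$end >= pan$start[i])
  }, logical(1))
  expect_false(any(touches))
})
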