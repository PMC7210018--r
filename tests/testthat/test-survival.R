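test_that("per-peak Cox estimates match an independent Newton-Raphson fit", {
  set.seed(31)
  n <- 60
  x <- rnorm(n)
  os <- simulate_survival_times(x, -0.5, h0 = 1 / 500, censor_rate = 0.25)
  ids <- sprintf("s%02d", 1:n)
  m <- matrix(x, 1, n, dimnames = list("pk", ids))
  rec <- cox_per_peak(m, surv_clinical(ids, os$os_time, os$os_event))
  beta_ref <- cox_nr_breslow(os$os_time, os$os_event, x)
  expect_equal(rec$beta, beta_ref, tolerance = 1e-6)
  expect_true(rec$ci_low < rec$hr && rec$hr < rec$ci_high)
  expect_gt(rec$hr, 0)
})

test_that("a null covariate gives a hazard ratio near one", {
  set.seed(32)
  n <- 500
  ids <- sprintf("s%03d", 1:n)
  os <- simulate_survival_times(rep(0, n), 0, h0 = 1 / 500, censor_rate = 0.3)
  x <- rnorm(n)  # independent of survival
  m <- matrix(x, 1, n, dimnames = list("pk", ids))
  rec <- cox_per_peak(m, surv_clinical(ids, os$os_time, os$os_event))
  expect_lt(abs(rec$beta), 0.15)
})

test_that("reversing the covariate sign inverts the hazard ratio exactly", {
  set.seed(33)
  n <- 80
  ids <- sprintf("s%02d", 1:n)
  x <- rnorm(n)
  os <- simulate_survival_times(x, 0.4, h0 = 1 / 300, censor_rate = 0.2)
  clin <- surv_clinical(ids, os$os_time, os$os_event)
  r1 <- cox_per_peak(matrix(x, 1, n, dimnames = list("pk", ids)), clin)
  r2 <- cox_per_peak(matrix(-x, 1, n, dimnames = list("pk", ids)), clin)
  expect_equal(r2$beta, -r1$beta, tolerance = 1e-8)
  expect_equal(r2$hr, 1 / r1$hr, tolerance = 1e-8)
  expect_equal(r2$ci_low, 1 / r1$ci_high, tolerance = 1e-8)
  expect_equal(r2$ci_high, 1 / r1$ci_low, tolerance = 1e-8)
  expect_equal(r2$p_wald, r1$p_wald, tolerance = 1e-8)
})

test_that("degenerate covariates are flagged, not propagated", {
  ids <- sprintf("s%d", 1:6)
  clin <- surv_clinical(ids, c(5, 8, 10, 12, 20, 30), c(1, 1, 0, 1, 1, 0))
  # constant covariate -> non-estimable, excluded from BH
  m <- rbind(flat = rep(2, 6), ok = c(1, 3, 2, 5, 4, 6))
  colnames(m) <- ids
  rec <- cox_per_peak(m, clin)
  expect_false(rec$estimable[1])
  expect_true(is.na(rec$q[1]))
  expect_true(rec$estimable[2])
  # monotone likelihood on the two-observation dataset: the covariate
  # perfectly orders the two events, beta diverges and the fit is flagged
  clin2 <- surv_clinical(c("a", "b"), c(1, 2), c(1, 1))
  m2 <- matrix(c(1, 0), 1, 2, dimnames = list("mono", c("a", "b")))
  rec2 <- cox_per_peak(m2, clin2)
  expect_false(rec2$estimable[1])
  # fewer than two events is an error
  expect_error(
    cox_per_peak(m, surv_clinical(ids, 1:6, c(1, 0, 0, 0, 0, 0))),
    "two events")
})

test_that("Cox direction agrees with the log-rank direction on two groups", {
  set.seed(34)
  agree <- 0
  n_trials <- 100
  for (trial in seq_len(n_trials)) {
    n <- 40
    grp <- rep(c(0, 1), each = n / 2)
    os <- simulate_survival_times(grp, runif(1, -1, 1), h0 = 1 / 100,
                                  censor_rate = 0.2)
    sd_fit <- survival::survdiff(survival::Surv(os$os_time, os$os_event) ~ grp)
    logrank_dir <- sign(sd_fit$obs[2] - sd_fit$exp[2])
    ids <- sprintf("s%02d", 1:n)
    rec <- cox_per_peak(matrix(grp, 1, n, dimnames = list("pk", ids)),
                        surv_clinical(ids, os$os_time, os$os_event))
    if (!rec$estimable || logrank_dir == 0) { agree <- agree + 1; next }
    agree <- agree + (sign(rec$beta) == logrank_dir)
  }
  expect_equal(agree, n_trials)
})

test_that("prognostic peaks are summarized per chromosome with directions", {
  peaks <- data.frame(peak_id = sprintf("p%d", 1:5),
                      chrom = c("chr2", "chr2", "chr2", "chr5", "chr5"))
  rec <- data.frame(peak_id = peaks$peak_id,
                    hr = c(1.2, 1.3, 0.8, 1.1, 0.9),
                    direction = c("positive", "positive", "negative",
                                  "positive", "negative"),
                    estimable = TRUE,
                    q = c(0.01, 0.02, 0.03, 0.9, 0.8))
  rec$prognostic <- rec$q < 0.05
  pl <- prognostic_landscape(rec, peaks)
  chr2 <- pl[pl$chrom == "chr2", ]
  expect_equal(chr2$n_prognostic, 3)
  expect_equal(chr2$pct_positive, 66.7)
  expect_equal(chr2$pct_negative, 33.3)
  chr5 <- pl[pl$chrom == "chr5", ]
  expect_equal(chr5$n_prognostic, 0)
  expect_equal(chr5$pct_positive, 0)
})

test_that("survival effects planted on one chromosome localize there", {
  sim <- simulate_cohort(sim_config(
    seed = 35, cohort_scale = 0.6, n_peaks = 1500, n_genes = 350,
    sex_effect = list(n_female_up = 5, n_male_up = 0, lfc_range = c(0.5, 2)),
    subtype_effect = list(n_each = 0, lfc_range = c(1, 2)),
    survival_effect = list(n_positive = 5, n_negative = 0,
                           beta_range = c(1.0, 1.3), chrom = "chr2")))
  norm <- normalize_counts(sim$counts, sim$replicate_map)
  prom <- sim$loci$peak_id[sim$loci$annotation == "promoter"]
  rec <- cox_per_peak(norm[prom, ], sim$clinical, alpha = 0.05)
  pl <- prognostic_landscape(rec, sim$loci)
  chr2 <- pl[pl$chrom == "chr2", ]
  other <- pl[pl$chrom != "chr2", ]
  expect_gt(chr2$n_prognostic, 2)
  expect_gt(chr2$pct_positive, 50)
  expect_lte(max(other$n_prognostic), 2)
})

test_that("Kaplan-Meier median split behaves at its boundaries", {
  ids <- sprintf("s%02d", 1:20)
  times <- rep(c(5, 10, 15, 20, 30), 4)
  events <- rep(c(1, 0, 1, 1, 0), 4)
  clin <- surv_clinical(ids, times, events)
  # identical survival in both groups -> log-rank p = 1
  v <- setNames(rep(c(0, 1), 10), ids)  # alternating, same times per group
  km <- km_median_split(v, clin)
  expect_equal(km$n_high + km$n_low, 20)
  expect_equal(km$logrank_p, 1, tolerance = 1e-9)
  # KM curves start at 1, never increase, drop only at event times
  expect_true(all(km$curves$surv <= 1))
  for (g in unique(km$curves$group)) {
    s <- km$curves$surv[km$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
  }
  drops <- km$curves[km$curves$n_event > 0, "time"]
  expect_true(all(drops %in% times[events == 1]))
  # constant intensities put everyone in the low group -> error
  expect_error(km_median_split(setNames(rep(3, 20), ids), clin),
               "fewer than 2")
})

test_that("a strong group effect is detected by the median-split log-rank test", {
  set.seed(36)
  n <- 300
  ids <- sprintf("s%03d", 1:n)
  grp <- rep(c(0, 1), each = n / 2)
  os <- simulate_survival_times(grp, log(0.5), h0 = 1 / 400, censor_rate = 0.3)
  km <- km_median_split(setNames(grp, ids),
                        surv_clinical(ids, os$os_time, os$os_event))
  expect_lt(km$logrank_p, 0.01)
  expect_equal(km$n_high, 150)
})
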