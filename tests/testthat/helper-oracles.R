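# Independent reference implementations used to cross-check the package.

# Literal greedy iterative removal: repeatedly pick the best remaining peak
# (highest score; ties by start, end, chromosome) and delete everything
# overlapping it. Deliberately naive and separate from the package's sweep.
greedy_reference <- function(peaks) {
  kept <- peaks[0, , drop = FALSE]
  pool <- peaks
  while (nrow(pool) > 0) {
    ord <- order(-pool$score, pool$start, pool$end, pool$chrom)
    best <- pool[ord[1], , drop = FALSE]
    kept <- rbind(kept, best)
    ov <- pool$chrom == best$chrom &
      pool$start <= best$end & pool$end >= best$start
    pool <- pool[!ov, , drop = FALSE]
  }
  kept <- kept[order(kept$chrom, kept$start, kept$end), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

# Random peak instance on up to two chromosomes, with integer scores so
# ties occur regularly.
random_peaks <- function(n, max_pos = 2000, width_range = c(1, 400)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             start = start, end = start + width - 1,
             score = sample(1:8, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Direct Benjamini-Hochberg step-up on a p-vector.
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Newton-Raphson maximization of the single-covariate Breslow partial
# likelihood, written from the score/information equations.
cox_nr_breslow <- function(time, event, x, tol = 1e-10, max_iter = 50) {
  beta <- 0
  for (it in seq_len(max_iter)) {
    w <- exp(beta * x)
    U <- 0
    I <- 0
    for (i in which(event == 1)) {
      rs <- time >= time[i]
      s0 <- sum(w[rs])
      s1 <- sum(w[rs] * x[rs])
      s2 <- sum(w[rs] * x[rs]^2)
      U <- U + x[i] - s1 / s0
      I <- I + s2 / s0 - (s1 / s0)^2
    }
    step <- U / I
    beta <- beta + step
    if (abs(step) < tol) break
  }
  beta
}

# Minimal genome for interval-level tests.
tiny_genome <- function(lengths = c(chr1 = 1e5, chr2 = 8e4), n_masked = NULL) {
  genome_model(data.frame(chrom = names(lengths),
                          length = as.numeric(lengths),
                          stringsAsFactors = FALSE),
               n_masked)
}

# Clinical table wrapper for survival helpers.
surv_clinical <- function(ids, time, event) {
  data.frame(sample_id = ids, cancer_type = "X", sex = NA, age = NA,
             stage = NA, histology = NA, pam50 = NA,
             os_time = time, os_event = event, stringsAsFactors = FALSE)
}

has_overlap <- function(peaks) {
  if (nrow(peaks) < 2) return(FALSE)
  any(vapply(seq_len(nrow(peaks) - 1), function(i) {
    j <- (i + 1):nrow(peaks)
    any(peaks$chrom[j] == peaks$chrom[i] &
          peaks$start[j] <= peaks$end[i] & peaks$end[j] >= peaks$start[i])
  }, logical(1)))
}
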