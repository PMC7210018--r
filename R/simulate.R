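# GRCh38 chromosome lengths (bp); the simulated genome is a scaled-down copy
grch38_lengths <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468, chrX = 156040895, chrY = 57227415)

#' Reference 23-cancer-type cohort composition
#'
#' The per-type sample counts of the 404-patient pan-cancer ATAC-seq cohort
#' (breast cancer largest with 74 patients, cervical cancer smallest with
#' 2). Used as the default cohort composition for simulated cohorts.
#'
#' @return data.frame with `cancer_type` and `n` columns (sum 404).
#' @export
tcga_cohort_table <- function() {
  data.frame(
    cancer_type = c("BRCA", "COAD", "KIRP", "PRAD", "LUAD", "STAD", "ESCA",
                    "LIHC", "KIRC", "LUSC", "THCA", "LGG", "SKCM", "UCEC",
                    "BLCA", "ACC", "GBM", "HNSC", "PCPG", "TGCT", "MESO",
                    "CHOL", "CESC"),
    n = c(74, 38, 34, 26, 22, 21, 18, 17, 16, 16, 14, 13, 13, 13, 10, 9, 9,
          9, 9, 9, 7, 5, 2),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Parameters of the synthetic pan-cancer cohort. Defaults emulate the
#' study conditions of the reference cohort: 23 cancer types in the printed
#' proportions (404 samples), a genome scaled to 1/100 of GRCh38 so
#' permutation nulls stay fast while the 92-segment statistic is unchanged,
#' negative-binomial peak counts (log-normal means, dispersion 0.3),
#' female-up chrX promoter peaks mimicking the X-inactivation signature,
#' fold-change-2 subtype peaks for the lung-histology and BRCA-basal
#' contrasts, and promoter peaks whose standardized intensity enters an
#' exponential survival hazard.
#'
#' @param seed master RNG seed.
#' @param chrom_scale genome length scale relative to GRCh38 (default 0.01).
#' @param n_genes number of annotated genes.
#' @param n_peaks number of peak loci in the count matrix.
#' @param promoter_fraction fraction of loci placed in promoter windows.
#' @param cohort data.frame `cancer_type`/`n` (default [tcga_cohort_table()]).
#' @param cohort_scale multiplier on per-type sample counts (minimum 2 per
#'   type), for desk-scale runs.
#' @param mu_meanlog,mu_sdlog log-normal parameters of per-peak mean counts.
#' @param dispersion negative-binomial dispersion phi (variance
#'   `mu + phi mu^2`).
#' @param libsize_sd sd of the log-normal per-replicate depth factor.
#' @param replicate_fraction fraction of samples with two technical
#'   replicates.
#' @param detect_prob probability a locus yields a summit call in a sample.
#' @param sex_effect list: `n_female_up` chrX promoter peaks up in females,
#'   `n_male_up` autosomal promoter peaks up in males, `lfc_range`.
#' @param subtype_effect list: `n_each` peaks up per side of the lung
#'   (LUAD/LUSC) and BRCA (basal/non-basal) contrasts, `lfc_range`.
#' @param survival_effect list: `n_positive`/`n_negative` promoter peaks
#'   with per-unit log-hazard `beta_range` (positive = worse survival),
#'   optional `chrom` restricting where they are planted.
#' @param censor_rate target administrative censoring fraction.
#' @param h0 baseline hazard per day.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, chrom_scale = 0.01, n_genes = 400,
                       n_peaks = 2000, promoter_fraction = 0.4,
                       cohort = tcga_cohort_table(), cohort_scale = 1,
                       mu_meanlog = log(50), mu_sdlog = 0.7,
                       dispersion = 0.3, libsize_sd = 0.2,
                       replicate_fraction = 0.1, detect_prob = 0.85,
                       sex_effect = list(n_female_up = 100, n_male_up = 20,
                                         lfc_range = c(0.5, 2)),
                       subtype_effect = list(n_each = 50,
                                             lfc_range = c(1, 2.5)),
                       survival_effect = list(n_positive = 8,
                                              n_negative = 8,
                                              beta_range = c(0.5, 0.8),
                                              chrom = NULL),
                       censor_rate = 0.3, h0 = 1 / 1000) {
  cohort$n <- pmax(2L, as.integer(round(cohort$n * cohort_scale)))
  cfg <- list(seed = seed, chrom_scale = chrom_scale, n_genes = n_genes,
              n_peaks = n_peaks, promoter_fraction = promoter_fraction,
              cohort = cohort, mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog,
              dispersion = dispersion, libsize_sd = libsize_sd,
              replicate_fraction = replicate_fraction,
              detect_prob = detect_prob, sex_effect = sex_effect,
              subtype_effect = subtype_effect,
              survival_effect = survival_effect,
              censor_rate = censor_rate, h0 = h0)
  n_planted <- sex_effect$n_female_up + sex_effect$n_male_up +
    4 * subtype_effect$n_each + survival_effect$n_positive +
    survival_effect$n_negative
  if (n_planted > floor(promoter_fraction * n_peaks))
    stop("infeasible config: more planted peaks than promoter peaks")
  class(cfg) <- "sim_config"
  cfg
}

#' Exponential survival times under proportional hazards
#'
#' Event times are exponential with per-sample hazard
#' `h0 * exp(z %*% beta)`; administrative censoring times are exponential
#' with rate `h0 * censor_rate / (1 - censor_rate)`, which yields
#' approximately the target censoring fraction at the baseline hazard.
#'
#' @param z numeric matrix (samples x covariates) of standardized
#'   intensities, or a vector for one covariate.
#' @param beta per-covariate log-hazard coefficients.
#' @param h0 baseline hazard.
#' @param censor_rate target censoring fraction in `[0, 1)`.
#' @return data.frame with `os_time` (days, >= 1) and `os_event` (0/1).
#' @export
simulate_survival_times <- function(z, beta, h0 = 1 / 1000,
                                    censor_rate = 0.3) {
  z <- as.matrix(z)
  stopifnot(ncol(z) == length(beta), censor_rate >= 0, censor_rate < 1)
  hazard <- h0 * exp(drop(z %*% beta))
  t_event <- stats::rexp(nrow(z), hazard)
  t_cens <- if (censor_rate > 0)
    stats::rexp(nrow(z), h0 * censor_rate / (1 - censor_rate))
  else rep(Inf, nrow(z))
  data.frame(os_time = pmax(1, ceiling(pmin(t_event, t_cens))),
             os_event = as.integer(t_event <= t_cens))
}

#' Simulate a complete synthetic pan-cancer cohort
#'
#' Generates every input the pipeline consumes — genome model (with
#' N-masked intervals and a chrY decoy), TSS annotation, per-sample summit
#' calls, raw peak-by-replicate count matrix with annotation columns,
#' clinical table with overall survival — plus a truth table recording
#' every planted effect. All randomness flows from `cfg$seed`; the same
#' config reproduces identical outputs.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `config`, `genome`, `genes`, `loci`
#'   (peak annotation), `summit_calls` (nested cancer type -> sample),
#'   `counts` (peaks x replicates), `replicate_map`, `clinical`, `truth`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  ## genome ------------------------------------------------------------
  lens <- round(grch38_lengths * cfg$chrom_scale)
  chroms <- data.frame(chrom = names(lens), length = as.numeric(lens),
                       stringsAsFactors = FALSE)
  analysis_chroms <- setdiff(chroms$chrom, "chrY")
  nmask <- do.call(rbind, lapply(analysis_chroms, function(ch) {
    L <- lens[[ch]]
    width <- max(200, round(L * 0.002))
    start <- sort(sample.int(L - width, 2))
    data.frame(chrom = ch, start = start, end = start + width - 1,
               stringsAsFactors = FALSE)
  }))
  genome <- genome_model(chroms, nmask)

  ## gene annotation ----------------------------------------------------
  sex_eff <- cfg$sex_effect
  n_x_genes <- max(ceiling(0.12 * cfg$n_genes),
                   ceiling(sex_eff$n_female_up / 3))
  auto <- setdiff(analysis_chroms, "chrX")
  gene_chrom <- c(rep("chrX", n_x_genes),
                  sample(auto, cfg$n_genes - n_x_genes, replace = TRUE,
                         prob = lens[auto]))
  gene_tss <- vapply(gene_chrom, function(ch)
    sample(2000:(lens[[ch]] - 2000), 1), numeric(1))
  genes <- gene_annotation(data.frame(
    gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
    symbol = sprintf("GENE%04d", seq_len(cfg$n_genes)),
    chrom = gene_chrom, tss = gene_tss,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    stringsAsFactors = FALSE), genome)

  ## peak loci ----------------------------------------------------------
  n_prom <- round(cfg$promoter_fraction * cfg$n_peaks)
  n_sex <- sex_eff$n_female_up
  chrx_gene_idx <- which(genes$chrom == "chrX")
  prom_gene <- c(sample(chrx_gene_idx, n_sex, replace = TRUE),
                 sample(seq_len(cfg$n_genes), n_prom - n_sex, replace = TRUE))
  offset <- sample(-1000:100, n_prom, replace = TRUE)  # transcription-oriented
  prom_summit <- ifelse(genes$strand[prom_gene] == "+",
                        genes$tss[prom_gene] + offset,
                        genes$tss[prom_gene] - offset)
  prom_chrom <- genes$chrom[prom_gene]
  n_other <- cfg$n_peaks - n_prom
  other_chrom <- sample(analysis_chroms, n_other, replace = TRUE,
                        prob = lens[analysis_chroms])
  other_summit <- vapply(other_chrom, function(ch)
    sample(300:(lens[[ch]] - 300), 1), numeric(1))
  loci <- data.frame(
    peak_id = sprintf("L%05d", seq_len(cfg$n_peaks)),
    chrom = c(prom_chrom, other_chrom),
    summit = pmin(pmax(c(prom_summit, other_summit), 300),
                  lens[c(prom_chrom, other_chrom)] - 300),
    annotation = c(rep("promoter", n_prom),
                   sample(c("distal", "intron", "exon", "3'UTR", "5'UTR"),
                          n_other, replace = TRUE,
                          prob = c(0.45, 0.35, 0.1, 0.05, 0.05))),
    stringsAsFactors = FALSE)
  loci$start <- loci$summit - 250
  loci$end <- loci$summit + 250

  ## planted-effect assignment (disjoint promoter loci) -----------------
  sub_eff <- cfg$subtype_effect
  surv_eff <- cfg$survival_effect
  pool_x <- seq_len(n_sex)                       # chrX promoter loci
  pool_auto <- setdiff(seq_len(n_prom), pool_x)  # remaining promoter loci
  draw <- function(pool, n) {
    if (n > length(pool)) stop("infeasible config: planted peaks exhausted promoter loci")
    pool[seq_len(n)]
  }
  idx_female <- pool_x
  idx_male <- draw(pool_auto, sex_eff$n_male_up)
  pool_auto <- setdiff(pool_auto, idx_male)
  idx_luad <- draw(pool_auto, sub_eff$n_each)
  pool_auto <- setdiff(pool_auto, idx_luad)
  idx_lusc <- draw(pool_auto, sub_eff$n_each)
  pool_auto <- setdiff(pool_auto, idx_lusc)
  idx_basal <- draw(pool_auto, sub_eff$n_each)
  pool_auto <- setdiff(pool_auto, idx_basal)
  idx_nonbasal <- draw(pool_auto, sub_eff$n_each)
  pool_auto <- setdiff(pool_auto, idx_nonbasal)
  surv_pool <- if (is.null(surv_eff$chrom)) pool_auto
    else intersect(pool_auto, which(loci$chrom == surv_eff$chrom))
  idx_surv_pos <- draw(surv_pool, surv_eff$n_positive)
  surv_pool <- setdiff(surv_pool, idx_surv_pos)
  idx_surv_neg <- draw(surv_pool, surv_eff$n_negative)

  runif_in <- function(n, r) stats::runif(n, r[1], r[2])
  truth_block <- function(idx, effect, contrast, lfc = NULL, beta = NULL) {
    n <- length(idx)
    data.frame(peak_id = loci$peak_id[idx],
               effect = rep_len(effect, n), contrast = rep_len(contrast, n),
               log2fc = if (is.null(lfc)) rep(NA_real_, n) else lfc,
               beta = if (is.null(beta)) rep(NA_real_, n) else beta,
               stringsAsFactors = FALSE)
  }
  truth <- rbind(
    truth_block(idx_female, "sex_female_up", "sex",
                lfc = runif_in(length(idx_female), sex_eff$lfc_range)),
    truth_block(idx_male, "sex_male_up", "sex",
                lfc = runif_in(length(idx_male), sex_eff$lfc_range)),
    truth_block(idx_luad, "luad_up", "histology_lung",
                lfc = runif_in(length(idx_luad), sub_eff$lfc_range)),
    truth_block(idx_lusc, "lusc_up", "histology_lung",
                lfc = runif_in(length(idx_lusc), sub_eff$lfc_range)),
    truth_block(idx_basal, "basal_up", "brca_basal",
                lfc = runif_in(length(idx_basal), sub_eff$lfc_range)),
    truth_block(idx_nonbasal, "nonbasal_up", "brca_basal",
                lfc = runif_in(length(idx_nonbasal), sub_eff$lfc_range)),
    truth_block(idx_surv_pos, "survival_positive", "survival",
                beta = runif_in(length(idx_surv_pos), surv_eff$beta_range)),
    truth_block(idx_surv_neg, "survival_negative", "survival",
                beta = -runif_in(length(idx_surv_neg), surv_eff$beta_range)))

  ## clinical table (survival filled in after counts) -------------------
  cohort <- cfg$cohort
  n_samples <- sum(cohort$n)
  cancer_type <- rep(cohort$cancer_type, cohort$n)
  sample_id <- sprintf("S%04d", seq_len(n_samples))
  sex <- ifelse(cancer_type %in% c("PRAD", "TGCT"), "male",
         ifelse(cancer_type %in% c("BRCA", "UCEC", "CESC"), "female",
                sample(c("male", "female"), n_samples, replace = TRUE)))
  age <- pmin(90, pmax(25, round(stats::rnorm(n_samples, 59, 12))))
  no_stage <- c("GBM", "LGG", "PCPG", "PRAD", "UCEC")
  stage <- ifelse(cancer_type %in% no_stage, NA_character_,
                  sample(c("I", "II", "III", "IV"), n_samples,
                         replace = TRUE, prob = c(0.30, 0.28, 0.25, 0.17)))
  stage[!is.na(stage) & stats::runif(n_samples) < 0.05] <- NA
  pam50 <- rep(NA_character_, n_samples)
  brca <- which(cancer_type == "BRCA")
  pam50[brca] <- sample(c("Basal", "LumA", "LumB", "Her2", "Normal"),
                        length(brca), replace = TRUE,
                        prob = c(13, 29, 16, 10, 3))
  # keep the basal/non-basal contrast formable in down-scaled cohorts
  if (length(brca) >= 4) {
    fix <- sample(brca, 4)
    if (sum(pam50[brca] == "Basal") < 2) pam50[fix[1:2]] <- "Basal"
    if (sum(pam50[brca] != "Basal") < 2) pam50[fix[3:4]] <- "LumA"
  }
  if (length(brca) > 20) pam50[sample(brca, 3)] <- NA

  ## raw counts (negative binomial, effects multiplicative on the mean) --
  mu <- stats::rlnorm(cfg$n_peaks, cfg$mu_meanlog, cfg$mu_sdlog)
  eff <- matrix(0, cfg$n_peaks, n_samples)  # log2 effect on the NB mean
  add_eff <- function(eff, idx, samples, lfc) {
    eff[idx, samples] <- eff[idx, samples] + lfc
    eff
  }
  eff <- add_eff(eff, idx_female, sex == "female",
                 truth$log2fc[truth$effect == "sex_female_up"])
  eff <- add_eff(eff, idx_male, sex == "male",
                 truth$log2fc[truth$effect == "sex_male_up"])
  eff <- add_eff(eff, idx_luad, cancer_type == "LUAD",
                 truth$log2fc[truth$effect == "luad_up"])
  eff <- add_eff(eff, idx_lusc, cancer_type == "LUSC",
                 truth$log2fc[truth$effect == "lusc_up"])
  eff <- add_eff(eff, idx_basal, !is.na(pam50) & pam50 == "Basal",
                 truth$log2fc[truth$effect == "basal_up"])
  eff <- add_eff(eff, idx_nonbasal,
                 !is.na(pam50) & pam50 %in% c("LumA", "LumB", "Her2", "Normal"),
                 truth$log2fc[truth$effect == "nonbasal_up"])

  n_reps <- 1L + (stats::runif(n_samples) < cfg$replicate_fraction)
  rep_sample <- rep(seq_len(n_samples), n_reps)
  column_id <- unlist(lapply(seq_len(n_samples), function(i)
    if (n_reps[i] == 1) sample_id[i]
    else paste0(sample_id[i], "_r", seq_len(n_reps[i]))))
  depth <- stats::rlnorm(length(column_id), 0, cfg$libsize_sd)
  MU <- (mu * 2^eff[, rep_sample, drop = FALSE]) *
    rep(depth, each = cfg$n_peaks)
  counts <- matrix(stats::rnbinom(length(MU), mu = MU,
                                  size = 1 / cfg$dispersion),
                   nrow = cfg$n_peaks,
                   dimnames = list(loci$peak_id, column_id))
  replicate_map <- data.frame(column_id = column_id,
                              sample_id = sample_id[rep_sample],
                              stringsAsFactors = FALSE)

  ## survival driven by standardized planted-peak intensities -----------
  idx_surv <- c(idx_surv_pos, idx_surv_neg)
  beta_surv <- truth$beta[truth$contrast == "survival"]
  per_sample <- vapply(seq_len(n_samples), function(i) {
    rowMeans(counts[idx_surv, rep_sample == i, drop = FALSE])
  }, numeric(length(idx_surv)))
  z <- t(scale(t(log2(per_sample + 1))))  # standardize per peak
  os <- simulate_survival_times(t(z), beta_surv, cfg$h0, cfg$censor_rate)
  os[sample.int(n_samples, min(3, n_samples)), ] <- NA  # samples lacking clinical data
  clinical <- data.frame(sample_id = sample_id, cancer_type = cancer_type,
                         sex = sex, age = age, stage = stage,
                         histology = cancer_type, pam50 = pam50,
                         os_time = os$os_time, os_event = os$os_event,
                         stringsAsFactors = FALSE)

  ## per-sample summit calls --------------------------------------------
  strength <- stats::rlnorm(cfg$n_peaks, 1, 0.5)
  chry_len <- lens[["chrY"]]
  summit_calls <- lapply(split(sample_id, cancer_type)[unique(cancer_type)],
    function(ids) {
      calls <- lapply(ids, function(s) {
        det <- stats::runif(cfg$n_peaks) < cfg$detect_prob
        jitter <- round(stats::rnorm(sum(det), 0, 20))
        summ <- pmin(pmax(loci$summit[det] + jitter, 251),
                     lens[loci$chrom[det]] - 250)
        # decoy chrY calls exercising the chrY filter
        data.frame(
          chrom = c(loci$chrom[det], rep("chrY", 2)),
          summit = c(summ, sample(300:(chry_len - 300), 2)),
          score = c(stats::rgamma(sum(det), 2, scale = strength[det]),
                    stats::rgamma(2, 2, scale = 1)),
          stringsAsFactors = FALSE)
      })
      stats::setNames(calls, ids)
    })

  list(config = cfg, genome = genome, genes = genes, loci = loci,
       summit_calls = summit_calls, counts = counts,
       replicate_map = replicate_map, clinical = clinical, truth = truth)
}

#' Write a simulated cohort as a plain-text fixture bundle
#'
#' Emits every pipeline input in its on-disk format: `chrom.sizes`,
#' `nmask.bed` (0-based half-open), `tss.tsv` (BED6-like), per-sample
#' summit TSVs under `summits/<cancer_type>/`, the annotated raw count
#' matrix, the replicate map, the clinical table, and the planted-effect
#' truth table. Files round-trip through the package readers without loss.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  ok <- dir.exists(dir) ||
    suppressWarnings(dir.create(dir, recursive = TRUE))
  if (!ok || file.access(dir, 2) != 0) stop("cannot write to directory: ", dir)
  chroms <- sim$genome$chromosomes
  utils::write.table(chroms, file.path(dir, "chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  nm <- sim$genome$n_masked
  utils::write.table(data.frame(nm$chrom, nm$start - 1, nm$end),
                     file.path(dir, "nmask.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- sim$genes
  utils::write.table(data.frame(g$chrom, g$tss - 1, g$tss, g$gene_id,
                                g$symbol, g$strand),
                     file.path(dir, "tss.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (ct in names(sim$summit_calls)) {
    ct_dir <- file.path(dir, "summits", ct)
    dir.create(ct_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(sim$summit_calls[[ct]]))
      utils::write.table(sim$summit_calls[[ct]][[s]],
                         file.path(ct_dir, paste0(s, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  write_count_matrix(sim$loci, sim$counts, file.path(dir, "counts.tsv"))
  utils::write.table(sim$replicate_map, file.path(dir, "replicate_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir bundle directory.
#' @return list with `genome`, `genes`, `loci`, `summit_calls`, `counts`,
#'   `replicate_map`, `clinical`, `truth`.
#' @export
read_fixture_bundle <- function(dir) {
  genome <- read_chrom_sizes(file.path(dir, "chrom.sizes"),
                             file.path(dir, "nmask.bed"))
  genes <- read_tss_table(file.path(dir, "tss.tsv"), genome)
  cm <- read_count_matrix(file.path(dir, "counts.tsv"))
  summit_root <- file.path(dir, "summits")
  summit_calls <- lapply(
    stats::setNames(nm = list.dirs(summit_root, recursive = FALSE,
                                   full.names = FALSE)),
    function(ct) {
      files <- list.files(file.path(summit_root, ct), pattern = "\\.tsv$",
                          full.names = TRUE)
      stats::setNames(
        lapply(files, utils::read.table, sep = "\t", header = TRUE, quote = "",
               stringsAsFactors = FALSE),
        sub("\\.tsv$", "", basename(files)))
    })
  list(genome = genome, genes = genes, loci = cm$peaks, counts = cm$counts,
       summit_calls = summit_calls,
       replicate_map = utils::read.table(file.path(dir, "replicate_map.tsv"), quote = "",
                                         sep = "\t", header = TRUE,
                                         stringsAsFactors = FALSE),
       clinical = read_clinical_table(file.path(dir, "clinical.tsv")),
       truth = utils::read.table(file.path(dir, "truth.tsv"), sep = "\t", quote = "",
                                 header = TRUE, stringsAsFactors = FALSE))
}
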