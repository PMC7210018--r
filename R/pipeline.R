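#' Pipeline configuration
#'
#' Paths, stage toggles, thresholds and seeds for an end-to-end run over a
#' fixture bundle: curate -> normalize -> annotate -> landscape /
#' associate / survive.
#'
#' @param input_dir fixture bundle directory (see [write_fixture_bundle()]).
#' @param out_dir output directory for result tables and the manifest.
#' @param stages character subset of
#'   `c("curate", "normalize", "landscape", "associate", "survive")`.
#' @param contrasts clinical contrasts to run (see [clinical_contrast()]).
#' @param fdr BH threshold for association contrasts (default 0.01).
#' @param alpha BH threshold for prognostic peaks (default 0.05).
#' @param prior prior count for normalization (default 5).
#' @param n_perm permutation replicates for the landscape (default 1000 at
#'   desk scale; the reference procedure uses 10^6).
#' @param n_segments segments per chromosome (default 92).
#' @param seed RNG seed for the permutation null.
#' @param peak_width fixed peak width (default 501).
#' @param promoter_only restrict association/survival to promoter peaks
#'   (default TRUE).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            stages = c("curate", "normalize", "landscape",
                                       "associate", "survive"),
                            contrasts = c("sex", "age", "stage",
                                          "histology_lung", "brca_basal"),
                            fdr = 0.01, alpha = 0.05, prior = 5,
                            n_perm = 1000, n_segments = 92, seed = 17,
                            peak_width = 501, promoter_only = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(fdr > 0, fdr < 1, alpha > 0, alpha < 1, n_perm >= 1)
  structure(list(input_dir = input_dir, out_dir = out_dir, stages = stages,
                 contrasts = contrasts, fdr = fdr, alpha = alpha,
                 prior = prior, n_perm = n_perm, n_segments = n_segments,
                 seed = seed, peak_width = peak_width,
                 promoter_only = promoter_only),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order over a fixture bundle
#' and writes one provenance-stamped TSV per result plus a run manifest
#' (package version, seed, parameters, input checksums). Re-running with an
#' identical config reproduces byte-identical outputs.
#'
#' Stages:
#' \describe{
#'   \item{curate}{[build_pan_cancer_set()] from the per-sample summit
#'     calls; writes `pan_cancer_peaks.bed`.}
#'   \item{normalize}{[normalize_counts()] on the raw matrix; writes
#'     `normalized_matrix.tsv`.}
#'   \item{landscape}{[ppmb()] by category and [permutation_landscape()]
#'     on the count-matrix peaks; writes `ppmb.tsv`, `landscape.tsv`.}
#'   \item{associate}{[mann_whitney_bh()] per clinical contrast on promoter
#'     peaks; writes `assoc_<contrast>.tsv`.}
#'   \item{survive}{[cox_per_peak()] on promoter peaks plus
#'     [prognostic_landscape()]; writes `survival.tsv`,
#'     `prognostic_by_chrom.tsv`.}
#' }
#'
#' @param cfg a [pipeline_config()].
#' @return list of in-memory results (invisibly): elements mirror the
#'   written files.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(cfg$input_dir)) stop("input directory not found: ",
                                       cfg$input_dir)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- read_fixture_bundle(cfg$input_dir)
  params <- cfg[setdiff(names(cfg), c("input_dir", "out_dir"))]
  results <- list()

  ## peak annotation shared by landscape/associate/survive
  peaks <- bundle$loci
  peaks$category <- assign_category(peaks$annotation)
  peaks <- assign_promoter_peaks(peaks, bundle$genes)
  analysis_genome <- genome_model(
    bundle$genome$chromosomes[bundle$genome$chromosomes$chrom != "chrY", ],
    bundle$genome$n_masked)

  if ("curate" %in% cfg$stages) {
    per_sample <- lapply(bundle$summit_calls, function(samples)
      lapply(samples, extend_summits, genome = bundle$genome,
             width = cfg$peak_width))
    results$pan_cancer <- build_pan_cancer_set(per_sample, bundle$genome)
    write_peak_bed(results$pan_cancer,
                   file.path(cfg$out_dir, "pan_cancer_peaks.bed"))
  }

  norm <- NULL
  if (any(c("normalize", "associate", "survive") %in% cfg$stages)) {
    norm <- normalize_counts(bundle$counts, bundle$replicate_map, cfg$prior)
    results$normalized <- norm
    if ("normalize" %in% cfg$stages) {
      out <- data.frame(peak_id = rownames(norm),
                        as.data.frame(unclass(norm), check.names = FALSE),
                        check.names = FALSE)
      write_result_tsv(out, file.path(cfg$out_dir, "normalized_matrix.tsv"),
                       "normalize", params)
    }
  }

  if ("landscape" %in% cfg$stages) {
    results$ppmb <- do.call(rbind, lapply(
      c("all", "promoter", "enhancer", "intron", "other"), function(cat) {
        d <- ppmb(peaks, analysis_genome,
                  category = if (cat == "all") NULL else cat)
        d$category <- cat
        d
      }))
    write_result_tsv(results$ppmb, file.path(cfg$out_dir, "ppmb.tsv"),
                     "landscape", params)
    results$landscape <- permutation_landscape(
      peaks, analysis_genome, n_perm = cfg$n_perm, seed = cfg$seed,
      n_segments = cfg$n_segments)
    write_result_tsv(
      results$landscape[, c("chrom", "segment", "seg_start", "seg_end",
                            "n_peaks", "density_per_mb", "p", "score")],
      file.path(cfg$out_dir, "landscape.tsv"), "landscape", params)
  }

  test_rows <- if (cfg$promoter_only) peaks$category == "promoter"
    else rep(TRUE, nrow(peaks))
  if ("associate" %in% cfg$stages) {
    results$association <- list()
    for (ct in cfg$contrasts) {
      contrast <- clinical_contrast(bundle$clinical, ct, cfg$fdr)
      rec <- mann_whitney_bh(norm[test_rows, , drop = FALSE], contrast)
      rec$gene <- peaks$nearest_gene[match(rec$peak_id, peaks$peak_id)]
      rec$dist_to_tss <- peaks$dist_to_tss[match(rec$peak_id, peaks$peak_id)]
      results$association[[ct]] <- rec
      write_result_tsv(rec, file.path(cfg$out_dir,
                                      sprintf("assoc_%s.tsv", ct)),
                       paste0("associate:", ct), params)
    }
  }

  if ("survive" %in% cfg$stages) {
    results$survival <- cox_per_peak(norm[test_rows, , drop = FALSE],
                                     bundle$clinical, alpha = cfg$alpha)
    results$survival$gene <-
      peaks$nearest_gene[match(results$survival$peak_id, peaks$peak_id)]
    write_result_tsv(results$survival,
                     file.path(cfg$out_dir, "survival.tsv"), "survive", params)
    results$prognostic_by_chrom <-
      prognostic_landscape(results$survival, peaks)
    write_result_tsv(results$prognostic_by_chrom,
                     file.path(cfg$out_dir, "prognostic_by_chrom.tsv"),
                     "survive", params)
  }

  manifest <- c(
    sprintf("package_version\t%s",
            as.character(utils::packageVersion("chromaccess"))),
    sprintf("seed\t%s", cfg$seed),
    sprintf("params_md5\t%s", params_hash(params)),
    sprintf("stages\t%s", paste(cfg$stages, collapse = ",")),
    vapply(sort(list.files(cfg$input_dir, recursive = TRUE,
                           full.names = TRUE)),
           function(f) sprintf("input_md5\t%s\t%s",
                               sub(paste0("^", cfg$input_dir, "/?"), "", f),
                               unname(tools::md5sum(f))),
           character(1), USE.NAMES = FALSE))
  writeLines(manifest, file.path(cfg$out_dir, "manifest.txt"))
  invisible(results)
}
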