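#' Extend summit calls to fixed-width peaks
#'
#' Each summit is extended equally on both sides to the target width
#' (501 bp by default, so 250 bp each side). Windows that would run past a
#' chromosome edge are dropped rather than clipped: the entire pipeline
#' relies on all peaks sharing one width so intensities are comparable.
#'
#' @param calls data.frame of summit calls with columns `chrom`, `summit`
#'   (1-based), `score`.
#' @param genome a [genome_model()].
#' @param width odd peak width in bp (default 501).
#' @return data.frame of peaks (`chrom`, `start`, `end`, `summit`, `score`);
#'   out-of-bounds windows are absent from the result.
#' @export
extend_summits <- function(calls, genome, width = 501) {
  if (width %% 2 == 0 || width <= 0) stop("peak width must be odd and positive")
  half <- (width - 1) / 2
  len <- chrom_length(genome, calls$chrom)
  start <- calls$summit - half
  end <- calls$summit + half
  keep <- start >= 1 & end <= len
  out <- data.frame(chrom = calls$chrom, start = start, end = end,
                    summit = calls$summit, score = calls$score,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative overlap removal
#'
#' Greedy curation that retains the most significant peaks: repeatedly keep
#' the highest-scoring remaining peak and discard every remaining peak that
#' overlaps it by at least 1 bp. Equal scores are broken deterministically
#' by smaller start, then smaller end, then chromosome name. The result is
#' pairwise non-overlapping, and every discarded peak overlaps some kept
#' peak of at least its score; the operation is idempotent and independent
#' of input row order.
#'
#' Implemented as a single score-ordered sweep: a peak is kept iff it does
#' not overlap any previously kept peak, which is equivalent to the literal
#' remove-as-you-go procedure.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, `score` (1-based
#'   inclusive intervals).
#' @return the kept subset, sorted by chromosome then start.
#' @export
iterative_overlap_removal <- function(peaks) {
  if (nrow(peaks) == 0) return(peaks)
  ord <- order(-peaks$score, peaks$start, peaks$end, peaks$chrom)
  p <- peaks[ord, , drop = FALSE]
  keep <- logical(nrow(p))
  kept_by_chrom <- split(seq_len(nrow(p)), p$chrom)
  for (idx in kept_by_chrom) {
    ks <- numeric(0)  # starts/ends of peaks kept so far on this chromosome
    ke <- numeric(0)
    for (i in idx) {
      if (!any(p$start[i] <= ke & p$end[i] >= ks)) {
        keep[i] <- TRUE
        ks <- c(ks, p$start[i])
        ke <- c(ke, p$end[i])
      }
    }
  }
  out <- p[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score normalization within a sample
#'
#' Score-per-million scaling for sample quality and sequencing depth: each
#' peak score is divided by the sample's total score divided by one million,
#' so normalized scores sum to 10^6 within the sample.
#'
#' @param peaks data.frame with a `score` column (one sample's peaks).
#' @return `peaks` with rescaled scores.
#' @export
normalize_sample_scores <- function(peaks) {
  total <- sum(peaks$score)
  if (nrow(peaks) == 0 || total <= 0)
    stop("score normalization needs at least one peak with positive score")
  peaks$score <- peaks$score / (total / 1e6)
  peaks
}

#' Count per-sample support for candidate peaks
#'
#' Support of a candidate peak is the number of samples whose peak set
#' overlaps it by at least 1 bp.
#'
#' @param candidates data.frame of candidate peaks (`chrom`, `start`, `end`).
#' @param per_sample_sets list of per-sample peak data.frames.
#' @return integer vector of per-candidate support counts.
#' @export
peak_sample_support <- function(candidates, per_sample_sets) {
  cand_gr <- GenomicRanges::GRanges(candidates$chrom,
                                    IRanges::IRanges(candidates$start,
                                                     candidates$end))
  support <- integer(nrow(candidates))
  for (ps in per_sample_sets) {
    if (nrow(ps) == 0) next
    gr <- GenomicRanges::GRanges(ps$chrom, IRanges::IRanges(ps$start, ps$end))
    support <- support +
      (GenomicRanges::countOverlaps(cand_gr, gr, ignore.strand = TRUE) > 0)
  }
  support
}

#' Quality filters on a pooled peak set
#'
#' Removes peaks observed in only one sample, peaks on the Y chromosome,
#' and peaks spanning a genomic region containing N nucleotides (any
#' overlap with an N-masked interval disqualifies).
#'
#' @param peaks data.frame of peaks (`chrom`, `start`, `end`, ...).
#' @param sample_support integer vector of per-peak sample support.
#' @param genome a [genome_model()] carrying the N-mask.
#' @return the filtered peak data.frame.
#' @export
filter_peaks <- function(peaks, sample_support, genome) {
  stopifnot(length(sample_support) == nrow(peaks))
  keep <- sample_support >= 2 & peaks$chrom != "chrY"
  nm <- genome$n_masked
  if (nrow(nm) > 0 && any(keep)) {
    peak_gr <- GenomicRanges::GRanges(peaks$chrom,
                                      IRanges::IRanges(peaks$start, peaks$end))
    nm_gr <- GenomicRanges::GRanges(nm$chrom, IRanges::IRanges(nm$start, nm$end))
    hitN <- GenomicRanges::countOverlaps(peak_gr, nm_gr, ignore.strand = TRUE) > 0
    keep <- keep & !hitN
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the fixed-width pan-cancer peak set
#'
#' Three-stage curation of per-sample fixed-width peaks into one
#' reproducible, pairwise non-overlapping pan-cancer set:
#'
#' 1. per sample: score normalization ([normalize_sample_scores()]) then
#'    [iterative_overlap_removal()];
#' 2. per cancer type: pool the sample sets, renormalize so scores sum to
#'    10^6 within the cancer type, then iterative overlap removal;
#' 3. pan-cancer: pool the per-cancer sets, drop peaks supported by fewer
#'    than two samples / on chrY / overlapping N-masked regions
#'    ([filter_peaks()]), then a final iterative overlap removal.
#'
#' @param per_sample_peaks nested list: `cancer type -> sample -> peak
#'   data.frame` (fixed-width peaks, e.g. from [extend_summits()]).
#' @param genome a [genome_model()].
#' @return data.frame of pan-cancer peaks with `peak_id` assigned in
#'   positional order; attribute `provenance` set to `"pan_cancer"`.
#' @export
build_pan_cancer_set <- function(per_sample_peaks, genome) {
  if (length(per_sample_peaks) == 0 ||
      sum(lengths(per_sample_peaks)) < 2)
    stop("need at least one cancer type and two samples overall")

  sample_sets <- list()
  per_cancer <- list()
  for (ct in names(per_sample_peaks)) {
    cleaned <- lapply(per_sample_peaks[[ct]], function(ps) {
      iterative_overlap_removal(normalize_sample_scores(ps))
    })
    sample_sets <- c(sample_sets, cleaned)
    pooled <- do.call(rbind, cleaned)
    pooled$score <- pooled$score / (sum(pooled$score) / 1e6)
    per_cancer[[ct]] <- iterative_overlap_removal(pooled)
  }

  candidates <- do.call(rbind, per_cancer)
  support <- peak_sample_support(candidates, sample_sets)
  filtered <- filter_peaks(candidates, support, genome)
  pan <- iterative_overlap_removal(filtered)
  pan <- pan[order(pan$chrom, pan$start), , drop = FALSE]
  pan$peak_id <- sprintf("peak_%05d", seq_len(nrow(pan)))
  rownames(pan) <- NULL
  attr(pan, "provenance") <- "pan_cancer"
  pan
}

#' Write a peak set as BED6+
#'
#' Coordinates are converted to the BED 0-based half-open convention;
#' extra columns (summit, score, category, nearest gene, distance to TSS)
#' follow the six standard fields.
#'
#' @param peaks peak data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_bed <- function(peaks, path) {
  bed <- data.frame(chrom = peaks$chrom,
                    start = peaks$start - 1,  # to 0-based half-open
                    end = peaks$end,
                    name = peaks$peak_id %||% sprintf("peak_%05d", seq_len(nrow(peaks))),
                    score = peaks$score,
                    strand = ".",
                    summit = peaks$summit,
                    category = peaks$category %||% NA,
                    nearest_gene = peaks$nearest_gene %||% NA,
                    dist_to_tss = peaks$dist_to_tss %||% NA)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a peak set written by [write_peak_bed()]
#' @param path BED6+ path.
#' @return peak data.frame in 1-based inclusive coordinates.
#' @export
read_peak_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           na.strings = "NA", stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start", "end", "peak_id", "score", "strand",
                  "summit", "category", "nearest_gene", "dist_to_tss")[seq_len(ncol(bed))]
  bed$start <- bed$start + 1  # back to 1-based inclusive
  bed$strand <- NULL
  bed
}
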