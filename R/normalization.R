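#' Prior-count CPM transform
#'
#' Adds a prior count to every cell (damping the variance contribution of
#' low-count peaks) and scales each column to counts per million of its
#' prior-added total, so every column sums to 10^6.
#'
#' @param raw numeric matrix of raw counts (peaks x replicates),
#'   nonnegative, with row and column names.
#' @param prior prior count added to every cell (default 5).
#' @return CPM matrix with `stage` attribute `"cpm"`.
#' @export
prior_cpm <- function(raw, prior = 5) {
  if (length(raw) == 0) stop("empty count matrix")
  if (any(raw < 0)) stop("raw counts must be nonnegative")
  if (prior < 0) stop("prior count must be nonnegative")
  v <- raw + prior
  cpm <- sweep(v, 2, colSums(v), "/") * 1e6
  structure(cpm, stage = "cpm")
}

#' Elementwise log2 transform
#'
#' @param m numeric matrix with strictly positive values (guaranteed after
#'   [prior_cpm()] with a positive prior).
#' @return log2 matrix with `stage` attribute `"log2"`.
#' @export
log2_transform <- function(m) {
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("nonpositive value at row %s, column %s",
                 rownames(m)[bad[1, 1]] %||% bad[1, 1],
                 colnames(m)[bad[1, 2]] %||% bad[1, 2]))
  structure(log2(m), stage = "log2", dimnames = dimnames(m))
}

#' Quantile normalization
#'
#' Classic quantile normalization: the k-th smallest value of each column is
#' replaced by the mean across columns of the k-th smallest values; ties
#' within a column receive the mean of the reference values at the ranks
#' they span. Afterwards all columns share one value distribution while
#' within-column ranks are preserved. Delegates to
#' [limma::normalizeQuantiles()] (with tie averaging), the standard
#' implementation of exactly this procedure.
#'
#' @param m numeric matrix with at least two columns; a single-column matrix
#'   is returned unchanged with a warning.
#' @return quantile-normalized matrix with `stage` attribute `"quantile"`.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2) {
    warning("quantile normalization needs >= 2 columns; returning input unchanged")
    return(structure(m, stage = "quantile"))
  }
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  structure(qn, stage = "quantile", dimnames = dimnames(m))
}

#' Average technical replicates into samples
#'
#' Collapses replicate columns to one column per sample by arithmetic mean
#' on the current (normalized) scale. Output columns are in sorted sample
#' order for determinism.
#'
#' @param m numeric matrix with replicate column names.
#' @param replicate_map data.frame with columns `column_id`, `sample_id`
#'   mapping every matrix column to its sample.
#' @return peaks x samples matrix with `stage` attribute `"sample_averaged"`.
#' @export
average_replicates <- function(m, replicate_map) {
  stopifnot(all(c("column_id", "sample_id") %in% names(replicate_map)))
  unmapped <- setdiff(colnames(m), replicate_map$column_id)
  if (length(unmapped))
    stop("unmapped column(s): ", paste(unmapped, collapse = ", "))
  samp <- replicate_map$sample_id[match(colnames(m), replicate_map$column_id)]
  samples <- sort(unique(samp))
  out <- vapply(samples, function(s) {
    rowMeans(m[, samp == s, drop = FALSE])
  }, numeric(nrow(m)))
  dimnames(out) <- list(rownames(m), samples)
  structure(out, stage = "sample_averaged")
}

#' Full normalization chain
#'
#' Raw counts -> prior-count CPM -> log2 -> quantile normalization ->
#' replicate averaging. This is the transform that turns the raw
#' peak-by-replicate count matrix into the analysis-ready peak-by-sample
#' log2 intensity matrix ("peak intensity") used by every downstream stage.
#'
#' @param raw numeric raw count matrix (peaks x replicates).
#' @param replicate_map optional `column_id`/`sample_id` map; when NULL each
#'   column is treated as its own sample.
#' @param prior prior count (default 5).
#' @return normalized peaks x samples matrix, stage `"sample_averaged"`.
#' @export
normalize_counts <- function(raw, replicate_map = NULL, prior = 5) {
  if (is.null(replicate_map))
    replicate_map <- data.frame(column_id = colnames(raw),
                                sample_id = colnames(raw),
                                stringsAsFactors = FALSE)
  m <- quantile_normalize(log2_transform(prior_cpm(raw, prior)))
  average_replicates(m, replicate_map)
}

#' Read a raw count matrix with peak annotation columns
#'
#' TSV layout mirroring pan-cancer ATAC count matrices: per-row peak
#' annotation (`peak_id`, `chrom`, `start`, `end`, `summit`, `annotation`)
#' followed by one column per replicate/sample.
#'
#' @param path file path.
#' @return list with `peaks` (annotation data.frame) and `counts`
#'   (numeric matrix, rownames = peak_id).
#' @export
read_count_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ann_cols <- c("peak_id", "chrom", "start", "end", "summit", "annotation")
  missing_cols <- setdiff(ann_cols, names(tab))
  if (length(missing_cols))
    stop("count matrix missing annotation column(s): ",
         paste(missing_cols, collapse = ", "))
  counts <- as.matrix(tab[, setdiff(names(tab), ann_cols), drop = FALSE])
  rownames(counts) <- tab$peak_id
  list(peaks = tab[, ann_cols], counts = counts)
}

#' Write a raw count matrix with annotation columns
#' @param peaks annotation data.frame (`peak_id`, `chrom`, `start`, `end`,
#'   `summit`, `annotation`).
#' @param counts numeric matrix, rows aligned with `peaks`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(peaks, counts, path) {
  stopifnot(nrow(peaks) == nrow(counts))
  tab <- cbind(peaks[, c("peak_id", "chrom", "start", "end", "summit",
                         "annotation")],
               as.data.frame(counts, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
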