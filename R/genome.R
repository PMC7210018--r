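#' Construct a genome model
#'
#' The coordinate frame shared by every stage: ordered chromosome lengths
#' plus the N-masked (assembly-gap) intervals that peaks must not span.
#' All coordinates held in memory are 1-based inclusive; conversion to the
#' BED 0-based half-open convention happens only in the readers/writers.
#'
#' @param chromosomes data.frame with columns `chrom` (unique names) and
#'   `length` (bp, positive).
#' @param n_masked optional data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive) of intervals containing N bases.
#' @return an object of class `genome_model` (a list with elements
#'   `chromosomes` and `n_masked`).
#' @export
genome_model <- function(chromosomes, n_masked = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length") %in% names(chromosomes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicated chromosome names in genome model")
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be strictly positive")
  if (is.null(n_masked)) {
    n_masked <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(n_masked)))
    n_masked$chrom <- as.character(n_masked$chrom)
    len <- chromosomes$length[match(n_masked$chrom, chromosomes$chrom)]
    if (anyNA(len))
      stop("N-mask interval on chromosome absent from genome model")
    if (any(n_masked$start < 1 | n_masked$end > len | n_masked$end < n_masked$start))
      stop("N-mask interval outside chromosome bounds")
  }
  structure(list(chromosomes = chromosomes, n_masked = n_masked),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %.1f Mb total, %d N-masked intervals\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              nrow(x$n_masked)))
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  len <- genome$chromosomes$length[match(chrom, genome$chromosomes$chrom)]
  if (anyNA(len)) stop("unknown chromosome: ",
                       paste(unique(chrom[is.na(len)]), collapse = ", "))
  len
}

#' Read a chrom.sizes file
#'
#' Two-column TSV (chromosome name, length in bp), the UCSC `chrom.sizes`
#' convention.
#'
#' @param path file path.
#' @param n_mask_bed optional path to a BED file (0-based half-open) of
#'   N-masked intervals.
#' @return a [genome_model()].
#' @export
read_chrom_sizes <- function(path, n_mask_bed = NULL) {
  sz <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  nm <- if (!is.null(n_mask_bed)) read_nmask_bed(n_mask_bed) else NULL
  genome_model(sz, nm)
}

#' Read an N-mask BED file
#'
#' BED intervals are 0-based half-open on disk; they are converted to the
#' package's 1-based inclusive convention on read.
#'
#' @param path BED3 file path.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_nmask_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  bed$start <- bed$start + 1  # 0-based half-open -> 1-based inclusive
  bed
}

#' Construct a gene (TSS) annotation table
#'
#' @param genes data.frame with columns `gene_id`, `symbol`, `chrom`, `tss`
#'   (1-based), `strand` (`+`/`-`).
#' @param genome optional [genome_model()] used to bound-check TSS positions.
#' @return the validated data.frame with class `gene_annotation`.
#' @export
gene_annotation <- function(genes, genome = NULL) {
  stopifnot(all(c("gene_id", "symbol", "chrom", "tss", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in annotation")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (!is.null(genome)) {
    len <- chrom_length(genome, genes$chrom)
    if (any(genes$tss < 1 | genes$tss > len))
      stop("TSS outside chromosome bounds")
  }
  class(genes) <- c("gene_annotation", "data.frame")
  genes
}

#' Read a TSS annotation table
#'
#' BED6-like TSV: chrom, tss-1, tss, gene_id, symbol, strand. The interval
#' is the 1 bp TSS in BED convention, so the 1-based TSS is the third column.
#'
#' @param path file path.
#' @param genome optional [genome_model()] for bound checks.
#' @return a [gene_annotation()] data.frame.
#' @export
read_tss_table <- function(path, genome = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "tss0", "tss", "gene_id",
                                         "symbol", "strand"))
  gene_annotation(tab[, c("gene_id", "symbol", "chrom", "tss", "strand")],
                  genome)
}

#' Read a clinical table
#'
#' TSV with header columns `sample_id`, `cancer_type`, `sex`, `age`,
#' `stage`, `histology`, `pam50`, `os_time`, `os_event`; missing values are
#' encoded as `NA`. Overall-survival times of zero are rejected (they are
#' filtered before any survival analysis).
#'
#' @param path file path.
#' @return data.frame of per-sample clinical annotations.
#' @export
read_clinical_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           na.strings = "NA", stringsAsFactors = FALSE)
  required <- c("sample_id", "cancer_type", "sex", "age", "stage",
                "histology", "pam50", "os_time", "os_event")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("clinical table missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(!is.na(tab$os_time) & tab$os_time <= 0))
    stop("os_time must be strictly positive where present")
  tab
}
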