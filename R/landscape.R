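#' Equal-width segment grid over a genome
#'
#' Divides every chromosome into `n_segments` evenly spaced segments
#' (92 by default) that jointly cover it with no gaps or overlaps. Segment
#' length varies across chromosomes with chromosome length. Segments are
#' half-open: a position exactly on an internal boundary belongs to the
#' right-hand (following) segment.
#'
#' @param genome a [genome_model()].
#' @param n_segments segments per chromosome (default 92).
#' @return data.frame with `chrom`, `segment` (1..n), `seg_start`, `seg_end`
#'   (1-based inclusive integer display coordinates) and `seg_length`
#'   (exact bp length `chrom_length / n_segments`).
#' @export
segment_grid <- function(genome, n_segments = 92) {
  stopifnot(n_segments >= 1)
  chroms <- genome$chromosomes
  grids <- lapply(seq_len(nrow(chroms)), function(i) {
    L <- chroms$length[i]
    b <- L * (0:n_segments) / n_segments  # real-valued half-open boundaries
    data.frame(chrom = chroms$chrom[i],
               segment = seq_len(n_segments),
               seg_start = floor(b[-(n_segments + 1)]) + 1,
               seg_end = floor(b[-1]),
               seg_length = L / n_segments,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, grids)
  attr(out, "n_segments") <- n_segments
  out
}

# segment index of a 1-based position on a chromosome of length L;
# boundary positions fall in the right-hand segment
segment_index <- function(pos, L, n_segments) {
  pmin(n_segments, floor((pos - 1) * n_segments / L) + 1L)
}

#' Peaks per megabase by chromosome
#'
#' Chromosome-level peak density: the number of (optionally
#' category-filtered) peaks on each chromosome divided by its length in Mb.
#'
#' @param peaks peak data.frame with `chrom` (and `category` if filtering).
#' @param genome a [genome_model()].
#' @param category optional single category from `promoter`, `enhancer`,
#'   `intron`, `other`.
#' @return data.frame with `chrom`, `n_peaks`, `ppmb`.
#' @export
ppmb <- function(peaks, genome, category = NULL) {
  if (!is.null(category)) {
    if (!category %in% c("promoter", "enhancer", "intron", "other"))
      stop("unknown category: ", category)
    peaks <- peaks[!is.na(peaks$category) & peaks$category == category, ,
                   drop = FALSE]
  }
  chroms <- genome$chromosomes
  n <- vapply(chroms$chrom, function(ch) sum(peaks$chrom == ch), integer(1))
  data.frame(chrom = chroms$chrom, n_peaks = n,
             ppmb = n / (chroms$length / 1e6), row.names = NULL)
}

#' Per-segment peak densities
#'
#' Counts peaks per grid segment (a peak belongs to the segment containing
#' its summit, preventing double counting across boundaries) and divides by
#' segment length.
#'
#' @param peaks peak data.frame with `chrom` and `summit`.
#' @param grid a [segment_grid()].
#' @param genome the [genome_model()] the grid was built from.
#' @return `grid` with `n_peaks`, `density` (peaks/bp) and `density_per_mb`
#'   columns added.
#' @export
segment_densities <- function(peaks, grid, genome) {
  n_segments <- attr(grid, "n_segments")
  counts <- segment_counts(peaks, genome, n_segments)
  key <- paste(grid$chrom, grid$segment)
  grid$n_peaks <- counts[match(key, names(counts))]
  grid$n_peaks[is.na(grid$n_peaks)] <- 0L
  grid$density <- grid$n_peaks / grid$seg_length
  grid$density_per_mb <- grid$density * 1e6
  grid
}

# named per-(chrom, segment) peak counts; errors on off-grid peaks
segment_counts <- function(peaks, genome, n_segments) {
  L <- chrom_length(genome, peaks$chrom)  # errors on unknown chromosome
  if (any(peaks$summit < 1 | peaks$summit > L))
    stop("peak summit outside chromosome bounds (off-grid)")
  idx <- segment_index(peaks$summit, L, n_segments)
  tab <- table(paste(peaks$chrom, idx))
  stats::setNames(as.integer(tab), names(tab))
}

#' Permutation-based chromosomal accessibility landscape
#'
#' Scores each grid segment by how unusually peak-dense it is under a
#' positional null. For each of `n_perm` replicates every peak is relocated
#' uniformly at random (by default over the whole genome: chromosome drawn
#' proportional to length, position uniform; optionally within its own
#' chromosome, preserving per-chromosome counts) and per-segment null
#' densities are collected. The empirical p-value uses the add-one
#' correction `p = (1 + #\{null >= observed\}) / (1 + n_perm)` so p is never
#' zero, and the accessibility score is `-log10(p)` (bounded above by
#' `log10(1 + n_perm)`).
#'
#' The landscape depends on peak positions only, never on peak scores.
#'
#' @param peaks peak data.frame with `chrom` and `summit`.
#' @param genome a [genome_model()].
#' @param n_perm number of permutation replicates (default 10^6; tests and
#'   desk-scale runs use 10^3).
#' @param seed optional RNG seed for reproducibility.
#' @param n_segments segments per chromosome (default 92).
#' @param scheme `"genome"` (default) or `"within_chromosome"` relocation.
#' @return a [segment_grid()] with `n_peaks`, `density_per_mb`, `p` and
#'   `score` columns; attributes `n_perm`, `seed`, `scheme`.
#' @export
permutation_landscape <- function(peaks, genome, n_perm = 1e6, seed = NULL,
                                  n_segments = 92,
                                  scheme = c("genome", "within_chromosome")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  grid <- segment_grid(genome, n_segments)
  grid <- segment_densities(peaks, grid, genome)

  chroms <- genome$chromosomes
  n_chrom <- nrow(chroms)
  n_peaks <- nrow(peaks)
  n_seg_total <- n_chrom * n_segments
  # global segment index aligned with grid row order
  grid_key <- (match(grid$chrom, chroms$chrom) - 1L) * n_segments + grid$segment
  observed <- integer(n_seg_total)
  observed[grid_key] <- grid$n_peaks

  cum <- cumsum(c(0, chroms$length))
  total_len <- cum[n_chrom + 1]
  peak_chrom_idx <- match(peaks$chrom, chroms$chrom)

  exceed <- integer(n_seg_total)
  # chunk replicates to bound both the position vector and the count matrix
  chunk <- max(1L, min(as.integer(n_perm),
                       as.integer(2e6 / max(1, n_peaks)),
                       as.integer(5e6 / n_seg_total)))
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    if (scheme == "genome") {
      gpos <- stats::runif(b * n_peaks, 0, total_len)
      ci <- findInterval(gpos, cum, rightmost.closed = TRUE)
      ci[ci > n_chrom] <- n_chrom
      pos <- gpos - cum[ci]        # 0-based offset within chromosome
      idx <- pmin(n_segments, floor(pos * n_segments / chroms$length[ci]) + 1L)
    } else {
      ci <- rep(peak_chrom_idx, times = b)
      pos <- stats::runif(b * n_peaks, 0, chroms$length[ci])
      idx <- pmin(n_segments, floor(pos * n_segments / chroms$length[ci]) + 1L)
    }
    gidx <- (ci - 1L) * n_segments + idx
    rep_id <- rep(seq_len(b), each = n_peaks)
    counts <- matrix(tabulate(gidx + (rep_id - 1L) * n_seg_total,
                              nbins = b * n_seg_total),
                     nrow = n_seg_total)
    exceed <- exceed + rowSums(counts >= observed)
    done <- done + b
  }

  p <- (1 + exceed[grid_key]) / (1 + n_perm)
  grid$p <- p
  grid$score <- -log10(p)
  attr(grid, "n_perm") <- n_perm
  attr(grid, "seed") <- seed
  attr(grid, "scheme") <- scheme
  grid
}
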