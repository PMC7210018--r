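#' Length of a 1-based inclusive interval
#'
#' Browser-style coordinates count both endpoints, so a single-base interval
#' has length 1.
#'
#' @param start,end 1-based inclusive coordinates (vectorized).
#' @return integer length(s) `end - start + 1`.
#' @export
#' @examples
#' interval_length(151689921, 151690150)  # 230
interval_length <- function(start, end) {
  if (any(end < start)) stop("invalid interval: end < start")
  end - start + 1
}

#' Promoter window around a TSS
#'
#' The promoter is the window from `upstream` bp upstream to `downstream`
#' bp downstream of the TSS (defaults -1000/+100), oriented by transcription:
#' on the minus strand the window is mirrored in genomic coordinates.
#' Windows are clipped to chromosome bounds when a length is supplied.
#'
#' @param tss 1-based TSS coordinate (vectorized).
#' @param strand `"+"` or `"-"` (recycled).
#' @param chromosome_length optional chromosome length for clipping.
#' @param upstream,downstream window extent in bp.
#' @return data.frame with columns `start`, `end` (1-based inclusive).
#' @export
#' @examples
#' promoter_window(151690496, "+")  # chr6:151689496-151690596
promoter_window <- function(tss, strand, chromosome_length = NULL,
                            upstream = 1000, downstream = 100) {
  if (!all(strand %in% c("+", "-")))
    stop("unknown strand: must be '+' or '-'")
  plus <- strand == "+"
  start <- ifelse(plus, tss - upstream, tss - downstream)
  end <- ifelse(plus, tss + downstream, tss + upstream)
  start <- pmax(start, 1)
  if (!is.null(chromosome_length)) end <- pmin(end, chromosome_length)
  data.frame(start = start, end = end)
}

#' Map peaks to promoters by summit position
#'
#' A peak is a promoter peak of a gene when its summit falls inside that
#' gene's promoter window. The signed distance to the TSS is
#' transcription-oriented (`summit - tss` on `+`, `tss - summit` on `-`;
#' negative means upstream of the TSS). When a summit lies in two genes'
#' windows, the gene with the smallest `|dist_to_tss|` wins, further ties
#' broken by lexicographic `gene_id`.
#'
#' @param peaks data.frame with at least `chrom` and `summit` columns.
#' @param genes a [gene_annotation()] data.frame.
#' @param upstream,downstream promoter extent passed to [promoter_window()].
#' @return `peaks` with `nearest_gene`, `gene_symbol` and `dist_to_tss`
#'   columns added (`NA` where no promoter window contains the summit).
#' @export
assign_promoter_peaks <- function(peaks, genes, upstream = 1000,
                                  downstream = 100) {
  win <- promoter_window(genes$tss, genes$strand,
                         upstream = upstream, downstream = downstream)
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(win$start, win$end))
  summit_gr <- GenomicRanges::GRanges(peaks$chrom,
                                      IRanges::IRanges(peaks$summit, peaks$summit))
  hits <- GenomicRanges::findOverlaps(summit_gr, gene_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  dist <- ifelse(genes$strand[sh] == "+",
                 peaks$summit[qh] - genes$tss[sh],
                 genes$tss[sh] - peaks$summit[qh])
  # per peak: smallest |dist|, then lexicographic gene_id
  ord <- order(qh, abs(dist), genes$gene_id[sh])
  first <- !duplicated(qh[ord])
  pick_peak <- qh[ord][first]
  pick_gene <- sh[ord][first]
  pick_dist <- dist[ord][first]
  peaks$nearest_gene <- NA_character_
  peaks$gene_symbol <- NA_character_
  peaks$dist_to_tss <- NA_real_
  peaks$nearest_gene[pick_peak] <- genes$gene_id[pick_gene]
  peaks$gene_symbol[pick_peak] <- genes$symbol[pick_gene]
  peaks$dist_to_tss[pick_peak] <- pick_dist
  peaks
}

#' Collapse annotation labels to the four peak categories
#'
#' Source matrices annotate each peak with a genomic-context label; the
#' landscape and association stages work with four categories: promoter,
#' enhancer (distal), intron, and other (exonic/UTR).
#'
#' @param label character vector of annotation labels; accepted values are
#'   `promoter`, `distal`, `enhancer`, `intron`, `exon`, `3'UTR`, `5'UTR`.
#' @param distal_as_enhancer treat `distal` as `enhancer` (default TRUE).
#' @return character vector over `promoter`, `enhancer`, `intron`, `other`.
#' @export
assign_category <- function(label, distal_as_enhancer = TRUE) {
  accepted <- c("promoter", "distal", "enhancer", "intron", "exon",
                "3'UTR", "5'UTR")
  bad <- setdiff(unique(label), accepted)
  if (length(bad))
    stop("unknown annotation label(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(accepted, collapse = ", "))
  out <- rep("other", length(label))
  out[label == "promoter"] <- "promoter"
  out[label == "enhancer"] <- "enhancer"
  out[label == "distal"] <- if (distal_as_enhancer) "enhancer" else "other"
  out[label == "intron"] <- "intron"
  out
}
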