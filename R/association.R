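#' Define a two-group contrast
#'
#' A named pair of disjoint sample sets plus the significance thresholds
#' used to call differential peaks. Fold changes are always oriented
#' group A over group B.
#'
#' @param name contrast name (e.g. `"sex"`, `"histology_lung"`).
#' @param group_a,group_b character vectors of sample IDs (disjoint,
#'   nonempty).
#' @param fdr_threshold BH q-value cutoff (default 0.01).
#' @param lfc_threshold |log2 fold change| cutoff: 0.3 for demographic
#'   contrasts, 1 (fold change 2) for histology/subtype contrasts.
#' @return a `group_contrast` list.
#' @export
group_contrast <- function(name, group_a, group_b, fdr_threshold = 0.01,
                           lfc_threshold = 0.3) {
  group_a <- unique(as.character(group_a))
  group_b <- unique(as.character(group_b))
  if (length(group_a) == 0 || length(group_b) == 0)
    stop(sprintf("contrast '%s': both groups must be nonempty", name))
  if (length(intersect(group_a, group_b)))
    stop(sprintf("contrast '%s': groups overlap", name))
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 fdr_threshold = fdr_threshold,
                 lfc_threshold = lfc_threshold),
            class = "group_contrast")
}

#' Standard clinical contrasts
#'
#' Builds the canonical two-group contrasts from a clinical table:
#' \describe{
#'   \item{sex}{male over female, |log2FC| threshold 0.3.}
#'   \item{age}{median split of age; age-high over age-low, threshold 0.3.
#'     Values equal to the median go to the low group.}
#'   \item{stage}{advanced (III/IV) over early (I/II), threshold 0.3;
#'     samples with missing stage are dropped.}
#'   \item{histology_lung}{LUAD over LUSC, fold-change-2 threshold
#'     (|log2FC| 1).}
#'   \item{brca_basal}{PAM50 basal over non-basal (LumA/LumB/Her2/Normal)
#'     within breast cancer, |log2FC| threshold 1.}
#' }
#'
#' @param clinical clinical data.frame (see [read_clinical_table()]).
#' @param which one of the contrast names above.
#' @param fdr_threshold BH cutoff (default 0.01).
#' @return a [group_contrast()].
#' @export
clinical_contrast <- function(clinical,
                              which = c("sex", "age", "stage",
                                        "histology_lung", "brca_basal"),
                              fdr_threshold = 0.01) {
  which <- match.arg(which)
  id <- clinical$sample_id
  switch(which,
    sex = group_contrast("sex",
      id[!is.na(clinical$sex) & clinical$sex == "male"],
      id[!is.na(clinical$sex) & clinical$sex == "female"],
      fdr_threshold, 0.3),
    age = {
      grp <- median_dichotomize(clinical$age, "age_low", "age_high")
      group_contrast("age", id[!is.na(grp) & grp == "age_high"],
                     id[!is.na(grp) & grp == "age_low"], fdr_threshold, 0.3)
    },
    stage = group_contrast("stage",
      id[!is.na(clinical$stage) & clinical$stage %in% c("III", "IV")],
      id[!is.na(clinical$stage) & clinical$stage %in% c("I", "II")],
      fdr_threshold, 0.3),
    histology_lung = group_contrast("histology_lung",
      id[clinical$cancer_type == "LUAD"],
      id[clinical$cancer_type == "LUSC"],
      fdr_threshold, 1),
    brca_basal = {
      brca <- clinical$cancer_type == "BRCA" & !is.na(clinical$pam50)
      group_contrast("brca_basal",
        id[brca & clinical$pam50 == "Basal"],
        id[brca & clinical$pam50 %in% c("LumA", "LumB", "Her2", "Normal")],
        fdr_threshold, 1)
    })
}

#' Per-peak Mann-Whitney test with BH correction
#'
#' For every matrix row (peak), a two-sided Mann-Whitney U test between the
#' contrast's two sample groups, Benjamini-Hochberg correction across all
#' tested peaks, and the log2 fold change as the difference of group means
#' on the log2 intensity scale (equivalently the log2 ratio of geometric
#' mean intensities), oriented A over B. The exact null distribution is
#' used when the smaller group has at most 8 samples and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param m normalized log2 intensity matrix (peaks x samples), typically
#'   restricted to promoter peaks.
#' @param contrast a [group_contrast()].
#' @return data.frame with one row per peak: `peak_id`, `n_a`, `n_b`,
#'   `u_statistic`, `p`, `q`, `log2fc`, `direction` (`up_in_a` / `up_in_b` /
#'   `ns` at the contrast's thresholds).
#' @export
mann_whitney_bh <- function(m, contrast) {
  a_cols <- intersect(contrast$group_a, colnames(m))
  b_cols <- intersect(contrast$group_b, colnames(m))
  if (length(a_cols) < 2 || length(b_cols) < 2)
    stop(sprintf("contrast '%s': need >= 2 samples with data per group",
                 contrast$name))
  A <- m[, a_cols, drop = FALSE]
  B <- m[, b_cols, drop = FALSE]
  res <- t(vapply(seq_len(nrow(m)), function(i) {
    x <- A[i, ][!is.na(A[i, ])]
    y <- B[i, ][!is.na(B[i, ])]
    if (length(x) == 0 || length(y) == 0)
      stop(sprintf("contrast '%s': a group is empty after missing-data removal",
                   contrast$name))
    exact <- min(length(x), length(y)) <= 8 && !anyDuplicated(c(x, y))
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                             correct = TRUE))
    c(n_a = length(x), n_b = length(y), u = unname(w$statistic),
      p = w$p.value, lfc = mean(x) - mean(y))
  }, numeric(5)))
  out <- data.frame(peak_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                    n_a = res[, "n_a"], n_b = res[, "n_b"],
                    u_statistic = res[, "u"], p = res[, "p"],
                    q = stats::p.adjust(res[, "p"], method = "BH"),
                    log2fc = res[, "lfc"], stringsAsFactors = FALSE)
  sig <- out$q < contrast$fdr_threshold &
    abs(out$log2fc) >= contrast$lfc_threshold
  out$direction <- ifelse(!sig, "ns",
                          ifelse(out$log2fc > 0, "up_in_a", "up_in_b"))
  attr(out, "contrast") <- contrast$name
  out
}

#' Partition significant peaks by direction
#'
#' @param records output of [mann_whitney_bh()].
#' @param contrast the [group_contrast()] the records were computed under
#'   (kept for the report; thresholds are already baked into `direction`).
#' @return list with `up_in_a` and `up_in_b` peak-id vectors and `n_up_in_a`,
#'   `n_up_in_b` counts.
#' @export
select_differential <- function(records, contrast = NULL) {
  up_a <- records$peak_id[records$direction == "up_in_a"]
  up_b <- records$peak_id[records$direction == "up_in_b"]
  list(up_in_a = up_a, up_in_b = up_b,
       n_up_in_a = length(up_a), n_up_in_b = length(up_b))
}
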