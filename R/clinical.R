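#' Cohort composition table
#'
#' Per-cancer-type sample counts and percentages of the cohort, sorted in
#' descending order of percentage. Percentages use half-up rounding to one
#' decimal, the convention of printed cohort tables.
#'
#' @param clinical clinical data.frame with a `cancer_type` column.
#' @return data.frame with `cancer_type`, `n`, `percent`.
#' @export
cohort_composition <- function(clinical) {
  if (nrow(clinical) == 0) stop("empty clinical table")
  if (any(is.na(clinical$cancer_type)))
    stop("every sample must have a cancer_type")
  n <- table(clinical$cancer_type)
  out <- data.frame(cancer_type = names(n), n = as.integer(n),
                    stringsAsFactors = FALSE)
  out$percent <- round_half_up(100 * out$n / sum(out$n), 1)
  out <- out[order(-out$percent, -out$n, out$cancer_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median dichotomization
#'
#' Splits samples at the median of the non-missing values: values less than
#' or equal to the median go to the low group, values above it to the high
#' group. Missing values stay `NA` (excluded from downstream contrasts).
#'
#' @param values numeric vector (e.g. ages or peak intensities).
#' @param label_low,label_high group labels.
#' @return character vector of group labels (NA for missing input).
#' @export
median_dichotomize <- function(values, label_low = "low", label_high = "high") {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least two non-missing values to dichotomize")
  med <- stats::median(values[ok])
  out <- rep(NA_character_, length(values))
  out[ok] <- ifelse(values[ok] <= med, label_low, label_high)
  out
}
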