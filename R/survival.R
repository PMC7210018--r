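#' Per-peak Cox proportional-hazards survival association
#'
#' Fits a single-covariate Cox model per peak with the (continuous) peak
#' intensity as predictor and overall survival as outcome, using the
#' Breslow tie approximation by default. Samples with missing or zero
#' survival time, or missing event indicator, are dropped first. Wald
#' p-values are BH-corrected across all estimable peaks; peaks with a
#' constant covariate or a monotone partial likelihood (coefficient
#' diverging) are flagged non-estimable and excluded from the correction.
#'
#' @param m normalized intensity matrix (peaks x samples), typically the
#'   promoter rows.
#' @param clinical clinical data.frame with `sample_id`, `os_time`
#'   (days, > 0), `os_event` (0/1).
#' @param alpha BH q-value cutoff defining "prognostic" (default 0.05).
#' @param ties tie method passed to [survival::coxph()] (`"breslow"`
#'   default, `"efron"` available).
#' @return data.frame with one row per peak: `peak_id`, `n`, `beta`, `se`,
#'   `hr`, `ci_low`, `ci_high` (95% Wald CI on the hazard ratio), `p_wald`,
#'   `q`, `direction` (`positive` for HR > 1, `negative` for HR < 1),
#'   `estimable`, `prognostic`.
#' @export
cox_per_peak <- function(m, clinical, alpha = 0.05,
                         ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  keep <- !is.na(clinical$os_time) & clinical$os_time > 0 &
    !is.na(clinical$os_event)
  cl <- clinical[keep, , drop = FALSE]
  cols <- intersect(cl$sample_id, colnames(m))
  cl <- cl[match(cols, cl$sample_id), , drop = FALSE]
  if (sum(cl$os_event) < 2)
    stop("need at least two events for survival analysis")
  mm <- m[, cols, drop = FALSE]
  surv <- survival::Surv(cl$os_time, cl$os_event)

  fit_one <- function(x) {
    ok <- !is.na(x)
    if (stats::sd(x[ok]) == 0)
      return(c(n = sum(ok), beta = NA, se = NA, p = NA, est = 0))
    diverged <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(surv[ok] ~ x[ok], ties = ties),
      warning = function(w) {
        if (grepl("infinite|converge|beta may be", conditionMessage(w)))
          diverged <<- TRUE
        invokeRestart("muffleWarning")
      })
    beta <- unname(stats::coef(fit))
    se <- sqrt(unname(fit$var[1, 1]))
    if (diverged || !is.finite(beta) || abs(beta) > 15)
      return(c(n = sum(ok), beta = beta, se = se, p = NA, est = 0))
    c(n = sum(ok), beta = beta, se = se,
      p = 2 * stats::pnorm(-abs(beta / se)), est = 1)
  }
  res <- t(apply(mm, 1, fit_one))

  out <- data.frame(peak_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                    n = res[, "n"], beta = res[, "beta"], se = res[, "se"],
                    stringsAsFactors = FALSE)
  out$hr <- exp(out$beta)
  z <- stats::qnorm(0.975)
  out$ci_low <- exp(out$beta - z * out$se)
  out$ci_high <- exp(out$beta + z * out$se)
  out$p_wald <- res[, "p"]
  out$estimable <- res[, "est"] == 1
  out$q <- NA_real_
  out$q[out$estimable] <- stats::p.adjust(out$p_wald[out$estimable],
                                          method = "BH")
  out$direction <- ifelse(!out$estimable, NA_character_,
                          ifelse(out$hr > 1, "positive", "negative"))
  out$prognostic <- out$estimable & !is.na(out$q) & out$q < alpha
  attr(out, "alpha") <- alpha
  attr(out, "ties") <- ties
  out
}

#' Chromosome-wise summary of prognostic peaks
#'
#' Counts prognostic peaks (BH q below the threshold used in
#' [cox_per_peak()]) per chromosome and splits them by hazard-ratio
#' direction: positive (HR > 1, higher intensity associated with worse
#' survival) versus negative (HR < 1, better survival). Chromosomes with no
#' prognostic peaks report zero percentages.
#'
#' @param records output of [cox_per_peak()].
#' @param peaks peak data.frame with `peak_id` and `chrom` for the join.
#' @return data.frame with `chrom`, `n_prognostic`, `pct_positive`,
#'   `pct_negative`.
#' @export
prognostic_landscape <- function(records, peaks) {
  chrom <- peaks$chrom[match(records$peak_id, peaks$peak_id)]
  if (anyNA(chrom)) stop("survival records contain peaks absent from the peak set")
  prog <- records$prognostic
  chroms <- unique(peaks$chrom)
  out <- do.call(rbind, lapply(chroms, function(ch) {
    sel <- prog & chrom == ch
    n <- sum(sel)
    npos <- sum(sel & records$direction == "positive")
    data.frame(chrom = ch, n_prognostic = n,
               pct_positive = if (n > 0) round_half_up(100 * npos / n, 1) else 0,
               pct_negative = if (n > 0) round_half_up(100 * (n - npos) / n, 1) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Median-split Kaplan-Meier comparison for one peak
#'
#' Dichotomizes samples at the median intensity of the peak (values above
#' the median form the high-intensity group, values at or below it the low
#' group), estimates Kaplan-Meier curves per group, and compares them with
#' a two-sided log-rank test.
#'
#' @param values named per-sample intensity vector (names = sample IDs).
#' @param clinical clinical data.frame with `sample_id`, `os_time` (> 0),
#'   `os_event`.
#' @return list with `n_high`, `n_low`, `logrank_chi2`, `logrank_p`, and
#'   `curves` (data.frame of per-group Kaplan-Meier coordinates: `group`,
#'   `time`, `n_risk`, `n_event`, `surv`).
#' @export
km_median_split <- function(values, clinical) {
  keep <- !is.na(clinical$os_time) & clinical$os_time > 0 &
    !is.na(clinical$os_event)
  cl <- clinical[keep, , drop = FALSE]
  ids <- intersect(cl$sample_id, names(values))
  cl <- cl[match(ids, cl$sample_id), , drop = FALSE]
  v <- values[ids]
  ok <- !is.na(v)
  v <- v[ok]; cl <- cl[ok, , drop = FALSE]
  grp <- factor(ifelse(v > stats::median(v), "high", "low"),
                levels = c("low", "high"))
  if (any(table(grp) < 2) || nlevels(droplevels(grp)) < 2)
    stop("median split leaves a group with fewer than 2 samples")
  surv <- survival::Surv(cl$os_time, cl$os_event)
  sd <- survival::survdiff(surv ~ grp)
  chi2 <- sd$chisq
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(surv ~ grp)
  strata <- rep(sub("^grp=", "", names(fit$strata)), fit$strata)
  curves <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv,
                       stringsAsFactors = FALSE)
  list(n_high = sum(grp == "high"), n_low = sum(grp == "low"),
       logrank_chi2 = unname(chi2), logrank_p = unname(p), curves = curves)
}
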