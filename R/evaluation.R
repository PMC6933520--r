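#' Correlation between two volume series
#'
#' @param a,b Equal-length numeric vectors (e.g. manual and predicted
#'   volumes in mm^3), `n >= 3`.
#' @param method `"pearson"` or `"spearman"`.
#' @return List of class `correlation_result`: `method`, `r`, `p_value`,
#'   `n`, and `defined` (FALSE when either series has zero variance).
#' @export
correlate_volumes <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 3L) stop("need at least 3 pairs")
  if (sd(a) == 0 || sd(b) == 0)
    return(structure(list(method = method, r = NA_real_,
                          p_value = NA_real_, n = length(a),
                          defined = FALSE),
                     class = "correlation_result"))
  ct <- suppressWarnings(cor.test(a, b, method = method, exact = FALSE))
  structure(list(method = method, r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(a), defined = TRUE),
            class = "correlation_result")
}

#' Bland-Altman agreement between two measurements
#'
#' Bias is `mean(a - b)`; the limits of agreement are
#' `bias +/- 1.96 * sd(a - b)` with the sample (n-1) standard deviation.
#'
#' @param a,b Equal-length numeric vectors, `n >= 2`.
#' @return List of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `lower`, `upper`, and per-case `differences` and `means`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  s <- sd(d)
  bias <- mean(d)
  structure(list(bias = bias, sd_diff = s,
                 lower = bias - 1.96 * s, upper = bias + 1.96 * s,
                 differences = d, means = (a + b) / 2),
            class = "bland_altman_result")
}

#' WMH prevalence at fixed volume thresholds
#'
#' Counts cases whose volume is at least each threshold ("at least" is
#' inclusive), e.g. the 100 / 1000 / 5000 / 10000 mm^3 strata.
#'
#' @param volumes Non-negative volumes in mm^3, one per case.
#' @param thresholds Thresholds in mm^3.
#' @return Named integer vector of counts, non-increasing in threshold.
#' @export
wmh_prevalence <- function(volumes,
                           thresholds = c(100, 1000, 5000, 10000)) {
  stopifnot(all(volumes >= 0))
  setNames(vapply(thresholds, function(t) sum(volumes >= t), integer(1)),
           paste0(">=", thresholds))
}

#' Median Dice stratified by true lesion volume
#'
#' For each threshold, the median Dice over cases whose truth volume for
#' the region is at least that threshold; cases with undefined (NA) Dice
#' are excluded and counted.
#'
#' @param reports [evaluate_case()]-style data frame.
#' @param region Region name to stratify.
#' @param thresholds Volume thresholds in mm^3.
#' @return Data frame with `threshold_mm3`, `n`, `n_undefined`,
#'   `median_dice` (NA for an empty stratum).
#' @export
stratified_median_dice <- function(reports, region = "WMH",
                                   thresholds = c(100, 1000, 5000, 10000)) {
  r <- reports[reports$region == region, ]
  out <- lapply(thresholds, function(t) {
    s <- r[r$truth_vol_mm3 >= t, ]
    ok <- !is.na(s$dice)
    data.frame(threshold_mm3 = t, n = sum(ok), n_undefined = sum(!ok),
               median_dice = if (any(ok)) median(s$dice[ok]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Correlation between lesion volume and Dice
#'
#' Correlates per-case truth volume (optionally log10-transformed, with
#' zero-volume cases excluded) against Dice for a region, or across
#' several regions pooled.
#'
#' @param reports [evaluate_case()]-style data frame.
#' @param region Region name, or a vector of regions to pool.
#' @param log10_volume Correlate on a log10 volume scale.
#' @param method Correlation method.
#' @return A `correlation_result` with an extra `n_excluded` field
#'   (zero-volume or NA-Dice cases dropped).
#' @export
volume_dice_correlation <- function(reports, region = "WT",
                                    log10_volume = FALSE,
                                    method = "pearson") {
  r <- reports[reports$region %in% region, ]
  keep <- !is.na(r$dice)
  if (log10_volume) keep <- keep & r$truth_vol_mm3 > 0
  excl <- sum(!keep)
  r <- r[keep, ]
  if (nrow(r) < 3L) stop("fewer than 3 usable cases")
  v <- if (log10_volume) log10(r$truth_vol_mm3) else r$truth_vol_mm3
  res <- correlate_volumes(v, r$dice, method)
  res$n_excluded <- excl
  res
}

#' Paired two-tailed t-test between per-case metrics of two models
#'
#' One-sample t-test of the paired differences against zero.  Identical
#' pairs (all differences zero) return statistic 0 and p = 1; a constant
#' nonzero difference has zero variance and is flagged undefined.
#'
#' @param a,b Equal-length numeric vectors aligned by case.
#' @return List of class `paired_test_result`: `statistic`, `p_value`,
#'   `n`, `mean_difference`, `defined`.
#' @export
paired_two_tailed_t <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  n <- length(d)
  tol <- 1e-10 * max(1, abs(mean(d)))
  if (sd(d) <= tol) {
    if (abs(mean(d)) <= tol)
      return(structure(list(statistic = 0, p_value = 1, n = n,
                            mean_difference = 0, defined = TRUE),
                       class = "paired_test_result"))
    return(structure(list(statistic = NA_real_, p_value = NA_real_, n = n,
                          mean_difference = mean(d), defined = FALSE),
                     class = "paired_test_result"))
  }
  tt <- t.test(a, b, paired = TRUE)
  structure(list(statistic = unname(tt$statistic),
                 p_value = tt$p.value, n = n,
                 mean_difference = mean(d), defined = TRUE),
            class = "paired_test_result")
}

#' Cohort-level summary report
#'
#' Aggregates a metric table into the standard cohort analyses: volume
#' correlation and Bland-Altman agreement per region, WMH prevalence
#' counts, and volume-stratified median WMH Dice.
#'
#' @param reports [evaluate_case()]-style data frame.
#' @param wmh_min_volume_mm3 Minimum truth WMH volume for inclusion in the
#'   WMH volume correlation (default 100).
#' @return Named list of summaries.
#' @export
cohort_report <- function(reports, wmh_min_volume_mm3 = 100) {
  out <- list()
  for (reg in unique(reports$region)) {
    r <- reports[reports$region == reg, ]
    if (reg == "WMH") r <- r[r$truth_vol_mm3 >= wmh_min_volume_mm3, ]
    if (nrow(r) >= 3 && sd(r$truth_vol_mm3) > 0 && sd(r$pred_vol_mm3) > 0) {
      out[[paste0(reg, "_volume_correlation")]] <-
        correlate_volumes(r$truth_vol_mm3, r$pred_vol_mm3, "pearson")
      out[[paste0(reg, "_bland_altman")]] <-
        bland_altman(r$truth_vol_mm3, r$pred_vol_mm3)
    }
  }
  wmh <- reports[reports$region == "WMH", ]
  if (nrow(wmh)) {
    out$wmh_prevalence <- wmh_prevalence(wmh$truth_vol_mm3)
    out$wmh_stratified_dice <- stratified_median_dice(reports, "WMH")
  }
  out
}
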