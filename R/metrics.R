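#' Binary mask of a composite region
#'
#' @param labels Integer array of on-disk label codes.
#' @param region A [region_spec()] or region name.
#' @return Logical array: TRUE where the voxel code belongs to the region.
#' @export
region_mask <- function(labels, region) {
  if (is.character(region)) region <- region_spec(region)
  m <- array(labels %in% region$label_codes, dim = dim(labels))
  m
}

#' Voxelwise confusion counts between two binary masks
#'
#' @param pred,truth Logical (or 0/1) arrays of identical shape.
#' @return List of class `confusion_counts`: `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("shape mismatch between pred and truth")
  p <- as.logical(pred); t <- as.logical(truth)
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  structure(list(TP = tp, FP = fp, FN = fn,
                 TN = length(p) - tp - fp - fn),
            class = "confusion_counts")
}

#' Dice overlap coefficient
#'
#' `2 TP / (2 TP + FP + FN)`.  When both masks are empty (TP = FP =
#' FN = 0) the score is undefined and returned as `NA` by default;
#' `empty_value = 1` gives the portal-style convention.  Empty prediction
#' against nonempty truth (or vice versa) scores 0.
#'
#' @param c A `confusion_counts` from [confusion()].
#' @param empty_value Value for the both-empty case (default `NA`).
#' @return Numeric in `[0, 1]`, or `empty_value`.
#' @export
dice <- function(c, empty_value = NA_real_) {
  denom <- 2 * c$TP + c$FP + c$FN
  if (denom == 0) return(empty_value)
  2 * c$TP / denom
}

surface_points <- function(mask) {
  d <- dim(mask)
  surface_voxels_cpp(as.integer(mask), d[1], d[2], d[3])
}

#' 95th-percentile symmetric Hausdorff distance (mm)
#'
#' Surfaces are the mask voxels with at least one face-adjacent (6-
#' connected) background neighbour, grid borders counting as background.
#' Directed distances are Euclidean nearest-neighbour distances between
#' the two surface point sets in mm; each direction is summarized by its
#' 95th percentile (linear interpolation between order statistics) and
#' the result is the maximum of the two directed percentiles
#' (`method = "max"`), or the percentile of the pooled directed distances
#' (`method = "pooled"`).
#'
#' @param pred,truth Logical arrays of identical shape, both nonempty.
#' @param spacing Voxel spacing in mm per axis.
#' @param percentile Percentile of the distance distribution (default 95).
#' @param method `"max"` (default) or `"pooled"`.
#' @return Distance in mm, or `NA` if either mask is empty.
#' @export
hausdorff95 <- function(pred, truth, spacing = c(1, 1, 1),
                        percentile = 95, method = c("max", "pooled")) {
  method <- match.arg(method)
  if (!identical(dim(pred), dim(truth)))
    stop("shape mismatch between pred and truth")
  if (!any(pred) || !any(truth)) return(NA_real_)
  sp <- surface_points(pred)
  st <- surface_points(truth)
  d_ps <- nn_dist_cpp(sp, st, as.numeric(spacing))
  d_sp <- nn_dist_cpp(st, sp, as.numeric(spacing))
  q <- percentile / 100
  if (method == "max")
    max(quantile(d_ps, q, names = FALSE), quantile(d_sp, q, names = FALSE))
  else
    quantile(c(d_ps, d_sp), q, names = FALSE)
}

#' Per-region metric report for one case
#'
#' For each region: Dice, HD95, and predicted/true volumes in mm^3
#' (voxel count times voxel volume).  Metrics that are undefined for a
#' region (both masks empty) are reported as `NA`.
#'
#' @param pred_labels,truth_labels Integer arrays of on-disk codes, same
#'   geometry.
#' @param regions Character vector of region names or list of
#'   [region_spec()].
#' @param spacing Voxel spacing in mm.
#' @param case_id Optional identifier copied into the report.
#' @param dice_empty_value Passed to [dice()].
#' @return Data frame with columns `case_id`, `region`, `dice`, `hd95`,
#'   `pred_vol_mm3`, `truth_vol_mm3`.
#' @export
evaluate_case <- function(pred_labels, truth_labels,
                          regions = c("WT", "TC", "ET", "WMH"),
                          spacing = c(1, 1, 1), case_id = NA_character_,
                          dice_empty_value = NA_real_) {
  if (!identical(dim(pred_labels), dim(truth_labels)))
    stop("geometry mismatch between prediction and truth")
  voxvol <- prod(spacing)
  rows <- lapply(regions, function(r) {
    rs <- if (is.character(r)) region_spec(r) else r
    pm <- region_mask(pred_labels, rs)
    tm <- region_mask(truth_labels, rs)
    cc <- confusion(pm, tm)
    data.frame(case_id = case_id, region = rs$name,
               dice = dice(cc, dice_empty_value),
               hd95 = hausdorff95(pm, tm, spacing),
               pred_vol_mm3 = sum(pm) * voxvol,
               truth_vol_mm3 = sum(tm) * voxvol)
  })
  do.call(rbind, rows)
}

#' Evaluate a cohort of predicted/true label volumes
#'
#' @param preds,truths Lists of label arrays (on-disk codes), aligned.
#' @param case_ids Identifiers (defaults to list indices).
#' @inheritParams evaluate_case
#' @return Row-bound [evaluate_case()] data frame.
#' @export
evaluate_cohort <- function(preds, truths, case_ids = NULL,
                            regions = c("WT", "TC", "ET", "WMH"),
                            spacing = c(1, 1, 1)) {
  stopifnot(length(preds) == length(truths))
  if (is.null(case_ids)) case_ids <- as.character(seq_along(preds))
  do.call(rbind, lapply(seq_along(preds), function(i)
    evaluate_case(preds[[i]], truths[[i]], regions, spacing,
                  case_id = case_ids[i])))
}
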