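#' Label codec between contiguous class indices and BraTS on-disk codes
#'
#' BraTS label volumes use the on-disk integer codes background = 0,
#' necrotic core (NCR) = 1, peritumoral edema (ED) = 2, enhancing/active
#' tumor (AT) = 4, and (in the 5-class extension) white matter
#' hyperintensities (WMH) = 3.  Network outputs use contiguous class
#' indices `0..n_classes-1`; a codec is the bijection between the two.
#'
#' @param n_classes 4 (background, NCR, ED, AT) or 5 (adding WMH).
#' @return An object of class `label_codec` with elements `n_classes` and
#'   `codes` (on-disk code for each contiguous index, starting at index 0).
#' @examples
#' codec <- label_codec(4)
#' codec$codes       # 0 1 2 4
#' @export
label_codec <- function(n_classes = 5L) {
  n_classes <- as.integer(n_classes)
  if (!n_classes %in% c(4L, 5L))
    stop("n_classes must be 4 or 5")
  codes <- if (n_classes == 4L) c(0L, 1L, 2L, 4L) else c(0L, 1L, 2L, 3L, 4L)
  structure(list(n_classes = n_classes, codes = codes),
            class = "label_codec")
}

#' Convert on-disk label codes to contiguous class indices
#'
#' @param raw Integer array (or vector) of on-disk codes.
#' @param codec A [label_codec()].
#' @return Integer array of the same shape holding indices
#'   `0..n_classes-1`.
#' @export
encode_labels <- function(raw, codec) {
  stopifnot(inherits(codec, "label_codec"))
  lut <- rep(NA_integer_, 6L)               # codes 0..5 -> index+1
  lut[codec$codes + 1L] <- seq_along(codec$codes) - 1L
  v <- as.integer(raw)
  if (any(v < 0L | v > 5L, na.rm = TRUE))
    stop("label code outside 0..5")
  out <- lut[v + 1L]
  if (anyNA(out))
    stop("label code not in codec code set {",
         paste(codec$codes, collapse = ","), "}")
  if (!is.null(dim(raw))) dim(out) <- dim(raw)
  out
}

#' Convert contiguous class indices back to on-disk label codes
#'
#' Inverse of [encode_labels()].
#'
#' @param idx Integer array of class indices.
#' @inheritParams encode_labels
#' @return Integer array of on-disk codes, same shape as `idx`.
#' @export
decode_labels <- function(idx, codec) {
  stopifnot(inherits(codec, "label_codec"))
  v <- as.integer(idx)
  if (any(v < 0L | v >= codec$n_classes, na.rm = TRUE))
    stop("class index out of range for this codec")
  out <- codec$codes[v + 1L]
  if (!is.null(dim(idx))) dim(out) <- dim(idx)
  out
}

#' Remap WMH labels to background
#'
#' Drops the WMH class (on-disk code 3) from a label volume, as needed to
#' train or score the 4-class model on cases annotated with WMH.
#'
#' @param labels Integer array of on-disk codes.
#' @return Same array with every code-3 voxel set to 0.
#' @export
remap_wmh_to_background <- function(labels) {
  labels[labels == 3L] <- 0L
  labels
}

#' Composite evaluation regions over on-disk label codes
#'
#' `WT` (whole tumor) is the union of NCR, ED and AT; `TC` (tumor core)
#' the union of NCR and AT; `ET` the enhancing tumor alone.  WMH is never
#' part of a tumor region.
#'
#' @param name One of `"WT"`, `"TC"`, `"ET"`, `"NCR"`, `"ED"`, `"WMH"`.
#' @return An object of class `region_spec` with elements `name` and
#'   `label_codes`.
#' @examples
#' region_spec("WT")$label_codes   # 1 2 4
#' @export
region_spec <- function(name) {
  codes <- switch(name,
    WT  = c(1L, 2L, 4L),
    TC  = c(1L, 4L),
    ET  = 4L,
    NCR = 1L,
    ED  = 2L,
    WMH = 3L,
    stop("unknown region: ", name))
  structure(list(name = name, label_codes = codes), class = "region_spec")
}
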