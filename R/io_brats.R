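CHANNEL_NAMES <- c("t1", "t1ce", "t2", "flair")

#' Construct a multi-parametric MRI case
#'
#' Bundles the four co-registered, skull-stripped channels (T1,
#' post-contrast T1, T2, T2-FLAIR), an optional label volume of on-disk
#' codes, and the voxel geometry.  The brain mask is derived as the union
#' of nonzero voxels across the four channels (skull-stripped inputs have
#' exactly-zero background).
#'
#' @param case_id Character identifier.
#' @param channels 4-D numeric array `c(nx, ny, nz, 4)`, channel order
#'   T1, T1PC, T2, FLAIR.
#' @param labels Optional integer array `c(nx, ny, nz)` of on-disk codes
#'   in `{0,1,2,3,4}`.
#' @param spacing Voxel spacing in mm per axis (default 1 mm isotropic).
#' @return An object of class `mpmri_case` with fields `case_id`,
#'   `channels`, `labels`, `brain_mask` (logical array) and `spacing`.
#' @export
mpmri_case <- function(case_id, channels, labels = NULL,
                       spacing = c(1, 1, 1)) {
  channels <- as.array(channels)
  if (length(dim(channels)) != 4L || dim(channels)[4] != 4L)
    stop("channels must be a 4-D array with 4 channels")
  shp <- dim(channels)[1:3]
  if (!is.null(labels)) {
    labels <- array(as.integer(labels), dim = dim(labels))
    if (!identical(dim(labels), shp))
      stop("labels shape ", paste(dim(labels), collapse = "x"),
           " does not match channel shape ", paste(shp, collapse = "x"))
    if (any(!labels %in% 0:4))
      stop("labels contain codes outside {0,1,2,3,4}")
  }
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  mask <- (channels[, , , 1] != 0) | (channels[, , , 2] != 0) |
          (channels[, , , 3] != 0) | (channels[, , , 4] != 0)
  structure(list(case_id = as.character(case_id), channels = channels,
                 labels = labels, brain_mask = mask, spacing = spacing),
            class = "mpmri_case")
}

#' @export
print.mpmri_case <- function(x, ...) {
  shp <- dim(x$channels)[1:3]
  cat("<mpmri_case> ", x$case_id, ": ",
      paste(shp, collapse = "x"), " voxels, ",
      paste(x$spacing, collapse = "x"), " mm, labels ",
      if (is.null(x$labels)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

nifti_path <- function(dir, suffix) {
  base <- file.path(dir, paste0(basename(dir), "_", suffix))
  for (ext in c(".nii.gz", ".nii")) {
    p <- paste0(base, ext)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Read a BraTS-layout case directory
#'
#' Expects one directory per case containing NIfTI files suffixed
#' `_t1`, `_t1ce`, `_t2`, `_flair` and optionally `_seg`
#' (`.nii` or `.nii.gz`), all on the same grid.
#'
#' @param directory_path Case directory; its basename is the case id.
#' @param codec [label_codec()] used to validate label codes.
#' @return An [mpmri_case()].
#' @export
read_case <- function(directory_path, codec = label_codec(5L)) {
  paths <- lapply(CHANNEL_NAMES, function(s) nifti_path(directory_path, s))
  missing <- CHANNEL_NAMES[vapply(paths, is.null, logical(1))]
  if (length(missing))
    stop("missing channel file(s): ", paste(missing, collapse = ", "),
         " in ", directory_path)
  vols <- lapply(paths, function(p) {
    v <- RNifti::readNifti(p)
    list(arr = as.array(v), pixdim = RNifti::pixdim(v))
  })
  shp <- dim(vols[[1]]$arr)
  sp <- vols[[1]]$pixdim
  for (i in seq_along(vols)) {
    if (!identical(dim(vols[[i]]$arr), shp))
      stop("channel shape mismatch in ", directory_path)
    if (max(abs(vols[[i]]$pixdim - sp)) > 1e-5)
      stop("channel spacing mismatch in ", directory_path)
  }
  channels <- array(0, dim = c(shp, 4L))
  for (i in 1:4) channels[, , , i] <- vols[[i]]$arr
  labels <- NULL
  seg_path <- nifti_path(directory_path, "seg")
  if (!is.null(seg_path)) {
    seg <- RNifti::readNifti(seg_path)
    labels <- array(as.integer(round(as.array(seg))), dim = dim(seg))
    if (!identical(dim(labels), shp))
      stop("label shape mismatch in ", directory_path)
    bad <- setdiff(unique(as.vector(labels)), codec$codes)
    if (length(bad))
      stop("unknown label code(s) ", paste(bad, collapse = ","),
           " for ", codec$n_classes, "-class codec")
  }
  mpmri_case(basename(directory_path), channels, labels, spacing = sp)
}

#' Write a case as a BraTS-layout directory
#'
#' @param case An [mpmri_case()].
#' @param out_dir Parent directory; a subdirectory named after the case id
#'   is created.
#' @param gzip Write `.nii.gz` (default) or plain `.nii`.
#' @return The case directory path, invisibly.
#' @export
write_case <- function(case, out_dir, gzip = TRUE) {
  stopifnot(inherits(case, "mpmri_case"))
  dir <- file.path(out_dir, case$case_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  for (i in 1:4) {
    img <- RNifti::asNifti(case$channels[, , , i],
                           pixdim = case$spacing)
    RNifti::writeNifti(img, file.path(dir, paste0(case$case_id, "_",
                                                  CHANNEL_NAMES[i], ext)))
  }
  if (!is.null(case$labels)) {
    img <- RNifti::asNifti(case$labels, pixdim = case$spacing)
    RNifti::writeNifti(img, file.path(dir, paste0(case$case_id, "_seg", ext)),
                       datatype = "uint8")
  }
  invisible(dir)
}

#' Write a label volume of class indices as an on-disk-coded NIfTI file
#'
#' @param labels Integer array of contiguous class indices.
#' @param codec [label_codec()] giving the index-to-code map.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm (geometry of the reference grid).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(labels, codec, path, spacing = c(1, 1, 1)) {
  codes <- decode_labels(labels, codec)
  img <- RNifti::asNifti(codes, pixdim = spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Zero-pad a case so each axis is divisible by a patch edge
#'
#' Padding is appended at the high-index end of each axis only, so original
#' voxel coordinates are preserved; added voxels are zero in all channels
#' and background in labels.  The canonical BraTS grid 240x240x155 with an
#' 80-voxel patch pads to 240x240x160.
#'
#' @param case An [mpmri_case()].
#' @param patch_edge Positive integer; every padded extent becomes the
#'   smallest multiple of `patch_edge` not below the original extent.
#' @return List with the padded `case` and a `record` (class
#'   `padding_record`: `original_shape`, `padded_shape`, `pad_before`,
#'   `pad_after`) for exact inversion by [crop_case()].
#' @export
pad_case <- function(case, patch_edge) {
  stopifnot(inherits(case, "mpmri_case"), patch_edge >= 1)
  shp <- dim(case$channels)[1:3]
  padded <- as.integer(ceiling(shp / patch_edge) * patch_edge)
  record <- structure(list(original_shape = as.integer(shp),
                           padded_shape = padded,
                           pad_before = c(0L, 0L, 0L),
                           pad_after = as.integer(padded - shp)),
                      class = "padding_record")
  if (all(padded == shp)) return(list(case = case, record = record))
  ch <- array(0, dim = c(padded, 4L))
  ch[seq_len(shp[1]), seq_len(shp[2]), seq_len(shp[3]), ] <- case$channels
  lab <- NULL
  if (!is.null(case$labels)) {
    lab <- array(0L, dim = padded)
    lab[seq_len(shp[1]), seq_len(shp[2]), seq_len(shp[3])] <- case$labels
  }
  list(case = mpmri_case(case$case_id, ch, lab, spacing = case$spacing),
       record = record)
}

#' Crop a padded case or array back to its original shape
#'
#' @param x A padded [mpmri_case()], or a 3-D/4-D array.
#' @param record The `padding_record` returned by [pad_case()].
#' @return Object of the same kind as `x`, restored to the original shape.
#' @export
crop_case <- function(x, record) {
  stopifnot(inherits(record, "padding_record"))
  shp <- record$original_shape
  ix <- seq_len(shp[1]); iy <- seq_len(shp[2]); iz <- seq_len(shp[3])
  if (inherits(x, "mpmri_case")) {
    ch <- x$channels[ix, iy, iz, , drop = FALSE]
    lab <- if (is.null(x$labels)) NULL else x$labels[ix, iy, iz, drop = FALSE]
    return(mpmri_case(x$case_id, ch, lab, spacing = x$spacing))
  }
  nd <- length(dim(x))
  if (nd == 3L) x[ix, iy, iz, drop = FALSE]
  else if (nd == 4L) x[ix, iy, iz, , drop = FALSE]
  else stop("cannot crop object of this shape")
}

#' Z-score channel intensities over the brain mask
#'
#' Each channel is standardized to zero mean and unit variance over
#' brain-mask voxels; background stays exactly zero.  Applied before
#' patch sampling at train time and before whole-volume inference.
#'
#' @param case An [mpmri_case()].
#' @return The case with normalized channels.
#' @export
normalize_case <- function(case) {
  stopifnot(inherits(case, "mpmri_case"))
  m <- case$brain_mask
  if (!any(m)) stop("empty brain mask")
  for (i in 1:4) {
    v <- case$channels[, , , i]
    mu <- mean(v[m]); s <- sd(v[m])
    if (s == 0) s <- 1
    v <- (v - mu) / s
    v[!m] <- 0
    case$channels[, , , i] <- v
  }
  case
}
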