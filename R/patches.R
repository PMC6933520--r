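#' Patch sampling specification
#'
#' @param edge Cubic patch edge in voxels (default 80); must be even and
#'   at least 8.
#' @param lesion_fraction Probability that a patch centerpoint is drawn
#'   uniformly from lesion voxels rather than from the whole brain mask
#'   (default 0.9).
#' @return Object of class `patch_spec`.
#' @export
patch_spec <- function(edge = 80L, lesion_fraction = 0.9) {
  edge <- as.integer(edge)
  stopifnot(edge >= 8L, edge %% 2L == 0L,
            lesion_fraction >= 0, lesion_fraction <= 1)
  structure(list(edge = edge, lesion_fraction = lesion_fraction),
            class = "patch_spec")
}

#' Augmentation specification
#'
#' Train-time augmentation: random left-right flips plus constrained
#' affine warps with rotation up to 45 degrees about each axis, per-axis
#' scaling within +/-25%, and shear factors within +/-0.1.
#'
#' @param flip_lr Enable left-right flipping (fair coin).
#' @param max_rotation_deg Maximum rotation magnitude per axis, degrees.
#' @param scale_low,scale_high Per-axis scale factor bounds.
#' @param max_shear Maximum shear factor magnitude.
#' @return Object of class `augment_spec`.
#' @export
augment_spec <- function(flip_lr = TRUE, max_rotation_deg = 45,
                         scale_low = 0.75, scale_high = 1.25,
                         max_shear = 0.1) {
  stopifnot(scale_low <= 1, scale_high >= 1, max_rotation_deg >= 0,
            max_shear >= 0)
  structure(list(flip_lr = flip_lr, max_rotation_deg = max_rotation_deg,
                 scale_low = scale_low, scale_high = scale_high,
                 max_shear = max_shear),
            class = "augment_spec")
}

#' Sample a training patch centerpoint
#'
#' With probability `lesion_fraction` the center is a uniformly drawn
#' nonzero-label voxel; otherwise a uniformly drawn brain-mask voxel.
#' Cases without any lesion voxel fall back to brain-uniform sampling.
#' Uses the R RNG, so sequences are reproducible under [set.seed()].
#'
#' @param case An [mpmri_case()] with labels.
#' @param spec A [patch_spec()].
#' @param lesion_idx,brain_idx Optional precomputed linear indices of
#'   lesion and brain voxels (computed from the case when missing).
#' @return List with `center` (1-based voxel coordinate, integer vector)
#'   and `provenance` (`"lesion"` or `"brain"`).
#' @export
sample_center <- function(case, spec = patch_spec(),
                          lesion_idx = NULL, brain_idx = NULL) {
  if (is.null(brain_idx)) brain_idx <- which(case$brain_mask)
  if (length(brain_idx) == 0L) stop("empty brain mask")
  if (is.null(lesion_idx))
    lesion_idx <- if (is.null(case$labels)) integer(0) else
      which(case$labels != 0L)
  use_lesion <- length(lesion_idx) > 0L && runif(1) < spec$lesion_fraction
  pool <- if (use_lesion) lesion_idx else brain_idx
  i <- pool[sample.int(length(pool), 1L)]
  shp <- dim(case$brain_mask)
  i0 <- i - 1L
  center <- c(i0 %% shp[1], (i0 %/% shp[1]) %% shp[2],
              i0 %/% (shp[1] * shp[2])) + 1L
  list(center = as.integer(center),
       provenance = if (use_lesion) "lesion" else "brain")
}

#' Extract a cubic patch around a centerpoint
#'
#' Regions falling outside the grid are zero-filled in the image and
#' background in the labels.
#'
#' @param case An [mpmri_case()].
#' @param center 1-based voxel coordinate (length 3).
#' @param spec A [patch_spec()].
#' @return List of class `patch` with `image` (`edge^3 x 4` array),
#'   `labels` (`edge^3` integer array of on-disk codes, or NULL),
#'   `center` and `provenance` (`NA` unless set by the caller).
#' @export
extract_patch <- function(case, center, spec = patch_spec()) {
  e <- spec$edge
  h <- e %/% 2L
  shp <- dim(case$brain_mask)
  lo <- as.integer(center) - h        # patch spans lo .. lo+e-1 (1-based)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s_lo <- max(1L, lo[a]); s_hi <- min(shp[a], lo[a] + e - 1L)
    if (s_lo > s_hi) stop("patch entirely outside the grid")
    src[[a]] <- s_lo:s_hi
    dst[[a]] <- (s_lo - lo[a] + 1L):(s_hi - lo[a] + 1L)
  }
  img <- array(0, dim = c(e, e, e, 4L))
  img[dst[[1]], dst[[2]], dst[[3]], ] <-
    case$channels[src[[1]], src[[2]], src[[3]], , drop = FALSE]
  lab <- NULL
  if (!is.null(case$labels)) {
    lab <- array(0L, dim = c(e, e, e))
    lab[dst[[1]], dst[[2]], dst[[3]]] <-
      case$labels[src[[1]], src[[2]], src[[3]], drop = FALSE]
  }
  structure(list(image = img, labels = lab, center = as.integer(center),
                 provenance = NA_character_), class = "patch")
}

#' Draw realized augmentation parameters
#'
#' @param spec An [augment_spec()].
#' @return List of class `augment_params`: `flip` (logical), `rotation_deg`
#'   (3 angles), `scale` (3 factors), `shear` (3 factors xy, xz, yz), and
#'   `identity` (TRUE when the transform is a no-op).
#' @export
draw_augment <- function(spec = augment_spec()) {
  flip <- spec$flip_lr && runif(1) < 0.5
  rot <- runif(3, -spec$max_rotation_deg, spec$max_rotation_deg)
  scl <- runif(3, spec$scale_low, spec$scale_high)
  shr <- runif(3, -spec$max_shear, spec$max_shear)
  if (spec$max_rotation_deg == 0) rot <- c(0, 0, 0)
  if (spec$max_shear == 0) shr <- c(0, 0, 0)
  ident <- !flip && all(rot == 0) && all(scl == 1) && all(shr == 0)
  structure(list(flip = flip, rotation_deg = rot, scale = scl, shear = shr,
                 identity = ident), class = "augment_params")
}

augment_matrix <- function(params) {
  d <- params$rotation_deg * pi / 180
  cx <- cos(d[1]); sx <- sin(d[1])
  cy <- cos(d[2]); sy <- sin(d[2])
  cz <- cos(d[3]); sz <- sin(d[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Sh <- diag(3)
  Sh[1, 2] <- params$shear[1]; Sh[1, 3] <- params$shear[2]
  Sh[2, 3] <- params$shear[3]
  Rz %*% Ry %*% Rx %*% Sh %*% diag(params$scale)
}

#' Apply flip/affine augmentation to a patch
#'
#' The left-right flip is applied first (exact index reversal along x),
#' then the affine warp about the patch center: images are resampled with
#' trilinear interpolation, labels with nearest-neighbour (no new label
#' values are created).  Identity parameters return the patch unchanged.
#'
#' @param patch A `patch` from [extract_patch()].
#' @param params An `augment_params` from [draw_augment()].
#' @return The augmented patch.
#' @export
apply_augment <- function(patch, params) {
  stopifnot(inherits(patch, "patch"), inherits(params, "augment_params"))
  e <- dim(patch$image)[1]
  if (params$flip) {
    patch$image <- patch$image[e:1, , , , drop = FALSE]
    if (!is.null(patch$labels))
      patch$labels <- patch$labels[e:1, , , drop = FALSE]
  }
  if (params$identity ||
      (all(params$rotation_deg == 0) && all(params$scale == 1) &&
       all(params$shear == 0)))
    return(patch)
  A <- augment_matrix(params)
  M <- solve(A)                      # output voxel p samples input at M p
  ctr <- rep((e - 1) / 2, 3)         # 0-based center
  img <- matrix(patch$image, nrow = e^3, ncol = 4L)
  img <- affine_warp_cpp(img, e, e, e, M, ctr, FALSE)
  patch$image <- array(img, dim = c(e, e, e, 4L))
  if (!is.null(patch$labels)) {
    lab <- matrix(as.numeric(patch$labels), nrow = e^3, ncol = 1L)
    lab <- affine_warp_cpp(lab, e, e, e, M, ctr, TRUE)
    patch$labels <- array(as.integer(lab), dim = c(e, e, e))
  }
  patch
}
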