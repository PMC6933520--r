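#' Default per-class intensity profile for the phantom generator
#'
#' Mean intensity (arbitrary units) of each tissue class on each channel.
#' The defaults encode the contrast relationships the segmentation task
#' relies on: active tumor (AT) is by far the brightest class on
#' post-contrast T1; edema (ED) and WMH are hyperintense to normal brain
#' on T2 and FLAIR and deliberately iso-intense to each other there, so
#' they can only be told apart through post-contrast T1 (ED sits below,
#' WMH at, the normal-brain level) and spatial context; necrotic core
#' (NCR) is dark on post-contrast T1; CSF is dark on FLAIR.
#'
#' @return 6 x 4 numeric matrix, rows `brain`, `csf`, `ncr`, `ed`, `at`,
#'   `wmh`; columns `t1`, `t1ce`, `t2`, `flair`.
#' @export
default_intensity_profile <- function() {
  m <- rbind(
    brain = c(100, 100,  80,  90),
    csf   = c( 40,  40, 160,  30),
    ncr   = c( 50,  40, 140, 100),
    ed    = c( 70,  80, 140, 160),
    at    = c( 90, 180, 110, 120),
    wmh   = c( 80, 100, 140, 160))
  colnames(m) <- CHANNEL_NAMES
  m
}

#' Specification of a synthetic multi-parametric MRI phantom case
#'
#' Describes one synthetic subject: an ellipsoidal brain with simple
#' ventricles, a contiguous tumor complex (necrotic core inside an
#' enhancing rim inside an edema envelope, built from concentric randomly
#' oriented ellipsoids), and zero or more small white matter
#' hyperintensity (WMH) blobs placed away from the tumor, preferentially
#' contralateral and periventricular.  Intensities follow a per-class
#' channel profile with additive Gaussian noise.
#'
#' @param grid_shape Grid extents in voxels (default `c(64, 64, 64)`).
#' @param spacing Voxel spacing in mm (default 1 mm isotropic).
#' @param brain_radius_fraction Brain semi-axis as a fraction of half the
#'   grid extent (default 0.88).
#' @param ncr_radius_mm Mean radius of the necrotic core (default 4).
#' @param at_rim_mm Thickness of the enhancing rim around the core
#'   (default 3).
#' @param ed_margin_mm Thickness of the edema envelope around the rim
#'   (default 5).
#' @param tumor_jitter Relative per-axis radius jitter of the tumor
#'   ellipsoids (default 0.2).
#' @param tumor_scale_range Range of a per-case global scale factor
#'   applied to all three tumor radii (default `c(1, 1)`, i.e. no
#'   inter-subject size variation); widen it (e.g. `c(0.7, 1.4)`) to
#'   emulate the large tumor-volume spread of clinical cohorts for
#'   volume-agreement analyses.
#' @param wmh_count_range Integer range `c(min, max)` of WMH blobs
#'   (default `c(0, 32)`); `c(0, 0)` disables WMH entirely.
#' @param wmh_radius_range_mm Per-blob mean radius range in mm
#'   (default `c(2, 9)`; draws lean toward the upper half while the
#'   realized total is far below the per-case volume target).
#' @param wmh_min_dist_mm Minimum distance between a WMH blob center and
#'   the edema surface (default 8).
#' @param wmh_target_volume_range_mm3 Range from which the per-case target
#'   total WMH volume is drawn (default `c(0, 12000)`); blobs are added
#'   until the realized volume reaches the target or the blob budget is
#'   exhausted.
#' @param intensity_profile Class-by-channel mean intensity matrix, see
#'   [default_intensity_profile()].
#' @param noise_sd Additive Gaussian noise standard deviation (default 5,
#'   well under half the smallest inter-class profile gap so classes stay
#'   separable).
#' @param seed Integer RNG seed; generation is fully deterministic given
#'   the spec.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing = c(1, 1, 1),
                         brain_radius_fraction = 0.88,
                         ncr_radius_mm = 4,
                         at_rim_mm = 3,
                         ed_margin_mm = 5,
                         tumor_jitter = 0.2,
                         tumor_scale_range = c(1, 1),
                         wmh_count_range = c(0L, 32L),
                         wmh_radius_range_mm = c(2, 9),
                         wmh_min_dist_mm = 8,
                         wmh_target_volume_range_mm3 = c(0, 12000),
                         intensity_profile = default_intensity_profile(),
                         noise_sd = 5,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               spacing = as.numeric(spacing),
               brain_radius_fraction = brain_radius_fraction,
               ncr_radius_mm = ncr_radius_mm,
               at_rim_mm = at_rim_mm,
               ed_margin_mm = ed_margin_mm,
               tumor_jitter = tumor_jitter,
               tumor_scale_range = as.numeric(tumor_scale_range),
               wmh_count_range = as.integer(wmh_count_range),
               wmh_radius_range_mm = as.numeric(wmh_radius_range_mm),
               wmh_min_dist_mm = wmh_min_dist_mm,
               wmh_target_volume_range_mm3 = as.numeric(wmh_target_volume_range_mm3),
               intensity_profile = intensity_profile,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  stopifnot(length(spec$grid_shape) == 3L, all(spec$grid_shape >= 16L),
            spec$brain_radius_fraction > 0, spec$brain_radius_fraction <= 1,
            spec$noise_sd >= 0,
            spec$wmh_count_range[1] <= spec$wmh_count_range[2],
            all(dim(spec$intensity_profile) == c(6L, 4L)))
  class(spec) <- "phantom_spec"
  spec
}

# Squared ellipsoid coordinate of every grid voxel: values <= 1 are inside.
# center in voxel coords (1-based), radii in voxels per axis, R a rotation.
ellipsoid_field <- function(shape, center, radii, R = diag(3)) {
  x <- seq_len(shape[1]) - center[1]
  y <- seq_len(shape[2]) - center[2]
  z <- seq_len(shape[3]) - center[3]
  # rotated coordinates u = R^T p, then sum((u/r)^2)
  f <- array(0, dim = shape)
  for (k in 1:3) {
    u <- outer(outer(x * R[1, k], y * R[2, k], `+`), z * R[3, k], `+`)
    f <- f + (u / radii[k])^2
  }
  f
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

#' Generate one synthetic phantom case
#'
#' Deterministic given `spec$seed`.  With `noise_sd = 0` every voxel of a
#' class takes exactly its profile intensity.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `phantom_case`: a list with the `case`
#'   (an [mpmri_case()] with labels in on-disk codes), the generating
#'   `spec`, `volumes` (named realized per-class volumes in mm^3 for
#'   NCR, ED, AT, WMH, WT), and `n_wmh_blobs` (number of blobs placed).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shp <- spec$grid_shape
  sp <- spec$spacing
  ctr <- (shp + 1) / 2
  brain_r <- spec$brain_radius_fraction * shp / 2 * c(1, 0.95, 0.88)
  brain <- ellipsoid_field(shp, ctr, brain_r) <= 1

  # ventricles: two small ellipsoids flanking the midline
  vent <- array(FALSE, dim = shp)
  for (s in c(-1, 1)) {
    vc <- ctr + c(s * 0.12 * shp[1], 0, 0.02 * shp[3])
    vr <- pmax(c(0.035, 0.16, 0.10) * shp, 1.2)
    vent <- vent | (ellipsoid_field(shp, vc, vr) <= 1)
  }
  vent <- vent & brain

  # tumor complex: concentric randomly oriented ellipsoids, one hemisphere
  tsr <- spec$tumor_scale_range
  tumor_scale <- if (tsr[1] == tsr[2]) tsr[1] else runif(1, tsr[1], tsr[2])
  ncr_r <- spec$ncr_radius_mm * tumor_scale
  at_rim <- spec$at_rim_mm * tumor_scale
  ed_margin <- spec$ed_margin_mm * tumor_scale
  ed_extent <- ncr_r + at_rim + ed_margin
  ed_extent_vox <- ed_extent / min(sp) * (1 + spec$tumor_jitter)
  max_off <- brain_r - ed_extent_vox - 1
  if (any(max_off <= 0))
    stop("infeasible phantom spec: tumor does not fit inside the brain")
  repeat {
    off <- c(runif(1, 0.35, 0.9) * max_off[1],        # lateralized: x > center
             runif(1, -0.5, 0.5) * max_off[2],
             runif(1, -0.5, 0.5) * max_off[3])
    tc <- ctr + off
    if (sum(((tc - ctr) / (brain_r - ed_extent_vox))^2) <= 1) break
  }
  jit <- 1 + runif(3, -spec$tumor_jitter, spec$tumor_jitter)
  R <- random_rotation()
  r_ncr <- ncr_r / sp * jit
  r_at <- r_ncr + at_rim / sp
  r_ed <- r_at + ed_margin / sp
  f_ncr <- ellipsoid_field(shp, tc, r_ncr, R)
  f_at <- ellipsoid_field(shp, tc, r_at, R)
  f_ed <- ellipsoid_field(shp, tc, r_ed, R)

  labels <- array(0L, dim = shp)
  labels[f_ed <= 1 & brain] <- 2L   # ED envelope
  labels[f_at <= 1 & brain] <- 4L   # enhancing rim
  labels[f_ncr <= 1 & brain] <- 1L  # necrotic core
  tumor <- labels != 0L

  # WMH blobs: centers drawn from the set of voxels that keep the whole
  # blob inside the brain and clear of the edema surface, with a
  # contralateral (periventricular-side) preference
  n_target <- spec$wmh_count_range[2]
  vol_target <- runif(1, spec$wmh_target_volume_range_mm3[1],
                      spec$wmh_target_volume_range_mm3[2])
  voxvol <- prod(sp)
  f_brain <- ellipsoid_field(shp, ctr, brain_r)
  dist_tc <- sqrt(ellipsoid_field(shp, tc, 1 / sp))   # mm from tumor center
  xgrid <- array(rep(seq_len(shp[1]), times = prod(shp[2:3])), dim = shp)
  wmh <- array(FALSE, dim = shp)
  n_placed <- 0L
  attempts <- 0L
  r_cap <- spec$wmh_radius_range_mm[2]      # shrinks when a radius proves
  while (attempts < 200L &&                 # unplaceable for this anatomy
         (n_placed < spec$wmh_count_range[1] ||
          (n_placed < n_target && sum(wmh) * voxvol < vol_target))) {
    attempts <- attempts + 1L
    r_lo <- spec$wmh_radius_range_mm[1]
    r_hi <- max(min(spec$wmh_radius_range_mm[2], r_cap), r_lo)
    deficit <- vol_target - sum(wmh) * voxvol
    # lean toward larger radii while far from the volume target
    if (r_hi > r_lo && deficit > 4 / 3 * pi * r_hi^3)
      r_lo <- (r_lo + r_hi) / 2
    r_mm <- runif(1, r_lo, r_hi)
    clearance <- ed_extent * (1 + spec$tumor_jitter) + r_mm +
      spec$wmh_min_dist_mm
    margin <- (r_mm + 1) / (min(brain_r) * min(sp))
    elig <- f_brain <= max(1 - margin, 0.05)^2 & dist_tc >= clearance & !wmh
    if (runif(1) < 0.8) {                   # contralateral preference
      contra <- elig & xgrid < ctr[1]
      if (any(contra)) elig <- contra
    }
    idx <- which(elig)
    if (length(idx) == 0L) {
      r_cap <- min(r_cap, r_mm * 0.95)
      next
    }
    i0 <- idx[sample.int(length(idx), 1L)] - 1L
    cc <- c(i0 %% shp[1], (i0 %/% shp[1]) %% shp[2],
            i0 %/% (shp[1] * shp[2])) + 1
    r_vox <- r_mm / sp * (1 + runif(3, -0.3, 0.3))
    blob <- ellipsoid_field(shp, cc, r_vox, random_rotation()) <= 1
    blob <- blob & brain & !tumor
    if (!any(blob)) next
    wmh <- wmh | blob
    n_placed <- n_placed + 1L
  }
  labels[wmh] <- 3L

  # intensities: profile means + noise inside the brain, hard zero outside
  prof <- spec$intensity_profile
  class_field <- array(0L, dim = shp)          # 0 outside, rows of prof inside
  class_field[brain] <- 1L
  class_field[vent] <- 2L
  class_field[labels == 1L] <- 3L
  class_field[labels == 2L] <- 4L
  class_field[labels == 4L] <- 5L
  class_field[labels == 3L] <- 6L
  channels <- array(0, dim = c(shp, 4L))
  nb <- sum(brain)
  for (i in 1:4) {
    v <- array(0, dim = shp)
    v[brain] <- prof[class_field[brain], i]
    if (spec$noise_sd > 0)
      v[brain] <- v[brain] + rnorm(nb, 0, spec$noise_sd)
    channels[, , , i] <- v
  }

  case <- mpmri_case(sprintf("phantom_%06d", spec$seed), channels, labels,
                     spacing = sp)
  counts <- tabulate(labels + 1L, nbins = 5L)   # codes 0..4
  volumes <- c(NCR = counts[2], ED = counts[3], WMH = counts[4],
               AT = counts[5],
               WT = counts[2] + counts[3] + counts[5]) * voxvol
  structure(list(case = case, spec = spec, volumes = volumes,
                 n_wmh_blobs = n_placed),
            class = "phantom_case")
}

#' Generate a seeded cohort of phantom cases
#'
#' Per-case seeds are derived deterministically from `master_seed`, and
#' per-case target WMH volumes are spread evenly across the spec's target
#' range so that volume-stratified analyses (e.g. the 100 / 1000 / 5000 /
#' 10000 mm^3 strata) are populated.
#'
#' @param n Number of cases.
#' @param spec_template A [phantom_spec()]; its seed and WMH volume target
#'   are overridden per case.
#' @param master_seed Integer seed for the cohort.
#' @return List of `phantom_case` objects.
#' @export
generate_cohort <- function(n, spec_template = phantom_spec(),
                            master_seed = 1L) {
  stopifnot(n >= 1)
  set.seed(master_seed)
  seeds <- sample.int(1000000000L, n)
  rng <- spec_template$wmh_target_volume_range_mm3
  targets <- if (n == 1) mean(rng) else seq(rng[1], rng[2], length.out = n)
  targets <- targets[sample.int(n)]          # decouple target from case order
  lapply(seq_len(n), function(i) {
    s <- spec_template
    s$seed <- seeds[i]
    s$wmh_target_volume_range_mm3 <- c(targets[i], targets[i])
    generate_phantom(s)
  })
}

#' Cohort manifest as a data frame
#'
#' @param cohort List of `phantom_case` objects from [generate_cohort()].
#' @return Data frame with case id, seed and realized per-class volumes.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(case_id = p$case$case_id, seed = p$spec$seed,
               ncr_mm3 = p$volumes[["NCR"]], ed_mm3 = p$volumes[["ED"]],
               at_mm3 = p$volumes[["AT"]], wmh_mm3 = p$volumes[["WMH"]],
               wt_mm3 = p$volumes[["WT"]])
  }))
}
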