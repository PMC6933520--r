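test_that("phantom generation is deterministic given the seed", {
  spec <- small_phantom_spec(seed = 21)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$case$channels, b$case$channels)
  expect_identical(a$case$labels, b$case$labels)
  expect_identical(a$volumes, b$volumes)
})

test_that("a zero WMH count range produces no code-3 voxels", {
  spec <- small_phantom_spec(seed = 22, wmh_count_range = c(0L, 0L))
  p <- generate_phantom(spec)
  expect_false(any(p$case$labels == 3L))
  expect_equal(p$volumes[["WMH"]], 0)
})

test_that("noiseless intensities equal the class profile exactly", {
  spec <- small_phantom_spec(seed = 23, noise_sd = 0)
  p <- generate_phantom(spec)
  prof <- spec$intensity_profile
  lab <- p$case$labels
  t1pc <- p$case$channels[, , , 2]
  expect_equal(unique(t1pc[lab == 4L]), prof["at", "t1ce"])
  expect_equal(unique(t1pc[lab == 3L]), prof["wmh", "t1ce"])
  # contrast relationships the classifier depends on
  expect_gt(mean(t1pc[lab == 4L]), max(mean(t1pc[lab == 1L]),
                                       mean(t1pc[lab == 2L]),
                                       mean(t1pc[lab == 3L])))
  expect_equal(prof["wmh", "t1ce"], prof["brain", "t1ce"])  # no enhancement
  expect_lt(prof["ncr", "t1ce"], prof["brain", "t1ce"])     # dark core
  for (chan in c("t2", "flair")) {
    expect_gt(prof["ed", chan], prof["brain", chan])
    expect_gt(prof["wmh", chan], prof["brain", chan])
  }
})

test_that("tumor sub-regions are concentric and WMH are distal", {
  p <- generate_phantom(small_phantom_spec(seed = 24))
  lab <- p$case$labels
  d <- dim(lab)
  shift <- function(a, o) {
    out <- array(0L, dim = d)
    sx <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    sy <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    sz <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    out[sx - o[1], sy - o[2], sz - o[3]] <- a[sx, sy, sz]
    out
  }
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (k in 1:6) {
    nb <- shift(lab, offs[k, ])
    # necrotic core only touches itself and the enhancing rim
    expect_true(all(nb[lab == 1L] %in% c(1L, 4L)))
    # the rim only touches core, rim, edema
    expect_true(all(nb[lab == 4L] %in% c(1L, 2L, 4L)))
    # WMH never touches tumor tissue
    expect_false(any(nb[lab == 3L] %in% c(1L, 2L, 4L)))
  }
  expect_true(all(p$case$brain_mask[lab != 0L]))
})

test_that("stored realized volumes match an independent recount", {
  p <- generate_phantom(small_phantom_spec(seed = 25))
  lab <- p$case$labels
  voxvol <- prod(p$case$spacing)
  expect_equal(p$volumes[["NCR"]], sum(lab == 1L) * voxvol)
  expect_equal(p$volumes[["ED"]], sum(lab == 2L) * voxvol)
  expect_equal(p$volumes[["AT"]], sum(lab == 4L) * voxvol)
  expect_equal(p$volumes[["WMH"]], sum(lab == 3L) * voxvol)
  expect_equal(p$volumes[["WT"]], sum(lab %in% c(1L, 2L, 4L)) * voxvol)
})

test_that("classes are separable by a nearest-profile voxel classifier", {
  spec <- small_phantom_spec(seed = 26)
  p <- generate_phantom(spec)
  lab <- p$case$labels
  prof <- spec$intensity_profile
  lesion <- which(lab != 0L)
  X <- sapply(1:4, function(i) p$case$channels[, , , i][lesion])
  d2 <- sapply(seq_len(nrow(prof)), function(r)
    rowSums(sweep(X, 2, prof[r, ], `-`)^2))
  pred_class <- rownames(prof)[max.col(-d2)]
  truth_class <- c("ncr", "ed", "wmh", "at")[match(lab[lesion], c(1, 2, 3, 4))]
  expect_gt(mean(pred_class == truth_class), 0.95)
})

test_that("the tumor scale factor grows every sub-region", {
  small <- generate_phantom(small_phantom_spec(seed = 28))
  big <- generate_phantom(small_phantom_spec(seed = 28,
                                             tumor_scale_range = c(1.4, 1.4)))
  for (reg in c("NCR", "AT", "ED", "WT"))
    expect_gt(big$volumes[[reg]], small$volumes[[reg]])
  # degenerate scale range consumes no randomness
  neutral <- generate_phantom(small_phantom_spec(seed = 28,
                                                 tumor_scale_range = c(1, 1)))
  expect_identical(neutral$case$channels, small$case$channels)
})

test_that("an infeasible tumor raises an error", {
  expect_error(generate_phantom(phantom_spec(grid_shape = c(32L, 32L, 32L),
                                             ncr_radius_mm = 20, seed = 27)),
               "infeasible")
})

test_that("cohorts are reproducible and spread WMH volume across strata", {
  a <- generate_cohort(2, small_phantom_spec(), master_seed = 7)
  b <- generate_cohort(2, small_phantom_spec(), master_seed = 7)
  expect_identical(lapply(a, function(p) p$case$labels),
                   lapply(b, function(p) p$case$labels))
  expect_identical(cohort_manifest(a), cohort_manifest(b))

  cohort <- generate_cohort(20, phantom_spec(), master_seed = 7)
  wmh <- vapply(cohort, function(p) p$volumes[["WMH"]], numeric(1))
  counts <- wmh_prevalence(wmh, c(100, 1000, 5000, 10000))
  expect_true(all(counts >= 1L))
  one <- generate_cohort(1, small_phantom_spec(), master_seed = 9)
  expect_length(one, 1)
  expect_s3_class(one[[1]]$case, "mpmri_case")
})
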