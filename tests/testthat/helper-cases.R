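# Fixture builders: everything is generated in code at test time.

# quick-to-generate phantom at reduced grid size for unit tests
small_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(grid_shape = c(32L, 32L, 32L),
               ncr_radius_mm = 2, at_rim_mm = 1.5, ed_margin_mm = 2,
               wmh_radius_range_mm = c(1.5, 3.5), wmh_min_dist_mm = 3,
               wmh_target_volume_range_mm3 = c(200, 1500),
               seed = seed, ...)
}

# hand-built tiny case: spherical brain, one labeled block per code
make_tiny_case <- function(shape = c(16L, 16L, 16L), seed = 1L,
                           with_labels = TRUE, codes = c(1L, 2L, 4L)) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  ctr <- (shape + 1) / 2
  brain <- array(sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 +
                      (g$z - ctr[3])^2) < min(shape) * 0.45, dim = shape)
  channels <- array(0, dim = c(shape, 4L))
  for (i in 1:4) {
    v <- array(0, dim = shape)
    v[brain] <- 50 + 10 * i + rnorm(sum(brain))
    channels[, , , i] <- v
  }
  labels <- NULL
  if (with_labels) {
    labels <- array(0L, dim = shape)
    at <- floor(ctr)
    for (k in seq_along(codes)) {
      o <- at + c(k - 2L, 0L, 0L) * 3L
      labels[o[1] + 0:1, o[2] + 0:1, o[3] + 0:1] <- codes[k]
    }
    labels[!brain] <- 0L
  }
  mpmri_case(sprintf("tiny_%d", seed), channels, labels)
}
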