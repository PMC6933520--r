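test_that("the channel plan doubles from the base width", {
  expect_equal(channel_plan(unet_config(levels = 4, base_filters = 32)),
               c(32L, 64L, 128L, 256L))
  expect_equal(channel_plan(unet_config(levels = 1, base_filters = 32)), 32L)
  expect_equal(channel_plan(unet_config(levels = 3, base_filters = 8)),
               c(8L, 16L, 32L))
})

test_that("the polynomial schedule decays from 1e-4 to zero", {
  tcfg <- train_config()
  expect_equal(lr_at_epoch(0, tcfg), 1e-4)
  expect_equal(lr_at_epoch(600, tcfg), 0)
  expect_equal(lr_at_epoch(300, tcfg), 2.5e-5)
  lrs <- lr_at_epoch(0:600, tcfg)
  expect_true(all(diff(lrs) <= 0))
  expect_error(lr_at_epoch(601, tcfg), "out of range")
  expect_error(lr_at_epoch(-1, tcfg), "out of range")
})

test_that("folds partition the cases with near-equal sizes", {
  ids <- sprintf("case%03d", 1:285)
  f <- make_folds(ids, 10, seed = 3)
  expect_setequal(names(f), ids)
  sizes <- as.vector(table(f))
  expect_setequal(sizes, c(28L, 29L))
  expect_equal(sum(sizes == 29L), 5L)
  f2 <- make_folds(sprintf("c%d", 1:20), 10, seed = 1)
  expect_true(all(table(f2) == 2L))
  expect_identical(make_folds(ids, 10, seed = 3), f)
  expect_error(make_folds(ids[1:5], 10), "more folds than cases")
})

test_that("model output preserves spatial shape and rejects bad edges", {
  set.seed(51)
  cfg <- unet_config(n_classes = 4, levels = 2, base_filters = 4)
  m <- build_model(cfg)
  X <- matrix(rnorm(16^3 * 4), ncol = 4)
  fw <- model_forward(m, X, rep(16L, 3L), 1L)
  expect_equal(dim(fw$scores), c(16L^3, 4L))
  expect_error(model_forward(m, matrix(rnorm(15^3 * 4), ncol = 4),
                             rep(15L, 3L), 1L), "not divisible")
})

test_that("4- and 5-class variants differ only by the classification head", {
  set.seed(52)
  cfg4 <- unet_config(n_classes = 4, levels = 3, base_filters = 8)
  cfg5 <- unet_config(n_classes = 5, levels = 3, base_filters = 8)
  n4 <- n_parameters(build_model(cfg4))
  n5 <- n_parameters(build_model(cfg5))
  expect_equal(n5 - n4, 8L + 1L)   # one more 1x1x1 filter plus its bias
})

test_that("training is seeded end-to-end and reduces the loss", {
  cohort <- lapply(c(61, 62), function(s)
    generate_phantom(small_phantom_spec(seed = s))$case)
  ucfg <- unet_config(n_classes = 5, levels = 2, base_filters = 8)
  pspec <- patch_spec(edge = 16, lesion_fraction = 0.9)
  tcfg <- train_config(initial_lr = 3e-3, epochs = 30, batch_size = 2,
                       patches_per_epoch = 4, ensemble_size = 1,
                       folds = 2, seed = 11)
  tm <- train_model(cohort, ucfg, tcfg, pspec, aspec = NULL)
  expect_lt(tail(tm$history$loss, 1), tm$history$loss[1])
  tcfg2 <- tcfg; tcfg2$epochs <- 3L
  a <- train_model(cohort, ucfg, tcfg2, pspec, aspec = augment_spec())
  b <- train_model(cohort, ucfg, tcfg2, pspec, aspec = augment_spec())
  expect_identical(a$history, b$history)
  expect_identical(a$model$params, b$model$params)
})

test_that("WMH-labeled cases are rejected by the 4-class configuration", {
  p <- generate_phantom(small_phantom_spec(seed = 63,
                                           wmh_count_range = c(2L, 6L)))
  expect_true(any(p$case$labels == 3L))
  ucfg4 <- unet_config(n_classes = 4, levels = 2, base_filters = 4)
  tcfg <- train_config(epochs = 1, patches_per_epoch = 1, folds = 2,
                       ensemble_size = 1)
  expect_error(train_model(list(p$case), ucfg4, tcfg, patch_spec(edge = 16)),
               "outside the 4-class codec")
  stripped <- p$case
  stripped$labels <- remap_wmh_to_background(stripped$labels)
  expect_silent(invisible(
    train_model(list(stripped), ucfg4, tcfg, patch_spec(edge = 16),
                aspec = NULL)))
})

test_that("ensembles train distinct members with recorded histories", {
  cs <- generate_phantom(small_phantom_spec(seed = 64))$case
  ucfg <- unet_config(n_classes = 5, levels = 2, base_filters = 4)
  tcfg <- train_config(initial_lr = 1e-3, epochs = 2, batch_size = 1,
                       patches_per_epoch = 2, ensemble_size = 2,
                       folds = 2, seed = 5)
  ens <- train_ensemble(list(cs), ucfg, tcfg, patch_spec(edge = 16),
                        aspec = NULL)
  expect_length(ens$members, 2)
  expect_length(ens$history, 2)
  expect_false(identical(ens$members[[1]]$model$params,
                         ens$members[[2]]$model$params))
})

test_that("inference restores the original grid and averages probabilities", {
  p <- generate_phantom(small_phantom_spec(seed = 65))
  cs <- p$case
  # non-divisible z extent exercises the pad/crop contract
  cs28 <- mpmri_case(cs$case_id, cs$channels[, , 1:28, , drop = FALSE],
                     cs$labels[, , 1:28], spacing = cs$spacing)
  ucfg <- unet_config(n_classes = 5, levels = 2, base_filters = 4)
  tcfg <- train_config(initial_lr = 1e-3, epochs = 1, batch_size = 1,
                       patches_per_epoch = 2, ensemble_size = 1,
                       folds = 2, seed = 6)
  tm <- train_model(list(cs), ucfg, tcfg, patch_spec(edge = 16), aspec = NULL)
  pred <- predict_case(tm, cs28)
  expect_equal(dim(pred$labels), dim(cs28$labels))
  expect_equal(dim(pred$prob), c(dim(cs28$labels), 5L))
  sums <- apply(pred$prob, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(pred$labels %in% c(0L, 1L, 2L, 3L, 4L)))
  # an ensemble of two identical members equals the single member
  twin <- structure(list(members = list(tm, tm), ucfg = ucfg, tcfg = tcfg,
                         history = NULL), class = "trained_ensemble")
  pred2 <- predict_case(twin, cs28)
  expect_identical(pred2$labels, pred$labels)
  expect_equal(pred2$prob, pred$prob, tolerance = 1e-12)
  expect_error(predict_case(structure(list(members = list(), ucfg = ucfg,
                                           tcfg = tcfg, history = NULL),
                                      class = "trained_ensemble"), cs28),
               "empty ensemble")
})
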