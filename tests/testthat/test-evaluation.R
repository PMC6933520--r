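test_that("volume correlations match the textbook formula", {
  a <- c(12, 40, 55, 70, 81, 95, 110, 140, 160, 220)
  b <- c(20, 35, 60, 62, 90, 100, 105, 150, 170, 210)
  res <- correlate_volumes(a, b, "pearson")
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t_hand <- r_hand * sqrt(8 / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), df = 8)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_equal(res$n, 10)
  expect_equal(correlate_volumes(a, a)$r, 1)
  expect_equal(correlate_volumes(a, -a)$r, -1)
  expect_false(correlate_volumes(c(1, 1, 1), c(1, 2, 3))$defined)
  expect_error(correlate_volumes(a, b[1:5]), "length mismatch")
  expect_error(correlate_volumes(a[1:2], b[1:2]), "at least 3")
})

test_that("pearson correlation is invariant to positive affine transforms", {
  set.seed(81)
  a <- rnorm(30); b <- a + rnorm(30)
  r0 <- correlate_volumes(a, b)$r
  expect_equal(correlate_volumes(3 * a + 10, b)$r, r0, tolerance = 1e-12)
  expect_equal(correlate_volumes(a, 0.5 * b - 2)$r, r0, tolerance = 1e-12)
})

test_that("bland-altman bias and limits follow the 1.96-sd convention", {
  a <- c(5, 7, 9, 11)
  expect_equal(bland_altman(a, a)$bias, 0)
  expect_equal(bland_altman(a, a)$lower, 0)
  expect_equal(bland_altman(a, a)$upper, 0)
  shifted <- bland_altman(a + 5, a)
  expect_equal(shifted$bias, 5)
  expect_equal(shifted$sd_diff, 0)
  expect_equal(c(shifted$lower, shifted$upper), c(5, 5))
  set.seed(82)
  x <- rnorm(20, 100, 10); y <- rnorm(20, 100, 10)
  ba <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd_diff, sqrt(sum((d - mean(d))^2) / 19), tolerance = 1e-12)
  expect_equal(ba$upper, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_true(ba$lower <= ba$bias && ba$bias <= ba$upper)
})

test_that("limits of agreement cover about 95% of normal differences", {
  set.seed(83)
  x <- rnorm(10000); y <- rnorm(10000)
  ba <- bland_altman(x, y)
  inside <- mean(ba$differences >= ba$lower & ba$differences <= ba$upper)
  expect_lt(abs(inside - 0.95), 0.01)
})

test_that("prevalence counts are inclusive, nested and order-invariant", {
  expect_equal(unname(wmh_prevalence(c(0, 50, 100, 2000), c(100, 1000))),
               c(2L, 1L))
  expect_equal(unname(wmh_prevalence(numeric(0))), rep(0L, 4))
  expect_equal(unname(wmh_prevalence(c(3, 9, 27), 0)), 3L)
  set.seed(84)
  v <- rexp(50, 1 / 2000)
  counts <- wmh_prevalence(v)
  expect_true(all(diff(counts) <= 0))
  expect_equal(wmh_prevalence(sample(v)), counts)
})

test_that("stratified medians respect strata and flag empty ones", {
  rep_df <- data.frame(case_id = as.character(1:6), region = "WMH",
                       dice = 0.5,
                       hd95 = 1, pred_vol_mm3 = 0,
                       truth_vol_mm3 = c(50, 200, 1500, 6000, 12000, 20000))
  s <- stratified_median_dice(rep_df)
  expect_equal(s$median_dice, rep(0.5, 4))
  expect_equal(s$n, c(5L, 4L, 3L, 2L))
  rep_df$dice <- c(0.1, 0.2, 0.4, 0.6, 0.8, 0.9)  # dice grows with volume
  s2 <- stratified_median_dice(rep_df)
  expect_true(all(diff(s2$median_dice) >= 0))
  s3 <- stratified_median_dice(rep_df, thresholds = 1e9)
  expect_true(is.na(s3$median_dice))
  expect_equal(s3$n, 0L)
})

test_that("volume-dice correlation supports the log10 transform", {
  set.seed(85)
  v <- 10^runif(40, 1, 5)
  d <- pmin(1, pmax(0, 0.15 * log10(v) + rnorm(40, 0, 0.05)))
  rep_df <- data.frame(case_id = as.character(1:40), region = "WT",
                       dice = d, hd95 = 1, pred_vol_mm3 = v,
                       truth_vol_mm3 = v)
  raw <- volume_dice_correlation(rep_df, "WT", log10_volume = FALSE)
  lg <- volume_dice_correlation(rep_df, "WT", log10_volume = TRUE)
  expect_gt(lg$r, raw$r)
  expect_equal(lg$n_excluded, 0)
  rep_df$truth_vol_mm3[1] <- 0
  lg2 <- volume_dice_correlation(rep_df, "WT", log10_volume = TRUE)
  expect_equal(lg2$n_excluded, 1)
  expect_equal(lg2$n, 39)
  rep_df$dice <- 0.7
  expect_false(volume_dice_correlation(rep_df, "WT")$defined)
})

test_that("the paired test matches the hand-computed t statistic", {
  a <- c(3.1, 2.8, 3.6, 3.0, 2.5, 3.3, 3.8, 2.9)
  b <- c(3.5, 2.9, 4.1, 3.2, 2.4, 3.9, 4.0, 3.4)
  res <- paired_two_tailed_t(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(8))
  p_hand <- 2 * pt(-abs(t_hand), df = 7)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  same <- paired_two_tailed_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  const <- paired_two_tailed_t(a + 2, a)
  expect_false(const$defined)
  expect_error(paired_two_tailed_t(a, b[1:3]), "length mismatch")
})

test_that("cohort reports aggregate correlations, agreement and strata", {
  set.seed(86)
  n <- 12
  truth <- 10^runif(n, 2, 4.2)
  pred <- truth * runif(n, 0.7, 1.3)
  rep_df <- rbind(
    data.frame(case_id = as.character(1:n), region = "WT",
               dice = runif(n, 0.8, 1), hd95 = runif(n, 0, 3),
               pred_vol_mm3 = pred * 3, truth_vol_mm3 = truth * 3),
    data.frame(case_id = as.character(1:n), region = "WMH",
               dice = runif(n, 0.2, 0.8), hd95 = runif(n, 0, 5),
               pred_vol_mm3 = pred, truth_vol_mm3 = truth))
  rep <- cohort_report(rep_df)
  expect_s3_class(rep$WT_volume_correlation, "correlation_result")
  expect_s3_class(rep$WMH_bland_altman, "bland_altman_result")
  expect_equal(unname(rep$wmh_prevalence[1]), sum(truth >= 100))
  expect_equal(nrow(rep$wmh_stratified_dice), 4)
})
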