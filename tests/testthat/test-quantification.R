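make_series <- function(controls, labels, ti = PROTOCOL_TIS, te = 0.220) {
  asl_series(controls, labels, ti_list = ti, te = te)
}

test_that("pairwise subtraction averages control minus label per TI", {
  dims <- c(4, 4, 2, 3)
  ctrl <- array(5, dims)
  lab <- array(3, dims)
  dm <- pairwise_subtract(make_series(ctrl, lab, ti = c(1, 2)))
  expect_equal(dim(dm), c(4, 4, 2))
  expect_true(all(dm == 2))
  # identical stacks -> zero image
  expect_true(all(pairwise_subtract(make_series(ctrl, ctrl, ti = c(1, 2))) == 0))
  # flipped convention
  dm2 <- pairwise_subtract(make_series(ctrl, lab, ti = c(1, 2)),
                           order = "label-control")
  expect_true(all(dm2 == -2))
  expect_error(asl_series(ctrl, lab[, , , 1:2], ti_list = c(1, 2), te = 0.02),
               "identical dimensions")
})

test_that("repetition averaging shrinks subtraction noise as 1/sqrt(n)", {
  set.seed(9)
  dims <- c(8, 8, 1, 20)
  ctrl <- array(rnorm(prod(dims), 10, 1), dims)
  lab <- array(rnorm(prod(dims), 8, 1), dims)
  dm <- pairwise_subtract(make_series(ctrl, lab, ti = 1))
  # truth 2, averaged SD sqrt(2)/sqrt(20); 64 voxels
  expect_lt(abs(mean(dm) - 2), 4 * sqrt(2 / 20) / 8)
  expect_lt(abs(sd(as.vector(dm)) - sqrt(2 / 20)), 0.15)
})

test_that("roi_sum and roi_mean aggregate under the mask", {
  m <- matrix(FALSE, 6, 6)
  m[2:4, 2:3] <- TRUE # 6 voxels
  roi <- roi_spec(m, voxel_dims = c(0.625, 0.625, 2.4))
  img <- matrix(1, 6, 6)
  expect_equal(roi_sum(img, roi), 6)
  expect_equal(roi_sum(matrix(0, 6, 6), roi), 0)
  set.seed(2)
  img2 <- matrix(rnorm(36), 6, 6)
  one <- matrix(FALSE, 6, 6)
  one[3, 3] <- TRUE
  expect_equal(roi_sum(img2, roi_spec(one)), img2[3, 3])
  expect_equal(roi_mean(img2, roi), mean(img2[m]))
  expect_error(roi_spec(matrix(FALSE, 3, 3)), "empty")
  expect_error(roi_sum(matrix(0, 3, 3), roi), "dimensions")
})

test_that("ROI volume arithmetic matches the acquisition geometry", {
  m <- matrix(FALSE, 32, 32)
  m[18:20, 12:13] <- TRUE
  m[18:20, 19:20] <- TRUE
  roi <- roi_spec(m, voxel_dims = c(20 / 32, 20 / 32, 2.4))
  expect_equal(sum(roi$mask), 12)
  expect_equal(roi$roi_volume, 11.25)
})

test_that("M0 ventricle correction rescales by the volume ratio", {
  m <- matrix(TRUE, 3, 4) # 12 voxels x 0.9375 mm^3 = 11.25 mm^3
  roi <- roi_spec(m, ventricle_volume = 3.75)
  expect_equal(m0_correction(100, roi), 300)
  roi_id <- roi_spec(m, ventricle_volume = 11.25)
  expect_equal(m0_correction(100, roi_id), 100)
  expect_error(m0_correction(100, roi_spec(m)), "ventricle_volume")
})

test_that("unit conversions reproduce the reported arithmetic", {
  expect_equal(flow_to_reporting_units(0.004), 24)
  expect_equal(flow_to_reporting_units(0), 0)
  expect_equal(flow_to_reporting_units(0.00216667), 13.00002)
  expect_equal(total_delivery_rate(24, 11.25), 2.7)
  expect_equal(total_delivery_rate(0, 99), 0)
  expect_equal(total_delivery_rate(13, 11.25), 1.4625)
  # conservation across units: f (s^-1) over V mm^3 = f*V*60 ul/min native
  f_native <- 0.004
  expect_equal(total_delivery_rate(flow_to_reporting_units(f_native), 11.25),
               f_native * 11.25 * 60)
})

test_that("CP blood flow scales delivery by mass with full extraction", {
  expect_equal(cp_blood_flow(2.7, 0.22), 2.7 / 0.22 * 100)
  expect_lt(abs(cp_blood_flow(2.7, 0.22) - 1227), 1)
  expect_equal(cp_blood_flow(0, 0.2), 0)
  expect_equal(cp_blood_flow(2.7, 0.44), cp_blood_flow(2.7, 0.22) / 2)
  expect_equal(cp_blood_flow(2.7, 0.22, extraction = 0.9),
               cp_blood_flow(2.7, 0.22) / 0.9)
  expect_error(cp_blood_flow(2.7, 0), "cp_mass")
  expect_error(cp_blood_flow(2.7, 0.22, extraction = 1.2), "extraction")
})

test_that("percent change reproduces the cohort contrasts", {
  expect_equal(percent_change(251, 218), 100 * (218 - 251) / 251)
  expect_lt(abs(percent_change(251, 218) + 13.1), 0.05)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(100, 37), -63)
  expect_error(percent_change(0, 1), "baseline")
})

test_that("group comparison behaves at the null and under separation", {
  d0 <- data.frame(value = rep(c(1, 2, 3), 2),
                   group = rep(c("a", "b"), each = 3))
  r0 <- cohort_compare(d0)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 0.5)
  d1 <- data.frame(value = c(11, 12, 13, 1, 2, 3),
                   group = rep(c("a", "b"), each = 3))
  expect_lt(cohort_compare(d1)$p_value, 0.001)
  expect_error(cohort_compare(data.frame(value = c(1, 2), group = c("a", "b"))),
               "at least 2")
})

test_that("t-test p agrees with a permutation null on a seeded example", {
  set.seed(13)
  a <- rnorm(6, 1.0, 1)
  b <- rnorm(6, 0.2, 1)
  d <- data.frame(value = c(a, b), group = rep(c("a", "b"), each = 6))
  p_t <- cohort_compare(d)$p_value
  # permutation oracle: one-tailed p of the mean difference
  obs <- mean(a) - mean(b)
  pooled <- c(a, b)
  set.seed(99)
  n_perm <- 1e5
  perm <- replicate(n_perm, {
    idx <- sample.int(12, 6)
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  p_perm <- (sum(perm >= obs) + 1) / (n_perm + 1)
  expect_lt(abs(p_t - p_perm), 0.02)
})

test_that("Pearson correlation handles exact and degenerate cases", {
  d <- data.frame(x = 1:6, y = 2 * (1:6) + 3)
  expect_equal(correlate(d)$r, 1)
  d2 <- data.frame(x = 1:6, y = -(1:6))
  expect_equal(correlate(d2)$r, -1)
  expect_error(correlate(data.frame(x = rep(1, 5), y = 1:5)), "constant")
  expect_error(correlate(data.frame(x = 1:2, y = 1:2)), "n >= 3")
})

test_that("correlation p agrees with a permutation null on a seeded example", {
  set.seed(21)
  n <- 12
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n, 0, sqrt(1 - 0.64))
  res <- correlate(data.frame(x = x, y = y))
  obs <- abs(res$r)
  set.seed(77)
  n_perm <- 1e5
  perm <- replicate(n_perm, abs(stats::cor(x, sample(y))))
  p_perm <- (sum(perm >= obs) + 1) / (n_perm + 1)
  expect_lt(abs(res$p_value - p_perm), 0.02)
})

test_that("scan-rescan error is the mean absolute difference", {
  expect_equal(scan_rescan_error(
    data.frame(baseline = c(20, 10), rescan = c(20, 10)))$mean_abs_diff, 0)
  expect_equal(scan_rescan_error(
    data.frame(baseline = c(20, 10), rescan = c(21, 9)))$mean_abs_diff, 1)
  # test-retest with within-subject SD s: |d| is half-normal with mean
  # s*sqrt(2)*sqrt(2/pi) when both scans carry independent error s
  set.seed(31)
  s <- 1.3
  n <- 4000
  base <- rnorm(n, 20, s)
  resc <- rnorm(n, 20, s)
  mad_hat <- scan_rescan_error(
    data.frame(baseline = base, rescan = resc))$mean_abs_diff
  expect_lt(abs(mad_hat - s * sqrt(2) * sqrt(2 / pi)), 0.1)
})
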