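test_that("threshold closed forms reproduce the worked testbed pair and limits", {
  lv <- derive_mask_levels(A0 = 1e4, thup = 4.2e3, rt = 6, rh = 18)
  expect_equal(signif(lv$thlow / 1e3, 3), 9.08)
  # thup = A0 e^{-1/2} -> sigma0 = rh exactly
  lv2 <- derive_mask_levels(1e4, 1e4 * exp(-0.5), rt = 6, rh = 18)
  expect_equal(lv2$sigma0, 18, tolerance = 1e-14)
  # rt -> 0 -> thlow -> A0
  expect_equal(derive_mask_levels(1e4, 4.2e3, rt = 1e-9, rh = 18)$thlow, 1e4,
               tolerance = 1e-12)
  expect_error(derive_mask_levels(1e4, 1e4, 6, 18), class = "apahtp_argument_error")
  expect_error(derive_mask_levels(1e4, 2e4, 6, 18), class = "apahtp_argument_error")
  expect_error(derive_mask_levels(1e4, 4.2e3, 18, 6), class = "apahtp_argument_error")
})

test_that("Gaussian target traces the intensity profile at centroid, rt and rh", {
  # line grid with voxel centers exactly at d = 0, rt, rh from the centroid
  grid <- voxel_grid(c(37, 1, 1), 1, origin = c(-18, 0, 0))
  lin <- seq_len(37)
  for (thup in exp(seq(log(1e3), log(9e3), length.out = 10))) {
    lv <- derive_mask_levels(1e4, thup, rt = 6, rh = 18)
    tf <- build_gaussian_target(1e4, lv$sigma0, c(0, 0, 0), "z", grid, lin)
    xyz <- voxel_centers(grid, lin)
    mag2 <- apahtp:::vec_mag2(tf$values)
    at <- function(x) mag2[which(xyz[, 1] == x)]
    expect_equal(at(0), 1e4, tolerance = 1e-14)
    expect_equal(at(18), thup, tolerance = 1e-14)
    expect_equal(at(6), lv$thlow, tolerance = 1e-14)
    # off-axis components are zero, phase is zero
    expect_true(all(tf$values[, c("x", "y")] == 0i))
    expect_true(all(Im(tf$values[, "z"]) == 0))
  }
  expect_error(build_gaussian_target(1e4, 10, c(0, 0, 0), "w", grid, lin),
               class = "apahtp_argument_error")
})

test_that("peak intensity bound is tight for one antenna and dominates random feedings", {
  fx <- coarse_fixture()
  EN <- fx$fields
  part <- fx$partition
  # N = 1: the bound is achieved exactly
  EN1 <- apahtp:::new_field_matrix(EN$values[, 1, drop = FALSE], EN$voxel_linear,
                                   EN$grid)
  b1 <- normalize_power(1 + 0i)
  tum <- which(part$tumor_mask[EN1$voxel_linear])
  reached <- max(apahtp:::vec_mag2(superpose_field(EN1, b1)$values)[tum])
  expect_equal(estimate_peak_intensity_bound(EN1, part), reached,
               tolerance = 1e-12)

  # two identical antennas: bound doubles and cophased feeding achieves it
  EN2 <- apahtp:::new_field_matrix(cbind(EN$values[, 1], EN$values[, 1]),
                                   EN$voxel_linear, EN$grid)
  expect_equal(estimate_peak_intensity_bound(EN2, part),
               2 * estimate_peak_intensity_bound(EN1, part), tolerance = 1e-12)
  phases <- seq(0, 2 * pi, length.out = 73)[-73]
  best <- max(vapply(phases, function(ph) {
    b <- normalize_power(c(1 + 0i, exp(1i * ph)))
    max(apahtp:::vec_mag2(superpose_field(EN2, b)$values)[tum])
  }, numeric(1)))
  expect_equal(best, estimate_peak_intensity_bound(EN2, part), tolerance = 1e-9)

  # randomized dominance on the full 8-antenna matrix
  bound <- estimate_peak_intensity_bound(EN, part)
  set.seed(9)
  for (i in 1:100) {
    b <- normalize_power(complex(real = rnorm(8), imaginary = rnorm(8)))
    expect_lte(max(apahtp:::vec_mag2(superpose_field(EN, b)$values)[tum]),
               bound * (1 + 1e-12))
  }
})

test_that("the sweep composes the closed forms and yields v10 >= v50", {
  fx <- coarse_fixture()
  cands <- exp(seq(log(0.1e4), log(0.9e4), length.out = 5))
  sweep <- run_threshold_sweep(fx$fields, fx$partition, fx$phantom,
                               A0 = 1e4, candidates = cands)
  expect_identical(nrow(sweep), 5L)
  for (i in seq_len(5)) {
    lv <- derive_mask_levels(1e4, cands[i], fx$partition$rt, fx$partition$rh)
    expect_equal(sweep$thlow[i], lv$thlow, tolerance = 1e-14)
    expect_equal(sweep$sigma0_mm[i], lv$sigma0, tolerance = 1e-14)
  }
  expect_true(all(sweep$v10_pct >= sweep$v50_pct))
  # duplicated candidates give identical metrics (pure function of inputs)
  dup <- run_threshold_sweep(fx$fields, fx$partition, fx$phantom,
                             A0 = 1e4, candidates = rep(cands[3], 2))
  expect_identical(dup$v10_pct[1], dup$v10_pct[2])
  expect_identical(dup$htq[1], dup$htq[2])
  expect_error(run_threshold_sweep(fx$fields, fx$partition, fx$phantom,
                                   candidates = numeric(0)),
               class = "apahtp_argument_error")
  expect_error(run_threshold_sweep(fx$fields, fx$partition, fx$phantom,
                                   candidates = c(2e4)),
               class = "apahtp_argument_error")
})

test_that("knee selection picks the max-distance nondominated point", {
  cands <- data.frame(v10_pct = c(0, 2, 10), v50_pct = c(10, 2, 0))
  out <- select_knee(cands)
  expect_identical(out$knee_id, 2L)
  expect_identical(out$nondominated_ids, 1:3)
  # dominated points are never selected
  cands2 <- data.frame(v10_pct = c(0, 2, 10, 5, 11),
                       v50_pct = c(10, 2, 0, 5, 10))
  out2 <- select_knee(cands2)
  expect_false(4L %in% out2$nondominated_ids)
  expect_false(5L %in% out2$nondominated_ids)
  expect_identical(out2$knee_id, 2L)
  # single candidate is its own knee
  expect_identical(select_knee(data.frame(v10_pct = 1, v50_pct = 1))$knee_id, 1L)
})
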