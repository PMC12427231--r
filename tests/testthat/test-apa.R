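test_that("projector matches the normal-equation oracle and is idempotent", {
  set.seed(5)
  A <- matrix(complex(real = rnorm(36), imaginary = rnorm(36)), nrow = 12)
  EN <- apahtp:::new_field_matrix(A, 1:4, voxel_grid(c(4, 1, 1), 1))
  proj <- build_projector(EN)
  v <- complex(real = rnorm(12), imaginary = rnorm(12))
  # independent least-squares oracle: P = A (A^H A)^{-1} A^H
  AH <- Conj(t(A))
  P <- A %*% solve(AH %*% A, AH)
  expect_equal(proj$project(v), as.vector(P %*% v), tolerance = 1e-10)
  # projection identity on the column space, annihilation off it
  incol <- as.vector(A %*% complex(real = rnorm(3), imaginary = rnorm(3)))
  expect_equal(proj$project(incol), incol, tolerance = 1e-10)
  ortho <- v - as.vector(P %*% v)
  expect_lt(max(Mod(proj$project(ortho))), 1e-10)
  # idempotence
  pv <- proj$project(v)
  expect_lt(sqrt(sum(Mod(proj$project(pv) - pv)^2)) / sqrt(sum(Mod(pv)^2)), 1e-10)
})

test_that("power normalization fixes ||b||^2/(2 R0) = P0 and is idempotent", {
  b <- c(2 + 0i, 2i, 0, -2) # ||b||^2 = 12 -> rescale
  b8 <- c(2, 2, 0, 0) * exp(1i * c(0, pi / 3, 0, 0)) # ||b||^2 = 8
  nb <- normalize_power(b8, P0 = 1, R0 = 50)
  C <- Mod(nb$coefficients[1]) / 2
  expect_equal(C, sqrt(100 / 8), tolerance = 1e-14) # ~3.5355
  expect_equal(sum(Mod(nb$coefficients)^2) / (2 * 50), 1, tolerance = 1e-14)
  # already satisfying the constraint -> C = 1; idempotence
  nb2 <- normalize_power(nb, P0 = 1, R0 = 50)
  expect_equal(nb2$coefficients, nb$coefficients, tolerance = 1e-14)
  expect_error(normalize_power(rep(0i, 4)), class = "apahtp_degenerate_error")
})

test_that("clipping enforces the mask, preserves direction, never touches the transition", {
  part <- toy_partition(4, tumor = 1, transition = 2)
  mask <- power_mask(part, thlow = 100, thup = 50)
  E <- toy_total_field(matrix(c(
    3 + 0i, 0i, 4i,       # tumor |E|^2 = 25 < 100 -> scale by 2
    10 + 0i, 0i, 10i,     # transition |E|^2 = 200 -> untouched
    6 + 0i, 8i, 0i,       # healthy |E|^2 = 100 > 50 -> scale down
    1 + 0i, 0i, 0i        # healthy inside mask -> untouched
  ), nrow = 4, byrow = TRUE))
  out <- clip_to_mask(E, mask)
  expect_identical(out$out_of_mask, 2L)
  expect_equal(out$field$values[1, ], c(6 + 0i, 0i, 8i), ignore_attr = TRUE)
  expect_identical(out$field$values[2, ], E$values[2, ])
  expect_identical(out$field$values[4, ], E$values[4, ])
  expect_equal(apahtp:::vec_mag2(out$field$values)[3], 50, tolerance = 1e-12)
  # complex colinearity of the modified healthy voxel
  ratio <- out$field$values[3, c(1, 2)] / E$values[3, c(1, 2)]
  expect_equal(ratio[1], ratio[2], tolerance = 1e-14)
  expect_equal(Im(ratio[1]), 0, tolerance = 1e-14)

  # field already inside the mask -> identity, count 0
  ok <- toy_total_field(matrix(c(11 + 0i, 0i, 0i,
                                 1 + 0i, 0i, 0i,
                                 1 + 0i, 0i, 0i,
                                 2 + 0i, 0i, 0i), nrow = 4, byrow = TRUE))
  res <- clip_to_mask(ok, mask)
  expect_identical(res$out_of_mask, 0L)
  expect_identical(res$field$values, ok$values)

  # zero-magnitude tumor voxel: left unchanged but counted
  z <- ok; z$values[1, ] <- 0i
  rz <- clip_to_mask(z, mask)
  expect_identical(rz$out_of_mask, 1L)
  expect_identical(unname(rz$field$values[1, ]), c(0i, 0i, 0i))
})

test_that("a feasible in-space target is a fixed point of the alternating loop", {
  fx <- coarse_fixture()
  b0 <- normalize_power(rep(1 + 0i, 8))
  realizable <- superpose_field(fx$fields, b0)
  mag2 <- apahtp:::vec_mag2(realizable$values)
  tum <- which(fx$partition$tumor_mask[realizable$voxel_linear])
  hea <- which(fx$partition$healthy_mask[realizable$voxel_linear])
  # thresholds chosen strictly feasible for this realizable field
  mask <- power_mask(fx$partition, thlow = min(mag2[tum]) * 0.9,
                     thup = max(mag2[hea]) * 1.1)
  res <- run_apa(fx$fields, realizable, mask, fx$phantom)
  expect_identical(res$stop_reason, "fixed_point")
  expect_true(all(res$oom_trace == 0L))
  expect_equal(res$best_excitation$coefficients, b0$coefficients,
               tolerance = 1e-10)
})

test_that("APA improves on the initial projection and honors its contracts", {
  fx <- coarse_fixture()
  lv <- derive_mask_levels(1e4, 4.2e3, fx$partition$rt, fx$partition$rh)
  target <- build_gaussian_target(1e4, lv$sigma0, fx$partition$centroid, "z",
                                  fx$fields$grid, fx$fields$voxel_linear)
  mask <- power_mask(fx$partition, lv$thlow, 4.2e3)
  res <- run_apa(fx$fields, target, mask, fx$phantom)
  expect_lte(res$best_htq, res$htq_initial)
  expect_equal(res$best_htq, min(res$htq_trace))
  expect_identical(length(res$htq_trace), res$iterations_run)
  expect_identical(length(res$oom_trace), res$iterations_run)
  # power conservation at every iterate
  expect_lt(max(abs(res$power_trace - 1)), 1e-12)
  # the returned excitation reproduces the reported HTQ
  sar <- compute_sar(res$final_field, fx$phantom, "peak")
  expect_equal(compute_htq(sar, fx$partition), res$best_htq, tolerance = 1e-12)
  # deterministic: identical inputs give bit-identical traces
  res2 <- run_apa(fx$fields, target, mask, fx$phantom)
  expect_identical(res2$htq_trace, res$htq_trace)
  expect_identical(res2$oom_trace, res$oom_trace)
  expect_identical(res2$best_excitation$coefficients,
                   res$best_excitation$coefficients)
})

test_that("degenerate APA inputs abort with classed errors", {
  fx <- coarse_fixture()
  zero <- fx$fields
  zero$values[] <- 0i
  lv <- derive_mask_levels(1e4, 4.2e3, 6, 18)
  target <- build_gaussian_target(1e4, lv$sigma0, fx$partition$centroid, "z",
                                  fx$fields$grid, fx$fields$voxel_linear)
  mask <- power_mask(fx$partition, lv$thlow, 4.2e3)
  expect_error(run_apa(zero, target, mask, fx$phantom),
               class = "apahtp_degenerate_error")
  expect_error(power_mask(fx$partition, -1, 10), class = "apahtp_argument_error")
  expect_error(stopping_config(max_iter = 0), class = "apahtp_argument_error")
})
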