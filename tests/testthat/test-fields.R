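test_that("surrogate decay follows 1/d in lossless and the lossy closed form otherwise", {
  # two phantoms sharing geometry, one with sigma = 0
  mk <- function(sigma) {
    ph <- toy_phantom(c(41, 5, 5), spacing = 2, sigma = sigma, eps_r = 56.9)
    ring <- antenna_ring(n = 1, radius_mm = 60, frequency_hz = 434e6)
    list(ph = ph, EN = synthesize_surrogate_fields(ph, ring, reference_tissue = "toy"))
  }
  # boresight ray: voxels on the x axis (j = k = middle), antenna at (60, 0, 0)
  probe <- function(f) {
    xyz <- voxel_centers(f$ph$grid, f$EN$voxel_linear)
    on_axis <- which(xyz[, 2] == 0 & xyz[, 3] == 0)
    ord <- on_axis[order(xyz[on_axis, 1], decreasing = TRUE)] # toward antenna first
    M <- f$EN$M
    z_mag <- Mod(f$EN$values[2L * M + ord, 1])
    d <- (60 - xyz[ord, 1]) * 1e-3
    list(mag = z_mag, d = d)
  }
  lossless <- probe(mk(0))
  expect_equal(lossless$mag[10] / lossless$mag[1],
               lossless$d[1] / lossless$d[10], tolerance = 1e-12)

  lossy <- probe(mk(0.81))
  alpha <- propagation_constants(56.9, 0.81, 434e6)$alpha
  expect_equal(lossy$mag[10] / lossy$mag[1],
               (lossy$d[1] / lossy$d[10]) * exp(-alpha * (lossy$d[10] - lossy$d[1])),
               tolerance = 1e-12)

  # strict monotone decay along the ray
  expect_true(all(diff(lossy$mag) < 0))
})

test_that("dominant axis magnitude exceeds 5x each transverse magnitude", {
  EN <- coarse_fixture()$fields
  M <- EN$M
  zmag <- Mod(EN$values[(2 * M + 1):(3 * M), , drop = FALSE])
  xmag <- Mod(EN$values[1:M, , drop = FALSE])
  ymag <- Mod(EN$values[(M + 1):(2 * M), , drop = FALSE])
  expect_true(all(zmag >= 5 * xmag))
  expect_true(all(zmag >= 5 * ymag))
  expect_identical(dominant_component(EN), "z")
})

test_that("stacking order and round-trip bijection hold", {
  grid <- voxel_grid(c(2, 1, 1), 1)
  f1 <- matrix(complex(real = 1:6, imaginary = 6:1), nrow = 2) # voxels x comps
  EN <- assemble_field_matrix(list(f1), mask = c(TRUE, TRUE), grid = grid)
  expect_identical(dim(EN$values), c(6L, 1L))
  # rows ordered x@v1, x@v2, y@v1, y@v2, z@v1, z@v2
  expect_identical(EN$values[, 1], c(f1[, 1], f1[, 2], f1[, 3]))
  # unstack(stack(F)) = F exactly
  expect_identical(apahtp:::unstack_field(EN$values[, 1], 2L),
                   matrix(EN$values[, 1], 2, 3, dimnames = list(NULL, c("x", "y", "z"))))

  # random 3-antenna toy: column n equals antenna n's flattened field
  set.seed(7)
  fs <- replicate(3, matrix(complex(real = rnorm(12), imaginary = rnorm(12)),
                            nrow = 4), simplify = FALSE)
  grid4 <- voxel_grid(c(4, 1, 1), 1)
  EN3 <- assemble_field_matrix(fs, mask = rep(TRUE, 4), grid = grid4)
  for (n in 1:3)
    expect_identical(EN3$values[, n], c(fs[[n]][, 1], fs[[n]][, 2], fs[[n]][, 3]))
})

test_that("superposition is the matrix product, linear and homogeneous", {
  set.seed(11)
  fs <- replicate(2, matrix(complex(real = rnorm(12), imaginary = rnorm(12)),
                            nrow = 4), simplify = FALSE)
  EN <- assemble_field_matrix(fs, rep(TRUE, 4), voxel_grid(c(4, 1, 1), 1))
  # unit coefficient -> exactly that antenna's field
  e1 <- superpose_field(EN, c(1 + 0i, 0))
  expect_identical(as.vector(e1$values), EN$values[, 1])
  # hand arithmetic with b = (1, i) on 4 voxels
  bi <- superpose_field(EN, c(1 + 0i, 1i))
  expect_equal(bi$values, fs[[1]] + 1i * fs[[2]], ignore_attr = TRUE)
  # linearity + homogeneity to machine precision
  b1 <- complex(real = rnorm(2), imaginary = rnorm(2))
  b2 <- complex(real = rnorm(2), imaginary = rnorm(2))
  cc <- 2.5 - 1.25i
  expect_equal(superpose_field(EN, b1 + b2)$values,
               superpose_field(EN, b1)$values + superpose_field(EN, b2)$values,
               tolerance = 1e-14)
  expect_equal(superpose_field(EN, cc * b1)$values, cc * superpose_field(EN, b1)$values,
               tolerance = 1e-14)
  expect_error(superpose_field(EN, c(1 + 0i)), class = "apahtp_shape_error")
})

test_that("dominant_component honors block magnitudes and the x<y<z tie-break", {
  grid <- voxel_grid(c(2, 1, 1), 1)
  mk <- function(x, y, z) {
    f <- matrix(0i, 2, 3); f[, 1] <- x; f[, 2] <- y; f[, 3] <- z
    assemble_field_matrix(list(f), rep(TRUE, 2), grid)
  }
  expect_identical(dominant_component(mk(0, 1, 0)), "y")
  expect_identical(dominant_component(mk(1, 0, 1)), "x") # tie -> x
  expect_error(dominant_component(mk(0, 0, 0)), class = "apahtp_degenerate_error")
})

test_that("field container round-trips bit-identically and validates its schema", {
  EN <- coarse_fixture()$fields
  path <- tempfile(fileext = ".json")
  write_field_container(EN, path)
  back <- read_field_container(path)
  expect_identical(back$values, EN$values)
  expect_identical(back$voxel_linear, EN$voxel_linear)
  expect_identical(back$grid$shape, EN$grid$shape)
  expect_identical(back$grid$spacing, EN$grid$spacing)
  expect_identical(back$grid$origin, EN$grid$origin)
  expect_identical(back$r0_ohm, 50)

  # M < N containers are read with a warning (ill-posed projection)
  small <- apahtp:::new_field_matrix(
    matrix(complex(real = rnorm(12), imaginary = rnorm(12)), nrow = 3),
    voxel_linear = 1L, grid = voxel_grid(c(1, 1, 1), 1))
  p2 <- tempfile(fileext = ".json")
  write_field_container(small, p2)
  expect_warning(read_field_container(p2), "ill-posed")

  # schema violations
  j <- jsonlite::read_json(path)
  j$grid$spacing_mm <- NULL
  p3 <- tempfile(fileext = ".json")
  jsonlite::write_json(j, p3, auto_unbox = TRUE, digits = NA)
  expect_error(read_field_container(p3), class = "apahtp_format_error")
  j2 <- jsonlite::read_json(path)
  j2$format_version <- "99"
  jsonlite::write_json(j2, p3, auto_unbox = TRUE, digits = NA)
  expect_error(read_field_container(p3), class = "apahtp_format_error")
})
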