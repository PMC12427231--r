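# Shared fixtures, built once per test run.

# Coarse (10 mm) reference testbed for fast unit tests; the acceptance tests
# use the default 5 mm resolution.
coarse_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- generate_reference_fixture(1L, run_config(spacing_mm = 10))
    fx
  }
})

full_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- generate_reference_fixture(1L)
    fx
  }
})

# A single-tissue phantom with hand-set properties, for closed-form checks.
toy_phantom <- function(shape, spacing = 1, eps_r = 50, sigma = 1, rho = 1000,
                        k = 0.5, cp = 3500, omega = 1, labels = NULL) {
  grid <- voxel_grid(shape, spacing)
  tab <- tissue_table(data.frame(
    name = "toy", eps_r = eps_r, sigma_S_per_m = sigma, rho_kg_per_m3 = rho,
    k_W_per_mC = k, cp_J_per_kgC = cp, omega_ml_per_min_kg = omega))
  if (is.null(labels)) labels <- rep(1L, prod(shape))
  structure(list(grid = grid, labels = as.integer(labels), table = tab),
            class = "tissue_phantom")
}

# Minimal sar_map over n voxels of a dummy 1-D grid.
toy_sar_map <- function(values) {
  n <- length(values)
  structure(list(values = values, voxel_linear = seq_len(n),
                 grid = voxel_grid(c(n, 1, 1), 1), convention = "peak"),
            class = "sar_map")
}

# Partition over n voxels from explicit index sets.
toy_partition <- function(n, tumor, transition = integer(0)) {
  tm <- tr <- he <- logical(n)
  tm[tumor] <- TRUE
  tr[transition] <- TRUE
  he[-c(tumor, transition)] <- TRUE
  structure(list(tumor_mask = tm, transition_mask = tr, healthy_mask = he,
                 centroid = c(0, 0, 0), rt = 1, rh = 2),
            class = "region_partition")
}

toy_total_field <- function(values, grid = NULL, voxel_linear = NULL) {
  n <- nrow(values)
  structure(list(values = values,
                 voxel_linear = voxel_linear %||% seq_len(n),
                 grid = grid %||% voxel_grid(c(n, 1, 1), 1)),
            class = "total_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force HTQ: full sort, top ceil(1%) of healthy, ratio.
oracle_htq <- function(sar_values, tumor_idx, healthy_idx) {
  n1 <- ceiling(0.01 * length(healthy_idx))
  top <- sort(sar_values[healthy_idx], decreasing = TRUE)[seq_len(n1)]
  mean(top) / mean(sar_values[tumor_idx])
}

# Independent Vchi: exhaustive count.
oracle_vchi <- function(sar_values, tumor_idx, healthy_idx, chi) {
  thr <- chi / 100 * max(sar_values[tumor_idx])
  100 * sum(sar_values[healthy_idx] > thr) / length(healthy_idx)
}
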