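#' Closed-form mask levels from a Gaussian intensity profile
#'
#' Given the fixed peak intensity A0 at the tumor center and a candidate
#' healthy cap `thup`, the Gaussian spread is chosen so the intensity falls
#' to `thup` exactly at the transition outer radius rh:
#' sigma0 = rh * (2 ln(A0/thup))^(-1/2); the tumor floor is then the same
#' Gaussian evaluated at the tumor radius: thlow = A0 exp(-rt^2/(2 sigma0^2)).
#'
#' @param A0 peak intensity, V^2/m^2.
#' @param thup candidate healthy cap, V^2/m^2, in (0, A0).
#' @param rt tumor radius, mm.
#' @param rh transition outer radius, mm (> rt).
#' @return list with `sigma0` (mm) and `thlow` (V^2/m^2).
#' @export
derive_mask_levels <- function(A0, thup, rt, rh) {
  if (!is.finite(A0) || A0 <= 0) stop_arg("A0 must be > 0")
  if (!is.finite(thup) || thup <= 0 || thup >= A0)
    stop_arg("need 0 < thup < A0 (log nonpositive otherwise)")
  if (!is.finite(rt) || !is.finite(rh) || rt <= 0 || rt >= rh)
    stop_arg("need 0 < rt < rh")
  sigma0 <- rh / sqrt(2 * log(A0 / thup))
  list(sigma0 = sigma0, thlow = A0 * exp(-rt^2 / (2 * sigma0^2)))
}

#' Gaussian target field centered on the tumor
#'
#' The Gaussian A0 exp(-d^2/(2 sigma0^2)) is an intensity profile (V^2/m^2):
#' the target field's squared magnitude traces it, so the field itself is
#' its square root with zero phase, placed entirely on the dominant
#' polarization component.
#'
#' @param A0 peak intensity, V^2/m^2.
#' @param sigma0 Gaussian spread, mm.
#' @param centroid tumor center, mm-triple.
#' @param axis dominant component, one of "x", "y", "z".
#' @param grid the sampling [voxel_grid()].
#' @param mask logical vector or indices selecting the sampled voxels.
#' @return a `total_field`.
#' @export
build_gaussian_target <- function(A0, sigma0, centroid, axis, grid, mask) {
  if (!axis %in% c("x", "y", "z")) stop_arg("axis must be x, y or z")
  if (!is.finite(A0) || A0 <= 0 || !is.finite(sigma0) || sigma0 <= 0)
    stop_arg("A0 and sigma0 must be > 0")
  lin <- if (is.logical(mask)) which(mask) else as.integer(mask)
  xyz <- voxel_centers(grid, lin)
  d2 <- (xyz[, 1] - centroid[1])^2 + (xyz[, 2] - centroid[2])^2 +
    (xyz[, 3] - centroid[3])^2
  amp <- sqrt(A0 * exp(-d2 / (2 * sigma0^2)))
  vals <- matrix(0i, nrow = length(lin), ncol = 3L,
                 dimnames = list(NULL, c("x", "y", "z")))
  vals[, axis] <- amp + 0i
  structure(list(values = vals, voxel_linear = lin, grid = grid),
            class = "total_field")
}

#' Upper bound on the achievable focal intensity
#'
#' Cauchy-Schwarz bound on |E(r)|^2 over all excitations respecting the
#' power constraint ||b||^2 = 2 R0 P0, assuming complete constructive
#' interference: 2 R0 P0 * sum_n |e_n(r)|^2, maximized over tumor voxels
#' (each antenna's contribution is its full 3-component magnitude).
#'
#' @param EN a `field_matrix`.
#' @param partition a `region_partition`.
#' @param P0 total input power, W.
#' @param R0 reference resistance, ohm.
#' @return intensity bound, V^2/m^2.
#' @export
estimate_peak_intensity_bound <- function(EN, partition, P0 = 1, R0 = 50) {
  tum <- which(partition$tumor_mask[EN$voxel_linear])
  if (!length(tum)) stop_arg("empty tumor mask on the sampled voxels")
  M <- EN$M
  per_voxel <- 0
  for (nn in seq_len(EN$N)) {
    e3 <- unstack_field(EN$values[, nn], M)[tum, , drop = FALSE]
    per_voxel <- per_voxel + vec_mag2(e3)
  }
  2 * R0 * P0 * max(per_voxel)
}

#' Sweep candidate upper thresholds through the full optimization
#'
#' For each candidate `thup`: derive (sigma0, thlow) from the Gaussian
#' closed forms, build the Gaussian target along the dominant field
#' component, run the alternating projections optimization, and score the
#' resulting SAR map with V10%H and V50%H. Candidates are evaluated
#' independently, so the sweep is order-invariant and deterministic.
#'
#' @param EN a `field_matrix`.
#' @param partition a `region_partition`.
#' @param phantom the `tissue_phantom`.
#' @param A0 fixed peak intensity, V^2/m^2 (default 1e4).
#' @param candidates vector of thup candidates; default 10 log-spaced values
#'   in [0.1, 0.9] * A0.
#' @param P0,R0 power normalization constants.
#' @param stop a [stopping_config()].
#' @param healthy_scope denominator scope for the V-metrics.
#' @return data frame of class `pareto_candidates` with one row per
#'   candidate: thup, thlow, sigma0_mm, v10_pct, v50_pct, htq, iterations;
#'   attribute `results` holds the `apa_result` objects.
#' @export
run_threshold_sweep <- function(EN, partition, phantom, A0 = 1e4,
                                candidates = NULL, P0 = 1, R0 = 50,
                                stop = stopping_config(),
                                healthy_scope = "healthy_plus_transition") {
  if (is.null(candidates))
    candidates <- exp(seq(log(0.1 * A0), log(0.9 * A0), length.out = 10))
  if (!length(candidates)) stop_arg("empty candidate set")
  if (any(candidates <= 0 | candidates >= A0))
    stop_arg("every candidate thup must lie in (0, A0)")
  axis <- dominant_component(EN)
  results <- vector("list", length(candidates))
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    thup <- candidates[i]
    lv <- derive_mask_levels(A0, thup, partition$rt, partition$rh)
    target <- build_gaussian_target(A0, lv$sigma0, partition$centroid, axis,
                                    EN$grid, EN$voxel_linear)
    mask <- power_mask(partition, lv$thlow, thup)
    res <- run_apa(EN, target, mask, phantom, partition,
                   P0 = P0, R0 = R0, stop = stop)
    sar <- compute_sar(res$final_field, phantom, "peak")
    rows[[i]] <- data.frame(
      thup = thup, thlow = lv$thlow, sigma0_mm = lv$sigma0,
      v10_pct = compute_vchi(sar, partition, 10, healthy_scope),
      v50_pct = compute_vchi(sar, partition, 50, healthy_scope),
      htq = res$best_htq, iterations = res$iterations_run)
    results[[i]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  class(out) <- c("pareto_candidates", "data.frame")
  out
}

#' Pareto front and knee selection over the threshold sweep
#'
#' Nondominated candidates under (minimize V10%H, minimize V50%H). The knee
#' is the nondominated point with the largest perpendicular distance to the
#' chord joining the two extreme nondominated points after min-max
#' normalization of both axes; a single nondominated point is its own knee;
#' distance ties go to the smaller V50%H.
#'
#' @param candidates data frame with columns `v10_pct` and `v50_pct`
#'   (e.g. from [run_threshold_sweep()]).
#' @return list with `candidates` (input, plus logical `nondominated` and
#'   `knee` columns), `nondominated_ids`, `knee_id` (row indices).
#' @export
select_knee <- function(candidates) {
  v10 <- candidates$v10_pct; v50 <- candidates$v50_pct
  n <- length(v10)
  if (!n) stop_arg("empty candidate set")
  nondom <- vapply(seq_len(n), function(i) {
    !any(v10 <= v10[i] & v50 <= v50[i] & (v10 < v10[i] | v50 < v50[i]))
  }, logical(1))
  ids <- which(nondom)
  if (length(ids) == 1L) {
    knee <- ids
  } else {
    r10 <- diff(range(v10[ids])); r50 <- diff(range(v50[ids]))
    x <- if (r10 > 0) (v10[ids] - min(v10[ids])) / r10 else rep(0, length(ids))
    y <- if (r50 > 0) (v50[ids] - min(v50[ids])) / r50 else rep(0, length(ids))
    ord <- order(x, y)
    a <- ord[1L]; b <- ord[length(ord)]
    chord <- c(x[b] - x[a], y[b] - y[a])
    len <- sqrt(sum(chord^2))
    dist <- if (len == 0) rep(0, length(ids)) else
      abs(chord[1] * (y - y[a]) - chord[2] * (x - x[a])) / len
    # ties (within floating tolerance) -> smaller v50
    best <- which(dist >= max(dist) - 1e-12)
    knee <- ids[best[which.min(v50[ids][best])]]
  }
  candidates$nondominated <- nondom
  candidates$knee <- seq_len(n) == knee
  list(candidates = candidates, nondominated_ids = ids, knee_id = knee)
}

#' Stability probe of the threshold selection
#'
#' Re-runs the sweep with A0 and rh perturbed by +/- `fraction` and reports
#' whether the knee's thup candidate index is unchanged — a verification
#' routine, not an assertion.
#'
#' @param EN,partition,phantom as in [run_threshold_sweep()].
#' @param A0 baseline peak intensity.
#' @param fraction relative perturbation (default 0.1).
#' @param ... passed to [run_threshold_sweep()].
#' @return data frame with one row per perturbation and the knee index.
#' @export
check_knee_stability <- function(EN, partition, phantom, A0 = 1e4,
                                 fraction = 0.1, ...) {
  runs <- list(base = list(A0 = A0, rh = partition$rh),
               a0_up = list(A0 = A0 * (1 + fraction), rh = partition$rh),
               a0_dn = list(A0 = A0 * (1 - fraction), rh = partition$rh),
               rh_up = list(A0 = A0, rh = partition$rh * (1 + fraction)),
               rh_dn = list(A0 = A0, rh = partition$rh * (1 - fraction)))
  out <- lapply(names(runs), function(nm) {
    p <- runs[[nm]]
    part <- partition; part$rh <- p$rh
    sw <- run_threshold_sweep(EN, part, phantom, A0 = p$A0, ...)
    data.frame(case = nm, knee_index = select_knee(sw)$knee_id)
  })
  do.call(rbind, out)
}
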