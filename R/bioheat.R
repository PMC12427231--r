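#' Convective (Robin) boundary condition
#'
#' Applied on tissue faces selected by `surface`: either `"exterior"` (every
#' face between a tissue voxel and the exterior — label 0 or outside the
#' grid) or a full-grid logical mask naming an interior cavity (faces between
#' tissue and masked voxels), e.g. a trachea lumen. The face flux is
#' -k dT/dn = h (T - Text), discretized as a half-cell conduction resistance
#' in series with the convective film, so very large `h` reproduces a fixed
#' face temperature.
#'
#' @param surface `"exterior"` or a logical vector over the full grid.
#' @param h heat transfer coefficient, W/m^2/degC (>= 0).
#' @param text external reference temperature, degC.
#' @return object of class `boundary_condition`.
#' @export
boundary_condition <- function(surface, h, text) {
  if (!is.finite(h) || h < 0) stop_arg("h must be >= 0")
  if (!(identical(surface, "exterior") || is.logical(surface)))
    stop_arg("surface must be \"exterior\" or a logical grid mask")
  structure(list(surface = surface, h = h, text = text),
            class = "boundary_condition")
}

# Blood properties and arterial temperature (constants of the bioheat model).
BLOOD_RHO <- 1060      # kg/m^3
BLOOD_CP <- 3890       # J/kg/degC
T_ARTERIAL <- 37       # degC

#' Steady-state Pennes bioheat solver
#'
#' Solves 0 = div(k grad T) - rho_b Cp_b omega_s (T - Ta) + Q_EM * P0_scale
#' on the tissue voxels with a 7-point finite-volume stencil: harmonic-mean
#' face conductivities between tissue voxels, Robin (convective) exterior or
#' cavity faces, and insulated faces where no boundary condition applies
#' (the documented default). The perfusion sink uses
#' omega_s [1/s] = omega [mL/min/kg] * rho_tissue [kg/m^3] * 1e-6 / 60.
#' Q_EM = SAR * rho (W/m^3); metabolic heat is omitted. Lengths are
#' converted from mm to SI internally.
#'
#' @param phantom a `tissue_phantom`.
#' @param sar a `sar_map` on the phantom's tissue voxels, or NULL for a
#'   zero source.
#' @param bcs list of [boundary_condition()]s; the first matching a face
#'   wins.
#' @param P0_scale unitless multiplier on the source (input-power rescale).
#' @param Ta arterial blood temperature, degC.
#' @return object of class `temperature_field` with `values` (degC per
#'   tissue voxel), `voxel_linear`, `grid`, and attribute `residual` (the
#'   relative discrete balance residual).
#' @export
solve_pennes_steady <- function(phantom, sar = NULL, bcs = list(),
                                P0_scale = 1, Ta = T_ARTERIAL) {
  if (inherits(bcs, "boundary_condition")) bcs <- list(bcs)
  grid <- phantom$grid
  lin <- tissue_indices(phantom)
  nT <- length(lin)
  if (!nT) stop_degenerate("phantom has no tissue voxels")
  row_of <- integer(n_voxels(grid)); row_of[lin] <- seq_len(nT)

  k <- lookup_property(phantom, "k_W_per_mC", lin)
  rho <- lookup_property(phantom, "rho_kg_per_m3", lin)
  omega <- lookup_property(phantom, "omega_ml_per_min_kg", lin)
  if (any(k <= 0) || any(rho <= 0) || any(omega < 0))
    stop_config("negative or zero thermal properties")
  omega_s <- omega * rho * 1e-6 / 60          # 1/s
  perf <- BLOOD_RHO * BLOOD_CP * omega_s      # W/m^3/degC

  q <- numeric(nT)                            # W/m^3
  if (!is.null(sar)) {
    pos <- match(lin, sar$voxel_linear)
    if (anyNA(pos)) stop_shape("SAR map does not cover all tissue voxels")
    q <- sar$values[pos] * rho * P0_scale
  }

  h_m <- grid$spacing * 1e-3                  # m
  vol <- prod(h_m)
  shape <- grid$shape
  idx <- grid_index_table(grid)[lin, , drop = FALSE]

  ii <- jj <- integer(0); xx <- numeric(0)
  robin_any <- FALSE
  diag_acc <- perf * vol                      # start from the perfusion sink
  rhs <- q * vol + perf * vol * Ta

  strides <- c(1L, shape[1], shape[1] * shape[2])
  for (ax in 1:3) {
    area <- vol / h_m[ax]
    for (dir in c(-1L, 1L)) {
      nb_idx <- idx[, ax] + dir
      in_grid <- nb_idx >= 0L & nb_idx <= shape[ax] - 1L
      nb_lin <- lin + dir * strides[ax]
      nb_row <- integer(nT)
      nb_row[in_grid] <- row_of[nb_lin[in_grid]]
      interior <- in_grid & nb_row > 0L

      # tissue-tissue faces: harmonic-mean conductivity
      if (any(interior)) {
        i <- which(interior)
        kh <- 2 * k[i] * k[nb_row[i]] / (k[i] + k[nb_row[i]])
        G <- area * kh / h_m[ax]
        ii <- c(ii, i); jj <- c(jj, nb_row[i]); xx <- c(xx, -G)
        diag_acc[i] <- diag_acc[i] + G
      }

      # boundary faces (exterior or interior cavity): first matching BC wins
      bfaces <- which(!interior)
      if (length(bfaces) && length(bcs)) {
        unassigned <- rep(TRUE, length(bfaces))
        for (bc in bcs) {
          if (identical(bc$surface, "exterior")) {
            sel <- unassigned
          } else {
            sel <- unassigned & in_grid[bfaces]
            sel[sel] <- bc$surface[nb_lin[bfaces[sel]]]
          }
          if (!any(sel) || bc$h == 0) { unassigned <- unassigned & !sel; next }
          i <- bfaces[sel]
          Gb <- area / (h_m[ax] / (2 * k[i]) + 1 / bc$h)
          diag_acc[i] <- diag_acc[i] + Gb
          rhs[i] <- rhs[i] + Gb * bc$text
          robin_any <- TRUE
          unassigned <- unassigned & !sel
        }
      }
    }
  }

  if (all(perf == 0) && !robin_any)
    stop_degenerate("singular system: no perfusion and no convective face")
  A <- Matrix::sparseMatrix(i = c(seq_len(nT), ii), j = c(seq_len(nT), jj),
                            x = c(diag_acc, xx), dims = c(nT, nT))
  Tsol <- tryCatch(as.vector(Matrix::solve(A, rhs)),
                   error = function(e) stop_degenerate(
                     "singular bioheat system: ", conditionMessage(e)))
  resid <- sqrt(sum((as.vector(A %*% Tsol) - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  structure(list(values = Tsol, voxel_linear = lin, grid = grid,
                 Ta = Ta, residual = resid),
            class = "temperature_field")
}

#' Thermal dose estimators T90/T50/T10
#'
#' Tq is the temperature exceeded (or equalled) by at least q percent of the
#' region voxels: the nearest-rank statistic `sort(T, decreasing)[ceiling(q/100 * n)]`.
#' Guarantees T90 <= T50 <= T10.
#'
#' @param temps a `temperature_field` (or numeric vector of temperatures).
#' @param region full-grid logical mask of the region (ignored when `temps`
#'   is a plain vector).
#' @param probs percentages (default the standard 90/50/10).
#' @return named numeric vector, degC.
#' @export
thermal_estimators <- function(temps, region = NULL, probs = c(90, 50, 10)) {
  v <- if (is.numeric(temps)) temps
       else temps$values[which(region[temps$voxel_linear])]
  if (!length(v)) stop_arg("empty region")
  vd <- sort(v, decreasing = TRUE)
  out <- vd[ceiling(probs / 100 * length(v))]
  names(out) <- paste0("T", probs)
  out
}

#' Calibrate the total input power to a target tumor temperature
#'
#' The steady solution is affine in the source: T(P) = T_hom + P * dT where
#' T_hom solves the zero-source problem and dT = T(1 W) - T_hom >= 0. The
#' statistic (default: tumor T90) is therefore non-decreasing in P; the
#' power matching `target_T` is found on the affine family and confirmed by
#' one full re-solve.
#'
#' @param phantom a `tissue_phantom`.
#' @param sar_at_1W `sar_map` computed at P0 = 1 W.
#' @param bcs boundary conditions, as in [solve_pennes_steady()].
#' @param region full-grid logical tumor mask.
#' @param target_T target temperature, degC (default 42).
#' @param stat which estimator to match: "T90", "T50", "T10", "min" or "max".
#' @return list with `P0` (W), `temperature` (confirming re-solve), and the
#'   achieved statistic.
#' @export
calibrate_input_power <- function(phantom, sar_at_1W, bcs, region,
                                  target_T = 42, stat = "T90") {
  t_hom <- solve_pennes_steady(phantom, NULL, bcs)
  t_1w <- solve_pennes_steady(phantom, sar_at_1W, bcs, P0_scale = 1)
  sel <- which(region[t_hom$voxel_linear])
  if (!length(sel)) stop_arg("empty calibration region")
  base <- t_hom$values[sel]
  dT <- t_1w$values[sel] - base
  stat_fun <- switch(stat,
    min = min, max = max,
    T90 = function(v) thermal_estimators(v, probs = 90)[[1]],
    T50 = function(v) thermal_estimators(v, probs = 50)[[1]],
    T10 = function(v) thermal_estimators(v, probs = 10)[[1]],
    stop_arg("unknown calibration statistic: ", stat))
  if (max(dT) <= 0) stop_degenerate("zero tumor heating at 1 W")
  if (target_T <= stat_fun(base))
    stop_arg("target temperature not above the zero-source baseline")
  f <- function(P) stat_fun(base + P * dT) - target_T
  hi <- 1
  while (f(hi) < 0 && hi < 1e9) hi <- hi * 2
  if (f(hi) < 0) stop_degenerate("target temperature unreachable")
  P0 <- stats::uniroot(f, c(0, hi), tol = 1e-12)$root
  temperature <- solve_pennes_steady(phantom, sar_at_1W, bcs, P0_scale = P0)
  achieved <- stat_fun(temperature$values[sel])
  list(P0 = P0, temperature = temperature, achieved = achieved, stat = stat)
}
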