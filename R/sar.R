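#' Compute the SAR map from a total field
#'
#' SAR(r) = pref * sigma(r)/rho(r) * |E(r)|^2 in W/kg, where |E|^2 is the sum
#' of the squared magnitudes of the three complex Cartesian components. The
#' prefactor is 1/2 under the complex-peak phasor convention and 1 under the
#' RMS convention; the caller must state which convention the fields use.
#'
#' @param E a `total_field`.
#' @param phantom the `tissue_phantom` providing sigma and rho per voxel.
#' @param convention "peak" or "rms"; no default — it is a property of the
#'   field source and omitting it is a configuration error.
#' @return object of class `sar_map` with `values` (W/kg per sampled voxel),
#'   `voxel_linear`, `grid`, `convention`.
#' @export
compute_sar <- function(E, phantom, convention) {
  if (missing(convention) || is.null(convention))
    stop_config("phasor convention ('peak' or 'rms') must be declared")
  convention <- match.arg(convention, c("peak", "rms"))
  pref <- if (convention == "peak") 0.5 else 1
  sigma <- lookup_property(phantom, "sigma_S_per_m", E$voxel_linear)
  rho <- lookup_property(phantom, "rho_kg_per_m3", E$voxel_linear)
  structure(list(values = pref * sigma / rho * vec_mag2(E$values),
                 voxel_linear = E$voxel_linear, grid = E$grid,
                 convention = convention),
            class = "sar_map")
}

# Positions (within the sampled voxel set) of the voxels selected by a
# full-grid logical mask.
sampled_positions <- function(map, mask) which(mask[map$voxel_linear])

#' Hotspot-to-target SAR quotient (HTQ)
#'
#' Mean SAR over the hottest 1 percent of the healthy-tissue volume (V1)
#' divided by the mean SAR in the tumor. Healthy tissue here includes the
#' transition shell, i.e. everything outside the tumor, per the standard
#' definition. V1 holds the ceil(0.01 * n_healthy) highest-SAR voxels (at
#' least one), ties resolved deterministically by a stable sort. Invariant
#' under global SAR rescaling.
#'
#' @param sar a `sar_map`.
#' @param partition a `region_partition`.
#' @return HTQ, unitless (lower is better).
#' @export
compute_htq <- function(sar, partition) {
  tum <- sampled_positions(sar, partition$tumor_mask)
  hea <- sampled_positions(sar, partition$healthy_mask | partition$transition_mask)
  if (!length(tum)) stop_arg("tumor mask is empty on the sampled voxels")
  if (!length(hea)) stop_arg("healthy-for-HTQ set is empty")
  target_mean <- mean(sar$values[tum])
  if (target_mean <= 0) stop_degenerate("zero mean tumor SAR")
  n1 <- ceiling(0.01 * length(hea))
  hv <- sort(sar$values[hea], decreasing = TRUE, method = "radix")
  mean(hv[seq_len(n1)]) / target_mean
}

#' Healthy-volume exceedance metric Vchi%H
#'
#' Percentage of the healthy-tissue volume whose SAR exceeds chi percent of
#' the maximum SAR within the tumor. `healthy_scope` selects whether the
#' transition shell counts as healthy; the default includes it, matching the
#' HTQ convention.
#'
#' @param sar a `sar_map`.
#' @param partition a `region_partition`.
#' @param chi percentage in (0, 100].
#' @param healthy_scope "healthy_plus_transition" (default) or "healthy_only".
#' @return percentage in [0, 100].
#' @export
compute_vchi <- function(sar, partition, chi,
                         healthy_scope = c("healthy_plus_transition",
                                           "healthy_only")) {
  healthy_scope <- match.arg(healthy_scope)
  if (!is.finite(chi) || chi <= 0 || chi > 100)
    stop_arg("chi must be in (0, 100]")
  tum <- sampled_positions(sar, partition$tumor_mask)
  mask <- if (healthy_scope == "healthy_only") partition$healthy_mask
          else partition$healthy_mask | partition$transition_mask
  hea <- sampled_positions(sar, mask)
  if (!length(tum) || !length(hea)) stop_arg("empty tumor or healthy region")
  tmax <- max(sar$values[tum])
  if (tmax <= 0) stop_degenerate("zero maximum tumor SAR")
  100 * sum(sar$values[hea] > (chi / 100) * tmax) / length(hea)
}

#' Tabulate a Vchi curve and HTQ into a metric report
#'
#' @param sar a `sar_map`.
#' @param partition a `region_partition`.
#' @param chis chi values to sweep, percent.
#' @param scopes healthy scopes to report.
#' @return data frame with columns (metric, chi_percent, value, scope).
#' @export
metric_report <- function(sar, partition, chis = seq(10, 90, by = 10),
                          scopes = "healthy_plus_transition") {
  rows <- list(data.frame(metric = "htq", chi_percent = NA_real_,
                          value = compute_htq(sar, partition),
                          scope = "healthy_plus_transition"))
  for (sc in scopes) {
    for (chi in chis) {
      rows[[length(rows) + 1L]] <- data.frame(
        metric = "vchi", chi_percent = chi,
        value = compute_vchi(sar, partition, chi, sc), scope = sc)
    }
  }
  do.call(rbind, rows)
}
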