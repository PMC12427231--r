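#' Two-level power mask
#'
#' Pairs a region partition with the intensity thresholds: a floor `thlow`
#' (V^2/m^2) enforced inside the tumor and a cap `thup` enforced in the outer
#' healthy region. The transition shell between rt and rh is unconstrained.
#'
#' @param partition a `region_partition`.
#' @param thlow tumor intensity floor, V^2/m^2.
#' @param thup healthy intensity cap, V^2/m^2.
#' @return object of class `power_mask`.
#' @export
power_mask <- function(partition, thlow, thup) {
  if (!is.finite(thlow) || !is.finite(thup) || thlow <= 0 || thup <= 0)
    stop_arg("thresholds must be finite and > 0")
  structure(list(partition = partition, thlow = thlow, thup = thup),
            class = "power_mask")
}

#' Stopping configuration for the alternating projections loop
#'
#' @param max_iter iteration cap (default 4000).
#' @param plateau_window iterations without sufficient improvement of the
#'   best HTQ before stopping (default 50).
#' @param plateau_tol relative HTQ improvement threshold (default 1e-4).
#' @param oom_persistence consecutive strict rises of the out-of-mask count
#'   that trigger a stop (default 20).
#' @return object of class `stopping_config`.
#' @export
stopping_config <- function(max_iter = 4000L, plateau_window = 50L,
                            plateau_tol = 1e-4, oom_persistence = 20L) {
  if (max_iter < 1L || plateau_window < 1L || oom_persistence < 1L)
    stop_arg("max_iter, plateau_window and oom_persistence must be >= 1")
  structure(list(max_iter = as.integer(max_iter),
                 plateau_window = as.integer(plateau_window),
                 plateau_tol = plateau_tol,
                 oom_persistence = as.integer(oom_persistence)),
            class = "stopping_config")
}

#' Column-space projector from the field matrix
#'
#' Caches the Moore-Penrose pseudo-inverse of EN (computed once via SVD,
#' singular values below `rcond * sigma_max` truncated) and exposes the two
#' maps the optimization loop needs: `coef(v) = pinv(EN) . v` and
#' `project(v) = EN . pinv(EN) . v`, the orthogonal projection onto the
#' space of fields realizable by the array.
#'
#' @param EN a `field_matrix`.
#' @param rcond relative singular-value cutoff (default 1e-10).
#' @return list with functions `coef(v)` and `project(v)` and the kept rank.
#' @export
build_projector <- function(EN, rcond = 1e-10) {
  sv <- svd(EN$values)
  keep <- sv$d > rcond * sv$d[1]
  if (!any(keep)) stop_degenerate("field matrix has rank 0")
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  dinv <- 1 / sv$d[keep]
  coef <- function(v) as.vector(V %*% (dinv * (Conj(t(U)) %*% v)))
  list(coef = coef,
       project = function(v) as.vector(EN$values %*% coef(v)),
       rank = sum(keep))
}

#' Normalize an excitation vector to a fixed total input power
#'
#' Scales b so that ||b||^2 / (2 R0) = P0 exactly, i.e. by
#' C = sqrt(2 R0 P0 / ||b||^2). (The printed constant P0/(||b||^2/(2R0)) is a
#' power ratio; its square root is the amplitude scale that actually fixes
#' the input power.)
#'
#' @param b raw complex coefficients (length N).
#' @param P0 total input power, W.
#' @param R0 reference input resistance, ohm.
#' @return object of class `excitation_vector` with fields `coefficients`,
#'   `P0`, `R0`.
#' @export
normalize_power <- function(b, P0 = 1, R0 = 50) {
  if (inherits(b, "excitation_vector")) b <- b$coefficients
  nrm2 <- sum(Mod(b)^2)
  if (nrm2 == 0) stop_degenerate("cannot normalize the zero excitation vector")
  C <- sqrt(2 * R0 * P0 / nrm2)
  structure(list(coefficients = as.complex(b) * C, P0 = P0, R0 = R0),
            class = "excitation_vector")
}

#' @export
print.excitation_vector <- function(x, ...) {
  cat(sprintf("excitation_vector: N=%d, P0=%g W, R0=%g ohm\n",
              length(x$coefficients), x$P0, x$R0))
  print(data.frame(amplitude_V = Mod(x$coefficients),
                   phase_deg = Arg(x$coefficients) * 180 / pi))
  invisible(x)
}

#' Clip a field to the two-level power mask
#'
#' Tumor voxels with |E|^2 below `thlow` are rescaled (pure magnitude
#' scaling, per-component phases preserved) up to the floor; healthy voxels
#' (outer healthy region only — the transition shell is never touched) with
#' |E|^2 above `thup` are rescaled down to the cap. A zero-magnitude tumor
#' voxel below the floor has no direction to scale along: it is left
#' unchanged but counted as out of mask.
#'
#' @param E a `total_field` sampled on the mask's partition.
#' @param mask a [power_mask()].
#' @return list with `field` (clipped `total_field`) and `out_of_mask`
#'   (number of voxels that violated the mask).
#' @export
clip_to_mask <- function(E, mask) {
  part <- mask$partition
  vals <- E$values
  mag2 <- vec_mag2(vals)
  tum <- which(part$tumor_mask[E$voxel_linear])
  hea <- which(part$healthy_mask[E$voxel_linear])

  low <- tum[mag2[tum] < mask$thlow]
  zero <- low[mag2[low] == 0]
  low_ok <- setdiff(low, zero)
  if (length(low_ok)) {
    scale <- sqrt(mask$thlow / mag2[low_ok])
    vals[low_ok, ] <- vals[low_ok, , drop = FALSE] * scale
  }
  high <- hea[mag2[hea] > mask$thup]
  if (length(high)) {
    scale <- sqrt(mask$thup / mag2[high])
    vals[high, ] <- vals[high, , drop = FALSE] * scale
  }
  out <- structure(list(values = vals, voxel_linear = E$voxel_linear,
                        grid = E$grid), class = "total_field")
  list(field = out, out_of_mask = length(low) + length(high))
}

#' Run the alternating projections optimization
#'
#' Alternates projection onto the realizable field space (the column space
#' of EN, via the cached pseudo-inverse) with projection toward the
#' mask-feasible set (two-level magnitude clipping), re-normalizing the
#' excitation to the fixed input power after every projection. HTQ is
#' evaluated on each reconstructed — physically realizable — field, and the
#' excitation achieving the minimum recorded HTQ is returned (not
#' necessarily the last iterate). Deterministic: a pure function of its
#' inputs.
#'
#' Stopping: mask fixed point (no voxel clipped and the field unchanged),
#' HTQ plateau, persistent growth of the out-of-mask count, or `max_iter`.
#'
#' @param EN a `field_matrix`.
#' @param target a `total_field` initial guess (e.g. the Gaussian target).
#' @param mask a [power_mask()].
#' @param phantom the `tissue_phantom` (for SAR weighting).
#' @param partition the `region_partition` (for HTQ); defaults to the mask's.
#' @param P0 total input power, W (default 1).
#' @param R0 reference input resistance, ohm (default 50).
#' @param stop a [stopping_config()].
#' @param convention phasor convention for SAR evaluation (default "peak").
#' @return object of class `apa_result`: `best_excitation`, `htq_trace`,
#'   `oom_trace`, `iterations_run`, `stop_reason`, `final_field`,
#'   `htq_initial`, `best_iteration`.
#' @export
run_apa <- function(EN, target, mask, phantom, partition = mask$partition,
                    P0 = 1, R0 = 50, stop = stopping_config(),
                    convention = "peak") {
  if (all(EN$values == 0)) stop_degenerate("all-zero field matrix")
  proj <- build_projector(EN)
  M <- EN$M
  pref <- if (match.arg(convention, c("peak", "rms")) == "peak") 0.5 else 1
  w <- pref * lookup_property(phantom, "sigma_S_per_m", EN$voxel_linear) /
    lookup_property(phantom, "rho_kg_per_m3", EN$voxel_linear)
  tum <- which(partition$tumor_mask[EN$voxel_linear])
  hea <- which((partition$healthy_mask | partition$transition_mask)[EN$voxel_linear])
  if (!length(tum) || !length(hea))
    stop_arg("partition has empty tumor or healthy set on the sampled voxels")
  n1 <- ceiling(0.01 * length(hea))
  htq_of <- function(v) {
    sar <- w * vec_mag2(unstack_field(v, M))
    tm <- mean(sar[tum])
    if (!is.finite(tm) || tm <= 0) return(NA_real_)
    hv <- sort(sar[hea], decreasing = TRUE, method = "radix")
    mean(hv[seq_len(n1)]) / tm
  }

  # initialization: project the target, fix the power, reconstruct
  b <- normalize_power(proj$coef(stack_field(target$values)), P0, R0)
  v <- as.vector(EN$values %*% b$coefficients)
  htq_initial <- htq_of(v)
  if (!is.finite(htq_initial))
    stop_degenerate("non-finite HTQ at initialization; aborting")

  htq_trace <- numeric(0)
  oom_trace <- integer(0)
  power_trace <- numeric(0)   # ||b||^2/(2 R0) per iterate; must equal P0
  best_htq <- Inf; best_b <- b; best_iter <- 0L
  best_since <- 0L; oom_rises <- 0L
  stop_reason <- "max_iter"

  for (it in seq_len(stop$max_iter)) {
    Ef <- structure(list(values = unstack_field(v, M),
                         voxel_linear = EN$voxel_linear, grid = EN$grid),
                    class = "total_field")
    cl <- clip_to_mask(Ef, mask)
    b <- normalize_power(proj$coef(stack_field(cl$field$values)), P0, R0)
    v_new <- as.vector(EN$values %*% b$coefficients)
    htq <- htq_of(v_new)
    if (!is.finite(htq)) stop_degenerate("non-finite HTQ at iteration ", it)
    htq_trace[it] <- htq
    oom_trace[it] <- cl$out_of_mask
    power_trace[it] <- sum(Mod(b$coefficients)^2) / (2 * R0)

    if (htq < best_htq * (1 - stop$plateau_tol)) {
      best_since <- 0L
    } else {
      best_since <- best_since + 1L
    }
    if (htq < best_htq) {
      best_htq <- htq; best_b <- b; best_iter <- it
    }
    if (it > 1L && oom_trace[it] > oom_trace[it - 1L]) {
      oom_rises <- oom_rises + 1L
    } else {
      oom_rises <- 0L
    }

    delta <- sqrt(sum(Mod(v_new - v)^2)) / sqrt(sum(Mod(v)^2))
    v <- v_new
    if (cl$out_of_mask == 0L && delta < 1e-12) {
      stop_reason <- "fixed_point"; break
    }
    if (best_since >= stop$plateau_window) {
      stop_reason <- "plateau"; break
    }
    if (oom_rises >= stop$oom_persistence) {
      stop_reason <- "oom_increase"; break
    }
  }

  vf <- as.vector(EN$values %*% best_b$coefficients)
  structure(list(best_excitation = best_b,
                 htq_trace = htq_trace, oom_trace = oom_trace,
                 power_trace = power_trace,
                 iterations_run = length(htq_trace),
                 stop_reason = stop_reason,
                 final_field = structure(list(values = unstack_field(vf, M),
                                              voxel_linear = EN$voxel_linear,
                                              grid = EN$grid),
                                         class = "total_field"),
                 htq_initial = htq_initial,
                 best_iteration = best_iter,
                 best_htq = best_htq),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf(
    "apa_result: %d iterations (%s), HTQ %0.4f -> %0.4f (best at iter %d)\n",
    x$iterations_run, x$stop_reason, x$htq_initial, x$best_htq,
    x$best_iteration))
  invisible(x)
}
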