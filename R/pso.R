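#' Particle swarm configuration
#'
#' Standard constriction-style global-best PSO over 2N real parameters
#' (per-antenna amplitude and phase). Hyperparameter defaults are the usual
#' constriction values (inertia 0.729, cognitive = social = 1.49445); the
#' swarm size default follows common SAR-optimization practice.
#'
#' @param swarm_size particles (>= 2, default 100).
#' @param max_iter iteration cap (default 200).
#' @param inertia,cognitive,social velocity-update coefficients.
#' @param seed RNG seed recorded in all outputs.
#' @param amax amplitude upper bound (arbitrary: the objective is
#'   scale-invariant after power normalization).
#' @param plateau_window,plateau_tol stop after this many iterations without
#'   relative improvement above the tolerance (mirrors the APA constants).
#' @return object of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 100L, max_iter = 200L, inertia = 0.729,
                       cognitive = 1.49445, social = 1.49445, seed = 1L,
                       amax = 1, plateau_window = 50L, plateau_tol = 1e-4) {
  if (swarm_size < 2L) stop_arg("swarm_size must be >= 2")
  if (inertia <= 0 || cognitive <= 0 || social <= 0)
    stop_arg("PSO coefficients must be positive")
  structure(list(swarm_size = as.integer(swarm_size),
                 max_iter = as.integer(max_iter), inertia = inertia,
                 cognitive = cognitive, social = social,
                 seed = as.integer(seed), amax = amax,
                 plateau_window = as.integer(plateau_window),
                 plateau_tol = plateau_tol),
            class = "pso_config")
}

#' Global-best PSO minimizing HTQ over antenna excitations
#'
#' Benchmark comparator: each particle encodes N amplitudes in [0, amax]
#' (reflective bounds) and N phases in [0, 360) degrees (wrapped), is
#' power-normalized before evaluation (so the objective is scale-invariant
#' by construction), and is scored by HTQ of the resulting SAR map.
#' Fully reproducible from the seed.
#'
#' @param EN a `field_matrix`.
#' @param partition a `region_partition`.
#' @param phantom the `tissue_phantom`.
#' @param P0,R0 power normalization constants.
#' @param cfg a [pso_config()].
#' @param convention phasor convention for SAR (default "peak").
#' @return object of class `pso_result`: `best_excitation`,
#'   `best_htq_trace` (non-increasing), `iterations_run`, `seed`.
#' @export
run_pso <- function(EN, partition, phantom, P0 = 1, R0 = 50,
                    cfg = pso_config(), convention = "peak") {
  N <- EN$N; M <- EN$M
  pref <- if (match.arg(convention, c("peak", "rms")) == "peak") 0.5 else 1
  w <- pref * lookup_property(phantom, "sigma_S_per_m", EN$voxel_linear) /
    lookup_property(phantom, "rho_kg_per_m3", EN$voxel_linear)
  tum <- which(partition$tumor_mask[EN$voxel_linear])
  hea <- which((partition$healthy_mask | partition$transition_mask)[EN$voxel_linear])
  n1 <- ceiling(0.01 * length(hea))
  objective <- function(x) {
    b <- x[1:N] * exp(1i * x[(N + 1):(2 * N)] * pi / 180)
    if (all(Mod(b) == 0)) return(Inf)
    b <- normalize_power(b, P0, R0)$coefficients
    sar <- w * vec_mag2(unstack_field(as.vector(EN$values %*% b), M))
    tm <- mean(sar[tum])
    if (!is.finite(tm) || tm <= 0) return(Inf)
    hv <- sort(sar[hea], decreasing = TRUE, method = "radix")
    mean(hv[seq_len(n1)]) / tm
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  S <- cfg$swarm_size; D <- 2L * N
  lo <- c(rep(0, N), rep(0, N))
  hi <- c(rep(cfg$amax, N), rep(360, N))
  pos <- matrix(stats::runif(S * D, lo, hi), nrow = S, ncol = D, byrow = TRUE)
  vel <- matrix(stats::runif(S * D, -(hi - lo), hi - lo) * 0.1,
                nrow = S, ncol = D, byrow = TRUE)
  fit <- apply(pos, 1L, objective)
  if (all(!is.finite(fit)))
    stop_degenerate("non-finite objective for every initial particle")
  pbest <- pos; pbest_fit <- fit
  g <- which.min(fit)
  gbest <- pos[g, ]; gbest_fit <- fit[g]

  trace <- numeric(0)
  power_trace <- numeric(0)   # input power of the normalized gbest per iter
  stagnant <- 0L
  for (it in seq_len(cfg$max_iter)) {
    r1 <- matrix(stats::runif(S * D), S, D)
    r2 <- matrix(stats::runif(S * D), S, D)
    vel <- cfg$inertia * vel +
      cfg$cognitive * r1 * (pbest - pos) +
      cfg$social * r2 * (sweep(pos, 2L, gbest, function(p, g) g - p))
    pos <- pos + vel
    # amplitudes reflect at bounds, phases wrap modulo 360
    amp <- pos[, 1:N, drop = FALSE]
    amp <- abs(amp)
    over <- amp > cfg$amax
    amp[over] <- 2 * cfg$amax - amp[over]
    amp[amp < 0] <- 0 # after double reflection on wild steps
    vel[, 1:N][over | pos[, 1:N, drop = FALSE] < 0] <-
      -vel[, 1:N][over | pos[, 1:N, drop = FALSE] < 0]
    pos[, 1:N] <- amp
    pos[, (N + 1):D] <- pos[, (N + 1):D, drop = FALSE] %% 360

    fit <- apply(pos, 1L, objective)
    improved <- fit < pbest_fit
    pbest[improved, ] <- pos[improved, , drop = FALSE]
    pbest_fit[improved] <- fit[improved]
    g <- which.min(pbest_fit)
    if (pbest_fit[g] < gbest_fit * (1 - cfg$plateau_tol)) stagnant <- 0L
    else stagnant <- stagnant + 1L
    if (pbest_fit[g] < gbest_fit) {
      gbest_fit <- pbest_fit[g]; gbest <- pbest[g, ]
    }
    trace[it] <- gbest_fit
    gb <- normalize_power(gbest[1:N] * exp(1i * gbest[(N + 1):D] * pi / 180),
                          P0, R0)
    power_trace[it] <- sum(Mod(gb$coefficients)^2) / (2 * R0)
    if (stagnant >= cfg$plateau_window) break
  }

  b <- normalize_power(gbest[1:N] * exp(1i * gbest[(N + 1):D] * pi / 180),
                       P0, R0)
  structure(list(best_excitation = b, best_htq_trace = trace,
                 power_trace = power_trace,
                 best_htq = gbest_fit, iterations_run = length(trace),
                 seed = cfg$seed),
            class = "pso_result")
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("pso_result: %d iterations, best HTQ %0.4f (seed %d)\n",
              x$iterations_run, x$best_htq, x$seed))
  invisible(x)
}
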