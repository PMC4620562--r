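#' Sampling protocol for FEP umbrella sampling
#'
#' Bundles the integrator and schedule parameters. Defaults: 21 evenly spaced
#' mapping windows on `[0, 1]`, Langevin (BAOAB) dynamics with `dt = 0.01`
#' internal time units and unit friction, a 5-stage heating schedule from 1 K
#' to the target temperature with a harmonic solute restraint decaying from
#' 10 to 0 kcal mol^-1 A^-2, 10,000 unrestrained equilibration steps, and
#' per-window equilibration before sampling. The sampling length per window
#' is sized so that the replicate-to-replicate scatter of barrier estimates
#' supports entropy extraction from a 290-310 K scan (see the methods
#' vignette for the error budget).
#'
#' The stability condition `dt * omega_max < 0.5` for the stiffest mode is
#' checked when the protocol is applied to a system.
#'
#' @param n_windows number of FEP windows (>= 2).
#' @param steps_equil_per_window discarded steps at the start of each window.
#' @param steps_sample_per_window recorded sampling steps per window.
#' @param dt time step, internal units.
#' @param friction Langevin friction, 1/time.
#' @param stride record one sample every `stride` steps.
#' @param heating_stages number of heating stages (1 K up to target T).
#' @param steps_per_heating_stage steps per heating stage.
#' @param steps_final_equil unrestrained equilibration steps after heating.
#' @param restraint_k_initial initial solute restraint stiffness,
#'   kcal mol^-1 A^-2, decaying linearly to 0 across the heating stages.
#' @return object of class `"sampling_protocol"`.
#' @export
sampling_protocol <- function(n_windows = 21L,
                              steps_equil_per_window = 2000L,
                              steps_sample_per_window = 150000L,
                              dt = 0.01, friction = 1.0, stride = 10L,
                              heating_stages = 5L,
                              steps_per_heating_stage = 2000L,
                              steps_final_equil = 10000L,
                              restraint_k_initial = 10) {
  n_windows <- as.integer(n_windows)
  if (n_windows < 2L) stop("`n_windows` must be >= 2", call. = FALSE)
  stopifnot(dt > 0, friction > 0, stride >= 1L,
            steps_sample_per_window >= stride)
  structure(list(n_windows = n_windows,
                 steps_equil_per_window = as.integer(steps_equil_per_window),
                 steps_sample_per_window = as.integer(steps_sample_per_window),
                 dt = dt, friction = friction, stride = as.integer(stride),
                 heating_stages = as.integer(heating_stages),
                 steps_per_heating_stage = as.integer(steps_per_heating_stage),
                 steps_final_equil = as.integer(steps_final_equil),
                 restraint_k_initial = restraint_k_initial),
            class = "sampling_protocol")
}

# Flatten an evb_system for the compiled kernel.
.sys_to_kernel <- function(system) {
  s1 <- system$states[[1]]; s2 <- system$states[[2]]
  list(k1 = s1$k_solute, x1 = s1$x0, a1 = s1$alpha,
       k2 = s2$k_solute, x2 = s2$x0, a2 = s2$alpha,
       h12 = system$h12, n_bath = system$n_bath,
       k_bath_ref = system$bath$k_ref,
       bath_delta = as.numeric(system$bath$delta),
       bath_center = as.numeric(system$bath$center),
       bath_width = as.numeric(system$bath$width),
       masses = as.numeric(system$masses))
}

# dt * omega_max < 0.5 for the stiffest curvature present anywhere.
.check_stability <- function(system, protocol) {
  x <- seq(system$domain[1], system$domain[2], length.out = 512L)
  k_max <- max(system$states[[1]]$k_solute, system$states[[2]]$k_solute)
  if (system$n_bath > 0) k_max <- max(k_max, bath_stiffness(system, x))
  omega <- sqrt(k_max / min(system$masses))
  if (protocol$dt * omega >= 0.5) {
    stop("unstable protocol: dt * omega_max = ",
         signif(protocol$dt * omega, 3), " >= 0.5; reduce dt", call. = FALSE)
  }
  invisible(TRUE)
}

#' Maxwell-Boltzmann velocity initialization
#'
#' Draws one velocity per coordinate from the Maxwell distribution at the
#' given temperature: each component Gaussian with variance `kB * T / m`.
#' Deterministic given `seed` (an internal counter-hashed stream; R's global
#' RNG state is untouched).
#'
#' @param masses positive masses, internal units.
#' @param temperature K, > 0.
#' @param seed integer seed.
#' @return numeric vector of velocities.
#' @export
initialize_velocities <- function(masses, temperature, seed = 1L) {
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  .maxwell_kernel(as.numeric(masses), temperature, as.integer(seed), 0L, 0L, 0L)
}

#' Equilibrate a replicate at a target temperature
#'
#' Emulates stepwise heating: the system starts at the reactant-state
#' minimum with Maxwell velocities at 1 K, is heated over
#' `heating_stages` geometrically spaced temperatures up to the target while
#' a harmonic solute restraint decays linearly from `restraint_k_initial` to
#' 0, and finally runs `steps_final_equil` unrestrained steps at the target
#' temperature on the first mapping window (`lambda = 0`). Replicates differ
#' only through their derived random streams: the per-replicate seed is a
#' fixed hash of `(seed, replicate_id, temperature, stage)`.
#'
#' @param system an [evb_system()].
#' @param protocol a [sampling_protocol()].
#' @param temperature target temperature, K.
#' @param replicate_id integer replicate label.
#' @param seed master seed.
#' @return numeric state vector `c(positions, velocities)` of length
#'   `2 * (1 + n_bath)`.
#' @export
equilibrate <- function(system, protocol, temperature, replicate_id = 1L,
                        seed = 1L) {
  .check_stability(system, protocol)
  ks <- .sys_to_kernel(system)
  nd <- 1L + system$n_bath
  x0 <- system$states[[1]]$x0
  temps <- exp(seq(log(1), log(temperature),
                   length.out = protocol$heating_stages))
  restraints <- seq(protocol$restraint_k_initial, 0,
                    length.out = protocol$heating_stages)
  state <- c(x0, rep(0, system$n_bath),
             .maxwell_kernel(as.numeric(system$masses), temps[1],
                             as.integer(seed), as.integer(replicate_id),
                             as.integer(temperature * 1000), -1L))
  for (stage in seq_len(protocol$heating_stages)) {
    out <- .langevin_kernel(ks, 0.0, temps[stage],
                            protocol$steps_per_heating_stage,
                            protocol$dt, protocol$friction, state,
                            restraints[stage], x0, protocol$stride, FALSE,
                            as.integer(seed), as.integer(replicate_id),
                            -stage, 0L)
    state <- out$state
  }
  out <- .langevin_kernel(ks, 0.0, temperature, protocol$steps_final_equil,
                          protocol$dt, protocol$friction, state,
                          0, x0, protocol$stride, FALSE,
                          as.integer(seed), as.integer(replicate_id),
                          -(protocol$heating_stages + 1L), 0L)
  out$state
}

#' Run the FEP umbrella-sampling windows of one replicate
#'
#' Samples every mapping potential
#' `eps_lambda = (1 - lambda) eps1 + lambda eps2` (+ bath) with Langevin
#' dynamics, windows run sequentially with the final configuration of window
#' m seeding window m+1. Each window discards `steps_equil_per_window` steps,
#' then records `(x, eps1, eps2, E_g, eps_lambda)` every `stride` steps.
#'
#' @inheritParams equilibrate
#' @param state starting configuration, usually from [equilibrate()].
#' @return list of `"window_samples"` objects (one per window), each with
#'   fields `lam`, `temperature`, `replicate_id`, `samples` (data frame with
#'   columns `x, eps1, eps2, e_ground, e_map`) and `seed_used`.
#' @export
run_fep_windows <- function(system, protocol, temperature, replicate_id = 1L,
                            seed = 1L, state = NULL) {
  .check_stability(system, protocol)
  ks <- .sys_to_kernel(system)
  if (is.null(state)) {
    state <- equilibrate(system, protocol, temperature, replicate_id, seed)
  }
  lams <- seq(0, 1, length.out = protocol$n_windows)
  x0 <- system$states[[1]]$x0
  out <- vector("list", protocol$n_windows)
  for (m in seq_along(lams)) {
    if (protocol$steps_equil_per_window > 0L) {
      eq <- .langevin_kernel(ks, lams[m], temperature,
                             protocol$steps_equil_per_window,
                             protocol$dt, protocol$friction, state,
                             0, x0, protocol$stride, FALSE,
                             as.integer(seed), as.integer(replicate_id),
                             m, 1L)
      state <- eq$state
    }
    run <- .langevin_kernel(ks, lams[m], temperature,
                            protocol$steps_sample_per_window,
                            protocol$dt, protocol$friction, state,
                            0, x0, protocol$stride, TRUE,
                            as.integer(seed), as.integer(replicate_id),
                            m, 2L)
    state <- run$state
    sm <- run$samples
    colnames(sm) <- c("x", "eps1", "eps2", "e_ground", "e_map")
    out[[m]] <- structure(list(lam = lams[m], temperature = temperature,
                               replicate_id = as.integer(replicate_id),
                               samples = as.data.frame(sm),
                               seed_used = .derive_stream_seed(
                                 as.integer(seed), as.integer(replicate_id),
                                 temperature, m, 2L)),
                          class = "window_samples")
  }
  out
}

# Quadrature marginal density of x under mapping potential lambda (bath
# integrated out analytically): p(x) proportional to
# exp(-beta * eps_lambda(x)) * k(x)^(-n_bath/2). Used by the Boltzmann
# fidelity tests.
window_marginal <- function(system, lam, temperature, grid_size = 4001L) {
  x <- seq(system$domain[1], system$domain[2], length.out = grid_size)
  e1 <- diabatic_energy(system$states[[1]], x)
  e2 <- diabatic_energy(system$states[[2]], x)
  u <- mapping_potential(e1, e2, lam)
  beta <- 1 / (KB * temperature)
  lw <- -beta * u
  if (system$n_bath > 0) {
    lw <- lw - (system$n_bath / 2) * log(bath_stiffness(system, x))
  }
  w <- exp(lw - max(lw))
  dx <- x[2] - x[1]
  dens <- w / (sum(w) * dx)
  cdf <- cumsum(w) / sum(w)
  list(x = x, density = dens, cdf = stats::approxfun(x, cdf, yleft = 0, yright = 1))
}
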