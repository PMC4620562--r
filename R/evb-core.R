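#' Two-state empirical valence bond (EVB) energy model
#'
#' An EVB system couples two diabatic states -- fixed-bonding-pattern potential
#' energy surfaces for a one-dimensional solute coordinate `x` -- through a
#' constant off-diagonal coupling `h12`. The adiabatic ground state is the
#' lowest eigenvalue of the 2x2 state Hamiltonian. A set of `n_bath` harmonic
#' bath modes with solute-coordinate-dependent stiffness `k(x)` (shared by both
#' states) supplies the configurational entropy of the surrounding environment.
#'
#' Each diabatic state is a harmonic well `0.5 * k_solute * (x - x0)^2 + alpha`,
#' where `alpha` is the gas-phase shift calibrated so the model reproduces
#' target free energies (see [calibrate()]). Equal well stiffness makes the
#' energy-gap reaction coordinate `X(x) = eps1(x) - eps2(x)` exactly linear in
#' `x`, hence strictly monotone with a constant Jacobian.
#'
#' @param k_solute harmonic stiffness of the well (kcal mol^-1 A^-2, > 0).
#' @param x0 position of the well minimum (Angstrom).
#' @param alpha gas-phase shift added to this state's energy (kcal/mol).
#' @return `diabatic_surface()` returns an object of class `"diabatic_surface"`.
#' @seealso [evb_system()], [ground_state_energy()]
#' @export
diabatic_surface <- function(k_solute, x0, alpha = 0) {
  .assert_finite(k_solute, "k_solute")
  .assert_finite(x0, "x0")
  .assert_finite(alpha, "alpha")
  if (k_solute <= 0) stop("`k_solute` must be > 0", call. = FALSE)
  structure(list(k_solute = k_solute, x0 = x0, alpha = alpha),
            class = "diabatic_surface")
}

#' @param x solute coordinate(s), Angstrom.
#' @param surface a `"diabatic_surface"` object.
#' @rdname diabatic_surface
#' @export
diabatic_energy <- function(surface, x) {
  0.5 * surface$k_solute * (x - surface$x0)^2 + surface$alpha
}

diabatic_gradient <- function(surface, x) {
  surface$k_solute * (x - surface$x0)
}

#' Construct a two-state EVB system with a harmonic bath
#'
#' @param state1,state2 [diabatic_surface()] objects for the reactant-like and
#'   product-like states.
#' @param h12 constant off-diagonal coupling, kcal/mol, must be >= 0.
#' @param n_bath number of harmonic bath modes (integer >= 0).
#' @param bath list describing the bath stiffness profile
#'   `log k(x) = log(k_ref) + sum_j delta_j * s((x - c_j) / w_j)` with
#'   `s(u) = (1 + tanh(u)) / 2`; fields `k_ref` (kcal mol^-1 A^-2),
#'   `delta`, `center`, `width` (equal-length numeric vectors, possibly empty).
#'   `k(x) > 0` everywhere by construction.
#' @param domain length-2 numeric, solute-coordinate bounds used for sampling
#'   and quadrature.
#' @param masses per-coordinate masses (length `1 + n_bath`), internal units.
#' @return an object of class `"evb_system"`.
#' @export
evb_system <- function(state1, state2, h12, n_bath = 0L,
                       bath = list(k_ref = 40, delta = numeric(0),
                                   center = numeric(0), width = numeric(0)),
                       domain = NULL, masses = NULL) {
  stopifnot(inherits(state1, "diabatic_surface"),
            inherits(state2, "diabatic_surface"))
  .assert_finite(h12, "h12")
  if (h12 < 0) stop("`h12` must be >= 0", call. = FALSE)
  n_bath <- as.integer(n_bath)
  if (n_bath < 0) stop("`n_bath` must be >= 0", call. = FALSE)
  if (bath$k_ref <= 0) stop("bath `k_ref` must be > 0", call. = FALSE)
  nb <- length(bath$delta)
  if (length(bath$center) != nb || length(bath$width) != nb) {
    stop("bath `delta`, `center`, `width` must have equal length", call. = FALSE)
  }
  if (nb > 0 && any(bath$width <= 0)) stop("bath `width` must be > 0", call. = FALSE)
  if (is.null(domain)) {
    pad <- 1.5
    domain <- range(state1$x0, state2$x0) + c(-pad, pad)
  }
  if (is.null(masses)) masses <- rep(1, 1L + n_bath)
  if (length(masses) != 1L + n_bath || any(masses <= 0)) {
    stop("`masses` must be length 1 + n_bath and positive", call. = FALSE)
  }
  structure(list(states = list(state1, state2), h12 = h12, n_bath = n_bath,
                 bath = bath, domain = as.numeric(domain), masses = masses),
            class = "evb_system")
}

#' @export
print.evb_system <- function(x, ...) {
  cat("Two-state EVB system\n")
  for (i in 1:2) {
    s <- x$states[[i]]
    cat(sprintf("  state %d: k = %.4g kcal/mol/A^2, x0 = %.4g A, alpha = %.6g kcal/mol\n",
                i, s$k_solute, s$x0, s$alpha))
  }
  cat(sprintf("  H12 = %.6g kcal/mol, n_bath = %d, bath k_ref = %.4g\n",
              x$h12, x$n_bath, x$bath$k_ref))
  cat(sprintf("  domain: [%.3g, %.3g] A\n", x$domain[1], x$domain[2]))
  invisible(x)
}

#' EVB ground-state energy
#'
#' Lowest eigenvalue of the 2x2 EVB Hamiltonian:
#' `E_g = (eps1 + eps2)/2 - sqrt((eps1 - eps2)^2 + 4 h12^2)/2`.
#' Symmetric under swapping `eps1`/`eps2`; equals `min(eps1, eps2)` when
#' `h12 = 0` and `eps - h12` when the states are degenerate.
#'
#' @param eps1,eps2 diabatic energies, kcal/mol (vectorized).
#' @param h12 coupling, kcal/mol, >= 0.
#' @return ground-state energy, kcal/mol.
#' @export
ground_state_energy <- function(eps1, eps2, h12) {
  .assert_finite(eps1, "eps1"); .assert_finite(eps2, "eps2")
  .assert_finite(h12, "h12")
  if (any(h12 < 0)) stop("`h12` must be >= 0", call. = FALSE)
  0.5 * (eps1 + eps2) - 0.5 * sqrt((eps1 - eps2)^2 + 4 * h12^2)
}

# Mixing weights (w1, w2) from the ground-state eigenvector:
# w1 = dE_g/deps1, w2 = dE_g/deps2, w1 + w2 = 1.
ground_state_weights <- function(eps1, eps2, h12) {
  d <- eps1 - eps2
  r <- sqrt(d^2 + 4 * h12^2)
  w1 <- if (all(r == 0)) rep(0.5, length(d)) else 0.5 - 0.5 * ifelse(r == 0, 0, d / r)
  cbind(w1 = w1, w2 = 1 - w1)
}

#' Solute force on the EVB ground-state surface
#'
#' Hellmann-Feynman gradient of [ground_state_energy()]:
#' `F = -(w1 * deps1/dx + w2 * deps2/dx)` with the mixing weights derived from
#' the ground-state eigenvector. Bath modes do not contribute to the
#' ground-state solute force beyond the stiffness-profile term, which is
#' handled by the sampler; this function reports the solute (electronic)
#' component only.
#'
#' @param system an [evb_system()].
#' @param x solute coordinate(s), Angstrom, within the system domain.
#' @return force along x, kcal mol^-1 A^-1 (vectorized over `x`).
#' @export
ground_state_force <- function(system, x) {
  .assert_finite(x, "x")
  e1 <- diabatic_energy(system$states[[1]], x)
  e2 <- diabatic_energy(system$states[[2]], x)
  w <- ground_state_weights(e1, e2, system$h12)
  g1 <- diabatic_gradient(system$states[[1]], x)
  g2 <- diabatic_gradient(system$states[[2]], x)
  unname(-(w[, "w1"] * g1 + w[, "w2"] * g2))
}

#' FEP mapping potential
#'
#' The mapping potential `eps_lambda = (1 - lambda) * eps1 + lambda * eps2`
#' drives the system between the two EVB states during free energy
#' perturbation umbrella sampling.
#'
#' @param eps1,eps2 diabatic energies, kcal/mol.
#' @param lam mapping parameter in `[0, 1]`.
#' @return mapping-potential energy, kcal/mol.
#' @export
mapping_potential <- function(eps1, eps2, lam) {
  .assert_finite(lam, "lam")
  if (any(lam < 0 | lam > 1)) {
    stop("`lam` must lie in [0, 1], got ", lam[which(lam < 0 | lam > 1)[1]],
         call. = FALSE)
  }
  (1 - lam) * eps1 + lam * eps2
}

#' Energy-gap reaction coordinate
#'
#' `X(x) = eps1(x) - eps2(x)`, the generalized reaction coordinate along which
#' EVB free-energy profiles are binned. `gap_jacobian()` returns `dX/dx`
#' (constant for equal-stiffness diabats).
#'
#' @inheritParams ground_state_force
#' @return gap energy (kcal/mol) or its derivative (kcal mol^-1 A^-1).
#' @export
energy_gap <- function(system, x) {
  diabatic_energy(system$states[[1]], x) - diabatic_energy(system$states[[2]], x)
}

#' @rdname energy_gap
#' @export
gap_jacobian <- function(system, x) {
  diabatic_gradient(system$states[[1]], x) - diabatic_gradient(system$states[[2]], x)
}

#' Bath-mode stiffness profile k(x)
#'
#' Smooth, strictly positive stiffness shared by all bath modes:
#' `log k(x) = log(k_ref) + sum_j delta_j * (1 + tanh((x - c_j)/w_j))/2`.
#' The profile plateaus at the stationary points of the solute surface so the
#' bath contributes an exactly T-linear term to barrier and reaction free
#' energies (entropy `-(n_bath/2) * kB * log` of the stiffness ratio).
#'
#' @inheritParams ground_state_force
#' @return stiffness k(x) > 0, kcal mol^-1 A^-2 (vectorized).
#' @export
bath_stiffness <- function(system, x) {
  b <- system$bath
  lnk <- rep(log(b$k_ref), length(x))
  for (j in seq_along(b$delta)) {
    lnk <- lnk + b$delta[j] * 0.5 * (1 + tanh((x - b$center[j]) / b$width[j]))
  }
  exp(lnk)
}

# Total potential on the ground state at coords (x, y_1..y_nb): used for
# checks; dynamics run on mapping potentials inside the compiled kernel.
evb_total_energy <- function(system, x, y = numeric(0)) {
  e1 <- diabatic_energy(system$states[[1]], x)
  e2 <- diabatic_energy(system$states[[2]], x)
  eg <- ground_state_energy(e1, e2, system$h12)
  if (system$n_bath > 0 && length(y)) {
    eg <- eg + 0.5 * bath_stiffness(system, x) * sum(y^2)
  }
  eg
}
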