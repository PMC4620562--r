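#' Thermodynamic decomposition container
#'
#' Holds an enthalpy/entropy decomposition of a temperature-dependent free
#' energy, from either an Arrhenius fit (activation quantities) or a van't
#' Hoff fit (reaction quantities): `dG(T)/T = dH/T - dS`, so an ordinary
#' least-squares regression of `dG/T` on `1/T` has slope `dH` and intercept
#' `-dS`.
#'
#' @param dH enthalpy, kcal/mol.
#' @param dS entropy, kcal mol^-1 K^-1.
#' @param T_ref reference temperature, K.
#' @param r_squared regression R^2 (NA for exact decompositions).
#' @param rms_residual_eu rms of regression residuals expressed in entropy
#'   units (1 e.u. = 1 cal mol^-1 K^-1).
#' @param covariance 2x2 parameter covariance matrix (dH, dS).
#' @param kind_label `"arrhenius"` (activation) or `"vant_hoff"` (reaction).
#' @return object of class `"thermo_decomposition"`; field `TdS_at_ref` is
#'   always exactly `T_ref * dS`.
#' @export
thermo_decomposition <- function(dH, dS, T_ref = 298,
                                 r_squared = NA_real_,
                                 rms_residual_eu = NA_real_,
                                 covariance = matrix(NA_real_, 2, 2),
                                 kind_label = c("arrhenius", "vant_hoff")) {
  kind_label <- match.arg(kind_label)
  structure(list(dH = dH, dS = dS, TdS_at_ref = T_ref * dS, T_ref = T_ref,
                 r_squared = r_squared, rms_residual_eu = rms_residual_eu,
                 covariance = covariance, kind_label = kind_label),
            class = "thermo_decomposition")
}

#' @export
print.thermo_decomposition <- function(x, ...) {
  lab <- if (x$kind_label == "arrhenius") "activation" else "reaction"
  cat(sprintf("%s decomposition (%s fit):\n", lab, x$kind_label))
  cat(sprintf("  dH = %8.3f kcal/mol\n", x$dH))
  cat(sprintf("  dS = %8.5f kcal/mol/K  (T*dS = %+.3f kcal/mol at %.0f K, %.1f e.u.)\n",
              x$dS, x$TdS_at_ref, x$T_ref, entropy_to_eu(x$TdS_at_ref, x$T_ref)))
  if (!is.na(x$r_squared)) {
    cat(sprintf("  R^2 = %.3f, rms residual = %.2f e.u.\n",
                x$r_squared, x$rms_residual_eu))
  }
  invisible(x)
}

.thermo_fit <- function(points, T_ref, kind, weighted = FALSE) {
  points <- as.data.frame(points)
  need <- c("temperature", "dG")
  if (!all(need %in% names(points))) {
    stop("`points` needs columns `temperature` and `dG` (optionally `sem`)",
         call. = FALSE)
  }
  tt <- points$temperature
  if (length(unique(tt)) < 3L) {
    stop("need >= 3 distinct temperatures for a ", kind, " fit", call. = FALSE)
  }
  y <- points$dG / tt
  invT <- 1 / tt
  w <- if (weighted && !is.null(points$sem) && all(points$sem > 0)) {
    (tt / points$sem)^2
  } else NULL
  # noiseless inputs trigger lm's "essentially perfect fit" chatter
  fit <- suppressWarnings(stats::lm(y ~ invT, weights = w))
  co <- stats::coef(fit)
  dH <- unname(co["invT"])
  dS <- -unname(co["(Intercept)"])
  res <- stats::residuals(fit)            # units kcal/mol/K
  vc <- stats::vcov(fit)                  # (intercept, slope) = (-dS, dH)
  covariance <- matrix(c(vc[2, 2], -vc[2, 1], -vc[1, 2], vc[1, 1]), 2, 2,
                       dimnames = list(c("dH", "dS"), c("dH", "dS")))
  thermo_decomposition(
    dH = dH, dS = dS, T_ref = T_ref,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    rms_residual_eu = sqrt(mean(res^2)) * 1000,
    covariance = covariance, kind_label = kind)
}

#' Arrhenius fit: activation enthalpy and entropy from dG_act(T)
#'
#' Ordinary least squares of `dG_act/T` on `1/T` over at least three distinct
#' temperatures: the slope is the activation enthalpy `dH` and the intercept
#' is `-dS`. Reports `R^2`, the rms residual converted to entropy units, and
#' the (dH, dS) covariance. Unweighted by default; set `weighted = TRUE` for
#' inverse-variance weighting by the per-point s.e.m.
#'
#' @param points data frame with columns `temperature` (K), `dG` (kcal/mol,
#'   the per-temperature mean activation free energy) and optionally `sem`.
#' @param T_ref reference temperature for `TdS_at_ref`, K.
#' @param weighted logical; inverse-variance weights from `sem`.
#' @return a [thermo_decomposition()] with `kind_label = "arrhenius"`.
#' @export
arrhenius_fit <- function(points, T_ref = 298, weighted = FALSE) {
  .thermo_fit(points, T_ref, "arrhenius", weighted)
}

#' van't Hoff fit: reaction enthalpy and entropy from dG_rxn(T)
#'
#' Identical regression to [arrhenius_fit()] applied to the reaction free
#' energy, yielding the reaction enthalpy and entropy.
#'
#' @inheritParams arrhenius_fit
#' @return a [thermo_decomposition()] with `kind_label = "vant_hoff"`.
#' @export
vant_hoff_fit <- function(points, T_ref = 298, weighted = FALSE) {
  .thermo_fit(points, T_ref, "vant_hoff", weighted)
}

#' Convert a T*dS term to entropy units
#'
#' 1 e.u. = 1 cal mol^-1 K^-1; `entropy_to_eu(TdS, T) = 1000 * TdS / T`.
#' At 298 K, 1 e.u. corresponds to about 0.3 kcal/mol in `T*dS`.
#'
#' @param TdS entropy term T*dS, kcal/mol.
#' @param T temperature, K, > 0.
#' @return entropy in cal mol^-1 K^-1.
#' @export
entropy_to_eu <- function(TdS, T) {
  stopifnot(all(T > 0))
  1000 * TdS / T
}

#' Eyring transition-state-theory rate from an activation free energy
#'
#' `k = (kB*T/h) * exp(-dG_act / (R*T))`, with the prefactor computed from
#' CODATA constants (6.25e12 s^-1 at 300 K). For a bimolecular barrier quoted
#' at a concentration standard state the returned rate is in M^-1 s^-1.
#'
#' @param dG_act activation free energy, kcal/mol.
#' @param T temperature, K, > 0.
#' @return rate constant, s^-1 (or M^-1 s^-1).
#' @seealso [dG_from_rate()], [convert_standard_state()]
#' @export
eyring_rate <- function(dG_act, T) {
  stopifnot(all(T > 0))
  KB_OVER_H * T * exp(-dG_act / (KB * T))
}

#' @param rate rate constant, s^-1 (or M^-1 s^-1), > 0.
#' @rdname eyring_rate
#' @export
dG_from_rate <- function(rate, T) {
  stopifnot(all(T > 0), all(rate > 0))
  -KB * T * log(rate / (KB_OVER_H * T))
}

#' Standard-state conversion of a bimolecular barrier
#'
#' `dG_to = dG_from - R*T*log(c_to / c_from)`: raising the standard-state
#' concentration of the attacking species lowers the association barrier.
#' E.g. 17.5 kcal/mol at 1 M becomes 17.5 - RT*ln(55) = 15.1 kcal/mol at the
#' 55 M water standard state (298 K).
#'
#' @param dG free energy, kcal/mol.
#' @param c_from,c_to standard-state concentrations, M, > 0.
#' @param T temperature, K.
#' @return converted free energy, kcal/mol.
#' @export
convert_standard_state <- function(dG, c_from, c_to, T = 298) {
  stopifnot(all(c_from > 0), all(c_to > 0), all(T > 0))
  dG - KB * T * log(c_to / c_from)
}

#' Combine a pre-equilibrium step with a subsequent activation step
#'
#' For a stepwise mechanism whose first step is a fast pre-equilibrium
#' (reaction decomposition, van't Hoff) followed by the rate-limiting attack
#' (activation decomposition, Arrhenius), the overall activation parameters
#' add: `dH_overall = dH0_pre + dH_act`, `dS_overall = dS0_pre + dS_act`.
#' Covariances add under independence of the two fits.
#'
#' @param pre a [thermo_decomposition()] with `kind_label = "vant_hoff"`.
#' @param attack a [thermo_decomposition()] with `kind_label = "arrhenius"`.
#' @return a [thermo_decomposition()] (`kind_label = "arrhenius"`) at the
#'   common `T_ref`.
#' @export
combine_stepwise <- function(pre, attack) {
  stopifnot(inherits(pre, "thermo_decomposition"),
            inherits(attack, "thermo_decomposition"))
  if (pre$kind_label != "vant_hoff" || attack$kind_label != "arrhenius") {
    stop("`pre` must be a van't Hoff (reaction) and `attack` an Arrhenius ",
         "(activation) decomposition", call. = FALSE)
  }
  if (!isTRUE(all.equal(pre$T_ref, attack$T_ref))) {
    stop("mismatched T_ref: ", pre$T_ref, " vs ", attack$T_ref, call. = FALSE)
  }
  covar <- if (all(is.finite(pre$covariance)) && all(is.finite(attack$covariance))) {
    pre$covariance + attack$covariance
  } else matrix(NA_real_, 2, 2)
  r2 <- suppressWarnings(min(pre$r_squared, attack$r_squared, na.rm = TRUE))
  thermo_decomposition(
    dH = pre$dH + attack$dH, dS = pre$dS + attack$dS, T_ref = attack$T_ref,
    r_squared = if (is.finite(r2)) r2 else NA_real_,
    rms_residual_eu = sqrt(sum(c(pre$rms_residual_eu, attack$rms_residual_eu)^2)),
    covariance = covar, kind_label = "arrhenius")
}

#' Plot-ready Arrhenius table
#'
#' Returns the `(1/T, dG/T)` pairs together with the fitted line, the form in
#' which Arrhenius and van't Hoff plots are drawn.
#'
#' @param points as in [arrhenius_fit()].
#' @param decomposition the fitted [thermo_decomposition()].
#' @return data frame with columns `inv_T`, `dG_over_T`, `fitted`.
#' @export
arrhenius_table <- function(points, decomposition) {
  points <- as.data.frame(points)
  invT <- 1 / points$temperature
  data.frame(inv_T = invT,
             dG_over_T = points$dG / points$temperature,
             fitted = decomposition$dH * invT - decomposition$dS)
}
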