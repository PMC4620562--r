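---
title: "Computational Arrhenius plots for EVB free-energy profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational Arrhenius plots for EVB free-energy profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Enzymatic rate enhancements are free-energy effects, but their *origin* —
enthalpic stabilization versus entropic release — is only visible in the
temperature dependence of the activation free energy. For a reaction step
with barrier $\Delta G^{\ddagger}(T)$, plotting
$\Delta G^{\ddagger}/T$ against $1/T$ gives a straight line whenever the
decomposition $\Delta G^{\ddagger} = \Delta H^{\ddagger} - T\Delta
S^{\ddagger}$ holds with temperature-independent $\Delta H^{\ddagger}$ and
$\Delta S^{\ddagger}$: the slope is $\Delta H^{\ddagger}$ and the intercept
$-\Delta S^{\ddagger}$. The same construction applied to a reaction free
energy $\Delta G^{0}(T)$ (a van't Hoff plot) yields $\Delta H^{0}$ and
$\Delta S^{0}$. GTP hydrolysis on the ribosome is the motivating system:
its stepwise mechanism — proton transfer from the catalytic water to the
$\gamma$-phosphate, then hydroxide attack on the protonated phosphate — is
driven by an unusually large, *positive* activation entropy, in contrast to
the near-zero activation entropies of the uncatalyzed associative and
dissociative pathways in water.

`evbtherm` implements this methodology at desk scale. Free-energy profiles
are computed with the empirical valence bond (EVB) method driven by free
energy perturbation (FEP) umbrella sampling on the energy-gap coordinate,
replicated over a temperature scan (290–310 K in 5 K steps, 15 replicates
per temperature by default), and regressed to enthalpy/entropy
decompositions. Instead of atomistic simulation systems, the package ships
low-dimensional *surrogate* systems — one solute coordinate plus a harmonic
bath — whose exact thermodynamics are available by quadrature, so that every
decomposition becomes a parameter-recovery exercise with a known ground
truth.

## The EVB model and the surrogate systems

A reaction step is a two-state EVB system: diabatic surfaces
$\varepsilon_1(x)$, $\varepsilon_2(x)$ mixed by a constant coupling
$H_{12}$, with ground state

$$E_g = \tfrac{1}{2}(\varepsilon_1+\varepsilon_2) -
\tfrac{1}{2}\sqrt{(\varepsilon_1-\varepsilon_2)^2 + 4H_{12}^2}.$$

Profiles are binned on the energy-gap reaction coordinate
$X = \varepsilon_1 - \varepsilon_2$. The diabats are displaced harmonic
wells of *equal* stiffness; this is a deliberate design choice rather than
a limitation: it makes $X(x)$ exactly linear in $x$, hence strictly
monotone with a constant Jacobian, so the gap-space and $x$-space barriers
coincide exactly and the quadrature oracle needs no numerical Jacobian
control. The second diabat carries a gas-phase shift $\alpha$, the standard
EVB calibration parameter.

Entropy enters through $n_{\mathrm{bath}}$ harmonic bath modes (default 12)
sharing a stiffness $k(x)$ that depends only on the solute coordinate.
Because the bath is Gaussian at fixed $x$, it integrates analytically:

$$F(x;T) = E_g(x) + \frac{n_{\mathrm{bath}}}{2}\,k_BT\,
\ln\frac{\beta k(x)}{2\pi},$$

so a softer environment at the transition state ($k_{TS} < k_R$) produces a
positive activation entropy of order
$-\tfrac{n}{2}k_B \ln(k_{TS}/k_R)$ that is *exactly* linear in $T$. This is
the surrogate's abstraction of an active site whose dipolar environment
gains configurational freedom as charge delocalizes in the transition
state. With $n = 12$, the +7.3 kcal/mol entropy term of the ribosomal
hydroxide attack needs $\ln(k_R/k_{TS}) \approx 2$ per mode — a moderate,
numerically benign stiffness ratio.

$k(x)$ interpolates between its regional values through broad `tanh`
switches centered midway between the stationary points, with widths of a
third of the spacing. Early designs used narrow switches that plateaued
sharply at the stationary points; these made the naive entropy formula
exact but erected a nearly discontinuous bath free-energy wall that the
$\lambda$ umbrella cannot flatten (the mapping potential drives only the
solute gap), starving windows of overlap and biasing the FEP chain by
several tenths of a kcal/mol. The broad switches remove the wall; the small
stationary-point drift with temperature they introduce is absorbed exactly
by the construction below. For barrier-only fixtures the bath simply stays
soft past the barrier (no product-side switch), which leaves the
(unconstrained) reaction entropy equal to the activation entropy.

### Solving fixtures to printed targets

`build_fixture()` takes target values $(\Delta G^{\ddagger},
T\Delta S^{\ddagger}[, \Delta G^{0}, T\Delta S^{0}])$ at a reference
temperature and returns a system whose *exact* decomposition matches them:

1. a bath-free calibration places the solute geometry at the target
   enthalpies $\Delta H = \Delta G + T\Delta S$;
2. switches are placed from the resulting stationary points and seeded with
   the closed-form stiffness ratios;
3. a damped Newton iteration solves $(\alpha, \ln k\text{-ratios}[,
   H_{12}])$ simultaneously against the oracle's $\Delta G$ and $T\Delta S$
   (the latter from a central difference over $T_{\mathrm{ref}} \pm 5$ K),
   so any residual switch-tail effects are folded into the solution.

The build verifies itself against `exact_decomposition()` to 0.05 kcal/mol
and checks that $\Delta G(T)$ stays linear over 280–320 K to ~$10^{-3}$
kcal/mol. The six packaged fixtures embody the reference decompositions of
the six modelled steps: the associative and dissociative uncatalyzed water
mechanisms (27 kcal/mol barrier at 55 M, $T\Delta S^{\ddagger} = -1.0$ and
$+1.2$), the aqueous proton transfer (15.7/12.2 kcal/mol), the aqueous
hydroxide attack (17.5 kcal/mol at 1 M, $+5.9$), the ribosomal proton
transfer ($T\Delta S^{0} = -0.2$) and the ribosomal hydroxide attack
($\Delta H^{\ddagger} = 18.4$, $T\Delta S^{\ddagger} = +7.3$).

Two quantities are not pinned by reference data and are package defaults,
configurable and excluded from acceptance checks: the ribosomal
proton-transfer step's reaction free energy (default 2.5 kcal/mol, keeping
the overall stepwise barrier near 13.6 kcal/mol, consistent through the
Eyring equation with rates above 500 s$^{-1}$) and its own barrier (6.0
kcal/mol, entropy-free — the step is described as mainly enthalpic).
Likewise the aqueous proton-transfer fixture carries zero entropy targets,
since only its free energies are quoted. Standard-state labels (1 M, 55 M)
are metadata handled by `convert_standard_state()`
($\Delta G \mapsto \Delta G - RT\ln(c_2/c_1)$), never baked into
potentials.

## Sampling

Dynamics are Langevin with the BAOAB splitting — chosen over Newtonian
dynamics plus a separate thermostat because its stationary distribution is
unconditionally correct and easiest to verify — at $dt = 0.01$ internal
time units, unit friction and unit masses (only equilibrium averages
matter, so the time scale is arbitrary; the oracle barrier is provably
invariant under mass rescaling, and a test confirms it). A stability check
$dt\,\omega_{\max} < 0.5$ runs whenever a protocol meets a system.

Each replicate emulates the production workflow: Maxwell–Boltzmann
velocities at 1 K, five-stage geometric heating to the target temperature
while a harmonic solute restraint decays from 10 to 0 kcal mol$^{-1}$
Å$^{-2}$, 10,000 unrestrained equilibration steps, then 21 FEP windows
$\varepsilon_\lambda = (1-\lambda)\varepsilon_1 + \lambda\varepsilon_2$
traversed sequentially, each window inheriting the previous window's final
configuration, with 2,000 discarded equilibration steps and (by default)
150,000 sampling steps per window recorded at stride 10.

All randomness flows from one master seed through a fixed splitmix64 hash
of (seed, replicate, temperature, window, phase), so any single window is
independently reproducible and a scan is byte-identical given its
configuration. The kernel is compiled (Rcpp): a default scan integrates
$\sim 2\times 10^8$ steps per fixture, far outside interpreted-R budgets.

### Why 150,000 steps per window

The entropy extraction is the precision bottleneck, and the budget can be
written down a priori. For a five-point scan at 290–310 K, the standard
error of the fitted $T_{\mathrm{ref}}\Delta S$ is
$T_{\mathrm{ref}}\,\sigma/\sqrt{\sum(T_i-\bar T)^2} \approx 19\,\sigma$,
where $\sigma$ is the per-temperature s.e.m. of the barrier. Recovering
entropy terms to a few tenths of a kcal/mol with five replicates (the
water-mechanism scans) therefore needs a per-replicate barrier SD near
0.04 kcal/mol. Measured per-replicate scatter is $\approx 0.58$ kcal/mol at
20,000 steps/window and $\approx 0.04$ at 150,000, which sets the default;
the resulting per-temperature s.e.m. ($\sim 0.015$ kcal/mol) sits well
inside the 0.4 kcal/mol noise budget the replicate design is meant to
respect. Shorter protocols remain available through
`sampling_protocol()` for exploratory work.

## Free-energy estimation

Window free energies chain through the Zwanzig estimator
$\Delta F_{m\to m+1} = -k_BT\ln\langle e^{-\beta(\varepsilon_{m+1}-
\varepsilon_m)}\rangle_m$, evaluated in log-sum-exp form. Profiles follow
the classic EVB umbrella-sampling assembly: per gap-coordinate bin,
$\Delta G(X_j) = \Delta G_{\mathrm{FEP}}(m) - k_BT\ln\langle
\mathbf{1}[X\in j]\, e^{-\beta(E_g-\varepsilon_m)}\rangle_m$, with the
window holding the most samples in a bin owning it (no WHAM/MBAR-style
global reweighting, which is out of scope by design). Profiles are anchored
at the reactant-side minimum; bins with fewer than 10 counts are flagged
unusable, never interpolated.

Two numerical choices deserve explanation:

* **300 bins, not a coarser histogram.** The constant gap Jacobian
  ($\sim$120 kcal mol$^{-1}$ Å$^{-1}$) stretches the sampled gap range to
  $\sim$300 kcal/mol. The per-bin log-sum-exp behaves as a *soft-min* of
  the true profile over the bin, so wide bins (e.g. 50 over this range)
  clip the barrier top by 0.4–0.6 kcal/mol — an error that does not vanish
  with more sampling and is fatal to entropy extraction. At 300 bins the
  assembled profiles converge to the quadrature PMF (residual bias
  $\sim$0.01 kcal/mol), which is verified against the oracle in the test
  suite at two sampling lengths.

* **Stationary points.** The transition state is the global maximum of the
  largest contiguous block of usable bins; the reactant (product) state is
  the deepest minimum on its low-$X$ (high-$X$) side; each value is refined
  by a three-point quadratic fit. Rules keyed to the *outermost* local
  minima are brittle at fine binning, where sparse flank bins fluctuate
  into shallow false minima; on clean profiles the two readings coincide.
  A profile with no interior maximum raises a "no barrier" error rather
  than returning zero.

Replicates are averaged per temperature with s.e.m. $= \mathrm{SD}/\sqrt n$
— the across-replicate error model; block averaging within a trajectory is
deliberately not used.

## Regression and rates

`arrhenius_fit()` / `vant_hoff_fit()` run ordinary (unweighted) least
squares of $\Delta G/T$ on $1/T$ — matching the reference procedure, where
regression scatter rather than per-point s.e.m. dominates the parameter
uncertainty — and report $R^2$, the rms residual in entropy units (1 e.u. =
1 cal mol$^{-1}$ K$^{-1}$ $\approx$ 0.3 kcal/mol of $T\Delta S$ at 298 K)
and the parameter covariance; inverse-variance weighting is available
behind a flag. `combine_stepwise()` adds a pre-equilibrium (van't Hoff)
decomposition to the rate-limiting step's (Arrhenius) decomposition —
enthalpies and entropies are additive for a stepwise mechanism, e.g.
$(-0.2) + (+7.3) = +7.1$ kcal/mol for the overall ribosomal reaction.
`eyring_rate()` converts barriers to rates with $k = (k_BT/h)\,
e^{-\Delta G^{\ddagger}/RT}$ ($k_BT/h = 6.25\times10^{12}$ s$^{-1}$ at
300 K from CODATA constants); physical constants are pinned package-wide
($R = 1.9872041\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$).

$T_{\mathrm{ref}} = 298$ K throughout, except the stepwise water-mechanism
rate, which is quoted at 300 K.

## The oracle

`exact_pmf()` evaluates $F(x;T)$ from the closed form above on a grid
(default 2,001 points, with a doubled-grid consistency bound reported),
refines the stationary points by continuous optimization, and transforms
to the gap coordinate with the exact Jacobian, refusing non-monotone gaps.
`exact_decomposition()` differentiates $\Delta G(T)$ centrally over
$\pm 5$ K and checks linearity over 280–320 K, warning beyond
$10^{-2}$ kcal/mol. The oracle is the ground truth for fixture
construction, for calibration (`calibrate()` solves $\alpha$, and $H_{12}$
when a reaction target is given, by damped Newton with a 2 kcal/mol step
cap, 0.01 kcal/mol tolerance, 100-iteration cap), and for every
convergence test of the sampled pipeline.

## What the surrogates do and do not show

The generator emulates the *statistical structure* of the production
calculations: replicate free-energy profiles with realistic scatter,
temperature scans of the published design, entropy arising from an
environment that stiffens or softens along the reaction coordinate, and
two-step mechanisms treated as independent two-state systems (mirroring
their separate published analyses). It does not emulate atomistic detail —
no explicit water, ions, force fields, electrostatics, or conformational
gating — so passing recovery tests demonstrates correctness of the
*methodology* (sampling, estimators, regression) on systems where truth is
computable, not reproducibility of the atomistic simulations themselves.
Real applications would also face sources of error the surrogate lacks:
force-field bias, incomplete conformational sampling, and slow degrees of
freedom coupling to the reaction coordinate.

## Problem sizes

The defaults used throughout the package and its checks: 6 fixtures built
by quadrature-level root finding (sub-second); scans of 5 temperatures
$\times$ 15 replicates (5 for the water-mechanism fixtures, matching their
published replicate count) $\times$ 21 windows $\times$ 150,000 steps —
about 1.5 minutes per fixture on one core; unit tests use shortened
protocols of a few thousand steps per window wherever only structural
behaviour is under test.

## Known limitations

* The Zwanzig chain is forward-only; cycle-closure tests bound, but do not
  eliminate, its small exponential-averaging bias.
* Entropy recovery inherits the $\times 19$ error amplification of the
  narrow temperature window; recovering $T\Delta S$ to better than
  $\sim$0.2 kcal/mol would require either longer sampling or a wider scan.
* The bath is strictly separable given $x$; anharmonic solvent response and
  heat-capacity effects ($\Delta C_p \neq 0$, curved Arrhenius plots) are
  out of scope, as are WHAM/MBAR estimators and more than two states per
  step.
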