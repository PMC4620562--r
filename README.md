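# evbtherm

Enthalpy–entropy decomposition of reaction free energies from empirical
valence bond (EVB) simulations, via computational Arrhenius plots.

## What it does

Whether an enzyme accelerates its reaction by lowering the activation
enthalpy or by releasing activation entropy is invisible in a single
free-energy profile — it lives in the temperature dependence of the
barrier. For a barrier ΔG‡(T) obeying ΔG‡ = ΔH‡ − TΔS‡, an ordinary
least-squares fit of

    ΔG‡/T  versus  1/T      (slope = ΔH‡, intercept = −ΔS‡)

over a scan of simulated temperatures extracts both components; the same
construction on a reaction free energy ΔG⁰(T) is a van't Hoff fit. The
motivating chemistry is GTP hydrolysis: the translational GTPases on the
ribosome use a stepwise mechanism (proton transfer to the γ-phosphate, then
hydroxide attack) whose large *positive* activation entropy term — more
than +7 kcal/mol at 298 K — enables their exceptionally high rates, in
contrast to the near-zero activation entropies of the uncatalyzed
associative/dissociative pathways in water.

`evbtherm` implements the full methodology at desk scale:

* **EVB engine** — two diabatic states mixed by a constant coupling H₁₂;
  free-energy profiles on the energy-gap coordinate X = ε₁ − ε₂ from
  21-window FEP umbrella sampling, sampled by compiled BAOAB Langevin
  dynamics with Maxwell velocity initialization and stepwise heating.
* **Surrogate systems** — one solute coordinate plus a harmonic bath whose
  stiffness k(x) varies along the reaction, giving exactly T-linear
  entropy. Quadrature makes their thermodynamics *exact*, so recovery of
  known decompositions tests the whole pipeline.
* **Packaged fixtures** — six systems solved so their exact decompositions
  equal the reference values of the six modelled reaction steps (water
  associative/dissociative hydrolysis, aqueous and ribosomal proton
  transfer and hydroxide attack).
* **Analysis** — replicate temperature scans with per-temperature s.e.m.,
  Arrhenius/van't Hoff regressions with R², residuals in entropy units and
  parameter covariance, stepwise combination of mechanisms, Eyring rate
  conversion and standard-state corrections.

## Worked example

Build the ribosomal hydroxide-attack fixture (solved to ΔH‡ = 18.4,
TΔS‡ = +7.3 kcal/mol at 298 K), run the default temperature scan and
recover the decomposition:

```r
library(evbtherm)

fx  <- packaged_fixtures()$oh_attack_ribosome
run <- run_scan(fx, seed = 1)       # 5 temperatures x 15 replicates, ~90 s
run$scan
#> Replicate temperature scan (mean +/- s.e.m., kcal/mol):
#>     290 K (n=15): dG_act =  11.317 +/- 0.015, dG_rxn =  -30.761 +/- 0.021
#>     295 K (n=15): dG_act =  11.171 +/- 0.014, dG_rxn =  -30.922 +/- 0.023
#>     300 K (n=15): dG_act =  11.046 +/- 0.014, dG_rxn =  -31.012 +/- 0.022
#>     305 K (n=15): dG_act =  10.963 +/- 0.013, dG_rxn =  -31.145 +/- 0.012
#>     310 K (n=15): dG_act =  10.830 +/- 0.014, dG_rxn =  -31.236 +/- 0.019

decompose_scan(run, "arrhenius")
#> activation decomposition (arrhenius fit):
#>   dH =   18.170 kcal/mol
#>   dS =  0.02368 kcal/mol/K  (T*dS = +7.057 kcal/mol at 298 K, 23.7 e.u.)
#>   R^2 = 0.999, rms residual = 0.05 e.u.
```

The barrier falls by ~0.5 kcal/mol across 20 K; the fit reads this slope as
an activation entropy term of +7.06 kcal/mol at 298 K (≈ 24 e.u.) with an
activation enthalpy of 18.17 kcal/mol — recovering the fixture's exact
values (+7.3 / 18.4, available from `exact_decomposition(fx$system)`)
within the regression uncertainty of this replicate design. Combining the
proton-transfer pre-equilibrium with the attack step, and converting
barriers to rates:

```r
fxs <- packaged_fixtures()
combine_stepwise(exact_decomposition(fxs$pt_ribosome$system)$reaction,
                 exact_decomposition(fxs$oh_attack_ribosome$system)$activation)
#> activation decomposition (arrhenius fit):
#>   dH =   20.700 kcal/mol
#>   dS =  0.02386 kcal/mol/K  (T*dS = +7.110 kcal/mol at 298 K, 23.9 e.u.)

eyring_rate(12.2 + 17.5, 300)       # stepwise water mechanism, M^-1 s^-1
#> [1] 1.445259e-09
```

Fixtures round-trip through YAML (`write_fixture_yaml()`,
`read_fixture_yaml()`, `write_fixture_manifest()`), scans export to
CSV/JSON, and `reproduce_targets("fig2" | "fig4" | "overall" | "rates")`
re-runs each group of reference decompositions end to end.

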