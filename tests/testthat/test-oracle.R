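test_that("bath-free PMF equals the ground-state energy up to the anchor", {
  sys <- two_well_system(alpha = -5, h12 = 1)
  prof <- exact_pmf(sys, 300)
  e1 <- diabatic_energy(sys$states[[1]], prof$grid)
  e2 <- diabatic_energy(sys$states[[2]], prof$grid)
  eg <- ground_state_energy(e1, e2, sys$h12)
  expect_equal(prof$pmf_x - min(prof$pmf_x), eg - min(eg), tolerance = 1e-6)
})

test_that("harmonic single-state PMF keeps the potential's curvature", {
  sys <- harmonic_system(k = 40)
  prof <- exact_pmf(sys, 300)
  # curvature from a quadratic fit near the minimum
  sel <- abs(prof$grid) < 0.3
  fit <- lm(prof$pmf_x[sel] ~ poly(prof$grid[sel], 2, raw = TRUE))
  expect_equal(unname(2 * coef(fit)[3]), 40, tolerance = 1e-3)
})

test_that("refusing the gap transform for a non-monotone gap", {
  sys <- evb_system(diabatic_surface(60, 0, 0), diabatic_surface(30, 2, -5),
                    h12 = 1, domain = c(-8, 4))  # unequal stiffness: gap turns
  expect_error(exact_pmf(sys, 300), "monotone")
})

test_that("packaged fixtures hit their design targets by the oracle", {
  fx <- packaged_fixtures()
  expect_length(fx, 6L)
  expect_named(fx, c("associative_water", "dissociative_water", "pt_water",
                     "oh_attack_water", "pt_ribosome", "oh_attack_ribosome"))
  for (f in fx) {
    dec <- exact_decomposition(f$system)
    expect_lt(abs(dec$activation$dH - f$targets$dH_act), 0.05)
    expect_lt(abs(dec$activation$TdS_at_ref - f$targets$TdS_act), 0.05)
    if (is.finite(f$targets$dG_rxn)) {
      expect_lt(abs(dec$reaction$dH - f$targets$dH_rxn), 0.05)
      expect_lt(abs(dec$reaction$TdS_at_ref - f$targets$TdS_rxn), 0.05)
    }
    # barrier at 298 K from the PMF equals the free-energy target
    expect_lt(abs(exact_barrier(f$system, 298)[["dG_act"]] - f$targets$dG_act),
              0.05)
  }
})

test_that("exact dG(T) is linear in T over 280-320 K for every fixture", {
  for (f in packaged_fixtures()) {
    dec <- exact_decomposition(f$system)
    expect_lt(dec$linearity_residual, 2e-3)
    expect_false(dec$nonlinearity_warning)
  }
})

test_that("a bath-free fixture has zero activation entropy", {
  fx <- build_fixture(fixture_targets(12, 0), n_bath = 0L, name = "nob")
  dec <- exact_decomposition(fx$system)
  expect_lt(abs(dec$activation$TdS_at_ref), 1e-3)
  # dG(T) constant in T
  expect_lt(abs(exact_barrier(fx$system, 290)[["dG_act"]] -
                exact_barrier(fx$system, 310)[["dG_act"]]), 1e-6)
})

test_that("bath entropy depends only on n * log stiffness ratio", {
  # doubling n_bath while halving each mode's log-ratio leaves the
  # decomposition unchanged: dS = -(n/2) kB log(k_TS/k_R)
  mk <- function(n, dl) {
    two_well_system(alpha = -6, h12 = 1, n_bath = n,
                    bath = list(k_ref = 40, delta = dl, center = 0.6,
                                width = 0.3))
  }
  d1 <- exact_decomposition(mk(6L, -1.0))
  d2 <- exact_decomposition(mk(12L, -0.5))
  expect_equal(d1$activation$TdS_at_ref, d2$activation$TdS_at_ref,
               tolerance = 1e-6)
  expect_equal(d1$activation$dH, d2$activation$dH, tolerance = 1e-6)
})

test_that("the oracle barrier is invariant under uniform mass rescaling", {
  fx <- packaged_fixtures()$oh_attack_ribosome
  sys2 <- fx$system
  sys2$masses <- sys2$masses * 7.5
  expect_equal(exact_barrier(sys2, 300), exact_barrier(fx$system, 300),
               tolerance = 1e-12)
})

test_that("grid refinement does not move the barrier beyond the bound", {
  fx <- packaged_fixtures()$oh_attack_water
  p1 <- exact_pmf(fx$system, 298, 1001L)
  p2 <- exact_pmf(fx$system, 298, 4001L)
  expect_lt(abs(p1$dG_act - p2$dG_act), max(p1$quadrature_error_bound, 1e-6))
})

test_that("entropy sign follows the stiffness change at the barrier", {
  fx <- packaged_fixtures()
  for (nm in c("oh_attack_ribosome", "oh_attack_water", "dissociative_water",
               "associative_water")) {
    sys <- fx[[nm]]$system
    orc <- exact_pmf(sys, 298)
    k_r <- bath_stiffness(sys, orc$x_reactant)
    k_ts <- bath_stiffness(sys, orc$x_ts)
    TdS <- fx[[nm]]$targets$TdS_act
    if (TdS > 0) expect_lt(k_ts, k_r)  # softer environment at the TS
    if (TdS < 0) expect_gt(k_ts, k_r)
  }
})
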