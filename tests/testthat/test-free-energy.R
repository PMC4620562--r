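test_that("identity perturbation has exactly zero free energy", {
  sys <- two_well_system(alpha = -5, h12 = 1)
  p <- short_protocol(steps_sample_per_window = 2000L)
  wins <- run_fep_windows(sys, p, 300, 1L, seed = 1L)
  expect_identical(fep_increment(wins[[3]], wins[[3]]$lam), 0)
})

test_that("FEP chain recovers the closed-form free energy of displaced wells", {
  # equal-stiffness displaced harmonic states: configurational partition
  # functions are identical, so dF(0 -> 1) = alpha exactly
  alpha <- -3.7
  sys <- two_well_system(k = 60, d = 1.2, alpha = alpha, h12 = 0)
  p <- short_protocol(steps_sample_per_window = 40000L)
  total <- numeric(4)
  for (r in 1:4) {
    wins <- run_fep_windows(sys, p, 300, r, seed = 8L)
    lams <- vapply(wins, `[[`, numeric(1), "lam")
    total[r] <- sum(vapply(seq_len(20), function(m)
      fep_increment(wins[[m]], lams[m + 1L]), numeric(1)))
  }
  expect_lt(abs(mean(total) - alpha), 3 * max(sd(total) / sqrt(4), 0.01))
})

test_that("forward and reverse FEP chains close the thermodynamic cycle", {
  fx <- packaged_fixtures()$pt_water
  p <- short_protocol(steps_sample_per_window = 40000L)
  closures <- numeric(3)
  for (r in 1:3) {
    wins <- run_fep_windows(fx$system, p, 300, r, seed = 13L)
    lams <- vapply(wins, `[[`, numeric(1), "lam")
    fwd <- sum(vapply(seq_len(20), function(m)
      fep_increment(wins[[m]], lams[m + 1L]), numeric(1)))
    rev <- sum(vapply(seq_len(20), function(m)
      fep_increment(wins[[m + 1L]], lams[m]), numeric(1)))
    closures[r] <- fwd + rev
  }
  expect_lt(abs(mean(closures)), 0.2)
})

test_that("a single-state system yields a flat profile and no barrier", {
  sys <- harmonic_system(k = 40, h12 = 0.5)  # eps2 == eps1: no reaction
  p <- short_protocol(steps_sample_per_window = 5000L)
  wins <- run_fep_windows(sys, p, 300, 1L, seed = 2L)
  # the gap is identically zero: assembly cannot bin a zero-width range,
  # and barrier analysis must refuse rather than return 0
  prof <- list(bin_centers = seq(-1, 1, length.out = 50),
               dG = rep(0, 50), counts = rep(100L, 50),
               usable = rep(TRUE, 50), temperature = 300,
               replicate_id = 1L)
  expect_error(barrier_and_reaction(prof), "no barrier")
  expect_true(all(abs(wins[[1]]$samples$eps1 - wins[[21]]$samples$eps2) >= 0))
})

test_that("hand-built coarse profiles give the expected stationary values", {
  prof <- list(bin_centers = c(-2, -1, 0, 1, 2),
               dG = c(0, 5, 27, 10, 3), counts = rep(1000L, 5),
               usable = rep(TRUE, 5), temperature = 298, replicate_id = 1L)
  br <- barrier_and_reaction(prof)
  expect_equal(br$dG_act, 27, tolerance = 2)   # quadratic refinement <= bin effect
  expect_equal(br$dG_rxn, 3, tolerance = 1e-9) # product bin is an endpoint
  expect_error(
    barrier_and_reaction(list(bin_centers = 1:10, dG = as.numeric(1:10),
                              counts = rep(100L, 10), usable = rep(TRUE, 10),
                              temperature = 298, replicate_id = 1L)),
    "no barrier")
})

test_that("sampled profiles match the oracle PMF on well-populated bins", {
  fx <- packaged_fixtures()$oh_attack_ribosome
  p <- sampling_protocol(steps_sample_per_window = 50000L,
                         steps_per_heating_stage = 500L,
                         steps_final_equil = 3000L)
  orc <- exact_pmf(fx$system, 300, 4001L)
  fo <- stats::approxfun(orc$gap, orc$pmf_gap)
  # each replicate has its own bin grid: compare profile shape against the
  # oracle per replicate, referencing both at the best-populated bin
  for (r in 1:3) {
    prof <- assemble_profile(run_fep_windows(fx$system, p, 300, r, seed = 21L))
    sel <- which(prof$usable & prof$counts >= 200)
    dev <- prof$dG[sel] - fo(prof$bin_centers[sel])
    dev <- dev - dev[which.max(prof$counts[sel])]
    # per-bin statistical scale ~ kT/sqrt(counts); 3x with a floor for
    # residual bin-discretization effects
    tol <- pmax(3 * (KB * 300) / sqrt(prof$counts[sel]), 0.2)
    expect_lt(mean(abs(dev) > tol), 0.05)
  }
})

test_that("profile convergence: longer sampling shrinks the oracle error", {
  fx <- packaged_fixtures()$pt_ribosome
  orc <- exact_barrier(fx$system, 300)
  err <- vapply(c(20000L, 100000L), function(steps) {
    p <- short_protocol(steps_sample_per_window = steps)
    res <- vapply(1:4, function(r) {
      br <- barrier_and_reaction(
        assemble_profile(run_fep_windows(fx$system, p, 300, r, seed = 31L)))
      br$dG_rxn
    }, numeric(1))
    abs(mean(res) - orc[["dG_rxn"]]) + sd(res) / sqrt(4)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("profiles are invariant under a constant shift of both diabats", {
  sys1 <- two_well_system(alpha = -5, h12 = 1)
  sys2 <- sys1
  sys2$states[[1]]$alpha <- sys2$states[[1]]$alpha + 50
  sys2$states[[2]]$alpha <- sys2$states[[2]]$alpha + 50
  p <- short_protocol(steps_sample_per_window = 20000L)
  b1 <- barrier_and_reaction(
    assemble_profile(run_fep_windows(sys1, p, 300, 1L, seed = 17L)))
  b2 <- barrier_and_reaction(
    assemble_profile(run_fep_windows(sys2, p, 300, 1L, seed = 17L)))
  expect_equal(b1$dG_act, b2$dG_act, tolerance = 1e-9)
  expect_equal(b1$dG_rxn, b2$dG_rxn, tolerance = 1e-9)
})

test_that("replicate averaging reports means and standard errors", {
  mk <- function(g, T1) structure(list(dG_act = g, dG_rxn = g - 8,
                                       temperature = T1, replicate_id = 1L),
                                  class = "barrier_result")
  scan <- average_replicates(list(mk(10, 300), mk(11, 300), mk(12, 300),
                                  mk(9, 310), mk(9, 310)))
  expect_equal(scan$dG_act[scan$temperature == 300], 11)
  expect_equal(scan$sem_act[scan$temperature == 300], sd(10:12) / sqrt(3))
  expect_equal(scan$sem_act[scan$temperature == 310], 0)
  expect_error(average_replicates(list(mk(10, 300))), "fewer than 2")
})

test_that("empty coverage between windows raises a hole error", {
  mkwin <- function(lam, xs, T1 = 300) {
    structure(list(lam = lam, temperature = T1, replicate_id = 1L,
                   samples = data.frame(x = xs, eps1 = 30 * xs,
                                        eps2 = -30 * xs,
                                        e_ground = pmin(30 * xs, -30 * xs),
                                        e_map = (1 - lam) * 30 * xs - lam * 30 * xs),
                   seed_used = 0), class = "window_samples")
  }
  w1 <- mkwin(0, rnorm(200, -2, 0.1))
  w2 <- mkwin(1, rnorm(200, +2, 0.1))   # gap ranges do not overlap
  expect_error(assemble_profile(list(w1, w2)), "hole")
})
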