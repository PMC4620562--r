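test_that("ground-state energy matches the closed form and an eigensolver", {
  # degenerate states: E_g = eps - h12
  expect_equal(ground_state_energy(10, 10, 2), 8)
  # zero coupling: min of the diabats
  expect_equal(ground_state_energy(0, 20, 0), 0)
  # hand evaluation: 5 - sqrt(16 + 9)/2 = 2.5
  expect_equal(ground_state_energy(3, 7, 1.5), 2.5)

  # generic agreement with a 2x2 eigensolver
  set.seed(11)
  for (i in 1:25) {
    e1 <- runif(1, -30, 30); e2 <- runif(1, -30, 30); h <- runif(1, 0, 8)
    expect_equal(ground_state_energy(e1, e2, h),
                 min(eigen(matrix(c(e1, h, h, e2), 2), symmetric = TRUE)$values),
                 tolerance = 1e-12)
  }
})

test_that("ground-state energy obeys symmetry, bounds and monotonicity", {
  set.seed(12)
  e1 <- runif(40, -20, 20); e2 <- runif(40, -20, 20)
  expect_equal(ground_state_energy(e1, e2, 2), ground_state_energy(e2, e1, 2))
  expect_true(all(ground_state_energy(e1, e2, 3) <= pmin(e1, e2)))
  # monotone non-increasing in h12
  h <- seq(0, 5, by = 0.5)
  vals <- vapply(h, function(hh) ground_state_energy(4, 9, hh), numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_equal(vals[1], 4)       # h12 -> 0 limit
})

test_that("non-finite inputs are rejected with a diagnostic", {
  expect_error(ground_state_energy(NaN, 1, 0), "finite")
  expect_error(ground_state_energy(1, Inf, 0), "finite")
  expect_error(ground_state_energy(1, 2, -0.5), ">= 0")
})

test_that("mapping potential interpolates the diabats", {
  expect_identical(mapping_potential(2, 6, 0), 2)
  expect_identical(mapping_potential(2, 6, 1), 6)
  expect_equal(mapping_potential(2, 6, 0.5), 4)
  expect_error(mapping_potential(2, 6, 1.2), "\\[0, 1\\]")
  expect_error(mapping_potential(2, 6, -0.1), "\\[0, 1\\]")
})

test_that("ground-state force matches a central finite difference", {
  sys <- two_well_system(alpha = -4, h12 = 1.5)
  h <- 1e-5
  for (x in seq(-0.4, 2.4, by = 0.35)) {
    e <- function(z) ground_state_energy(
      diabatic_energy(sys$states[[1]], z), diabatic_energy(sys$states[[2]], z),
      sys$h12)
    fd <- -(e(x + h) - e(x - h)) / (2 * h)
    expect_equal(ground_state_force(sys, x), fd, tolerance = 1e-6)
  }
})

test_that("zero-coupling force follows the lower diabat exactly", {
  sys <- two_well_system(alpha = 3, h12 = 0)
  x <- 0.2  # state 1 strictly lower here
  expect_lt(diabatic_energy(sys$states[[1]], x),
            diabatic_energy(sys$states[[2]], x))
  expect_identical(ground_state_force(sys, x),
                   -sys$states[[1]]$k_solute * (x - sys$states[[1]]$x0))
})

test_that("solute force vanishes at the crossing of a symmetric system", {
  sys <- two_well_system(alpha = 0, h12 = 1)  # mirror diabats, crossing at d/2
  expect_equal(ground_state_force(sys, 1), 0, tolerance = 1e-12)
})

test_that("the gap coordinate is exactly linear and strictly monotone", {
  sys <- two_well_system(alpha = -7, h12 = 1)
  x <- seq(-1, 3, length.out = 101)
  X <- energy_gap(sys, x)
  expect_equal(diff(X), rep(diff(X)[1], 100), tolerance = 1e-12)
  expect_true(all(gap_jacobian(sys, x) > 0))
  # crossing: the gap changes sign exactly once
  expect_equal(sum(diff(sign(X)) != 0), 1L)
})

test_that("bath stiffness is positive and hits its asymptotic values", {
  bath <- list(k_ref = 40, delta = c(-2, 1), center = c(0.5, 1.5),
               width = c(0.2, 0.2))
  sys <- two_well_system(n_bath = 4L, bath = bath)
  x <- seq(-1, 3, length.out = 201)
  k <- bath_stiffness(sys, x)
  expect_true(all(k > 0))
  expect_equal(k[1], 40, tolerance = 1e-4)              # left asymptote
  expect_equal(k[201], 40 * exp(-2 + 1), tolerance = 1e-3)  # right asymptote
})

test_that("EVB systems round-trip through YAML to 12 significant digits", {
  bath <- list(k_ref = 40.123456789012, delta = c(-2.0546807, 0.9876543),
               center = c(0.456789012345, 1.33333333333),
               width = c(0.2222222222, 0.27182818284))
  sys <- evb_system(diabatic_surface(60.123456789, 0.1234567890123, 0),
                    diabatic_surface(59.987654321, 1.9876543210987,
                                     -23.456789012345),
                    h12 = 1.23456789012, n_bath = 12L, bath = bath)
  path <- withr::local_tempfile(fileext = ".yml")
  write_evb_yaml(sys, path)
  back <- read_evb_yaml(path)
  flat <- function(s) c(s$states[[1]]$k_solute, s$states[[1]]$x0,
                        s$states[[1]]$alpha, s$states[[2]]$k_solute,
                        s$states[[2]]$x0, s$states[[2]]$alpha, s$h12,
                        s$bath$k_ref, s$bath$delta, s$bath$center,
                        s$bath$width, s$domain, s$masses)
  expect_equal(flat(back), flat(sys), tolerance = 1e-12)
  expect_identical(back$n_bath, sys$n_bath)
})

test_that("fixtures round-trip through YAML with targets and calibration", {
  fx <- build_fixture(fixture_targets(10, 2), n_bath = 6L, name = "rt")
  path <- withr::local_tempfile(fileext = ".yml")
  write_fixture_yaml(fx, path)
  back <- read_fixture_yaml(path)
  expect_equal(back$targets$dG_act, 10)
  expect_equal(back$targets$TdS_act, 2)
  expect_equal(exact_barrier(back$system, 298)[["dG_act"]],
               exact_barrier(fx$system, 298)[["dG_act"]], tolerance = 1e-10)
  expect_equal(back$calibration$alpha, fx$calibration$alpha, tolerance = 1e-12)
})
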