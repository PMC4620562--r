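test_that("Arrhenius fit is exact on noiseless linear input", {
  temps <- c(290, 295, 300, 305, 310)
  pts <- data.frame(temperature = temps, dG = 18.4 - temps * (7.3 / 298))
  dec <- arrhenius_fit(pts)
  expect_equal(dec$dH, 18.4, tolerance = 1e-9)
  expect_equal(dec$TdS_at_ref, 7.3, tolerance = 1e-9)
  expect_equal(dec$r_squared, 1, tolerance = 1e-9)
  expect_lt(dec$rms_residual_eu, 1e-6)
  expect_equal(dec$TdS_at_ref, 298 * dec$dS)
  # self-consistency: dH - T dS reproduces the inputs
  expect_equal(dec$dH - temps * dec$dS, pts$dG, tolerance = 1e-9)
})

test_that("a temperature-independent barrier has zero entropy", {
  pts <- data.frame(temperature = c(290, 300, 310), dG = 12.5)
  dec <- arrhenius_fit(pts)
  expect_equal(dec$dH, 12.5, tolerance = 1e-9)
  expect_equal(dec$dS, 0, tolerance = 1e-12)
})

test_that("fits reject degenerate temperature designs", {
  expect_error(arrhenius_fit(data.frame(temperature = c(300, 310), dG = 1:2)),
               "3 distinct")
  expect_error(vant_hoff_fit(data.frame(temperature = rep(300, 5),
                                        dG = rnorm(5))), "3 distinct")
})

test_that("van't Hoff fit recovers entropy without bias over many seeds", {
  temps <- c(290, 295, 300, 305, 310)
  true_dH <- 2.3; true_TdS <- -0.2
  est <- vapply(1:200, function(s) {
    set.seed(s)
    pts <- data.frame(temperature = temps,
                      dG = true_dH - temps * (true_TdS / 298) +
                        rnorm(5, 0, 0.05))
    vant_hoff_fit(pts)$TdS_at_ref
  }, numeric(1))
  bias <- mean(est) - true_TdS
  expect_lt(abs(bias), 3 * sd(est) / sqrt(200))
  expect_identical(vant_hoff_fit(data.frame(temperature = temps,
                                            dG = 1 - temps * 0.001))$kind_label,
                   "vant_hoff")
})

test_that("entropy units conversion matches the printed anchors", {
  expect_equal(entropy_to_eu(7.3, 298), 24.49664, tolerance = 1e-5)
  # agrees with the printed 25 e.u. within half a unit of the last digit
  expect_lte(abs(entropy_to_eu(7.3, 298) - 25), 0.51)
  expect_identical(entropy_to_eu(0, 310), 0)
  expect_equal(entropy_to_eu(0.298, 298), 1.0)
})

test_that("Eyring rates have the right prefactor and invert exactly", {
  expect_equal(eyring_rate(0, 300), 6.25e12, tolerance = 1e-3)
  k <- eyring_rate(29.7, 300)
  expect_equal(k, 1.4e-9, tolerance = 0.05)
  expect_equal(dG_from_rate(k, 300), 29.7, tolerance = 1e-12)
  expect_equal(dG_from_rate(500, 298), 13.8, tolerance = 0.02)
  expect_equal(eyring_rate(dG_from_rate(500, 298), 298), 500, tolerance = 1e-9)
})

test_that("standard-state conversion shifts by RT log(c ratio) and round-trips", {
  expect_equal(convert_standard_state(17.5, 1, 55, 298), 17.5 - 2.373,
               tolerance = 1e-3)
  expect_identical(convert_standard_state(9.9, 2, 2, 310), 9.9)
  expect_equal(convert_standard_state(
    convert_standard_state(17.5, 1, 55, 298), 55, 1, 298), 17.5,
    tolerance = 1e-12)
})

test_that("stepwise combination adds enthalpies and entropies", {
  pre <- thermo_decomposition(dH = 2.3, dS = -0.2 / 298,
                              kind_label = "vant_hoff")
  attack <- thermo_decomposition(dH = 18.4, dS = 7.3 / 298,
                                 kind_label = "arrhenius")
  ov <- combine_stepwise(pre, attack)
  expect_equal(ov$TdS_at_ref, 7.1, tolerance = 1e-12)
  expect_equal(ov$dH, 20.7, tolerance = 1e-12)
  # zero pre-equilibrium leaves the attack decomposition unchanged
  zero <- thermo_decomposition(dH = 0, dS = 0, kind_label = "vant_hoff")
  expect_equal(combine_stepwise(zero, attack)$TdS_at_ref, attack$TdS_at_ref)
  # mismatched reference temperatures are rejected
  pre310 <- thermo_decomposition(dH = 2.3, dS = 0, T_ref = 310,
                                 kind_label = "vant_hoff")
  expect_error(combine_stepwise(pre310, attack), "T_ref")
  expect_error(combine_stepwise(attack, attack), "van't Hoff")
})

test_that("weighted fits honour inverse-variance weights", {
  temps <- c(290, 295, 300, 305, 310)
  pts <- data.frame(temperature = temps,
                    dG = 10 - temps * 0.01 + c(0, 0, 0, 0, 2),
                    sem = c(0.05, 0.05, 0.05, 0.05, 5))
  w <- arrhenius_fit(pts, weighted = TRUE)
  u <- arrhenius_fit(pts, weighted = FALSE)
  # the outlier with huge sem barely moves the weighted fit
  expect_lt(abs(w$TdS_at_ref - 298 * 0.01), abs(u$TdS_at_ref - 298 * 0.01))
})

test_that("arrhenius_table returns the plot-ready line", {
  temps <- c(290, 300, 310)
  pts <- data.frame(temperature = temps, dG = 12 - temps * 0.004)
  dec <- arrhenius_fit(pts)
  tab <- arrhenius_table(pts, dec)
  expect_equal(tab$inv_T, 1 / temps)
  expect_equal(tab$dG_over_T, tab$fitted, tolerance = 1e-9)
})
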