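test_that("alpha-amino pKa variants agree at 298 K and diverge elsewhere", {
  expect_equal(alpha_amino_pka(298), 7.8)
  expect_equal(alpha_amino_pka(298, "paper-literal"), 7.8)
  # hand-evaluated closed forms at 323.15 K
  expect_equal(alpha_amino_pka(323.15), 7.173200, tolerance = 1e-6)
  expect_equal(alpha_amino_pka(323.15, "paper-literal"), -89.374596,
               tolerance = 1e-6)
  expect_error(alpha_amino_pka(200), "range")
  expect_error(alpha_amino_pka(450), "range")
})

test_that("dissociation degree follows the logistic form and is monotone", {
  expect_equal(dissociation_degree(7.2, 7.2), 0.5)
  expect_equal(dissociation_degree(9.2, 7.2), 100 / 101, tolerance = 1e-12)
  expect_equal(dissociation_degree(4.2, 7.2), 1 / 1001, tolerance = 1e-12)
  grid <- seq(0, 14, by = 0.25)
  a <- dissociation_degree(grid, pka = 7.5)
  expect_true(all(diff(a) > 0))
  expect_true(all(a > 0 & a < 1))
})

test_that("degree of hydrolysis matches the chained closed form", {
  # C = 0.1 mol/L, V = 10 mL, pH 8, 323.15 K, m = 2 g, h_tot = 7.35
  expect_equal(degree_of_hydrolysis(0.1, 10, 8, 323.15, 2),
               7.816359, tolerance = 1e-5)
  expect_equal(degree_of_hydrolysis(0.1, 0, 8, 323.15, 2), 0)
  # high-pH limit: a -> 1 so DH -> 100 C V / (m h_tot)
  expect_equal(degree_of_hydrolysis(0.1, 10, 14, 323.15, 2),
               100 * 0.1 * 10 / (2 * 7.35), tolerance = 1e-4)
})

test_that("degree of hydrolysis is linear in volume, inverse in mass", {
  set.seed(11)
  for (i in 1:20) {
    C <- runif(1, 0.05, 0.5); V <- runif(1, 1, 20)
    ph <- runif(1, 6.5, 9); temp <- runif(1, 300, 340); m <- runif(1, 0.5, 5)
    base <- degree_of_hydrolysis(C, V, ph, temp, m)
    expect_equal(degree_of_hydrolysis(C, 3 * V, ph, temp, m), 3 * base,
                 tolerance = 1e-12)
    expect_equal(degree_of_hydrolysis(C, V, ph, temp, 2 * m), base / 2,
                 tolerance = 1e-12)
  }
  expect_error(degree_of_hydrolysis(0.1, 10, 8, 323.15, 0), "protein_mass")
  expect_error(degree_of_hydrolysis(0.1, 10, 8, 323.15, 2, h_tot = 0), "h_tot")
})

test_that("initial-rate fits recover generating curves exactly when noiseless", {
  t_min <- seq(0, 10, by = 1 / 6)
  quad <- kinetic_trace(t_min, 0.10 + 0.020 * t_min - 5e-4 * t_min^2,
                        time_unit = "min")
  expect_equal(fit_initial_rate(quad)$initial_rate, 0.020, tolerance = 1e-9)
  lin <- kinetic_trace(t_min * 60, 0.05 + 0.015 * t_min, time_unit = "s")
  expect_equal(fit_initial_rate(lin, "linear")$initial_rate, 0.015,
               tolerance = 1e-9)
  # exponential approach to plateau: rate at 0 is k * (plateau - a0)
  expo <- kinetic_trace(t_min, 0.5 - 0.4 * exp(-0.3 * t_min), time_unit = "min")
  expect_equal(fit_initial_rate(expo, "exponential")$initial_rate, 0.3 * 0.4,
               tolerance = 1e-6)
  expect_true(fit_initial_rate(quad)$fit_residual >= 0)
})

test_that("kinetic trace constructor enforces its invariants", {
  expect_error(kinetic_trace(c(0, 10), c(0.1, 0.2)), "3 points")
  expect_error(kinetic_trace(c(0, 10, 10), c(0.1, 0.2, 0.3)), "increasing")
  expect_error(kinetic_trace(c(0, 10, 20), c(0.1, 0.2)), "length")
})

test_that("assay rate formulas hit their fixed points and rescale invariantly", {
  expect_equal(adh_activation_rate(2, 2), 0)
  expect_equal(adh_activation_rate(3, 2), 50)
  expect_equal(adh_activation_rate(1.6, 2), -20)
  expect_error(adh_activation_rate(1, 0), "v_control")

  expect_equal(xod_inhibition_rate(0.6, 0.1, 0.9, 0.1), 37.5)
  expect_equal(xod_inhibition_rate(0.9, 0.1, 0.9, 0.1), 0)   # A-B == C-D
  expect_equal(xod_inhibition_rate(0.3, 0.3, 0.9, 0.1), 100) # A == B
  expect_error(xod_inhibition_rate(0.6, 0.1, 0.5, 0.5), "blank")

  expect_equal(dpph_scavenging_rate(0.8, 0.45, 0.05), 50)
  expect_equal(dpph_scavenging_rate(0.8, 0.8, 0), 0)
  expect_equal(dpph_scavenging_rate(0.8, 0.05, 0.05), 100)
  expect_error(dpph_scavenging_rate(0, 0.5, 0.1), "a_control")

  # uniform rescaling of all absorbances leaves each statistic unchanged
  set.seed(3)
  for (i in 1:10) {
    ab <- runif(4, 0.1, 1); s <- runif(1, 0.5, 4)
    expect_equal(xod_inhibition_rate(ab[1], ab[2], ab[3], ab[4]),
                 xod_inhibition_rate(s * ab[1], s * ab[2], s * ab[3], s * ab[4]),
                 tolerance = 1e-10)
    expect_equal(dpph_scavenging_rate(ab[1], ab[2], ab[3]),
                 dpph_scavenging_rate(s * ab[1], s * ab[2], s * ab[3]),
                 tolerance = 1e-10)
    expect_equal(adh_activation_rate(ab[1], ab[2]),
                 adh_activation_rate(s * ab[1], s * ab[2]), tolerance = 1e-10)
  }
})
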