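test_that("undissociated amine mass is Cb * M * Vr", {
  expect_equal(undissociated_amine_mass(0.069183, alcoholamine_spec(), 0.003),
               0.069183 * 105.14 * 0.003)
  expect_equal(undissociated_amine_mass(0), 0)
  expect_equal(undissociated_amine_mass(0.05, Vr = 0.006),
               2 * undissociated_amine_mass(0.05, Vr = 0.003))
  expect_error(undissociated_amine_mass(-1), "non-negative")
})

test_that("reacted amine mass subtracts and clamps pH-rise artifacts", {
  expect_equal(as.numeric(reacted_amine_mass(0.021822, 0.0021822)),
               0.019640, tolerance = 1e-4)
  expect_equal(as.numeric(reacted_amine_mass(0.02, 0.02)), 0)
  clamped <- reacted_amine_mass(0.01, 0.02)
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "clamped"))
  raw <- reacted_amine_mass(0.01, 0.02, policy = "raw")
  expect_equal(as.numeric(raw), -0.01)
  expect_true(attr(raw, "clamped"))
})

test_that("acid-mass conversion directions are reciprocal", {
  expect_equal(reacted_acid_mass(0.019640), 0.019640 * 284.48 / 105.14)
  expect_equal(reacted_acid_mass(0), 0)
  x <- 0.0123
  expect_equal(reacted_acid_mass(reacted_acid_mass(x, direction = "physical"),
                                 direction = "as_printed"),
               x, tolerance = 1e-14)
})

test_that("sebum mass and volume scalings match their definitions", {
  sb <- sebum_composition()
  expect_equal(reacted_sebum_mass(0.053140, sb), 0.053140 / 0.24)
  expect_equal(reacted_sebum_mass(0, sb), 0)
  sb_pure <- sebum_composition(fractions = c(stearic_acid = 1))
  expect_equal(reacted_sebum_mass(0.01, sb_pure), 0.01)
  expect_equal(reacted_sebum_volume(0.842e-3, sb), 1)  # density definition
  expect_equal(reacted_sebum_volume(0, sb), 0)
})

test_that("full pH -> volume chain matches the hand-computed case", {
  v <- ph_to_reacted_volume(10.80, 10.30)
  expect_equal(as.numeric(v), 262.96, tolerance = 1e-4)
  expect_equal(as.numeric(ph_to_reacted_volume(10.5, 10.5)), 0)
})

test_that("chain equals the independent one-expression oracle", {
  set.seed(7)
  for (i in 1:30) {
    ph0 <- stats::runif(1, 10, 11.5)
    phn <- stats::runif(1, 9, ph0)
    vr <- stats::runif(1, 0.001, 0.01)
    expect_equal(
      as.numeric(ph_to_reacted_volume(ph0, phn, Vr = vr)),
      oracle_chain_volume(ph0, phn, Vr = vr),
      tolerance = 1e-12)
  }
})

test_that("reacted volume is monotone in the pH drop and linear in Vr", {
  phn <- seq(10.79, 9.5, by = -0.01)
  v <- as.numeric(ph_to_reacted_volume(10.80, phn))
  expect_true(all(diff(v) > 0))
  v1 <- as.numeric(ph_to_reacted_volume(10.8, 10.2, Vr = 0.003))
  v2 <- as.numeric(ph_to_reacted_volume(10.8, 10.2, Vr = 0.006))
  expect_equal(v2, 2 * v1)
})

test_that("only the physical direction respects the applied-amine budget", {
  # implied reacted AMPD mass behind each published 216-min volume must
  # not exceed the amine actually applied in 3 g of solution
  tab <- ampd_fixture_tables()$method_comparison
  applied_g <- tab$concentration_pct / 100 * 3
  implied_mzp <- function(v_mm3, direction) {
    m_kp <- v_mm3 * 0.842e-3 * 0.24
    if (direction == "physical") m_kp * 105.14 / 284.48
    else m_kp * 284.48 / 105.14
  }
  phys <- implied_mzp(tab$ph_reacted_mm3, "physical")
  lit <- implied_mzp(tab$ph_reacted_mm3, "as_printed")
  expect_true(all(phys <= applied_g))
  expect_true(any(lit > applied_g))
})

test_that("sebum composition validation rejects malformed mixtures", {
  expect_error(sebum_composition(fractions = c(stearic_acid = 0.5,
                                               lanolin = 0.4)),
               "sum to 1")
  expect_error(sebum_composition(fractions = c(lanolin = 1)),
               "stearic_acid")
  expect_error(sebum_composition(density_mg_per_mm3 = 0), "positive")
})
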