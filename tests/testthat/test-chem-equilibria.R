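ampd <- acid_base_constants(pKb = 5.24)

test_that("weak-base pH formula matches hand-evaluated cases", {
  expect_equal(ph_of_weak_base(0.1, ampd), 14 - 0.5 * (5.24 + 1))
  expect_equal(ph_of_weak_base(1.0, ampd), 14 - 5.24 / 2)
  # 0.5% w/v AMPD is ~0.0476 mol/dm^3; pH must sit in the observed
  # 10.47-10.94 window for the concentration range
  expect_equal(ph_of_weak_base(0.0476, ampd), 10.72, tolerance = 1e-3)
})

test_that("concentration inversion matches hand-evaluated cases", {
  expect_equal(conc_from_ph(10.88, ampd), 0.1)
  expect_equal(conc_from_ph(10.30, ampd), 10^(-2.16))
})

test_that("pH <-> concentration round trip is exact over the working range", {
  for (cb in 10^seq(-4, 0, by = 0.25)) {
    expect_equal(conc_from_ph(ph_of_weak_base(cb, ampd), ampd), cb,
                 tolerance = 1e-12)
  }
  for (ph in seq(6.1, 13.9, by = 0.37)) {
    expect_lt(abs(ph - ph_of_weak_base(conc_from_ph(ph, ampd), ampd)),
              1e-10)
  }
})

test_that("pH is increasing in concentration and decreasing in pKb", {
  cb <- 10^seq(-4, 0, length.out = 25)
  expect_true(all(diff(ph_of_weak_base(cb, ampd)) > 0))
  phs <- vapply(c(4, 4.5, 5, 5.5, 6),
                function(pkb) ph_of_weak_base(0.05,
                                              acid_base_constants(pKb = pkb)),
                numeric(1))
  expect_true(all(diff(phs) < 0))
})

test_that("domain errors and nonphysical-pH warnings fire", {
  expect_error(ph_of_weak_base(0, ampd), "positive")
  expect_error(ph_of_weak_base(-0.1, ampd), "positive")
  expect_error(conc_from_ph(-1, ampd), "positive")
  expect_warning(conc_from_ph(14.5, acid_base_constants(pKb = 5, pKw = 14.4)),
                 "nonphysical")
})

test_that("hydrolysis constant satisfies Kh * Ka * Kb = Kw", {
  expect_equal(hydrolysis_constant(1, 1, 1), 1)
  set.seed(42)
  for (i in 1:25) {
    ka <- 10^stats::runif(1, -10, -2)
    kb <- 10^stats::runif(1, -10, -2)
    kw <- 10^stats::runif(1, -15, -13)
    expect_equal(hydrolysis_constant(ka, kb, kw) * ka * kb, kw,
                 tolerance = 1e-12)
  }
  expect_error(hydrolysis_constant(0, 1e-6), "positive")
  expect_error(hydrolysis_constant(1e-6, -1), "positive")
})

test_that("salt solution pH follows the weak-acid/weak-base formula", {
  expect_equal(salt_solution_ph(acid_base_constants(pKb = 4.2, pKa = 4.2)),
               7)
  expect_equal(salt_solution_ph(acid_base_constants(pKb = 3, pKa = 5)), 8)
  expect_error(salt_solution_ph(acid_base_constants(pKb = 5.24)), "pKa")
})

test_that("the two shipped AMPD constant sets are distinct and consistent", {
  a <- ampd_constants("pka876")
  b <- ampd_constants("hydrolysis")
  expect_equal(a$pKb, 5.24)
  expect_equal(b$Kb, 6.309e-6)
  expect_equal(b$Ka, 1.778e-5)
  # round-trip pX <-> 10^-pX
  expect_equal(-log10(b$Kb), b$pKb)
  expect_equal(-log10(a$Kw), a$pKw)
})
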