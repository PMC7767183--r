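test_that("simulation is bit-reproducible for a fixed config and seed", {
  cfg <- simulation_config(concentration_pct = 1.5)
  a <- simulate_reaction(cfg, seed = 42)
  b <- simulate_reaction(cfg, seed = 42)
  expect_identical(a$ph$ph, b$ph$ph)
  expect_identical(a$heights$replicates, b$heights$replicates)
  expect_identical(a$truth, b$truth)
  c <- simulate_reaction(cfg, seed = 43)
  expect_false(identical(a$ph$ph, c$ph$ph))
})

test_that("noiseless pH series starts at the equilibrium pH of the
           prepared solution", {
  cfg <- simulation_config(concentration_pct = 2.0, noise_sd_ph = 0)
  run <- simulate_reaction(cfg, seed = 1)
  cb0 <- 2 / 100 * 3 / (105.14 * 0.003)
  expect_equal(run$ph$ph[1], ph_of_weak_base(cb0, ampd_constants("pka876")))
})

test_that("the pH method inverts noiseless simulations to the truth", {
  set.seed(202)
  for (i in 1:6) {
    cfg <- random_sim_config(noise_sd_ph = 0)
    run <- simulate_reaction(cfg, seed = 300 + i)
    v <- run_ph_method(run$ph, Vr = cfg$Vr_cm3 / 1000)
    scale <- max(run$truth$v_s_mm3)
    expect_lt(max(abs(v$reacted_mm3 - run$truth$v_s_mm3)) / scale, 1e-9)
  }
})

test_that("the optical method recovers simulated heights from images", {
  cfg <- simulation_config(concentration_pct = 2.0, noise_sd_height_mm = 0)
  run <- simulate_reaction(cfg, seed = 7)
  i <- nrow(run$truth)
  hl <- layer_heights(run$truth$h_penetration_mm[i],
                      run$truth$h_increase_mm[i])
  img <- render_tube_image(hl, calibration = pixel_calibration(50),
                           seed = 70)
  m <- measure_layer_heights(img)
  expect_lte(abs(m$penetration_depth_mm - hl$penetration_depth_mm), 0.02)
  expect_lte(abs(m$increase_height_mm - hl$increase_height_mm), 0.02)
})

test_that("ground truth obeys its own invariants", {
  cfg <- simulation_config(concentration_pct = 1.0)
  run <- simulate_reaction(cfg, seed = 5)
  tr <- run$truth
  expect_true(all(diff(tr$m_zp_g) >= 0))
  m_z0 <- 1 / 100 * 3
  expect_lte(max(tr$m_zp_g), cfg$max_reacted_fraction * m_z0)
  expect_true(all(tr$v_s_mm3 >= 0))
  expect_true(all(diff(tr$turbidity) >= 0))
  expect_equal(tr$turbidity[1], 0)
})

test_that("a low-concentration run plateaus before the end of observation", {
  run <- simulate_reaction(simulation_config(concentration_pct = 0.5,
                                             noise_sd_ph = 0), seed = 2)
  ph <- run$ph$ph
  n <- length(ph)
  expect_true(all(diff(ph) < 0))
  # amine depletion: late drift is tiny compared with the initial drop
  late_drop <- ph[n - 24] - ph[n]
  total_drop <- ph[1] - ph[n]
  expect_lt(late_drop, 0.01 * total_drop)
})

test_that("simulated turbidity falls with concentration at each time", {
  runs <- lapply(c(0.5, 1.0, 1.5, 2.0),
                 function(cc) simulate_reaction(
                   simulation_config(concentration_pct = cc), seed = 11))
  rep <- turbidity_trend_check(lapply(runs, `[[`, "turbidity"))
  expect_true(rep$ok)
})

test_that("rendered images are seed-deterministic and flag empty bands", {
  a <- render_tube_image(layer_heights(2, 3), seed = 5)
  b <- render_tube_image(layer_heights(2, 3), seed = 5)
  expect_identical(a$intensities, b$intensities)
  empty <- measure_layer_heights(render_tube_image(layer_heights(0, 0),
                                                   seed = 5))
  expect_equal(empty$flag, "no_reacted_band")
  expect_error(render_tube_image(layer_heights(10, 10), height_px = 100),
               "exceed")
})

test_that("packaged reference tables carry the published values", {
  ft <- ampd_fixture_tables()
  expect_equal(
    ft$alcoholamine_screen$penetrated_mm3[
      ft$alcoholamine_screen$alcoholamine == "AMPD"], 397)
  expect_equal(ft$turbidity$ampd_0.5[ft$turbidity$time_h == 4], 0.532)
  expect_equal(
    ft$method_comparison$optical_penetrated_mm3[
      ft$method_comparison$concentration_pct == 2.5], 310.00)
})

test_that("both methods agree on a self-consistent noiseless run", {
  cfg <- simulation_config(concentration_pct = 1.5, noise_sd_ph = 0,
                           noise_sd_height_mm = 0)
  run <- simulate_reaction(cfg, seed = 9)
  opt <- run_optical_method(run$heights)
  phm <- run_ph_method(run$ph)
  # penetration height is the reacted volume over the tube cross-section,
  # so the optical and pH routes must coincide without noise
  expect_equal(opt$v_penetrated_mm3, phm$reacted_mm3, tolerance = 1e-9)
  # water binding inflates only the increase layer
  expect_equal(opt$v_increased_mm3,
               (cfg$water_binding_factor - 1) * phm$reacted_mm3,
               tolerance = 1e-9)
})
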