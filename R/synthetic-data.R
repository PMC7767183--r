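# Self-consistent synthetic experiments: a seeded generator producing pH
# series, replicate height series, turbidity and tube images, together
# with the ground truth they were generated from. The kinetic form (a
# first-order approach to a reacted-mass ceiling) is a test harness that
# reproduces the qualitative "fast then stabilizing" trajectory, not a
# mechanistic model.

#' Configuration of a synthetic penetration experiment
#'
#' Describes one tube: the applied solution, the sebum, the tube geometry
#' and the (deliberately simple) reaction trajectory
#' \deqn{m_{zp}(t) = m_{max}\,(1 - e^{-k t}),}
#' where `m_max = max_reacted_fraction x initial amine mass`. The
#' concentration dependence of `max_reacted_fraction` emulates the two
#' failure modes at the ends of the concentration range: near-complete
#' amine depletion at low % and a product plug limiting conversion above
#' `plug_threshold_pct`. `water_binding_factor` (>= 1) inflates the
#' observed layer volume relative to the stoichiometric reacted volume,
#' standing in for the water bound by the formed amine soap.
#'
#' @param concentration_pct Amine concentration, % w/w (typical 0.5-2.5).
#' @param Vr_cm3 Applied solution volume, cm^3 (default 3; solution
#'   density is taken as 1 g/cm^3 so this is also the solution mass in g).
#' @param amine An [alcoholamine_spec()].
#' @param sebum A [sebum_composition()].
#' @param geometry A [tube_geometry()].
#' @param calibration A [pixel_calibration()] used when rendering images.
#' @param rate_k First-order rate constant, per minute; `NULL` (default)
#'   selects `0.03 / concentration_pct`, so dilute solutions exhaust
#'   their amine and plateau well before the end of a four-hour
#'   observation while concentrated ones are still reacting at 240 min.
#' @param max_reacted_fraction Ceiling on the reacted fraction of the
#'   initial amine mass; `NULL` (default) selects 0.95 at or below
#'   `plug_threshold_pct` and 0.80 above it.
#' @param plug_threshold_pct Concentration above which the plug regime
#'   applies (default 2.0).
#' @param water_binding_factor Observed/stoichiometric layer volume ratio
#'   (>= 1, default 2.5).
#' @param noise_sd_ph SD of Gaussian pH noise (default 0.01, the pH-meter
#'   accuracy).
#' @param noise_sd_height_mm SD of Gaussian height noise per replicate
#'   (default 0.05).
#' @param duration_min Observation length, minutes (default 240).
#' @param dt_min Sampling interval, minutes (default 1).
#' @param n_replicates Number of optical replicates (default 4).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(concentration_pct = 2.0,
                              Vr_cm3 = 3,
                              amine = alcoholamine_spec(),
                              sebum = sebum_composition(),
                              geometry = tube_geometry(),
                              calibration = pixel_calibration(),
                              rate_k = NULL,
                              max_reacted_fraction = NULL,
                              plug_threshold_pct = 2.0,
                              water_binding_factor = 2.5,
                              noise_sd_ph = 0.01,
                              noise_sd_height_mm = 0.05,
                              duration_min = 240,
                              dt_min = 1,
                              n_replicates = 4) {
  if (!is.finite(concentration_pct) || concentration_pct <= 0)
    stop("concentration_pct must be positive")
  if (is.null(rate_k)) rate_k <- 0.03 / concentration_pct
  if (!is.finite(rate_k) || rate_k <= 0) stop("rate_k must be positive")
  if (is.null(max_reacted_fraction))
    max_reacted_fraction <-
      if (concentration_pct > plug_threshold_pct) 0.80 else 0.95
  if (max_reacted_fraction <= 0 || max_reacted_fraction >= 1)
    stop("max_reacted_fraction must lie in (0, 1)")
  if (water_binding_factor < 1)
    stop("water_binding_factor must be >= 1")
  if (noise_sd_ph < 0 || noise_sd_height_mm < 0)
    stop("noise SDs must be non-negative")
  if (duration_min <= 0 || dt_min <= 0 || n_replicates < 1)
    stop("invalid duration, sampling interval or replicate count")
  structure(list(concentration_pct = concentration_pct, Vr_cm3 = Vr_cm3,
                 amine = amine, sebum = sebum, geometry = geometry,
                 calibration = calibration, rate_k = rate_k,
                 max_reacted_fraction = max_reacted_fraction,
                 plug_threshold_pct = plug_threshold_pct,
                 water_binding_factor = water_binding_factor,
                 noise_sd_ph = noise_sd_ph,
                 noise_sd_height_mm = noise_sd_height_mm,
                 duration_min = duration_min, dt_min = dt_min,
                 n_replicates = n_replicates),
            class = "simulation_config")
}

# Independent sub-seed per output stream, derived from the master seed so
# adding one stream never perturbs another. Kept below 2^31.
.stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + stream * 7919) %% 2147483647)
}

#' Simulate one penetration experiment
#'
#' Generates a self-consistent synthetic run from a
#' [simulation_config()]: the reacted amine mass follows a first-order
#' approach to its ceiling; the undissociated amine concentration and
#' hence the pH follow from the weak-base equilibrium; the true reacted
#' sebum volume follows from the neutralization stoichiometry (computed
#' inline, independently of the analysis chain, so recovery tests are not
#' circular); penetration height is that volume spread over the tube
#' cross-section, and the increase height is
#' `(water_binding_factor - 1)` times the penetration height. Turbidity
#' grows with time and scales inversely with concentration. Each output
#' stream draws from its own seeded noise stream.
#'
#' @param config A [simulation_config()].
#' @param seed Integer master seed; all outputs are bit-reproducible for
#'   a fixed config + seed.
#' @return A list with elements `ph` ([ph_series()]), `heights`
#'   ([height_series_set()]), `turbidity` ([turbidity_series()]) and
#'   `truth` (data frame of class `simulation_truth`: `time_min`,
#'   `m_zp_g`, `v_s_mm3`, `h_penetration_mm`, `h_increase_mm`,
#'   `turbidity`).
#' @examples
#' run <- simulate_reaction(simulation_config(concentration_pct = 1), seed = 1)
#' head(run$truth)
#' @export
simulate_reaction <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  t <- seq(0, config$duration_min, by = config$dt_min)
  M <- config$amine$molar_mass
  Vr_dm3 <- config$Vr_cm3 / 1000
  m_z0 <- config$concentration_pct / 100 * config$Vr_cm3  # g, density ~1
  m_max <- config$max_reacted_fraction * m_z0
  m_zp <- m_max * (1 - exp(-config$rate_k * t))
  Cb <- (m_z0 - m_zp) / (M * Vr_dm3)

  # ground-truth stoichiometry, written out in one expression
  f_st <- config$sebum$fractions[["stearic_acid"]]
  d_g_mm3 <- config$sebum$density_mg_per_mm3 * 1e-3
  v_s <- m_zp * (config$sebum$stearic_molar_mass / M) / f_st / d_g_mm3
  h_p <- v_s / (pi * config$geometry$radius_mm^2)
  h_i <- (config$water_binding_factor - 1) * h_p

  ph_true <- ph_of_weak_base(Cb, config$amine$constants)
  set.seed(.stream_seed(seed, 1L))
  ph_obs <- ph_true + stats::rnorm(length(t), 0, config$noise_sd_ph)
  ph_obs <- pmin(pmax(ph_obs, 1e-3), 13.999)

  set.seed(.stream_seed(seed, 2L))
  reps <- lapply(seq_len(config$n_replicates), function(k) {
    data.frame(
      time_min = t,
      h_penetration_mm = pmax(
        h_p + stats::rnorm(length(t), 0, config$noise_sd_height_mm), 0),
      h_increase_mm = pmax(
        h_i + stats::rnorm(length(t), 0, config$noise_sd_height_mm), 0))
  })

  # turbidity: monotone rise, amplitude inversely related to concentration
  turb_true <- 0.28 / config$concentration_pct *
    (1 - exp(-t / 90))
  set.seed(.stream_seed(seed, 3L))
  turb_obs <- turb_true  # kept noise-free: a qualitative trend stream

  lab <- sprintf("%.1f%%", config$concentration_pct)
  truth <- structure(
    data.frame(time_min = t, m_zp_g = m_zp, v_s_mm3 = v_s,
               h_penetration_mm = h_p, h_increase_mm = h_i,
               turbidity = turb_true),
    class = c("simulation_truth", "data.frame"))
  list(
    ph = ph_series(t, ph_obs, concentration_label = lab),
    heights = height_series_set(reps, concentration_label = lab),
    turbidity = turbidity_series(t / 60, turb_obs,
                                 config$concentration_pct),
    truth = truth
  )
}

#' Render a synthetic grayscale tube image
#'
#' Draws the three optical zones as horizontal bands: solution (~128)
#' above, the bright reacted band (~220) spanning `increase_height_mm`
#' above and `penetration_depth_mm` below the baseline row, and intact
#' sebum (~30) below, with seeded Gaussian pixel noise clamped to
#' [0, 255].
#'
#' @param heights A [layer_heights()] object.
#' @param geometry A [tube_geometry()] (frame height defaults to the
#'   sebum column plus solution headroom).
#' @param calibration A [pixel_calibration()].
#' @param noise_sd Pixel noise SD in intensity units (default 5).
#' @param seed Integer seed for the pixel noise.
#' @param width_px Image width in pixels (default 64).
#' @param height_px Optional frame height in pixels; the default sizes
#'   the frame to fit. Explicit frames too small for the bands raise an
#'   error.
#' @return A [tube_image()].
#' @export
render_tube_image <- function(heights, geometry = tube_geometry(),
                              calibration = pixel_calibration(),
                              noise_sd = 5, seed = 1, width_px = 64,
                              height_px = NULL) {
  stopifnot(inherits(heights, "layer_heights"),
            inherits(calibration, "pixel_calibration"))
  ppm <- calibration$pixels_per_mm
  h_i_px <- as.integer(round(heights$increase_height_mm * ppm))
  h_p_px <- as.integer(round(heights$penetration_depth_mm * ppm))
  pad <- 25L
  if (is.null(height_px)) {
    n_above <- h_i_px + pad
    height_px <- n_above + h_p_px + pad
  } else {
    n_above <- h_i_px + pad
    if (n_above + h_p_px + pad > height_px)
      stop("layer heights exceed the image frame")
  }
  b <- n_above + 1L
  img <- matrix(128, nrow = height_px, ncol = width_px)
  if (h_i_px > 0) img[(b - h_i_px):(b - 1L), ] <- 220
  if (h_p_px > 0) img[b:(b + h_p_px - 1L), ] <- 220
  img[(b + h_p_px):height_px, ] <- 30
  set.seed(seed)
  img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                      nrow = height_px)
  img <- pmin(pmax(img, 0), 255)
  tube_image(img, baseline_row = b, calibration = calibration)
}
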