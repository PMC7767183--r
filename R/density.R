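# Pycnometer density determination of model sebum.

#' Pycnometer weighing record
#'
#' The three weighings of the pharmacopoeial pycnometer method: the sebum
#' sample alone (`m1`), the water-filled pycnometer (`w`), and the
#' pycnometer holding the sebum topped up with water (`m2`), all at
#' 20 degrees C. The displaced water mass `w + m1 - m2` must be positive.
#'
#' @param m1 Sebum mass, g (>= 0).
#' @param w Mass of the pycnometer filled with water, g (>= 0).
#' @param m2 Mass of the pycnometer with sebum plus topped-up water, g
#'   (>= 0).
#' @param water_density Density of water at 20 degrees C, g/cm^3
#'   (default 0.997).
#' @param air_correction Additive correction for weighing in air
#'   (default 0.0012).
#' @return An object of class `pycnometer_measurement`.
#' @export
pycnometer_measurement <- function(m1, w, m2, water_density = 0.997,
                                   air_correction = 0.0012) {
  vals <- c(m1 = m1, w = w, m2 = m2)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all masses must be non-negative and finite")
  if (w + m1 - m2 <= 0)
    stop("displaced water mass (w + m1 - m2) must be positive")
  structure(list(m1 = m1, w = w, m2 = m2, water_density = water_density,
                 air_correction = air_correction),
            class = "pycnometer_measurement")
}

#' Density of model sebum from pycnometer weighings
#'
#' Standard pharmacopoeial water-displacement formula:
#' \deqn{d = \frac{m_1}{w + m_1 - m_2}\times 0.997 + 0.0012}
#' where the denominator is the mass of water displaced by the sample,
#' 0.997 g/cm^3 is the density of water at 20 degrees C and 0.0012 is the
#' air-buoyancy correction applied additively, as in the standard method.
#'
#' @param meas A [pycnometer_measurement()].
#' @return Density in g/cm^3 (numerically equal to mg/mm^3).
#' @examples
#' pycnometer_density(pycnometer_measurement(2.000, 25.000, 24.621))
#' @export
pycnometer_density <- function(meas) {
  stopifnot(inherits(meas, "pycnometer_measurement"))
  meas$m1 * meas$water_density / (meas$w + meas$m1 - meas$m2) +
    meas$air_correction
}

#' Synthesize pycnometer weighings for a target density
#'
#' Inverts the pycnometer formula for `m2` given the target density and
#' the other two weighings:
#' `m2 = w + m1 - m1 * water_density / (d - air_correction)`.
#' [pycnometer_density()] applied to the result returns the target exactly
#' (to floating precision). The inversion is deterministic; a `seed`
#' argument is accepted for interface uniformity with the other
#' generators and ignored.
#'
#' @param target_density Target density, g/cm^3; must exceed the air
#'   correction.
#' @param m1 Sebum mass, g (default 2).
#' @param w Water-filled pycnometer mass, g (default 25).
#' @param seed Ignored (deterministic inversion).
#' @return A [pycnometer_measurement()].
#' @examples
#' pycnometer_density(synth_pycnometer(0.842))
#' @export
synth_pycnometer <- function(target_density, m1 = 2, w = 25, seed = NULL) {
  if (!is.finite(target_density) || target_density <= 0.0012)
    stop("target_density must exceed the air correction 0.0012")
  m2 <- w + m1 - m1 * 0.997 / (target_density - 0.0012)
  if (m2 < m1)
    stop("infeasible weighing: topped-up water mass would be negative")
  pycnometer_measurement(m1, w, m2)
}
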