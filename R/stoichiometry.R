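# Mass/volume bookkeeping from a pH change to a reacted sebum volume.
#
# Unit conventions (explicit, never implicit): masses in g, molar
# concentrations in mol/dm^3, solution volumes in dm^3, sebum volumes in
# mm^3, sebum density stored in mg/mm^3 (= g/cm^3).

#' Unit conversion constants
#'
#' `MM3_PER_DM3` (1 dm^3 = 1e6 mm^3) and `G_PER_MG` (1 mg = 1e-3 g) are the
#' only unit conversions used by the stoichiometric chain.
#' @name unit-constants
#' @keywords internal
MM3_PER_DM3 <- 1e6
G_PER_MG <- 1e-3

#' Model skin sebum composition
#'
#' Component mass fractions and bulk density of the model sebum mixture.
#' The defaults describe the standard five-component model: triglycerides
#' 34%, stearic acid 24% (the free fatty acid consumed by the
#' neutralization), lanolin 26%, squalene 12%, cholesterol 4%, with a
#' pycnometer-determined density of 0.842 mg/mm^3.
#'
#' @param fractions Named numeric vector of mass fractions summing to 1;
#'   must contain a positive `stearic_acid` entry, the divisor that scales
#'   reacted acid mass back up to reacted sebum mass.
#' @param density_mg_per_mm3 Sebum bulk density, mg/mm^3 (> 0).
#' @param stearic_molar_mass Molar mass of stearic acid, g/mol
#'   (default 284.48).
#' @return An object of class `sebum_composition`.
#' @examples
#' sebum_composition()$fractions["stearic_acid"]
#' @export
sebum_composition <- function(fractions = c(triglycerides = 0.34,
                                            stearic_acid = 0.24,
                                            lanolin = 0.26,
                                            squalene = 0.12,
                                            cholesterol = 0.04),
                              density_mg_per_mm3 = 0.842,
                              stearic_molar_mass = 284.48) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)))
  if (any(fractions < 0) || any(fractions > 1))
    stop("all mass fractions must lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("mass fractions must sum to 1 (got ", format(sum(fractions)), ")")
  if (!("stearic_acid" %in% names(fractions)) ||
      fractions[["stearic_acid"]] <= 0)
    stop("a positive stearic_acid fraction is required")
  if (!is.finite(density_mg_per_mm3) || density_mg_per_mm3 <= 0)
    stop("density must be positive")
  if (!is.finite(stearic_molar_mass) || stearic_molar_mass <= 0)
    stop("stearic_molar_mass must be positive")
  structure(list(fractions = fractions,
                 density_mg_per_mm3 = density_mg_per_mm3,
                 stearic_molar_mass = stearic_molar_mass),
            class = "sebum_composition")
}

#' Mass of undissociated alcoholamine in solution
#'
#' \deqn{m_z = C_b \cdot M \cdot V_r}
#'
#' @param Cb Molar base concentration, mol/dm^3 (>= 0, vectorized).
#' @param amine An [alcoholamine_spec()].
#' @param Vr Solution volume in dm^3 (> 0); the default 0.003 dm^3 matches
#'   a 3 cm^3 application.
#' @return Mass in g.
#' @examples
#' undissociated_amine_mass(0.069183, alcoholamine_spec(), 0.003)
#' @export
undissociated_amine_mass <- function(Cb, amine = alcoholamine_spec(),
                                     Vr = 0.003) {
  stopifnot(is.numeric(Cb), inherits(amine, "alcoholamine_spec"),
            is.numeric(Vr), length(Vr) == 1L)
  if (any(!is.finite(Cb)) || any(Cb < 0)) stop("Cb must be non-negative")
  if (!is.finite(Vr) || Vr <= 0) stop("Vr must be positive")
  Cb * amine$molar_mass * Vr
}

#' Mass of alcoholamine consumed between two time points
#'
#' `m_zp = m_z0 - m_zn`. A negative difference means the pH rose between
#' the two time points (e.g. an electrode transient caused by flotation of
#' reacted sebum particles); under the default `"clamp"` policy such values
#' are returned as 0 and flagged in the `"clamped"` attribute, while
#' `"raw"` preserves them for diagnostics.
#'
#' @param m_z0 Undissociated amine mass at the baseline time, g (>= 0).
#' @param m_zn Undissociated amine mass at the later time, g (>= 0,
#'   vectorized).
#' @param policy `"clamp"` (default) or `"raw"`.
#' @return Reacted amine mass in g, with a logical attribute `"clamped"`
#'   marking entries that were negative before clamping.
#' @examples
#' reacted_amine_mass(0.021822, 0.0021822)
#' @export
reacted_amine_mass <- function(m_z0, m_zn, policy = c("clamp", "raw")) {
  policy <- match.arg(policy)
  stopifnot(is.numeric(m_z0), is.numeric(m_zn))
  if (any(!is.finite(m_z0)) || any(m_z0 < 0) ||
      any(!is.finite(m_zn)) || any(m_zn < 0))
    stop("masses must be non-negative")
  out <- m_z0 - m_zn
  clamped <- out < 0
  if (policy == "clamp") out[clamped] <- 0
  attr(out, "clamped") <- clamped
  out
}

#' Mass of stearic acid neutralized by the reacted alcoholamine
#'
#' The neutralization R1-COOH + R2-NH2 -> R1-COO-[NH3+-R2] is 1:1 in moles,
#' so the physically consistent conversion is
#' `m_kp = m_zp * M_acid / M_amine` (`direction = "physical"`, the
#' default). The transposed ratio `m_zp * M_amine / M_acid`
#' (`direction = "as_printed"`) is retained for audit only: at the volume
#' scales this assay produces, it implies more reacted amine than was ever
#' applied (see the mass-balance discussion in the package vignette).
#'
#' @param m_zp Reacted alcoholamine mass, g (>= 0, vectorized).
#' @param amine_molar_mass Amine molar mass, g/mol (default AMPD 105.14).
#' @param acid_molar_mass Acid molar mass, g/mol (default stearic 284.48).
#' @param direction `"physical"` (default) or `"as_printed"`.
#' @return Reacted acid mass in g.
#' @examples
#' reacted_acid_mass(0.019640)  # ~0.05314 g
#' @export
reacted_acid_mass <- function(m_zp, amine_molar_mass = 105.14,
                              acid_molar_mass = 284.48,
                              direction = c("physical", "as_printed")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(m_zp))
  if (any(!is.finite(m_zp)) || any(m_zp < 0))
    stop("m_zp must be non-negative")
  if (direction == "physical") m_zp * acid_molar_mass / amine_molar_mass
  else m_zp * amine_molar_mass / acid_molar_mass
}

#' Reacted sebum mass from reacted stearic acid mass
#'
#' Scales the neutralized free-fatty-acid mass up to whole-sebum mass via
#' the stearic acid mass fraction: `m_s = m_kp / f_stearic`.
#'
#' @param m_kp Reacted stearic acid mass, g (>= 0, vectorized).
#' @param sebum A [sebum_composition()].
#' @return Reacted sebum mass in g.
#' @export
reacted_sebum_mass <- function(m_kp, sebum = sebum_composition()) {
  stopifnot(is.numeric(m_kp), inherits(sebum, "sebum_composition"))
  if (any(!is.finite(m_kp)) || any(m_kp < 0))
    stop("m_kp must be non-negative")
  m_kp / sebum$fractions[["stearic_acid"]]
}

#' Reacted sebum volume from reacted sebum mass
#'
#' `V_s = m_s / d_s`, with the density converted from mg/mm^3 to g/mm^3 so
#' that gram masses yield volumes in mm^3.
#'
#' @param m_s Reacted sebum mass, g (>= 0, vectorized).
#' @param sebum A [sebum_composition()].
#' @return Reacted sebum volume in mm^3.
#' @export
reacted_sebum_volume <- function(m_s, sebum = sebum_composition()) {
  stopifnot(is.numeric(m_s), inherits(sebum, "sebum_composition"))
  if (any(!is.finite(m_s)) || any(m_s < 0)) stop("m_s must be non-negative")
  m_s / (sebum$density_mg_per_mm3 * G_PER_MG)
}

#' Reacted sebum volume from a pH drop (full stoichiometric chain)
#'
#' Composes the five-step chain pH -> concentration -> amine mass ->
#' reacted amine -> reacted acid -> reacted sebum mass -> volume:
#' concentrations at `ph0` and `phn` from [conc_from_ph()], masses via
#' [undissociated_amine_mass()], their difference via
#' [reacted_amine_mass()], then [reacted_acid_mass()],
#' [reacted_sebum_mass()] and [reacted_sebum_volume()].
#'
#' @param ph0 Baseline pH (single value, at the moment of application).
#' @param phn Later pH (vectorized over time points).
#' @param amine An [alcoholamine_spec()]; its constants drive the
#'   equilibrium inversion.
#' @param Vr Solution volume, dm^3 (default 0.003).
#' @param sebum A [sebum_composition()].
#' @param direction Passed to [reacted_acid_mass()].
#' @param policy Passed to [reacted_amine_mass()].
#' @return Reacted sebum volume(s) in mm^3, carrying the `"clamped"`
#'   attribute from [reacted_amine_mass()].
#' @examples
#' ph_to_reacted_volume(10.80, 10.30)  # ~263 mm^3
#' @export
ph_to_reacted_volume <- function(ph0, phn, amine = alcoholamine_spec(),
                                 Vr = 0.003, sebum = sebum_composition(),
                                 direction = c("physical", "as_printed"),
                                 policy = c("clamp", "raw")) {
  direction <- match.arg(direction)
  policy <- match.arg(policy)
  stopifnot(length(ph0) == 1L)
  cb0 <- conc_from_ph(ph0, amine$constants)
  cbn <- conc_from_ph(phn, amine$constants)
  m_z0 <- undissociated_amine_mass(cb0, amine, Vr)
  m_zn <- undissociated_amine_mass(cbn, amine, Vr)
  m_zp <- reacted_amine_mass(m_z0, m_zn, policy = policy)
  m_kp <- reacted_acid_mass(m_zp, amine$molar_mass,
                            sebum$stearic_molar_mass, direction = direction)
  v <- reacted_sebum_volume(reacted_sebum_mass(m_kp, sebum), sebum)
  attr(v, "clamped") <- attr(m_zp, "clamped")
  v
}
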