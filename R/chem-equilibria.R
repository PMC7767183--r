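# Weak-base pH equilibrium, its inversion, and salt-hydrolysis equilibrium.
# pH conventions: all logarithms are base 10; pX = -log10(X).

#' Acid-base equilibrium constants
#'
#' Bundle of the dissociation exponents needed by the weak-base pH formulas
#' and by the salt-hydrolysis equilibrium. `pKa` is optional and only needed
#' for the hydrolysis operations ([hydrolysis_constant()],
#' [salt_solution_ph()]).
#'
#' @param pKb Base dissociation exponent, \eqn{-\log_{10} K_b}. Must be > 0.
#' @param pKa Acid dissociation exponent, or `NA` when no conjugate weak
#'   acid is involved.
#' @param pKw Exponent of the ionic product of water; defaults to 14.0
#'   (25 degrees C).
#' @return An object of class `acid_base_constants`: a list with elements
#'   `pKw`, `pKb`, `pKa` and the derived constants `Kw`, `Kb`, `Ka`
#'   (each `10^-pX`).
#' @examples
#' acid_base_constants(pKb = 5.24)
#' @export
acid_base_constants <- function(pKb, pKa = NA_real_, pKw = 14.0) {
  stopifnot(is.numeric(pKb), length(pKb) == 1L, is.finite(pKb),
            is.numeric(pKw), length(pKw) == 1L, is.finite(pKw))
  if (pKw <= 0) stop("pKw must be positive")
  if (pKb <= 0) stop("pKb must be positive")
  if (!is.na(pKa) && !is.finite(pKa)) stop("pKa must be finite or NA")
  structure(
    list(pKw = pKw, pKb = pKb, pKa = pKa,
         Kw = 10^(-pKw), Kb = 10^(-pKb),
         Ka = if (is.na(pKa)) NA_real_ else 10^(-pKa)),
    class = "acid_base_constants"
  )
}

#' @export
print.acid_base_constants <- function(x, ...) {
  cat("Acid-base constants: pKw =", x$pKw, " pKb =", x$pKb,
      " pKa =", ifelse(is.na(x$pKa), "-", format(x$pKa)), "\n")
  invisible(x)
}

#' Alcoholamine specification
#'
#' Identity and physical constants of the weak base applied over the sebum
#' layer. The default describes AMPD (2-amino-2-methyl-1,3-propanediol),
#' molar mass 105.14 g/mol, pKa = 8.76 at 25 degrees C hence pKb = 5.24.
#'
#' Two slightly different AMPD basicity values circulate: pKa 8.76 implies
#' pKb 5.24, while Kb = 6.309e-6 implies pKb ~ 5.20. Both are shipped (see
#' [ampd_constants()]); the pH-method default is pKb = 5.24, and the
#' hydrolysis functions take constants explicitly so the two are never
#' silently mixed.
#'
#' @param name Character label for the base.
#' @param molar_mass Molar mass in g/mol; must be > 0.
#' @param constants An [acid_base_constants()] object.
#' @return An object of class `alcoholamine_spec`.
#' @examples
#' ampd <- alcoholamine_spec()
#' ampd$molar_mass
#' @export
alcoholamine_spec <- function(name = "AMPD",
                              molar_mass = 105.14,
                              constants = acid_base_constants(pKb = 5.24)) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(molar_mass), length(molar_mass) == 1L)
  if (!is.finite(molar_mass) || molar_mass <= 0)
    stop("molar_mass must be positive")
  if (!inherits(constants, "acid_base_constants"))
    stop("constants must be an acid_base_constants object")
  structure(list(name = name, molar_mass = molar_mass, constants = constants),
            class = "alcoholamine_spec")
}

#' Named AMPD constant sets
#'
#' Returns one of the two published AMPD basicity parameterizations:
#' `"pka876"` (pKa 8.76 at 25 degrees C, hence pKb = 14 - 8.76 = 5.24; the
#' pH-method default) or `"hydrolysis"` (Kb = 6.309e-6, pKb ~ 5.200, paired
#' with stearic acid Ka = 1.778e-5, pKa ~ 4.750; the set used in the
#' salt-hydrolysis discussion).
#'
#' @param which `"pka876"` or `"hydrolysis"`.
#' @return An [acid_base_constants()] object.
#' @examples
#' ampd_constants("hydrolysis")$Kb
#' @export
ampd_constants <- function(which = c("pka876", "hydrolysis")) {
  which <- match.arg(which)
  switch(which,
    pka876 = acid_base_constants(pKb = 5.24),
    hydrolysis = acid_base_constants(pKb = -log10(6.309e-6),
                                     pKa = -log10(1.778e-5))
  )
}

#' pH of a weak-base solution
#'
#' For a weak base of total molar concentration `Cb`,
#' \deqn{pH = pK_w - \tfrac{1}{2}(pK_b - \log_{10} C_b).}
#' Valid in the usual dilute regime where the base dominates the proton
#' balance; activity corrections are not applied.
#'
#' @param Cb Total molar base concentration, mol/dm^3; must be > 0
#'   (vectorized).
#' @param constants An [acid_base_constants()] object.
#' @return pH value(s).
#' @examples
#' ph_of_weak_base(0.1, acid_base_constants(pKb = 5.24))  # 10.88
#' @seealso [conc_from_ph()] for the exact algebraic inverse.
#' @export
ph_of_weak_base <- function(Cb, constants) {
  stopifnot(is.numeric(Cb), inherits(constants, "acid_base_constants"))
  if (any(!is.finite(Cb)) || any(Cb <= 0))
    stop("Cb must be positive and finite")
  constants$pKw - 0.5 * (constants$pKb - log10(Cb))
}

#' Molar base concentration from measured pH
#'
#' Algebraic inverse of [ph_of_weak_base()]:
#' \deqn{C_b = 10^{2\,pH - 2\,pK_w + pK_b}.}
#' A pH at or above pKw would imply a nonphysical concentration
#' (Cb >= 10^pKb); such inputs are flagged with a warning rather than an
#' error so that noisy series can still be processed.
#'
#' @param pH Measured solution pH (vectorized); must be positive.
#' @param constants An [acid_base_constants()] object.
#' @return Molar concentration(s), mol/dm^3.
#' @examples
#' conc_from_ph(10.88, acid_base_constants(pKb = 5.24))  # 0.1
#' @export
conc_from_ph <- function(pH, constants) {
  stopifnot(is.numeric(pH), inherits(constants, "acid_base_constants"))
  if (any(!is.finite(pH)) || any(pH <= 0))
    stop("pH must be positive and finite")
  if (any(pH >= constants$pKw))
    warning("pH >= pKw: implied concentration is nonphysical (Cb >= 10^pKb)")
  10^(2 * pH - 2 * constants$pKw + constants$pKb)
}

#' Hydrolysis constant of a salt of a weak acid and a weak base
#'
#' \deqn{K_h = \frac{K_w}{K_a \cdot K_b}}
#' For AMPD stearate (Ka = 1.778e-5, Kb = 6.309e-6, Kw = 1e-14) this
#' evaluates to about 8.9e-5, i.e. hydrolysis of the formed amine soap is
#' negligible on the hours timescale of a penetration experiment.
#'
#' @param Ka Acid dissociation constant (> 0).
#' @param Kb Base dissociation constant (> 0).
#' @param Kw Ionic product of water (> 0, default 1e-14).
#' @return The hydrolysis constant Kh.
#' @examples
#' hydrolysis_constant(Ka = 1.778e-5, Kb = 6.309e-6)
#' @export
hydrolysis_constant <- function(Ka, Kb, Kw = 1e-14) {
  stopifnot(is.numeric(Ka), is.numeric(Kb), is.numeric(Kw))
  if (any(!is.finite(c(Ka, Kb, Kw))) || any(c(Ka, Kb, Kw) <= 0))
    stop("Ka, Kb and Kw must all be positive")
  Kw / (Ka * Kb)
}

#' pH of an aqueous solution of a weak-acid / weak-base salt
#'
#' \deqn{pH = \tfrac{1}{2}(pK_w + pK_a - pK_b)}
#' Independent of the salt concentration to first order. For AMPD stearate
#' the result is slightly acidic because the acid is marginally stronger
#' than the base.
#'
#' @param constants An [acid_base_constants()] object with `pKa` present.
#' @return The salt solution pH.
#' @examples
#' salt_solution_ph(ampd_constants("hydrolysis"))  # 6.775
#' @export
salt_solution_ph <- function(constants) {
  stopifnot(inherits(constants, "acid_base_constants"))
  if (is.na(constants$pKa))
    stop("pKa is required for the salt solution pH")
  0.5 * (constants$pKw + constants$pKa - constants$pKb)
}
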