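---
title: "Two routes to the reacted sebum volume: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two routes to the reacted sebum volume: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sebumetry)
```

## The system

Alcoholamines — weak organic bases carrying hydroxyl groups, such as AMPD
(2-amino-2-methyl-1,3-propanediol, molar mass 105.14 g/mol, pKa 8.76 at
25 °C) — neutralize the free fatty acids in skin sebum to form amine
soaps. In the model experiment this package analyses, an aqueous AMPD
solution (0.5–2.5 % w/w, 3 cm³) sits on a column of model sebum
(triglycerides 34 %, stearic acid 24 %, lanolin 26 %, squalene 12 %,
cholesterol 4 %; density 0.842 mg/mm³) in a 16 mm tube. The
neutralization

$$\mathrm{R_1{-}COOH + R_2{-}NH_2 \rightarrow R_1{-}COO^-\,[NH_3^+{-}R_2]}$$

etches a bright reacted layer into the sebum surface and simultaneously
consumes base from the solution, so the amount of reacted sebum can be
read out in two independent ways:

* **Optical method** — measure the depth of the etched layer below the
  initial sebum level (*penetration depth*) and the height of products
  risen above it (*increase height*), convert pixel counts to mm via the
  calibration, and to volumes via $V = \pi r^2 h$.
* **pH method** — invert the weak-base equilibrium
  $\mathrm{pH} = pK_w - \tfrac12(pK_b - \log_{10} C_b)$ to get
  $C_b = 10^{\,2\mathrm{pH} - 2pK_w + pK_b}$, convert the drop in
  undissociated base between $t_0$ and $t_n$ to a reacted amine mass
  ($m_z = C_b M V_r$, $m_{zp} = m_{z0} - m_{zn}$), then through the 1:1
  stoichiometry to reacted stearic acid
  ($m_{kp} = m_{zp} \cdot 284.48/105.14$), up to whole sebum via the 24 %
  stearic fraction, and to a volume via the sebum density.

`compare_methods()` takes the difference (optical − pH-derived) at a
reference time (default 216 min). A *negative* difference — the solution
lost more base than the visible etching accounts for — signals a rigid
product plug at the interface.

## Equilibrium assumptions

All logarithms are base 10. $pK_w$ defaults to 14.0 (25 °C) and is
configurable. Activity coefficients and ionic strength are deliberately
ignored: the solutions are dilute and the reacting mixture too complex
for a meaningful ionic-strength correction, so the inferred
concentrations are equilibrium estimates, not activities. Hydrolysis of
the formed amine soap is neglected within the four-hour observation
window; the package's own hydrolysis module justifies this: with
$K_a = 1.778\times10^{-5}$ (stearic acid) and $K_b = 6.309\times10^{-6}$
(AMPD), $K_h = K_w/(K_a K_b) \approx 8.9\times10^{-5}$ and the salt
solution pH $\tfrac12(pK_w + pK_a - pK_b) \approx 6.78$ — a nearly
neutral, essentially unhydrolysed salt on this timescale.

Two AMPD basicity values circulate: pKa 8.76 gives pKb 5.24, while
$K_b = 6.309\times10^{-6}$ gives pKb ≈ 5.200. Both ship as named sets
(`ampd_constants("pka876")`, `ampd_constants("hydrolysis")`). The pH
method defaults to 5.24; the hydrolysis functions take explicit
constants. They are never mixed silently, because a 0.04 pKb shift moves
every inferred concentration by ~10 %.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `Vr_cm3` | 3 | cm³ | applied solution volume; mass and volume treated as equal (density ≈ 1) |
| `radius_mm` | 8 | mm | 16 mm tube diameter |
| `pixels_per_mm` | 50 | px/mm | fifty-fold magnification; 1 px = 0.02 mm is the optical resolution |
| `density_mg_per_mm3` | 0.842 | mg/mm³ | pycnometer-determined model sebum density (shipped as a constant; the underlying weighings are not published, so it is not recomputed) |
| `ph_accuracy` | 0.01 | pH | meter accuracy; propagated to an SD for single-run pH series |
| `reference_time_min` | 216 | min | comparison time of the packaged reference table |
| `eq8_direction` | `"physical"` | — | see below |
| `clamp_policy` | `"clamp"` | — | negative reacted masses (pH rose) clamp to 0 with a flag; `"raw"` keeps them for diagnosing electrode transients |

**The stoichiometric conversion direction.** The acid/amine molar-mass
ratio can be typeset ambiguously. The package defaults to the physically
consistent direction $m_{kp} = m_{zp} \cdot 284.48/105.14$ (1:1 moles).
The deciding argument is a mass balance, asserted in the test suite: at
the reference-table volume scales the physical direction implies at most
~12 mg of reacted AMPD out of the 15–75 mg applied, while the transposed
ratio would require more AMPD than some solutions ever contained. The
literal reading remains selectable (`direction = "as_printed"`) for
audit.

**Pycnometer formula.** The density expression is implemented in its
standard pharmacopoeial form
$d = m_1 \cdot 0.997/(w + m_1 - m_2) + 0.0012$, with 0.997 g/cm³ the
water density at 20 °C and 0.0012 an additive air-buoyancy correction.
Placing the correction additively (rather than inside the product)
follows the standard method; the alternative bracketing would change the
result by under 0.2 % but is not what the symbol definitions describe.
Note the direction of the $m_2$ dependence: a larger $m_2$ means less
displaced water, a smaller sample volume, and therefore a *higher*
density.

**SD for single-run pH series.** A pH series measured once still gets an
uncertainty: the chain is evaluated at $\mathrm{pH} \pm 0.01$ and half
the spread is reported. This is a documented modelling choice for how a
replicate-free run can carry an SD, not a claim about any particular
published error bar.

## The synthetic generator

`simulate_reaction()` produces a self-consistent experiment with known
ground truth so that every pipeline stage can be tested without
laboratory data. The reacted amine mass follows a first-order approach
to a ceiling,

$$m_{zp}(t) = m_{\max}\,(1 - e^{-kt}), \qquad
  m_{\max} = f_{\max} \cdot m_{z0},$$

which is the simplest trajectory with the observed "fast, then slowing,
then stable" shape. It is a test harness, not a kinetic claim. From
$m_{zp}(t)$ the generator derives, in one inline expression independent
of the analysis code, the true reacted volume, the penetration height
(volume over the tube cross-section), the increase height
($(\text{water-binding factor} - 1) \times$ penetration height — amine
soaps bind water, which is why the optically visible layers outgrow the
stoichiometric volume), the equilibrium pH trajectory, and a turbidity
curve rising in time and scaled by $1/\text{concentration}$.

Defaults, chosen once to reproduce the qualitative phenomenology of the
concentration sweep:

* $k = 0.03/\text{concentration}_{\%}$ per minute — dilute solutions
  exhaust their amine and plateau well before 240 min; concentrated ones
  are still reacting when observation ends.
* $f_{\max} = 0.95$ at or below the plug threshold (2.0 %), 0.80 above
  it — near-complete conversion at low concentration, conversion limited
  by a dense product layer above the threshold.
* water-binding factor 2.5; pH noise SD 0.01 (the meter accuracy);
  height noise SD 0.05 mm per replicate; 4 replicates; 240 min at 1-min
  sampling.

With pKb 5.24 these defaults give starting pH ≈ 10.7 at 0.5 % decaying
to ≈ 10.2, inside the observed 10.5–10.9 → 9.7–10.3 envelope at low
concentrations; at 2.5 % the computed starting pH (≈ 11.07) sits
slightly above the measured ceiling, a reminder that the
activity-free equilibrium overestimates pH in stronger solutions. The
published per-concentration pH endpoints and the published pH-derived
volumes at 216 min are not mutually consistent under any single constant
set, so the generator follows the pH-range phenomenology rather than the
tabulated volumes.

What the generator does **not** emulate: diffusion-limited transport
through the growing product layer, meniscus optics, lens distortion or
lighting gradients, electrode transients from floating sebum particles
(these can be injected manually via `policy = "raw"` diagnostics), or
soap-decomposition kinetics on multi-day timescales. Passing recovery
tests therefore demonstrate that the analysis chain is a correct inverse
of the stated forward model — not that the forward model captures every
feature of a real tube.

Each output stream (pH noise, height noise, turbidity) draws from its
own sub-seed derived from the master seed, so adding a stream never
perturbs the others, and identical config + seed gives bit-identical
output.

## Image analysis choices

Synthetic tube images have three vertical zones — solution (~128),
reacted band (~220), intact sebum (~30) — classified by two fixed
thresholds (dark < 60, bright > 180). Fixed thresholds keep the
measurement deterministic and testable; with band contrasts of 90+ grey
levels and pixel noise SD 5, misclassification would require a > 8σ
excursion. Boundaries are found per column scanning from the baseline
row (first dark pixel downward, first solution pixel upward), aggregated
by the *lower* median across columns — robust to meniscus and wall
artifacts, with ties broken toward the baseline — and converted to mm in
a single final step so rounding happens once. A column whose zones are
out of order (dark above bright) raises an error; an image with no
bright band at the baseline returns zero heights with a
`no_reacted_band` flag rather than failing.

## Degenerate inputs and numerical conventions

* pH readings at or above $pK_w$ imply nonphysical concentrations and
  warn rather than stop.
* A pH that *rises* between baseline and a later point yields a negative
  reacted mass; clamped to zero and flagged by default.
* Replicate aggregation is mean ± sample SD ($n-1$); a single replicate
  reports `NA` SD.
* CSV writers emit a fixed column order and `%.17g` floats, so files are
  byte-stable and numeric round trips are exact.

## Known limitations and documented discrepancies

* The packaged 216-min reference table's 2.5 % column carries a published
  difference (121.77 mm³) that does not equal the difference of its own
  per-method entries (310.00 − 31.77 = 278.23 mm³). The package
  recomputes the subtraction and leaves the discrepancy documented;
  comparison tests exclude that column.
* The packaged hourly turbidity table contains one violation of the
  "turbidity decreases with concentration" trend, at hour 3 (the 1.0 %
  reading 0.269 is below the 1.5 % reading 0.294).
  `turbidity_trend_check()` reports it honestly; the test suite pins it
  as exactly one violation.
* Equilibrium inversion without activity corrections overestimates
  concentrations at the top of the range; the pH method is therefore
  most trustworthy for dilute solutions and relative comparisons.
* The initial sebum column is configured as 20 mm; descriptions of the
  sample geometry elsewhere (a "2 cm³ piece" vs. a 2 cm layer, ≈ 4 cm³
  in this tube) disagree, so the height is a config field, not a fact.

## Problem sizes in the test suite

The suite exercises the full 240-point series where the pipeline is
involved and smaller 120 min / 5 min-step configurations (25 points, 2
replicates) for the randomized-recovery loops: 20 seeded configurations
for pH-method recovery, 100 rendered images (32 px wide) for optical
recovery, and a 10⁶-cell voxel grid for the cylinder-volume oracle.
These sizes give the property checks comfortable coverage while keeping
the whole suite in the seconds range.
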