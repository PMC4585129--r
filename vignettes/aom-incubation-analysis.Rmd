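---
title: "Energetics, tracer accounting and growth assessment for AOM batch incubations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetics, tracer accounting and growth assessment for AOM batch incubations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aombatch)
```

## The scientific setting

Anaerobic oxidation of methane (AOM) in marine sediments is carried out by
anaerobic methanotrophic archaea (ANME) in consortia with sulfate-reducing
bacteria, with the net catabolism

$$\mathrm{CH_4 + SO_4^{2-} \rightarrow CO_2 + HS^- \;(+\,H_2O)}.$$

The ANME clades (ANME-1, ANME-2a/b, ANME-2c) occupy distinct sediment
horizons, plausibly set by the local methane, sulfate and sulfide
concentrations through the free energy the reaction can deliver. This
package implements the quantitative pipeline of a defined-condition batch
incubation study of that hypothesis: seven sulfate/sulfide/methane regimes
held at setpoints for 947 days, AOM activity read out by ¹³CH₄ labeling
from day 540, and clade growth assessed by qPCR at days 0 and 344.

## The energy model

The transformed Gibbs energy at in-situ concentrations is

$$\Delta_r G' = \Delta_r G^{\circ\prime} + RT \ln Q, \qquad
Q = \frac{[\mathrm{CO_2}][\mathrm{HS^-}]}{[\mathrm{CH_4}][\mathrm{SO_4^{2-}}]}.$$

Parameter choices, each a deliberate simplification:

* $\Delta_r G^{\circ\prime} = -21$ kJ mol⁻¹ CH₄, for methane as a gas
  molecule and products as CO₂ and HS⁻.
* **T = 293.15 K** in the $RT$ term, not the 15 °C incubation temperature.
  The dissolved-methane term is pinned to the solubility value of 1.31 mM,
  whose reference state is salinity 30 at 20 °C; using the matching
  temperature keeps the two terms consistent. We verified by direct
  evaluation that this choice reproduces every tabulated energy value of
  the study design to within ±0.05 kJ mol⁻¹; 288.15 K is available through
  `thermo_params(temperature_K = 288.15)`.
* Activities equal molar concentrations (coefficients 1, water activity 1);
  no ionic-strength or pH correction. Because the stoichiometry is
  1:1:1:1, $Q$ is dimensionless and mM concentrations enter directly.
* Total measured sulfide is treated entirely as HS⁻ — defensible at the
  medium pH of 7.2–7.5, where HS⁻ dominates — and no speciation model is
  applied to "total CO₂" either; both values are used as tabulated.
* The headspace overpressure of 0.5–1 bar is taken as negligible for
  methane solubility (`dissolved_methane()`); linear Henry scaling is
  available as an explicit extension flag.

Regime classification uses two thresholds on the signed energy scale:
growth-permissive at or below −19 kJ mol⁻¹ CH₄ (the estimated cost of one
proton translocation in sulfate reducers, i.e. the minimum biological
energy quantum), maintenance-only between −19 and −10.6 kJ mol⁻¹ (the
methanogen minimum). Boundary ties resolve to the more permissive class:
the methane-only condition sits at −19.2 kJ mol⁻¹ and is treated as
active, so a value exactly at a threshold counts as meeting it. Note a unit
ambiguity inherited from the literature: the −19 figure originates per mol
sulfate, but with 1:1 stoichiometry it is applied here per mol methane.

```{r}
energetics_table(incubation_conditions())[, c("id", "delta_g_label", "regime")]
```

## Tracer accounting

Mass-spectral deconvolution is upstream of this package: inputs are
two-isotopologue amounts (¹²C, ¹³C) per species, bottle and day. The
produced-¹³CO₂ readout is *baseline-anchored*: `percent_13co2()` reports
$100\,(f_{13}(t) - f_{13}(t_0))$ with $t_0$ the label-start day, which
makes it invariant to the natural-abundance background (natural-abundance
correction is therefore off by default in `isotope_fraction()`). The
label-dilution estimate `methane_oxidized()` divides produced ¹³CO₂ by the
labeled fraction of the methane pool (default 0.2/1.8 ≈ 0.111: the
headspace was topped to 1.6 bar with unlabeled CH₄ and then to 1.8 bar with
¹³CH₄). Isotope fractionation factors and raw m/z channel corrections are
out of scope.

## Setpoint control

Sulfide above its trigger is precipitated to the *target* (not the
boundary) as FeS, assumed instantaneous, complete, 1:1 and irreversible;
sulfate below its trigger is replenished to target. When both occur at
once, FeSO₄ covers min(excess, deficit) — its single dose performs both
corrections — and single-purpose reagents top up the remainder. This
min-then-top-up rule is one of several dosings consistent with the
experimental description; it is chosen because it can never overshoot
either setpoint. `sulfur_balance()` checks that total sulfur (dissolved
sulfate + sulfide + FeS) changes only by the sulfate-bearing doses.

## qPCR quantification

Standard curves are ordinary least squares of Cq on log₁₀ copies over
triplicate 10-fold dilutions (2 × 10⁵ down to 2 × 10⁻² copies µl⁻¹), with
efficiency $10^{-1/\text{slope}} - 1$. Back-calculation to absolute
abundance is an explicit reconstruction with all conversion factors as
parameters: copies in the reaction from the curve, ÷ template mass (5 ng)
for copies per ng DNA, × total extracted DNA ÷ sample wet mass for copies
per g wet weight. Both normalizations are reported because fold changes
are only normalization-invariant when DNA yield is constant across
samples. Growth calls are strict ratio > 1. Cq values outside the
calibrated range are flagged as extrapolations (warning), not errors.

Group comparisons use Welch's unequal-variance t-test at α = 0.05 on raw
pairwise p-values, mirroring the study's statistics; no multiple-testing
correction enters the letter display (`letter_groups()`, an
insert-and-absorb compact letter display: conditions share a letter iff
not significantly different). A Holm-adjusted column can be obtained with
`stats::p.adjust` on the `pairwise_p` matrix if a corrected view is
wanted.

## The synthetic study generator

`generate_study()` emulates the full design so the pipeline is testable
end to end. Mechanistic choices:

* **Rate law**: $r = v_{max}\,[\mathrm{SO_4^{2-}}]/(K_m +
  [\mathrm{SO_4^{2-}}])$ gated by a **hard threshold**: $r = 0$ unless the
  in-state $\Delta_r G' \le -19$ kJ mol⁻¹. The study argues a threshold,
  not a functional form, so a step gate is the defaults; a smooth
  thermodynamic limitation factor would be a straightforward extension.
  $K_m = 1.5$ mM honors the observation that the sulfate half-saturation
  of this sediment is below 2 mM.
* **$v_{max} = 0.005$ mM d⁻¹** is an order-of-magnitude placeholder for a
  non-seep sediment slurry — the study reports no absolute rates — so all
  rate-dependent checks are relative (rankings, significance, recovery of
  planted parameters), never absolute magnitudes.
* **Integration**: forward Euler with dt = 1 day over 947 steps. Rates
  change on week-to-month scales here, so the explicit scheme is far
  inside its stability region; the 1:1:1:1 stoichiometry is preserved
  exactly in the noiseless ledger, which is what the conservation tests
  assert (|residual| < 10⁻⁹ mmol).
* **Background methanogenesis** runs only in the sulfide-only condition,
  where methane accumulation was observed; it converts CO₂ to CH₄ with a
  CO₂-saturating term (half-saturation 0.5 mM) so the dissolved inorganic
  carbon pool is drawn down asymptotically rather than exhausted. The
  label-free simplification (produced CH₄ is ¹²C from the CO₂ pool) stands
  in for the AOM back-flux narrative.
* **Growth** is linear-yield: copies += yield × clade-niche ×
  CH₄ oxidized. This is sufficient for fold-change *ranking* tests — the
  planted niche structure makes ANME-2a/b dominate under methane + high
  sulfate — but deliberately cannot reproduce growth observed in
  conditions without methane turnover (e.g. ANME-2c in the sulfate-only
  control), which the study attributes to processes outside this model.
* **Noise**: multiplicative lognormal (sd 0.05) on observed concentration
  and gas series — concentrations stay positive — and additive Gaussian Cq
  noise (sd 0.15 cycles ≈ 10% in copies). Ground truth is always emitted
  noiseless.
* **Seeding**: one master seed; per-bottle streams derived by fixed
  offsets, so replicates are independent but the whole study is
  bit-reproducible.

What passing tests on this generator do **not** show: real sediment
heterogeneity, transport limitation within aggregates, sulfide toxicity as
a mechanism distinct from thermodynamics, isotope fractionation, and any
absolute-rate agreement with wet-lab data.

```{r}
study <- generate_study(sim_params(seed = 42))
summary(study)[1:6, ]
```

## Numerical choices and degenerate inputs

* $Q$ with zero methane or sulfate is an error naming the species; the
  report layer instead blanks conditions without methane (em-dash) and
  flags contradictory rows (methane declared but zero concentration) as
  row-level errors.
* Zero total gas amount makes the isotope fraction an error, not NaN.
* A missing pre-label baseline is an error for the %¹³CO₂ readout.
* Two constant qPCR groups with equal means give t = 0, p = 1 by
  convention; constant with different means is a degenerate-variance error.
* `fit_monod()` starts from a Lineweaver–Burk linearization and uses an
  `nls` `scaleOffset` so that convergence is well-defined on noiseless
  (zero-residual) calibration data.
* Amendment dosing is exact-stoichiometric (no reagent excess), and FeCl₂
  overdoses precipitate only the sulfide actually present.

## Problem sizes used in the test suite

The suite runs the generator at full scale (7 × 3 bottles, 947 days, ~30
sampling days) for the conservation and narrative checks — about two
seconds per study — and at shortened horizons (120–600 days) where only
plumbing is under test. Parameter recovery uses a 13-level sulfate grid in
triplicate, 20 noisy replicates. The exhaustive letter-display check
enumerates all 64 + 1024 significance graphs on 3 and 4 conditions.

## Known limitations

* No carbonate/sulfide speciation, ionic-strength activity corrections, or
  van 't Hoff temperature correction of $\Delta_r G^{\circ\prime}$.
* The energetic gate is binary; near-threshold kinetics are not modeled.
* Headspace–liquid partitioning of CO₂ and CH₄ is handled by the
  simulator's bookkeeping (per-bottle totals), not re-inferred from Henry
  equilibria.
* The qPCR chain from reaction copies to per-gram copies assumes complete,
  unbiased DNA extraction; extraction efficiency is a free multiplier that
  cancels only in fold changes.
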