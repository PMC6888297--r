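---
title: "The AMPK–mTORC1–ULK1 autophagy switch: model, calibration, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The AMPK–mTORC1–ULK1 autophagy switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampkswitch)
```

## The model

Autophagy induction is controlled by two nutrient/energy sensors with
opposite agendas: mTORC1 (active when nutrients are plentiful, inhibits
autophagy) and AMPK (active when energy is scarce, promotes it). Both act
on ULK1, the kinase that initiates autophagosome formation: AMPK activates
ULK1 by phosphorylating Ser555, mTORC1 inactivates it via Ser757. ULK1 in
turn feeds back on both of its regulators, and — the hypothesis this model
is built around — mTORC1 also inhibits AMPK directly, closing a
double-negative feedback loop (AMPK ┤ mTORC1 ┤ AMPK) that behaves as a
bistable toggle.

`ampkswitch` represents four lumped species by their active fraction:
AMPK-Thr172-P (`A`), active mTORC1 (`M`), ULK1-Ser555-P (`U`), and a
lumped autophagy activator ATG (`G`), experimentally proxied by LC3-II
accumulation and p62 degradation. Each species is a covalent-modification
(Goldbeter–Koshland) cycle with Michaelis–Menten activation and
inactivation fluxes; the total of each protein is conserved at one unit,
so the inactive pools are implicit:

$$\frac{dA}{dt} = k_{aA} S \frac{A_T - A}{J_{aA} + A_T - A}
  - \left(k_{iA} + k_{iAU} U + w\, k_{iAM} M\right) \frac{A}{J_{iA} + A}$$

$$\frac{dM}{dt} = k_{amtor} \frac{M_T - M}{J_{aM} + M_T - M}
  - \left(k_{iM} + k_{iMA} A + k_{iMU} U\right) \frac{M}{J_{iM} + M}$$

$$\frac{dU}{dt} = k_{aUA}\, A \frac{U_T - U}{J_{aU} + U_T - U}
  - \left(k_{iU} + k_{iUM} M\right) \frac{U}{J_{iU} + U}$$

$$\frac{dG}{dt} = \left(k_{aG0} + k_{aGU} U\right) \frac{G_T - G}{J_{aG} + G_T - G}
  - \left(k_{iG} + k_{iGM} M\right) \frac{G}{J_{iG} + G}$$

All variables are dimensionless, rate constants are in 1/min, Michaelis
constants are dimensionless. `w` switches the mTOR ┤ AMPK edge: `w = 1`
is the extended model, `w = 0` the template network against which the
edge's necessity is judged. Every other edge of the wiring can be ablated
individually through `model_variant()`, which is numerically identical to
zeroing the corresponding coefficient.

Two structural commitments are baked in rather than calibrated. ULK1 has
no basal activation: its activation flux is proportional to active AMPK,
which is what makes AMPK *essential* for autophagy induction in the
model. Conversely `kaG0 > 0` is small but nonzero, reflecting the
residual autophagic activity that cells maintain under physiological
conditions.

## Parameters

`kamtor = 0.025`/min is fixed by the convention that mTOR
hyper-activation (TSC1/2 silencing) is a 2-fold increase of `kamtor` to
0.05; the totals are fixed at one unit each. Everything else is a
calibration product, not a measured quantity. The calibrated set balances
five groups of constraints:

* **Physiological rest state.** At `S = 1` the system is monostable with
  mTOR on (`M ≈ 0.98`) and AMPK, ULK1, ATG off (`A ≈ 0.03`). This
  requires the A-cycle's drive `kaA·S` to sit well below its
  mTOR-dependent inactivation capacity `kiA + kiAM·M`.
* **The rapamycin choreography.** When total mTOR is sequestered, AMPK-P
  must surge within minutes (`kaA` sets the rise), ULK1-P must follow
  with a visible delay (`kaUA`), and ULK1 must then pull AMPK-P back
  below its low threshold within the 2-hour window (`kiAU`), while the
  treated system still converges to a stable autophagy-on state with
  ULK1-P high (`kiU` small enough that moderate AMPK sustains it).
* **Silencing phenotypes.** With the edge present, `kiAM·M` alone keeps
  AMPK-P off when ULK1 is depleted or mTOR hyper-activated; without the
  edge both perturbations light AMPK up — the central contrast.
* **Toggle structure.** Mutual inhibition between A and M
  (`kiAM`, `kiMA`) with small Michaelis constants on the M cycle
  produces a hysteretic bistable window in `S`. The inactivation
  constant `kiM` is deliberately close to `kamtor` so that the margin by
  which mTOR defends its on-state depends strongly on `kamtor`: the
  stress level that flips the baseline switch fails to flip the
  hyper-activated one, which is what discriminates starvation from
  siTSC1/2 + starvation.
* **Recovery vs. lock-in.** After a stress flip, mTOR must stay off
  (`kiMA·A + kiMU·U` exceeds its reactivation capacity at the
  autophagy-on state), yet at `S = 1` the same state must *not* be
  self-sustaining, or the control condition would be bistable. The
  difference is carried by the lower AMPK-P and ULK1-P levels of the
  `S = 1` autophagy state.

The shipped values live in `inst/extdata/default_parameters.yaml` with a
provenance header; `calibrate_parameters()` re-verifies them against the
constraint battery (`analysis/01_calibrate.R` prints the zero-violation
check), and offers Latin-hypercube screening over log-uniform ranges
(rates $[10^{-4}, 1]$/min, Michaelis constants $[10^{-3}, 1]$) with
coordinate-wise refinement for re-deriving a set from scratch.

## Treatments

Treatments are pure parameter overrides, applied at protocol stage
onsets; doses map to fixed magnitudes (no pharmacokinetics):

| treatment | override | rationale |
|---|---|---|
| rapamycin | `MT -> 0.01` | mTORC1 sequestration; active M is capped by the remaining total |
| Compound C | `kaA x 0.05` | kinase-activity inhibition of AMPK activation |
| starvation | `S -> 2.5` | energy stress multiplies the AMPK activation drive |
| resveratrol | `S -> 2.5` | treated as an AMPK activator of the same strength |
| AMPK hyper-activation | `S -> 12` | saturating stress |
| siULK1 | `UT -> 0.001` | near-complete depletion |
| siTSC1/2 | `kamtor -> 0.05` | loss of the upstream mTORC1 brake |
| mTOR hyper | `kamtor x 2` | the same perturbation expressed as a fold change |

The starvation magnitude `S = 2.5` is itself a calibrated treatment
intensity: the baseline switch flips between `S ≈ 2.1` and `2.2`, while
with `kamtor = 0.05` the mTOR-on state survives past `S = 3`, so 2.5 sits
inside the discriminating band — strong enough to flip a normal cell,
too weak to defeat hyper-activated mTOR (rapamycin, which removes the
protein rather than out-competing it, wins either way).

When a stage reduces a total below the current active level, the state
is clamped to the new total at onset (silencing removes active protein
too); otherwise the state is continuous across stages.

## Classification and the phenotype matrix

Immunoblots in this literature are read as "significantly changed or
not", so trajectory calls use a declared convention on the one-unit
scale: `theta_high = 0.5` and `theta_low = 0.25`. A readout is **HIGH**
if it ends at or above `theta_high`; **TRANSIENT** if it was *induced*
(rose through `theta_high` from below) and ended at or below
`theta_low`; **LOW** if it ended at or below `theta_low` without an
induction, or never reached `theta_high`; anything else is **AMBIGUOUS**
and only matched by wildcards. Requiring an induction for TRANSIENT is
deliberate: mTOR shut off by rapamycin from its high resting level is a
shut-off ("LOW"), not a transient, even though its maximum over the
window equals its starting level.

The scenario suite encodes 16 perturbations — every single treatment,
silencing, hyper-activation, and the staged combinations — with expected
patterns per readout; set-valued expectations and wildcards are allowed
where only part of the outcome is constrained (e.g. siTSC1/2 +
rapamycin: strong AMPK phosphorylation that may have relaxed by 2 h,
with some autophagy activity). Combination scenarios whose expected
pattern is a model prediction rather than a measured blot are tagged
`provenance = "predicted"` and can be filtered out of a gate.
Classification is invariant to the output-grid resolution at or below
one minute.

Variant comparisons (`compare_variants()`) start both variants from the
*extended* model's physiological steady state — the biological resting
state — so that differences reflect the edge, not different initial
conditions. At the shipped defaults the template network has no resting
state with mTOR on: left at `S = 1` it transiently hyper-activates AMPK
before induced ULK1 pulls it back down. That baseline defect is reported
as-is; the edge-necessity tests are phrased on the silencing and
hyper-activation scenarios, where the contrast is clean (final AMPK-P
0.03 with the edge vs. 0.97–1.0 without).

## Numerics

* **Integration.** `deSolve::lsoda` on a compiled right-hand side,
  relative tolerance $10^{-8}$, absolute $10^{-10}$, 1-minute output
  grid (finer on request); halving the tolerances moves endpoints by
  less than $10^{-5}$. Trajectories leaving $[0, \text{total}]^4$ by
  more than $10^{-6}$ are an error, not a warning.
* **Steady states.** Damped Newton iteration from Latin-hypercube
  starts (plus box corners and forward-integration endpoints), roots
  merged at $10^{-5}$, stability from the eigenvalue real parts of a
  central-difference Jacobian (step $10^{-6}$) with a $10^{-8}$
  dead band. The all-rates-zero system is reported as degenerate
  (every point is fixed) instead of returning an arbitrary root list.
* **Continuation.** One-parameter scans re-run the multi-start search
  at each grid value and additionally polish the neighbours' roots from
  both sweep directions; fold positions are reported as grid brackets,
  not refined. This brute-force continuation is adequate for a
  four-dimensional desk-scale system.
* **Phase plane.** The AMPK–mTOR reduction treats U and G as fast
  variables at quasi-steady state. It is a visualization device: the
  reported time-scale ratio is ~0.9 at the rest state but drops to
  ~0.05 on the autophagy branch (U is genuinely slow there), so all
  quantitative claims use the full 4-D system. Nullclines are traced as
  zero contours of the reduced field on a grid, and intersections are
  Newton-polished and re-verified against the full system.

## The synthetic densitometry generator

The generator emulates replicated, loading-control-normalized band
intensities at the 0/30/60/90/120-min schedule: per-band multiplicative
lognormal noise (mean-corrected, so the expected noisy band equals the
noise-free one) times a per-lane loading-control factor shared by all
readouts of a lane, triplicates by default. Model species map to the
measured bands (AMPK-T172-P, ULK1-S555-P, p70S6K-P for mTOR activity);
autophagy is proxied by declared monotone transforms, LC3-II = 0.1 + G
and p62 = 1.1 − G, with a floor so intensities never reach zero. These
proxies are testing conventions, not mechanistic claims about LC3/p62
turnover. The generator reproduces the statistical *structure* of blot
quantification — positivity, ratio normalization, lane correlation —
but not saturation, blocking artifacts, batch drift, or biological
replicate variance, so passing recovery tests demonstrate identifiability
under the stated noise model only.

Parameter fitting (`fit_time_course`) is multi-start Levenberg–Marquardt
on log-transformed parameters with box bounds; identifiability is not
assumed (a warning fires above three simultaneous free parameters). At
the shipped defaults, the AMPK–ULK1 loop rates `(kaUA, kiAU)` are
recovered to better than 1% from noise-free tables and a few percent at
10% band noise.

## Known limitations

* No phosphosite resolution (Ser555 vs. Ser757 are not separate
  states) and no explicit TSC1/2 or Raptor species; upstream biology is
  funneled through `kamtor` and `S`.
* Thresholds are conventions; calls near a threshold are sensitive to
  them, which is why the matrix expectations use set values or
  wildcards where the underlying claim is partial.
* The hysteresis window in `S` (roughly 1.15–2.15 at the defaults)
  contains a narrow sliver (≈1.35–1.55) where the autophagy-on branch
  is a small stable oscillation around an unstable focus rather than a
  fixed point. No treatment scenario lands there, the bistable-interval
  report is phrased on fixed-point bistability, and limit cycles are
  not tracked further. Under 10% parameter jitter the robustness tests
  occasionally sample this sliver; they then check that the integrator
  and the root finder agree about the attractor structure instead of
  demanding a fixed-point match.
* Problem sizes used throughout (26-point scans, 100 random draws,
  20 recovery seeds, 60–80-point nullcline grids) are the package's
  chosen desk scale; they resolve every qualitative feature the
  analysis reports.
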