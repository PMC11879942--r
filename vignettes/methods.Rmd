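---
title: "Methods: pressure gradients, inflow patterns, and the synthetic cohort"
author: "cmmeivpg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pressure gradients, inflow patterns, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmmeivpg)
```

## Scope

`cmmeivpg` analyzes how transmitral inflow morphology (EA-separation /
EA-half-separation / EA-fusion) and heart rate relate to color-M-mode
derived intraventricular pressure gradients (IVPG) and to E/E′ in a rat
model of hypertensive cardiomyopathy. Because the original per-animal
recordings are not publicly available, the package pairs the analysis
stages with a synthetic velocity-field and cohort generator that
reproduces the study's *structure*; every empirical claim in this
vignette is one the package's own tests or scripts compute.

## The pressure engine

Along a single scanline from the mitral annulus (s = 0, cm) toward the
apex, with velocity positive toward the apex, the one-dimensional Euler
equation gives the spatial pressure gradient

$$\frac{\partial P}{\partial s} = -\rho\left(\frac{\partial v}{\partial t}
  + v\,\frac{\partial v}{\partial s}\right), \qquad \rho = 1060\ \mathrm{kg/m^3}.$$

`pressure_gradient_field()` evaluates this with second-order finite
differences — central in the interior and 3-point one-sided at the
boundaries, so the truncation error is $O(h^2)$ everywhere; the test
suite verifies second-order convergence against a traveling-sine closed
form and exactness on a uniform-acceleration field. `ivpd_trace()`
integrates $-\partial P/\partial s$ over space (trapezoid rule) into the
intraventricular pressure difference IVPD(t) in mmHg: base pressure
minus apex pressure, positive while early filling accelerates.

### Segmental decomposition and the peak summary

The basal segment spans $[0, L/3]$ and the mid-to-apical segment
$[L/3, L]$. Two numerical decisions matter:

* **Same-instant evaluation, full-length normalization.** The scalar
  IVPGs are the IVPDs at the instant the *total* IVPD peaks inside the
  filling window, each divided by the full LV length. This is the only
  summary under which the segmental values add exactly to the total
  (`2.61 = 1.60 + 1.01` in the reference data holds only with this
  reading); per-segment peaks or per-segment-length normalization both
  break additivity. The tests assert `total = basal + mid_apical` to
  1e-9 mmHg on every trace.
* **Split snapping.** If $L/3$ is not a grid node the split snaps to
  the nearest node and a note records the snapped coordinate;
  reproducible snapping is preferred over silent interpolation.

Maps carrying several cycles are evaluated per cycle and averaged
(`ivpg()`), mirroring measurement over consecutive heart cycles. No
smoothing is applied by default; `smooth_sigma` enables a Gaussian
time-smoother for noisy maps but is off so that defaults remain
oracle-checkable.

## Inflow-pattern classification

`extract_wave_features()` detects local maxima above 10 % of the trace
maximum on the mitral-annulus row (where pulsed-wave Doppler samples
inflow). `classify_pattern()` then applies:

| peaks | valley vs. smaller peak | label | code |
|-------|------------------------|-------|------|
| 2     | ≤ 5 %                  | EA-separation | 1 |
| 2     | > 5 %                  | EA-half-separation | 2 |
| 1     | —                      | EA-fusion | 3 |

The reference definitions are qualitative; the single quantitative
choice is the 5 % valley threshold for "separated", which is therefore a
documented operational parameter (`sep_threshold`), not a measured
quantity. Fusion needs no threshold — it is the structural condition of
a single local maximum. Per-animal labels are modal across cycles with
ties broken toward the higher (more merged) code. Tests verify that the
code is monotone as the inter-pulse gap closes and changes only when
the valley crosses the threshold.

## Derived indices

* LV mass (g, dimensions in cm):
  $\mathrm{LVM} = 0.8 \cdot 1.04\,[(\mathrm{LVIDd}+\mathrm{IVSd}+\mathrm{LVFWd})^3 - \mathrm{LVIDd}^3] + 0.6$.
  The source prints this formula with its exponents typographically
  mangled; the standard cube-formula reading is implemented, and zero
  wall thickness is admitted (the cube terms cancel).
* $E/E' = \tfrac12\,(E/E'_{IVS} + E/E'_{LVFW})$ with E converted from
  m/s to cm/s internally — the only reading consistent with printed
  values near 13–18.
* $\mathrm{LVEDP} = 17.1 + 0.19\,E/E'$ and
  $\text{Pre-A LVDP} = 6.97 + 0.3\,E/E'$ (mmHg), exact affine maps;
  rounding happens only at presentation. One published LVEDP cell
  (HTN-CM EA-fusion) is inconsistent with its own E/E′ under this map
  (19.85 computed vs. 19.61 printed, apparently a copy of the
  neighbouring column); it is documented and excluded from the
  reproduction checks. A and E/A are recorded only for EA-separation
  animals, matching the reference table's empty cells for both merged
  morphologies.

## The synthetic generator

### What it emulates

Each cycle is a systolic no-flow interval followed by an E wave and an
A wave. Both are raised-cosine (Hann) pulses: compact support makes
"separation" an exact zero valley rather than a thresholding accident.
The A wave is anchored to the cycle end, so

$$\text{diastasis} = \frac{60000}{\mathrm{HR}} - \text{systole} - D_E - D_A \quad (\mathrm{ms}),$$

which decreases monotonically in HR and goes negative (overlap) at high
rates — the causal route from heart rate to pattern. Waves propagate
apically at a finite velocity with exponential amplitude decay and sum
where they overlap.

### Defaults and why

All values live in `sim_config()`; rat wave durations and propagation
velocities are stated assumptions chosen once for physiological
plausibility, not literature measurements:

* systole 85 ms, $D_E$ = 50 ms, $D_A$ = 45 ms: diastasis vanishes near
  333 bpm, putting the separation→half boundary at ≈ 345 bpm and the
  half→fusion boundary at ≈ 385 bpm — inside the anesthetized-rat HR
  range (≈ 220–420 bpm), so all three morphologies occur at the
  configured per-cell HR distributions (taken from the reference
  cohort's HR cells, e.g. Sham EA-separation 304.14 ± 43.97 bpm).
* E amplitude 0.90 ± 0.10 m/s, A amplitude 0.60 ± 0.07 m/s, E′
  5.5 ± 0.8 cm/s: the reference EA-separation cells.
* propagation 150 cm/s (E) / 130 cm/s (A), penetration depth 1.5 cm (E)
  / 0.5 cm (A) on a 2.0 ± 0.1 cm LV: fast propagation and deep E-wave
  penetration are required for the instantaneous spatial acceleration
  integral to reach mmHg-scale IVPDs in a 2 cm ventricle; the shallow
  A wave concentrates atrial filling basally.
* grid 0.05 cm × 1 ms, 2 cycles per map.

### Couplings

Three couplings are driven by the merging fraction
$m = \min(\max(-\text{diastasis}, 0)/D_A, 1)$:

* **Preload:** latent E scales by $(1 + 0.20\,m)$ and latent E′ by
  $(1 + 0.65\,m)$. The E′ coefficient is constrained (validated) to be
  strictly larger — the mechanism by which merging raises E′ more than
  E and therefore *lowers* E/E′. The sizes are set so that full
  merging reproduces the reference fusion/separation amplitude ratios
  (≈ 1.4 for E′, ≈ 1.15 for E).
* **Atrial attenuation:** the A amplitude scales by $(1 - 0.75\,m)$ —
  with no diastasis the atrium has not refilled, so the atrial kick
  shrinks rather than stacking fully on the E wave; without this the
  fused wave's velocity overshoots far above observed values.
* **Left-atrial loading:** the E-wave penetration depth scales by
  $(1 - 0.10\,m)$, concentrating early inflow basally as filling
  becomes atrial-driven. This loads basal IVPG with the pattern while
  leaving mid-to-apical IVPG (which stands for active relaxation)
  nearly independent of it — the study's central contrast.

### Cohort assembly

`generate_cohort()` draws HR and latent amplitudes per animal and
**rejects** draws until the classifier run on the generated trace
matches the cell's target pattern, so the pattern counts (Sham 7/7/19,
HTN-CM 15/25/26 by default) are exact while the HR→pattern mechanism
stays causal; an attempt budget turns an inconsistent configuration
(e.g. a fusion cell whose HR distribution cannot reach fusion) into a
clear error. HTN-CM animals get additive shifts in systolic pressure
(+69 mmHg) and wall thickness (+0.045 cm). Measured E is the filling
peak of the generated trace plus Gaussian noise; E′ at both walls,
dimensions, and blood pressures get configured noise as well.
Everything is driven by one seed; identical configurations are
bit-identical.

### What the generator does *not* emulate

Beat-to-beat variability, respiratory motion, Doppler aliasing and
angle error, pixel-level color decoding, and any feedback of afterload
on relaxation rate. Absolute simulated IVPG levels (≈ 1.4 mmHg/cm
total) sit below the reference means (≈ 2.2–2.6 mmHg/cm), and the
cube-formula LV masses sit above the printed ones; the package's
recovery claims are therefore about *signs and orderings* of effects,
which large simulated cohorts reproduce (positive r(HR, pattern),
r(pattern, E′) > r(pattern, E) > 0, negative r(pattern, E/E′), and
|r(pattern, mid-to-apical IVPG)| ≪ |r(pattern, basal IVPG)|), not about
absolute levels. Passing tests show the pipeline is correct and the
mechanisms are sufficient for the observed sign structure — not that
real rat data were reproduced.

## Statistics

Two-way ANOVA uses Type-II sums of squares by default — the
conventional choice for an unbalanced factorial without strong
interaction; Type I/III sit behind a flag. Tukey's HSD runs on the six
group × pattern cells (the reference table annotates cells, not
marginals) via the studentized range with the Tukey–Kramer adjustment
for unequal cell sizes, and the pairwise decisions are summarized by a
hand-implemented insert-and-absorb compact-letter display. Pearson
correlations code the pattern 1/2/3 as printed. No multiplicity
correction is applied across outcomes, matching the emulated analysis;
p-values should be read accordingly.

## Problem sizes

The test suite runs the engine oracles at grids up to 256 × 1024, the
default 99-animal cohort, and a 3000-animal cohort (500 per cell) for
correlation-sign recovery; these sizes give stable signs while keeping
a full test run in a few minutes on one CPU.

## Known limitations

* The Euler integration is one-dimensional along the scanline; lateral
  flow and scanline misalignment are outside the model.
* The classifier's 5 % valley threshold is an operational convention;
  boundary cases near half-separation are threshold-sensitive by
  construction (and tested to be *only* threshold-sensitive).
* The filling-pressure maps are affine regressions calibrated on
  invasive data elsewhere; in fused patterns LVEDP and pre-A LVDP
  conceptually coincide while the two maps still return different
  numbers — a caveat inherited from the index definitions, not from
  this implementation.
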