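---
title: "Methods: beam-model commissioning with beamtune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beam-model commissioning with beamtune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamtune)
```

## The problem

Planning systems for MLC-modulated photon therapy expose four user-tunable
beam-model parameters: the effective target spot sizes σX and σY (mm), the
dosimetric leaf gap DLG (mm) and the MLC transmission T (a fraction).
Mis-set values show up as penumbra errors, systematic dose offsets in
sliding-window and VMAT deliveries, and small-field output-factor
deviations. `beamtune` implements a staged tuning workflow — spot sizes
from penumbras, transmission from a closed/open ratio, DLG from
asynchronous oscillating sweeping gap (aOSG) doses, a designed experiment
quantifying small-field sensitivity, and gamma-index plan QA — together
with a synthetic dose engine that stands in for both the linac
("measured") and the planning system ("calculated") so the whole pipeline
is testable offline against a known ground truth.

The stages run in a fixed order (spot sizes → transmission → DLG → DOE →
QA). The order matters: penumbra tuning is insensitive to DLG and T (we
verify a ≤ 0.1 mm penumbra perturbation when they vary over their full
ranges), transmission is measured independently rather than co-fitted, and
DLG tuning takes both as fixed inputs. Tuning parameters on small-field
output factors directly is deliberately *not* offered: the sensitivity
analysis below shows strong interactions there, so the DOE stage ranks and
quantifies influences instead of optimizing over them.

## The synthetic dose engine

The engine is declared synthetic: it is the simplest family of closed-form
laws that reproduces the qualitative behaviour the workflow relies on, not
a transport calculation.

**Profiles.** A square MLC field of side `2a` scanned along one axis is

    reading(x) = (1 - T) * 0.5 * [erf((a + Δ - x)/(√2 σeff)) + erf((a + Δ + x)/(√2 σeff))] + T

with Δ = DLG/2 on the MLC-defined (crossline) edges and Δ = 0 inline,
normalized to 100% at the central axis. For the measured role the detector
response is added in quadrature, `σeff² = σaxis² + σdet²`; the calculated
role uses the model spot size alone. The 20–80% width of a single erf edge
is `2√2 erfinv(0.6) σeff ≈ 1.683 σeff` mm, which makes the penumbra
deviation curve almost linear in σ and gives the tuner a clean
zero crossing.

**Sweeping deliveries.** A uniform gap `g` sweeping a length `L` with
adjacent leaf pairs shifted by `s = τ g` (tongue-and-groove fraction τ)
deposits

    D = C (g + DLG - λ s) / L + T (1 - g / L)

where λ is a tongue-and-groove fluence-loss coefficient and `C` a
calibration constant (`C = 1` makes the open reading 1.000). Giving the
measured and calculated sides different λ emulates a planning system whose
tongue-and-groove rendering does not match the machine — the mismatch aOSG
tests exist to expose. The law is affine in `g`, so the classic
sweeping-gap extrapolation recovers the physical DLG exactly in the
noise-free engine, while the aOSG optimum shifts by roughly
`(λ_calc − λ_meas)` times a weighted median of the shifts `s` over the
plan set.

**Output factors.** `OF = (1 - T) E(a + DLG/2, σX) E(a, σY) + T` with
`E(w, σ) = erf(w / (√2 σ))` (and `E = 1` at σ = 0). OF rises with DLG and
T, falls with either spot size, and saturates at 1 for large fields — the
directions reported for real small-field output factors — and its
products of edges generate genuine DLG×σ interactions at the smallest
fields.

**Dose planes.** Sums of erf-edged rectangular apertures with seeded
random positions and weights; smooth, deterministic, and re-evaluable with
perturbed parameters for QA comparisons.

## Default study conditions

| Quantity | Default | Why |
|---|---|---|
| Profile field sizes | 5, 10, 20, 30, 40 mm | the five MLC-defined penumbra fields |
| Scan range / step | edges ± 15 mm, 0.1 mm | penumbra-region scan step |
| σ grid | 0–2 mm, 0.2 mm step (11 points) | tuning range of the spot size |
| DLG grid | 0–3.4 mm, 0.1 mm step | tuning range; 0.1 mm matches reported precision |
| aOSG plans | gaps 10/20/30 mm × τ ∈ {0, .25, .5, .75, 1} | 15 plans spanning clinical complexity |
| Sweep length L | 100 mm | typical sweeping-delivery travel |
| Calibration C | 1 | open 10-cm reading ≈ 1.000 |
| Detector blur σdet | 0.3 mm | sub-mm diode response width |
| Noise CV | 0.003 | measurement reproducibility below 1% |
| λ_meas / λ_calc | 0.05 / 0.20 | places the aOSG−sweeping DLG offset near 1 mm, inside the 0.4–1.7 mm range reported clinically for HD MLCs |
| DOE levels | per-beam presets (`levels_*()`) | three levels bracketing each tuned value |
| Gamma | 3% / 2 mm global, 10% threshold | TG-218 convention; 95% / 90% limits |
| OF field sizes | 5–20 mm (0.5 cm steps), 30, 40 mm | small-field detector measurements |

Tests that check *recovery* of a ground truth switch `σdet` and the noise
off: the calculated side of the engine never contains detector blur, so
with a blurred measured profile the tuned spot size converges to
`√(σ² + σdet²)` rather than σ. That is not an artifact — on real machines
the effective spot size absorbs whatever the profile detector adds — but
it means exact recovery is only a well-posed question for the unblurred
engine.

## Numerical choices

- **Level crossings** (20%/80%, and the zero crossing of the deviation
  curve) are linearly interpolated between bracketing samples; with 0.1 mm
  scan steps higher-order schemes change nothing at the 0.01 mm level.
  Interpolated zero crossings also produce off-grid optima such as
  1.25 mm, which a nearest-grid rule could not.
- Each profile side must cross each level exactly once in its edge region;
  multiple crossings raise an error naming the side rather than silently
  picking one.
- When the deviation curve never changes sign (a point source already
  over-broadens the calculated penumbra, as happens for some MLC/axis
  combinations), the tuner falls back to the grid argmin of the absolute
  deviation and records `method = "argmin"`.
- **DLG cost** is the mean absolute *relative* difference,
  `(calc − meas)/meas`, in percent. Ties on the grid return the smallest
  DLG with a flag. An optional 3-point parabolic refinement of the argmin
  is available (the cost curve is approximately parabolic) but off by
  default, so the default result is a grid point.
- **ANOVA error term.** The engine provides no replicates, so the error
  sum of squares pools the five unassigned array columns (10 df) — the
  standard Taguchi treatment when replication is absent. If a response is
  an exact function of one factor, the pooled error can be numerically
  zero; the analysis then flags `zero_error` and ranks sources by sum of
  squares instead of F tests.
- **Responses are signed** (calculated minus corrected-measured, percent,
  averaged over the two detectors): deviations of either sign are real
  and cancellation across detectors is informative.
- **Gamma** uses global normalization to the reference-plane maximum, a
  threshold mask applied to the reference plane, bilinear upsampling of
  the evaluated plane with search step ≤ DTA/10 and search radius 3×DTA —
  a standard accuracy/speed compromise recorded in the result metadata.
  Exhaustive brute-force search on small grids agrees with the optimized
  implementation to 1e-6.

## The L27 design

The 27-run, 13-column, 3-level orthogonal array is generated over GF(3):
runs are the triples `(x1, x2, x3) ∈ {0,1,2}³` and each column is a
normalized nonzero coefficient vector `(a, b, c)` with level
`(a x1 + b x2 + c x3) mod 3`. Two assigned columns confound their
interaction in the columns `u+v` and `u+2v`, which is how the two columns
of each requested interaction (by default DLG×σX and DLG×σY, 4 df each)
are located. Factor columns are placed by a depth-first search that keeps
every factor off any column confounded with a two-factor interaction of
already-placed factors and keeps the three diagonal runs (all-low,
all-mid, all-high) distinguishable on every factor column; the published
array's defining properties — 27 trials, per-column level balance,
pairwise orthogonality, estimable main effects plus the two DLG×σ
interactions, and the canonical all-1/all-2/all-3 corner rows — are
reproduced rather than its verbatim row order. Factor amplitudes are
level-mean spreads; interaction amplitudes are the spread of the 3×3 cell
means after removing the additive part. Because the array balances factor
levels only pairwise, level means of a non-additive response need not be
stepwise monotone even when the response is pointwise monotone in every
parameter; the sensitivity tests therefore check the level-3 minus level-1
contrasts and pointwise directions.

## What the synthetic engine does and does not show

Passing the recovery suite demonstrates that the estimators are correct
for data generated by the stated laws: interpolation, grid search, least
squares, ANOVA bookkeeping and the gamma search are doing what they claim.
It does not validate the laws themselves against a linac: real penumbras
are not pure erf edges (spectrum, scatter, detector volume), real
sweeping-gap doses deviate from affinity at small gaps, real
tongue-and-groove losses depend on leaf geometry rather than a single λ,
and film-based QA adds registration and calibration error that the smooth
synthetic planes omit. The FFF "cone" shape is also omitted: profiles are
normalized at the central axis, which removes the cone's influence at the
small field sizes used here.

## Problem sizes

The test and acceptance runs use profiles of ~700 samples (0.1 mm step),
the 15-plan aOSG set on a 35-point DLG grid, 41×41 dose planes at 2 mm
spacing (gamma search: 0.2 mm step, 6 mm radius), and 13×13 planes for the
brute-force gamma cross-check; a full synthetic commission completes in a
few seconds. These sizes were chosen so the whole suite exercises every
stage at realistic sampling densities while remaining quick to run.

## Known limitations

- The calculated side of the pipeline is the built-in engine; connecting a
  real TPS means exporting its doses into the same CSV/plane formats and
  supplying them as the "calculated" inputs, which the file formats allow
  but no vendor converter is included.
- Gamma is 2D single-plane; no 3D dose grids, no DICOM RT Dose reader
  (plain-text planes only).
- The DOE stage quantifies sensitivity; it deliberately offers no
  automated parameter selection from output factors.
- With a tongue-and-groove mismatch, the per-plan spread of the dose
  differences at the aOSG optimum is below the worse end of the DLG grid
  but not necessarily below both ends; only the mismatch-free engine
  attains a zero-spread optimum.
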