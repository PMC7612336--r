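---
title: "Methods: from head-impact kinematics to sulcal strain statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from head-impact kinematics to sulcal strain statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sulcalstrain` is a desk-scale computational pipeline for studying how
American-football head-impact exposure translates into mechanical strain at
the depths of cortical sulci — the location where chronic traumatic
encephalopathy (CTE) tau pathology concentrates. It chains five stages:

1. **Kinematics generation** — synthetic six-degree-of-freedom head loading
   pulses for three player-position exposure profiles;
2. **Finite-element simulation** — explicit dynamics of an idealized 2D
   sulcated brain cross-section driven by prescribed rigid skull motion;
3. **Field encoding** — per-element peak maximum-principal Green–Lagrange
   strain and strain rate, rasterized to NIfTI volumes with a congruent
   sulcal/gyral atlas;
4. **Region-of-interest summary** — whole-brain 90th percentiles and
   per-impact sulcal and gyral means;
5. **Cohort statistics** — paired sulci-vs-gyri comparison, one-way and
   mixed repeated-measures ANOVA across profiles, Pearson correlations and
   multiple regression of sulcal metrics on peak kinematics.

This vignette records the model, its assumptions, the parameter choices
that matter, and the design decisions taken where the design was genuinely
open. Every empirical statement here is computed by the package's test
suite or acceptance script; nothing is quoted from external data.

## The synthetic kinematics generator

No public corpus of reconstructed football-impact kinematics exists, so the
generator stands in for laboratory reconstructions. Each impact is a smooth,
compactly supported half-sine acceleration pulse — the standard idealization
of helmeted-impact accelerometer traces — sampled at 0.05 ms (at least 40
samples across the shortest admissible 2 ms pulse) with a 10 ms quiet tail
so integrated velocities settle.

Three exposure profiles are built in, reflecting the published grouping of
positions by impact magnitude and frequency: profile 1 (defensive
back/quarterback/wide receiver: high magnitude, low frequency, n = 49),
profile 2 (n = 69) and profile 3 (linemen: low magnitude, high frequency,
n = 30), 148 impacts in a default cohort. Per-profile peak targets
(means, with parent-normal SDs in parentheses):

| quantity | profile 1 | profile 2 | profile 3 |
|---|---|---|---|
| peak linear velocity (m/s) | 3.9 (2.2) | 3.1 (1.7) | 2.8 (1.5) |
| peak rotational velocity (rad/s) | 25 | 19 | 18 |
| peak rotational acceleration (krad/s²) | 3 | 2 | 2 |

Calibration conventions:

- **Zero-truncated, moment-matched normals.** Peaks are physically
  non-negative, so each is drawn from a normal truncated at zero whose
  parent location is solved (by `uniroot`) so the *post-truncation* mean
  equals the target. A naive parent-mean parameterization would bias the
  profile-1 linear-velocity mean upward by about 0.19 m/s. The realized SD
  is slightly below the parent SD — the price of truncation.
- **Rotational dispersions by CV transfer.** The source table's rotational
  SDs are typographically inconsistent with their means (e.g. 25 ± 0.012
  rad/s), so every rotational SD is set to the mean times the coefficient
  of variation of the matching linear quantity. One rule, applied uniformly.
- **Pulse duration from the rotational pair.** A half-sine pulse links its
  peak velocity and acceleration through Δv = 2AT/π, so at most three of
  the four peak quantities can be calibrated independently. The generator
  draws peak linear velocity, peak rotational velocity and peak rotational
  acceleration, derives the impact's single duration T = πω/(2α) (clipped
  to 2–30 ms, re-deriving α if the clip engages so the drawn velocity is
  preserved), and derives the linear acceleration A = πv/(2T). Anchoring T
  to the rotational pair lets rotational acceleration carry the
  pulse-sharpness role it has in real impacts; anchoring it to the linear
  pair would instead make the *linear*-acceleration column the only carrier
  of 1/T information, distorting the kinematics-to-strain regressions by
  construction. Typical durations land near 13 ms. The drawn velocities are
  exact by construction; derived linear accelerations average near (though
  not exactly at) the published 428/329/273 m/s² values.
- **Loading directions.** Each impact gets an independent uniform random
  unit direction for linear acceleration and axis for rotational
  acceleration, fixed over the pulse; the impact-location taxonomy of the
  original reconstructions is not reproducible without video.

What the generator deliberately does *not* emulate: correlation between
linear and rotational severity within an impact beyond the shared duration,
impact-location structure, helmet/neckform mechanics, and the fall-specific
pulse shapes (falls reuse the collision pulse with the fall speed-class
ladder).

## The idealized brain model

The simulation domain is a 2D plane-strain coronal cross-section: an
annulus of brain tissue whose outer cortical surface carries 12 sinusoidal
folds of 12 mm trough-to-crest amplitude, a cerebrospinal-fluid (CSF) layer
filling the gap up to a rigid circular skull of 80 mm radius (2 mm gap at
fold crests), and a small free inner boundary of 12 mm radius standing in
for the ventricular void. Default element size is 1 mm (about 20k
quadrilaterals); the structured polar mesh keeps all interior angles well
inside (20°, 160°).

Two geometric choices deserve comment:

- **Annulus, not disc.** A structured polar mesh degenerates at r = 0; a
  small central hole keeps every element well-shaped. The hole is kept
  *small* deliberately: a large free inner boundary lets pure translation
  ovalize the annulus and generate spurious shear. At 12 mm, a typical
  translational load produces between a quarter and a half of the sulcal
  strain of a typical rotational load (the in-plane projection of the
  random impact direction sets the exact fraction), against near parity at
  25 mm; rotation dominates, as it should for a brain enclosed in
  near-incompressible fluid.
- **Open sinusoidal folds.** Real sulci are slits whose opposing walls
  nearly touch; desk-scale meshing of slits is not robust, so the folds are
  open valleys. This preserves the fundus-focused strain concentration but
  changes the smooth-versus-sulcated comparison (see *Limitations*).

The ROI atlas mirrors fundus-focused sulcal labelling: cortical elements
(within 6 mm of the local brain surface) are labelled per fold, *sulcal*
where the surface modulation is in the deeper half of its trough-to-crest
span (fundus and lower walls), *gyral* around the crests; deep brain and
CSF are class `other`. The smooth control mesh (zero fold amplitude) has
gyral-class sectors only. Region counts are configurable and are not meant
to replicate the 30-gyri/33-sulci Destrieux parcellation.

## The explicit finite-element solver

The solver is total-Lagrangian explicit central-difference dynamics with
lumped mass, single-point quadrature and stiffness-based hourglass control
(coefficient 0.05), written in C++ via Rcpp. Skull nodes follow the rigid
motion obtained by twice-integrating the kinematics trace — in-plane
projection of linear acceleration for translation, resultant rotational
acceleration magnitude for planar rotation about the domain centroid (2D
cannot represent three-axis rotation; magnitudes preserve load severity).
Interior nodes evolve under internal forces; the inner boundary is free.

The constitutive model is compressible neo-Hookean,
σ = μ J^(−5/3) dev(B) + K(J − 1)I in plane strain, with optional
Prony-series relaxation applied to the deviatoric Cauchy stress by the
standard recursive update. Defaults: brain μ = 2.5 kPa, CSF μ = 0.05 kPa
(a very soft solid that transmits little shear, standing in for fluid CSF),
K = 50 MPa for both, densities 1040/1000 kg/m³. These sit in the range
standard for brain finite-element models; the exact values are
configuration-exposed, and the near-incompressibility level (K/μ = 2×10⁴
for brain) is chosen so the dilatational wave speed, hence the explicit
time step, stays tractable.

Numerical choices:

- **Adaptive time step.** The CFL estimate (0.9 × element characteristic
  length / dilatational wave speed) is re-evaluated every 25 steps from the
  *current* geometry. This matters: while the brain lags the rotating
  skull, CSF elements shear to γ ≫ 1 and their characteristic length
  collapses far below its reference value; a fixed reference-based step
  diverges mid-pulse. With adaptation, full cohorts at 4 mm resolution
  complete without divergences.
- **Strain measures.** Per element, F is evaluated at the centroid from
  reference shape-function gradients (affine-exact), E = ½(FᵀF − I), and
  the running peak of the maximum principal value of E is recorded at
  every step. The strain rate is the maximum principal value of the
  finite-difference (E_now − E_prev)/Δt — the tensor is differentiated
  first, then its principal value taken — also tracked every step, since
  rate peaks are cadence-sensitive.
- **Damping** is mass-proportional, default 0; it suppresses low-frequency
  ringing but biases strain-rate peaks, so it is off unless requested.
- **Divergence handling.** Non-finite or runaway displacements, or a
  collapsed time step, abort the run with the failure time in the error.

## Rasterization, NIfTI and ROI summaries

Per-element peak fields are transferred to a regular voxel grid by
piecewise-constant point-in-element lookup (no smoothing — interpolation
would blur exactly the sulcal concentrations of interest), stored as
one-slice float32 NIfTI-1 volumes with an RAS+ affine. The atlas volume is
produced by the same transfer on the same grid, so field-to-atlas
registration is exactly the identity — the synthetic setting has no real
MRI to register to.

Per impact: the whole-brain severity scalar is the 90th percentile of
in-brain voxel values (linear interpolation between order statistics, the
dominant software convention; index 0.9(n−1)), robust against abnormally
large strains in poorly shaped elements. Per-ROI means are arithmetic voxel
means within each label; the collapse to one sulcal and one gyral value per
impact is the *unweighted mean over ROI means* (each region counts once);
the voxel-weighted alternative is computed alongside and carried in the
cohort table.

## Cohort statistics

All engines are the classical base-R fits; the package adds the selection
logic, effect sizes and reporting:

- **Paired sulci vs gyri:** Shapiro–Wilk on the paired differences at
  α = 0.05 gates a two-tailed paired t-test versus the Wilcoxon signed-rank
  test. Cohen's d is the paired variant, mean(diff)/SD(diff) — the variant
  consistent with a large reported d despite near-equal group SDs.
- **One-way ANOVA** of each kinematic and deformation measure on profile,
  reported as F(k−1, N−k) with Tukey HSD post hoc via the
  studentized-range distribution.
- **Two-way mixed repeated-measures ANOVA** (between = profile, within =
  region with the two levels gyral/sulcal) via the standard
  `aov(... + Error(subject/region))` partition. The response is
  square-root transformed by default, falling back to log when
  Shapiro–Wilk on the cell residuals still rejects; the choice is recorded
  in the result.
- **Correlations:** Pearson r per kinematics/metric pair, reported as r²
  with a 95% CI from the Fisher z-transform on r, then squared and ordered
  (lower bound 0 when the r interval straddles zero).
- **Regression:** OLS of each sulcal metric on the four peak-kinematics
  predictors with per-predictor β, two-sided p and 95% CI; a condition
  number above 100 on the scaled design flags collinearity in the result
  without suppressing estimates.

Degenerate inputs (zero-variance strain columns, e.g. from zero-amplitude
pulses) are flagged in the report rather than raised as errors.

## Problem sizes and reproducibility

The package's own desk scale, used throughout the tests and examples:
cohort simulations run on a 4 mm element mesh (~1.3k elements) for 45 ms
per impact with 2 mm voxels; the sulci-vs-gyri smoke cohort is
n = 5/7/3 = 15 impacts, the profile-contrast cohort n = 16/23/10 = 49;
generator-calibration checks use 10,000 impacts per profile. A full
148-impact cohort at this resolution simulates in about five minutes on
one core. The default 1 mm mesh is for higher-fidelity single-impact
studies.

Reproducibility: every stochastic element is seeded; cohorts derive
per-event child seeds from the master seed by a counter, so cohort
composition is invariant to processing order, and a repeated pipeline run
writes byte-identical CSV outputs.

## What the synthetic setting does and does not show

The generator and idealized mesh reproduce the *conditions* of the study —
cohort sizes, per-profile peak-velocity calibration, pulse time scales, a
folded cortex inside rigid skull-prescribed motion — but not its anatomy or
measurement noise. Accordingly, passing tests demonstrate internal
correctness (strain algebra against closed forms, calibration of the
statistics, directional reproduction of the headline orderings), not
quantitative agreement with subject-specific simulations: absolute strain
magnitudes here are several-fold larger than values from million-element
head models, because a 2D plane-strain slice cannot shed load
out-of-plane.

Known limitations found and kept, with their mechanisms:

- **Smooth-versus-sulcated contrast is reversed.** With open sinusoidal
  valleys, the skull couples to the brain mainly through the crest caps,
  concentrating the transmitted shear into less cortical area: gyral strain
  in the sulcated mesh *exceeds* the smooth control's cortical strain.
  Reproducing the published reduction of non-sulcal cortical strain when
  sulci are introduced appears to require slit-like sulci whose opposing
  walls decouple the gyral crowns. The within-mesh concentration (sulcal >
  gyral) is reproduced robustly, with a paired effect size comparable to
  the published one.
- **Strain-rate direction between sulci and gyri is reversed** (gyral
  slightly higher): rate peaks occur during the pulse at the strongly
  coupled crests, while fundus strain builds more slowly.
- **Linear kinematics remain weakly predictive in the joint regression.**
  The pipeline is noise-free — the FE response is a deterministic function
  of the pulse — so the small but genuine 2D translation pathway (CSF
  squeeze flow around the annulus) is detected as significant at any
  realistic cohort size, where real reconstruction noise would swamp it.
  The directional result — rotational velocity and acceleration carry far
  higher r² than their linear counterparts and dominate the joint fit — is
  reproduced.
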