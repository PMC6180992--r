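---
title: "Greedy-snake adipose quantification on abdominal CT: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy-snake adipose quantification on abdominal CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoquant)
```

This vignette is the package's account of its science: the segmentation
model and its assumptions, the parameters that matter, what the synthetic
generators do and do not emulate, the numerical choices, and the known
limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The segmentation model

An axial abdominal CT slice, in Hounsfield units (HU), is assumed to show
one connected body cross-section surrounded by air, with (from outside
in) skin, a subcutaneous fat layer, the abdominal muscle wall, and the
visceral compartment. Quantification proceeds in four stages.

**Body mask.** Air is below roughly −900 HU and every tissue of interest
above −190 HU, so a fixed threshold separates body from background.
The default `body_hu_min = -500` sits halfway between the two regimes:
it keeps the full adipose window ([−190, −30]) while excluding air. The
scanner table and trays pass this threshold too, but are thin; a
morphological opening with a disc of radius 3 px deletes them, the
largest 8-connected component removes any remaining debris, and interior
holes (bowel gas) are filled. On a noiseless phantom the resulting mask
equals the drawn body exactly (this is asserted in the tests).

**Outer body contour.** The mask boundary is traced with Moore-neighbor
tracing. The walk starts at the top-most then left-most foreground pixel
and proceeds clockwise; termination is Jacob's criterion — the walk ends
when its start state (pixel plus entry direction) recurs — implemented as
cycle detection on the (pixel, backtrack-direction) state space, which is
robust to spur pixels the walk legitimately visits twice. One property
worth knowing: a foreground pixel whose only background contact is
diagonal is *not* part of the Moore walk. This is canonical behavior (the
suite cross-checks the visited set pixel-for-pixel against
`EBImage::ocontour`, an independent implementation), so the
boundary-set-equivalence tests use masks in which every boundary pixel
touches background 4-adjacently — the regime where the walk and the
8-neighbor boundary enumeration provably coincide.

**Greedy snake.** The traced contour is resampled to (default) 5 px
arc-length spacing and refined by a discrete greedy active contour. Each
point `v`, visited in order, moves to the position in its 3×3 window
minimizing

`E(v) = α·Ê_cont(v) + β·Ê_curv(v) + γ·e_img(v) + δ·Ê_pres(v)`

with `E_cont = (d̄ − |v − v_prev|)²` (deviation from the mean spacing
d̄), `E_curv = |v_prev − 2v + v_next|²` (discrete curvature),
`e_img = 1 − g/max(g)` for the Gaussian-smoothed gradient magnitude `g`
of the HU image clipped to the soft-tissue window [−200, 200], and
`E_pres` the signed displacement along the local outward normal, so that
inward candidates score lower. The geometric terms are min–max normalized
within each candidate window; the image term is normalized globally so
that edge strength remains comparable across the image. Ties keep the
current position; otherwise the smallest row, then column, wins — the
algorithm contains no randomness.

Three numerical choices deserve explanation:

* *Snapshot neighbors.* Candidates are evaluated against the contour as
  it stood at the start of the pass, not against already-updated
  neighbors. With immediate updates, one point's inward move drags the
  next point's curvature optimum inward, and the chain becomes a
  self-sustaining contraction wave that erodes a contour even on a
  featureless image. With snapshot neighbors every update is
  greedy-optimal with respect to the pass-start contour (the test oracle
  re-derives each update by brute-force window enumeration under exactly
  this semantics) and a smooth closed contour is a fixed point.
* *Real-valued positions.* Resampled points keep their exact arc-length
  positions; moves are whole-pixel steps and the raster (energy, clamp,
  bounds) is consulted at the nearest pixel. Snapping resampled points to
  the lattice makes the discrete curvature term jagged, and strict greedy
  descent then never reaches a fixed point on smooth contours. No
  sub-pixel *edge refinement* is claimed — the snake's moves are still
  integer steps.
* *Corner relaxation omitted.* Body and cavity outlines are smooth, so
  the classic corner-relaxation pass is dropped. The consequence,
  measured in the tests, is that sharp fixture corners are rounded: on a
  16 px square a point spacing of ~3 px is needed for every point to land
  within 1 px of the edge, while anatomical contours are well served by
  the default 5 px.

Default weights are α = 1, β = 1, γ = 1.5 (edge term emphasized, common
greedy-snake practice) and δ = 0 for the body stage.

**Abdominal cavity contour.** The refined body contour is contracted
inward by the same snake with pressure δ = 0.3 and a clamp restricting
candidates to the body mask eroded by one pixel (initial points are
snapped to the nearest clamped pixel). Left alone, the snake would lock
onto the strongest gradient it starts on — the skin edge — so the energy
is recomputed with all gradients within `skin_band_px = 4` of the body
contour zeroed *before* normalization. Zeroing before normalization
matters: the air–skin interface is by far the strongest gradient in the
image, and normalizing by it would compress the abdominal-wall edge
contrast the contraction must stall on. The pressure term then drives the
contour through the (featureless) subcutaneous fat ring until the wall's
gradient ridge outweighs it. δ = 0.3 traverses the ring and stalls on
the wall; substantially larger pressure (δ = 1 at the default smoothing
σ = 2) walks through the wall's Gaussian-tail flanks and collapses the
contour, which the code reports as a `CavityNotFound` condition (also
raised when the enclosed area falls below 25 px², the behavior on
genuinely featureless interiors).

**Quantification.** Adipose pixels are those with −190 ≤ HU ≤ −30,
bounds inclusive (clinical pixel HU are effectively integers; inclusivity
is declared and configurable). Regions come from rasterizing the filled
body and cavity polygons with boundary pixels included; SAT is the exact
set difference, so `TAT = VAT + SAT` holds at the pixel-count level by
construction, and `VTR = VSR/(1+VSR)` wherever both ratios are defined.
Areas are pixel counts × pixel area; waist circumference is the physical
(anisotropic-spacing) perimeter of the body contour — the simplest
operational reading; a convex-hull perimeter was considered and rejected
because the traced body is already convex for the anatomy modeled here.
Analysis-slice selection takes the first maximum of TAT area or of waist
circumference.

## 2. The phantom generator

`generate_phantom()` draws concentric ellipses: air background
(−1000 HU), a 2 px skin shell (20 HU), a subcutaneous fat ring
(−100 ± 15 HU, centered in the adipose window), a muscle wall
(40 ± 10 HU), and an organ interior (40 ± 12 HU) carrying
rejection-sampled, non-overlapping visceral fat blobs kept ≥ 2 px inside
the organ region; optionally a detached table strip (−300 HU) below the
body; plus global acquisition noise (5 HU). Default geometry (192×192 px
at 2 mm pixels; body semi-axes 60×75 px; 12 px fat ring; 5 px wall; 8
blobs of radius 5–10 px) yields areas around 180 cm² SAT and 60 cm² VAT
— a realistic mid-abdominal slice. Ellipses are rasterized by
center-of-pixel inclusion so truth areas are exact pixel counts; the same
seed reproduces a phantom bit-for-bit.

The truth `cavity_mask` is the region enclosed by the *outer* margin of
the muscle wall (the fat–muscle interface). The wall's inner margin is
invisible by construction — organ and muscle share a 40 HU mean — so the
interface is the only edge a gradient-driven contour can converge to;
the adipose areas are invariant to this convention because the wall
contains no fat-window pixels.

What the phantom does *not* emulate: bone, organ texture, contrast
agents, beam hardening, arms-down or multi-body fields of view, and
non-convex body outlines. Passing the phantom suite therefore
demonstrates the pipeline's correctness under its stated anatomical
assumptions, not clinical-grade performance on real scans.

One inherited consequence worth stating plainly: when the subcutaneous
ring is absent (`sat_thickness_px = 0`), the wall's outer margin sits
directly under the skin, inside the suppression band, so the contraction
can only stall on visceral-fat edges much deeper in. Total fat is still
recovered exactly (the wall contains none), but the VAT/SAT split is
unreliable for bodies with essentially no subcutaneous fat. The tests
assert the conserving behavior, not a near-body contour, for this
configuration.

## 3. The synthetic EHR generator

`generate_synth_ehr()` emulates the association structure of an
imaging-PheWAS cohort: age ~ Normal(54, 17) truncated to 18–95, 51.4 %
female; VAT and SAT lognormal with latent correlation 0.5 and
sex-specific means (male VAT higher, female SAT higher); diagnoses drawn
from logistic models with user-chosen odds ratios per standard deviation
of log-adipose measure plus age/sex effects; visit counts of
`2 + Poisson(3)` for diseased subjects and 0 (90 %) or
`1 + Poisson(0.5)` for healthy ones, populating all three bands of the
case/control rule; labs linear in the standardized measures with Gaussian
noise. Effect sizes are always user choices — the defaults are
illustrative, not estimates of any cohort. The truth object records every
generating parameter and the standardized exposures the effects were
applied to.

The visit-count mechanism slightly contaminates case sets (a healthy
subject has a ~0.9 % chance of ≥3 visits), attenuating recovered odds
ratios by roughly 5 % at the default prevalence — visible in, and
accepted by, the parameter-recovery bounds.

## 4. The association procedure

Exposures are Box-Cox transformed (power chosen by profile-likelihood
grid search on [−5, 5], step 0.01; the λ = 0 branch is the natural log;
non-positive inputs are a hard error, no automatic shifting) and then
standardized. Diagnosis outcomes use logistic regression via IRLS
(tolerance 1e−8, ≤100 iterations) with Wald standard errors,
normal-approximation p-values, and `exp(β ± 1.96·SE)` confidence
intervals; separation or non-convergence sets a `converged = FALSE` flag
rather than raising, because non-converged models are a reported,
filtered category in this kind of analysis. Lab outcomes are trimmed in
a single two-sided pass at 2.5 SD (mean and SD from the full sample;
trimming precedes any log transform — the order is not identifiable from
standard practice, so one order is fixed and exposed) and fit by least
squares. Sex-combined models adjust for age and sex (optionally a
diabetes flag); sex-stratified models adjust for age.

Multiple testing uses the exact Bonferroni arithmetic
`α/(n_outcomes × n_exposures)` per outcome family (0.01/(35×4) =
7.14×10⁻⁵ for a 35-lab, 4-exposure family) and Benjamini–Hochberg
step-up at q = 0.01 within family × stratum × model over converged rows;
BH is the declared choice for the otherwise unnamed FDR procedure.

## 5. Problem sizes used by the checks

The accuracy suite runs 50 default phantoms (consecutive seeds); the
greedy-step oracle enumerates all candidate windows for 100 random
contours and energy fields on 32×32 images; the boundary-tracing oracle
uses 200 random disc/rectangle masks; type-I calibration uses 1000
simulated null cohorts of n = 400 and parameter recovery 100 cohorts of
n = 5000 with a planted odds ratio of 2.0. These sizes give stable
estimates (binomial SE ≈ 0.7 % for the type-I rate) while keeping the
full suite around a minute of CPU.

## 6. Known limitations

* Real CT: no bone handling, no multi-body/arms-in-field logic, no
  contrast-agent or beam-hardening correction; the body threshold and
  snake weights were chosen for the phantom's textbook HU contrasts and
  are exposed as configuration for tuning on real data.
* The cavity contour's radial position inside the muscle wall is only
  defined up to the wall's edge profile (±1–2 px); adipose areas are
  insensitive to it, but the cavity *area* itself carries that
  uncertainty (≈2–3 % on the default phantom, asserted at ≤5 %).
* Thin-SAT anatomy: see Section 2 — the VAT/SAT split degrades when the
  subcutaneous layer vanishes.
* DICOM support covers uncompressed little-endian single-frame CT only.
* The PheWAS stage models each outcome independently; no phecode
  grouping, longitudinal modeling, or survival analysis.
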