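---
title: "Quantifying axon initial segment geometry from fluorescence line profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axon initial segment geometry from fluorescence line profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
set.seed(1)
```

```{r setup, message = FALSE}
library(aismorph)
library(dplyr)
```

## The measurement problem

The axon initial segment (AIS) is the proximal axonal domain where action
potentials initiate; in fluorescence micrographs it appears as a span of
enriched ankyrin-G (ankG) labeling along one neurite. Two geometric
variables carry physiological meaning: the **distance from the soma edge to
the AIS onset** and the **AIS length**. Both shift in activity- and
disease-dependent ways, so a reproducible, operator-independent way of
reading them off an image matters.

The raw observable is an intensity line profile: an analyst traces the
labeled neurite from the soma edge outward, and the marker channel is
sampled along that polyline. Calling AIS bounds by eye on such profiles is
subjective; this package implements the systematic alternative — a fixed
processing chain with every constant exposed — plus a synthetic-data
generator that produces neurons with *known* geometry, so the whole chain
can be validated as a measurement instrument before it touches real data.

A cell's AIS **localization** is an annotation made at tracing time:
`direct` (the AIS sits on a process stemming directly from the soma),
`acd` (on an axon-carrying dendrite, distal to a bifurcation in a primary
dendrite), or `multi` (ankG enrichment on several neurites, indicating
failed axon specification).

## The processing chain

Given an arc-length profile $I(d)$ sampled every `step` µm from the soma
edge, `quantify_ais()` applies three stages:

1. **Rolling-ball background subtraction.** The baseline is estimated as
   the grayscale opening of the profile with a ball structuring element —
   a semicircle spanning `rolling_ball_radius` samples whose vertical
   semi-axis equals the profile's dynamic range — and subtracted.
   Scaling the element with the signal range (as classic rolling-ball
   implementations do) makes the subtraction *exactly* invariant to
   additive offsets and positive gain, which the downstream threshold rule
   then inherits.
2. **Savitzky–Golay smoothing.** Sliding-window least-squares fits of a
   first-order polynomial (`savgol_window` samples, default 11); at the
   profile ends the window is truncated and the fit evaluated at the
   sample position. A first-order fit with a symmetric window reduces to a
   running mean in the interior but handles the edges without padding
   artifacts.
3. **Half-of-range bounds.** With baseline $b = \min$ and maximum $M$ of
   the smoothed profile, the AIS is the maximal contiguous run of samples
   strictly above $\tau = b + \tfrac12 (M - b)$ that contains the global
   maximum (first occurrence on ties). The start distance is the first
   sample of that run; the length is the run's span plus one sampling
   step. Other supra-threshold runs are only counted (`n_extra_runs`),
   never measured — multi-AIS classification is a per-cell annotation,
   not a per-profile inference.

A profile whose smoothed dynamic range falls below
`min_prominence_fraction` × max(M, 1 intensity unit) is reported
`undetermined` rather than measured. This makes the otherwise informal
"too weak to call" exclusion explicit and auditable. Note the floor mixes
a relative and an absolute scale: in intensity units where the noise floor
exceeds 1 unit, a profile containing only noise can still clear it. The
floor is a guard against degenerate inputs, not a general detection test.

```{r}
sim <- simulate_profiles(1, generator_config(), seed = 42)
quantify_ais(sim$profiles)
sim$truth[, c("localization_class", "true_start_um", "true_length_um")]
plot_profile(sim$profiles)
```

### Choosing the rolling-ball radius

The radius is dimensionless — it is measured in profile *samples* — so the
value that works depends on the sampling density. The opening removes
(from the background estimate) only features narrower than the ball: an
AIS spanning more samples than about twice the radius is absorbed into the
baseline and destroyed by the subtraction. At this package's default
sampling of one pixel-equivalent (0.2 µm/sample), AIS spans of 5–40 µm
occupy 25–200 samples, so the default radius is **250 samples**,
comfortably above the widest genuine span; the same analysis exported at a
coarser per-pixel scale of about 1 µm/sample is matched by a radius of
50. The radius is a `bounds_config()` field, and profiles at other scales
should set it to at least the widest expected AIS span in samples.

### Numerical behavior worth knowing

* **Tie-breaks.** If several samples share the global maximum, the run
  containing the first one is measured.
* **Discrete ball curvature.** A single-sample spike is not mathematically
  invisible to the discrete ball: the background may rise by up to
  $(\sqrt{r^2-1}-r+1) \cdot \text{range}/r$ at the spike (about 0.02
  intensity units at `r = 50` on a range-100 profile).
* **Gain equivariance of the peak.** Detected geometry is exactly
  gain-invariant; the reported `peak_intensity` scales with gain up to
  floating-point rounding.
* **Edges.** Rolling-ball padding is by replication; the Savitzky–Golay
  edge fit uses the truncated window. Both choices avoid fabricating
  out-of-range data.
* **Degenerate inputs.** Empty profiles, non-finite intensities,
  even smoothing windows, and windows longer than the profile are errors;
  a flat profile is `undetermined`.

## Profile extraction

`extract_profile()` emulates the ImageJ line-profile export: samples every
`step` µm (default one pixel-equivalent) along the hand-traced polyline,
each the mean of `line_width` (default 3) bilinear interpolations taken
perpendicular to the local direction. Distance 0 is the first trace vertex
— the soma edge — because the biological convention measures AIS distance
from the soma edge, and the soma interior is never part of the trace. The
far endpoint is included when it lands on the sampling grid.
Perpendicular samples falling outside the image are clamped to the border;
a 3-px width tolerates roughly ±1 px of tracing error. The freehand line
width used for the original exports is not recoverable, so it is exposed
as a parameter rather than guessed as a constant.

## The synthetic generator as a validation instrument

`simulate_neuron()` renders a two-channel scene: a fill channel (soma disk
plus anti-aliased neurite strokes, default 3 px wide) and a marker channel
carrying intensity only along the true AIS spans. Truth values are drawn
from truncated normals:

| quantity | default | rationale |
|---|---|---|
| direct AIS start | N(3, 1.5) µm, ≥ 0 | proximal onsets for soma-attached axons |
| AcD AIS start | N(8, 3) µm, > bifurcation + 1 | AcD onsets sit farther out, strictly distal to the branch |
| AIS length | N(20, 5) µm, ≥ 0.5 | typical AIS extent at this developmental stage |
| bifurcation distance | U(2, 5) µm | short primary-dendrite stems |
| pixel size | 0.2 µm/px | typical of a 60× confocal acquisition |
| class probabilities | 0.593 / 0.353 / 0.054 | the localization mix of the microfluidic culture condition |

The AIS longitudinal profile is a raised-cosine plateau whose smooth
shoulders span 10% of the length on each side, positioned so the
half-maximum crossings fall *exactly* at the true start and end. Bound
recovery is therefore non-trivial (the edges are ramps, not steps) yet has
an analytic answer. Noise is composed in a fixed order — clean → Poisson
(`poisson_scale` photons per unit) → additive Gaussian → smooth background
(constant plus linear gradient) — so a seed fully determines a scene. At
the defaults the marker-channel SNR (AIS amplitude over noise SD) is
about 19; the recovery guarantees quoted below are stated for SNR ≥ 5.

`simulate_profiles()` is the 1D fast path: it draws the same truth and
noise structure directly on an arc-length grid, skipping rasterization.
Property sweeps over hundreds of neurons use it; scene-level tests and the
end-to-end experiment exercise the full raster → trace → extract chain.

What the generator does *not* emulate: PSF blur, 3D structure,
photobleaching, tracing error beyond the line-width tolerance, and
biological profile irregularity (real ankG spans are not smooth plateaus).
Passing the synthetic suite therefore shows the *algorithmic* chain is
correct and stable under realistic noise — it does not certify
performance on real micrographs with out-of-model artifacts.

### The axonopathy mode

`apply_axonopathy()` models a microtubule-destabilizing axonal insult as
it manifests in this assay: the AIS start moves **toward** the soma by
`ais_start_shift` (clamped at zero and flagged), varicosity bumps appear
on the fill channel distal to the AIS, and intensities beyond an onset
distance are attenuated (axon retraction / transport loss). The default
shift of 3 µm was chosen once: small enough that clamping at the soma is
rare under the AcD start distribution (< 5% of draws), large enough (15
sampling steps) to be unambiguous. Varicosity bumps are placed uniformly
at random but at least 4σ apart, so each remains a distinct local
maximum and the configured count is recoverable from the noiseless
profile.

`run_endtoend()` stages the paired experiment: every cell is simulated as
vehicle; cells in the effect classes (default AcD only) are re-rendered
with the effect, *sharing the vehicle noise stream*. Pairing removes
cohort-sampling variance from the truth-recovery comparison — the
recovered shift estimates the configured shift directly rather than a
difference of two independent samples — which is what a parameter-recovery
validation should measure. Cells outside the effect classes are
bit-identical across arms.

```{r, eval = FALSE}
report <- run_endtoend(run_config(seed = 1))
glance(report) # truth-vs-recovered shift table
```

## Group statistics and exclusion rules

`summarize_dimensions()` applies the dimension-analysis exclusions in a
fixed order and reports every tally: (1) `undetermined` cells, (2) `multi`
cells (no primary axon can be assigned), (3) replicates with fewer than
`min_ais_per_device` (default 3) determined AISs of a localization type.
The unit of analysis is the replicate: group statistics are computed over
per-replicate means, never over pooled cells. The device threshold is a
package default — the underlying exclusion practice ("too few identifiable
AISs") has no published number — so it is configurable and logged.

`localization_proportions()` reports percentages at a mixed precision
(integers below 200 cells per group, one decimal above), matching how such
cohorts are conventionally reported; raw proportions are always kept.
`grubbs_test()` is the two-sided single-outlier variant with the
Student-t critical value, applied at most once per comparison group.
`chi_square_homogeneity()` delegates to `stats::chisq.test()` without
continuity correction after dropping classes absent from every group.
Downstream inferential machinery (ANOVA, multiple-comparison procedures,
non-parametric tests) is deliberately left to standard R routines.

## Problem sizes used in validation

The shipped suite validates bound recovery on 500 seeded profiles (≥ 95%
must be determined with start error ≤ 2 samples and length error ≤ 4
samples), sweeps true length 5→40 µm for monotonicity, drives amplitude to
zero for the undetermined-fraction limit, and runs the paired axonopathy
experiment at 6 replicates × 30 cells per arm, requiring the recovered
AcD shift to land within 2 sampling steps of the configured one with
direct starts and all lengths unchanged. Every stage with a closed-form or
brute-force alternative (rolling ball, Savitzky–Golay, Pearson
correlation, chi-square, Otsu threshold, Grubbs critical value) is checked
elementwise against an independently coded oracle.

## Known limitations

* The prominence floor is a degenerate-input guard, not a detection test;
  at noise floors above ~1 intensity unit it will not, by itself, reject
  noise-only profiles (the original exclusions were made by a human
  looking at the image).
* The rolling-ball radius must be re-chosen when the sampling density
  changes; no automatic scaling is attempted.
* The generator's AIS is a smooth plateau; real profiles with strong
  internal structure (e.g., beaded ankG) may split at the half-maximum
  threshold, in which case only the run containing the global maximum is
  measured.
* Colocalization is the global masked Pearson coefficient (with optional
  Manders coefficients); no Costes-style significance randomization is
  provided.
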