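---
title: "Quantifying synapses in 3D: models, corrections and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synapses in 3D: models, corrections and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapse3d)
```

## What this package computes

Volume electron microscopy (FIB/SEM) yields stacks of aligned serial
sections from which every chemical synapse in a block of cortical neuropil
can be reconstructed in 3D. Downstream of segmentation, a quantitative
study of two subject groups needs five layers of analysis, and `synapse3d`
implements all of them:

1. **Stereology** — Cavalieri point counting of semithin sections for the
   volume fractions of neurons, glia, blood vessels and neuropil, with the
   neuropil obtained by complement
   (`Vv_neuropil = 100 - (Vv_neurons + Vv_glia + Vv_vessels)`), plus
   cortical-thickness summaries.
2. **Corrections** — tissue shrinkage from EM processing (the areal factor
   `p²`, default 0.933) and discounting of fixation artifacts (swollen
   processes) from counting volumes.
3. **Counting** — an unbiased 3D counting frame (Howard–Reed brick) over
   fully reconstructed synaptic junctions, giving densities per µm³ and
   asymmetric/symmetric (AS/SS) proportions.
4. **Morphometry** — area, perimeter and curvature of the synaptic
   apposition surface (SAS), the interface between pre- and post-synaptic
   densities, with log-normal fits of the size distributions.
5. **Spatial statistics** — 3D G, F and K functions with complete spatial
   randomness (CSR) envelopes from 100 simulations, nearest-neighbour
   distances, and the hard-core "dead space" readout.

Because segmented human material cannot be redistributed, the package
includes a first-class synthetic generator whose defaults emulate the
statistical structure of layer-II transentorhinal neuropil in a
5-control-vs-5-patient design; every stage of the pipeline is exercised
and validated against it.

## The synthetic generator: what it emulates

`generate_study()` draws two groups of cases. Each case contributes three
image stacks with the standard FIB/SEM geometry (2048 × 1536 px at
5 nm/px, 20 nm sections; 270 sections by default, i.e. a raw
10.24 × 7.68 × 5.4 µm window whose shrinkage-corrected volume, 471 µm³,
matches the mean stack volume of the emulated design).

* **Positions.** Synapse centroids follow a hard-core process generated by
  random sequential adsorption (RSA) with a fixed target count
  `round(intensity × available volume)`. RSA was chosen over thinning
  because it matches the phenomenology — synapses are extended objects
  that cannot overlap — while keeping the realised intensity controllable.
  The default hard-core radius is 250 nm (minimum centroid separation
  500 nm), consistent with the empty "dead space" seen in empirical
  G functions; the true biological hard-core scale is not identifiable
  from group summaries, so this default is configurable rather than
  asserted.
* **Intensity scale.** Group intensities (0.51 ± 0.14 µm⁻³ control,
  0.37 ± 0.15 µm⁻³ disease, between-case SD) are interpreted on the
  *shrinkage-corrected* scale on which results are reported. The generator
  converts to raw stack coordinates (dividing by `p2^{3/2}`), so
  quantifying the stacks at `p2 = 0.933` recovers the requested values.
  The same convention applies to SAS areas.
* **Types.** Each synapse is AS with probability 0.9564 (control) or
  0.9447 (disease), independently.
* **SAS geometry.** Each synapse carries a log-normal area
  (`mu = log(mean) − sigma²/2`, `sigma = 0.73`, giving the heavy right
  tail typical of synaptic sizes; means 117,800/76,190 nm² for control
  AS/SS and 123,200/67,750 nm² for disease) and a Beta-distributed
  curvature index (mean 0.049, SD 0.05). When meshes are requested, each
  synapse is realised as a randomly oriented spherical cap — the only
  simple surface family in which area and the area-ratio curvature index
  can be dialled independently (`curvature = (1 − cos θ)/2` for a cap of
  half-angle θ; 0 is a flat disc, 0.5 a hemisphere).
* **Artifacts.** Fixation-artifact volumes are axis-aligned ellipsoids
  placed in disjoint slabs of the window (guaranteeing non-overlap up to a
  45% fill), occupying a per-stack fraction drawn uniformly from 3–33%,
  the empirically observed range. Their total volume is analytic and
  exact.
* **Thickness and volume fractions.** Case thickness is Normal
  (2.66 ± 0.37 mm control, 1.74 ± 0.39 mm disease) with 3–5 sections × 3
  measurements and small within-case noise; cortical-element fractions
  are Normal around 7.17/0.50/3.28% (control) and 5.86/0.35/3.71%
  (disease). Semithin sections are rendered by thresholding smoothed
  Gaussian random fields at exact empirical quantiles, so rendered label
  counts equal the requested fractions to the nearest pixel.

**What the generator does not emulate:** grayscale EM texture, membrane
ultrastructure, PSD morphology, segmentation errors, spatial correlation
between synapse size and position, or anisotropic z-artifacts. Passing
tests therefore demonstrate that the *measurement chain* is correct and
calibrated on data with the assumed statistical structure — not that the
assumed structure exhausts real tissue.

## Corrections: direction and order

Processed tissue is measured *after* shrinkage, so corrected values are
scaled up: `corrected = measured / p2^(d/2)` for dimension d ∈ {1, 2, 3}.
This convention reproduces the printed corrected stack-volume range
(260.2–824.4 µm³) from the raw stack geometry to within 0.1%, which is how
the direction was fixed (it is not stated explicitly in the sources the
design emulates). Per-volume densities transform inversely
(`dimension = -3` multiplies by `p2^{3/2}`). Artifact discounting and
shrinkage correction are both multiplicative on the counting volume, so
their order is immaterial; the pipeline discounts first, then corrects.
Cortical thickness is reported uncorrected, since it is measured by light
microscopy before EM processing.

## The counting rule

The counting frame is the Howard–Reed unbiased brick: an inner box with
three inclusion faces (low x/y/z) and three exclusion faces (high faces,
extended to planes). The rule is applied to the full reconstructed
junction extent, not the centroid: an object is counted iff it intersects
the frame and touches no exclusion plane. Objects truncated by the
physical stack boundary are flagged "incomplete" and discarded *before*
frame logic, mirroring the two-step discard used in practice. The default
guard margin is 5% of each window dimension per side, which puts the frame
volume at ~73% of the stack — close to the ratio of reported
counting-frame volumes to stack volumes in the emulated design. Unbiasedness
holds because the rule reduces, for axis-aligned extents, to "the object's
upper corner lies in the frame box", and that corner is uniform for a
stationary object process.

## Spatial statistics: estimators and envelopes

* **Edge corrections.** G and F are censored-distance CDFs: each
  nearest-neighbour (or empty-space) distance is censored at the distance
  to the window boundary. The default estimator is the Kaplan–Meier
  product-limit ("km"), which is monotone and bounded in [0, 1] by
  construction; the reduced-sample/border estimator ("rs") is also
  provided. The km default was chosen so that the estimator itself honours
  the CDF axioms (the rs estimator can be locally non-monotone), while rs
  remains available for comparison with older analyses. K uses the
  translation correction. All three match naive O(n²) implementations
  exactly on small patterns.
* **CSR references.** `G = F = 1 − exp(−λ·(4/3)πr³)` and `K = (4/3)πr³`,
  with λ estimated as n/V.
* **Envelopes.** `csr_envelope()` conditions on the observed n (binomial
  process), simulates 100 patterns by default, and takes pointwise
  min/max — rank-1 envelopes, the common practice at 100 simulations.
  Global (simultaneous) envelopes are deliberately out of scope. The
  verdict reports the fraction of the r grid at which the observed curve
  exits the envelope; under CSR the pointwise exit rate is 2/(n_sim + 1)
  per grid point, so a "consistent with CSR" call allows up to twice that.
* **r grid.** 512 points from 0 to a quarter of the shortest window side;
  estimates beyond half the shortest side are refused (truncated with a
  warning) because boundary censoring leaves too little information there.
* **Mean nearest-neighbour distance.** The raw mean is biased upward near
  the boundary (the true nearest neighbour may lie outside the window);
  where an unbiased value is needed the package integrates the
  KM-corrected survival of G, which reproduces the CSR closed form
  `Γ(4/3)(4πλ/3)^{-1/3}` within Monte-Carlo error.

## SAS morphometry

Area is the sum of triangle areas; perimeter the length of the single
boundary loop (meshes with zero or multiple loops are rejected). The
curvature index is `1 − projected_area / area`, projected onto the
*least-squares plane of the vertices* — a rotation-invariant choice made
here because the projection plane is not specified in the sources this
design follows. Projected area counts overlapping (folded) triangles
once: if the projected triangles share a consistent orientation the
projection is fold-free and the signed-area sum is exact; otherwise an
exact sweep-line union over vertical slabs is computed (slab boundaries at
all vertex and edge-intersection abscissae make the midpoint rule exact
within each slab). Without the union, folds would double-count and could
push the curvature index below zero.

Log-normal fits use the closed-form MLE on logs, with a one-sample KS
statistic of the logs against the fitted normal as the goodness-of-fit
summary. Frequency tables default to Freedman–Diaconis binning (falling
back to Sturges for degenerate cells), configurable because no binning
rule is canonical.

A known limitation of the spherical-cap model: at a given area, caps have
the smallest possible perimeter, so synthetic mean perimeters
(~1100–1200 nm at control AS areas) sit below empirically reported values
(~1650 nm) that reflect irregular, elongated junction outlines. Area and
curvature are matched; perimeter recovery is only internally consistent
with the cap family.

## Group comparison

The unit of analysis is the case (subject): Mann–Whitney tests compare
per-case values, 5 vs 5 in the default design — never per-stack values,
which would inflate the effective sample size. Tests are two-sided; the
p-value is exact by enumeration when the combined n is ≤ 12 without ties,
otherwise normal-approximate with tie and continuity corrections. The KS
comparison of SAS size distributions pools synapses within group (the
pooled reading of "frequency distribution analysis"; a per-case KS is not
defined for a single pair of group-level distributions). No
multiple-testing correction is applied, matching the emulated analysis.

With 5 vs 5 cases the exact Mann–Whitney null distribution is discrete:
the largest attainable level not exceeding 0.05 is `2·P(U ≤ 2) = 8/252 ≈
0.0317`. Calibration checks therefore compare empirical rejection rates
against this attainable level (and verify they do not exceed the nominal
0.05 band) rather than against 0.05 itself, which no exact 5-vs-5 rank
test can attain.

## Numerical and scale choices

* Coordinates are physical nm, origin at the stack corner, x/y in-plane,
  z along the milling axis; voxel indices 0-based; intervals half-open.
* Ellipsoid–box intersection volumes (artifact-in-frame) are analytic when
  the ellipsoid is inside the box and otherwise use vectorised midpoint
  slicing (relative error below ~0.5% of the clipped part).
* Cap meshes default to ~480 triangles (32 angular × 8 radial
  subdivisions), keeping discretisation error under 1% before calibration;
  meshes are isotropically rescaled ("calibrated") so the triangulated
  area equals the requested area exactly, which removes polygonisation
  bias from area recovery while leaving the curvature index unchanged.
* Validation suites run the spatial calibration at λ = 0.5 µm⁻³ in
  10 × 10 × 10 µm windows (≈500 points) with 100-simulation envelopes over
  50 seeds, the parameter-recovery study at the full 5-vs-5 × 3-stack
  design with meshes, and the null calibration on 500 reduced-window
  (3 × 3 × 3 µm) studies; these sizes give stable Monte-Carlo estimates
  while keeping the suites quick to run.
* All randomness flows through explicit integer seeds; child streams are
  derived with a mixed Lehmer hash so that neighbouring seeds do not
  produce correlated draws.

## Known limitations

* The generator's independence assumptions (size independent of position,
  no cross-correlation between AS/SS labels and geometry) are simplifying;
  real neuropil may violate them.
* The brick counting rule is the standard unbiased choice, but the exact
  frame rule used by any particular segmentation tool may differ in edge
  conventions.
* Envelope verdicts are pointwise, not global; they calibrate the
  estimators, they are not a formal hypothesis test with familywise
  control.
* Published per-case supplementary values are not reproducible from group
  summaries; the comparison table is validated by its statistical
  properties (type-I calibration, power on the thickness effect), not by
  matching individual published p-values.
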