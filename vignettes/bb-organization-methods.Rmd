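---
title: "Methods: basal-body detection and organization analysis"
author: "ciliarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: basal-body detection and organization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ciliarray` reconstructs the cortical basal-body (BB) organization of a
*Tetrahymena* cell from a calibrated multi-channel 3D fluorescence stack:
it segments the cell, detects BBs as diffraction-limited spots under
strong depth-dependent attenuation, removes internalized and
oral-apparatus (OA) signals, estimates the anteroposterior axis and
polarity, connects BBs into ciliary rows, and quantifies spacing,
orientation, spatial-domain statistics, daughter-BB frequencies,
cell-cycle kinetics and polarity-aligned 3D particle averages.  Because
original micrographs are not distributable, the package carries a
ground-truthed synthetic cell generator that emulates the imaging
conditions, so every stage is testable end to end.

# The detection model

## Cell segmentation

The BB-marker maximum-intensity projection is mean-subtracted, blurred
with a 1 µm Gaussian to homogenize spot texture into cell-scale features,
enhanced with a 0.12 µm Laplacian-of-Gaussian term, blurred again and
thresholded with the Triangle method.  Two implementation choices are
deliberately recorded in the configuration rather than hard-coded:

* Kernel "radius" is interpreted as the Gaussian sigma in µm.  Imaging
  software parameterizes these kernels inconsistently; sigma is the
  reproducible reading, and `blur_large_um` / `log_radius_um` can be
  remapped if a different convention is wanted.
* The LoG stage is applied as an *edge-enhancing additive term*
  (image + negated Laplacian response).  A pure band-pass response has no
  DC component, so a homogenized cell would not survive a histogram
  threshold as a filled object; the additive form separates touching
  features while keeping the cell a single bright region.

Objects above threshold are filtered on shape — area ≤ 2000 µm², maximum
Feret diameter ≤ 60 µm, circularity ≥ 0.85 — and the largest survivor is
the cell of interest.  Perimeter (for circularity) is measured on the
convex polygonal contour of the region: these cells are convex at the
mask scale, and the polygon avoids the pixel-staircase overestimate that
would otherwise depress circularity for perfectly sound cells.  The mask
is dilated by 5 µm (disc element, configurable) before cropping.

## Spot detection and the depth-adaptive threshold

The cropped stack is smoothed with a 0.12 µm Gaussian and 3D local maxima
are collected in an anisotropic ellipsoidal neighbourhood (0.25 µm
laterally, 0.6 µm axially — the approximate BB dimensions).  Plateau ties
keep the lexicographically smallest coordinate, making the maxima set
deterministic.  No intensity cut is applied at this stage; the list
deliberately oversamples camera and staining noise.

For each z plane, the intensities of all maxima within a rolling window
of 1.5 µm total depth (symmetric ±0.75 µm — the unbiased reading of a
"rolling" window) give a mean `I_avg`, standard deviation `I_sd` and
coefficient of variation `I_cv`.  A maximum is accepted iff its peak
exceeds

```
((S − I_cv · S) · I_sd) + I_avg        with sensitivity S = 6
```

The multiplier is clamped at zero when `I_cv > 1`, so the threshold never
drops below the window mean.  The formula is scale-invariant (a global
intensity rescaling moves `I_avg` and `I_sd` together and leaves `I_cv`
unchanged), which is what makes it robust to depth attenuation: deep
windows are uniformly dimmer, so their thresholds scale down with them.
The sensitivity constant is a named configuration parameter, not a magic
number.

## Interior and oral-apparatus filters

Cortical BBs lie on the convex hull of the accepted maxima; internalized
BBs fall inside it.  The hull is built by an in-package incremental
(beneath-beyond) algorithm and every maximum farther than 2.25 µm from
the hull surface — exact point-to-triangle distances, not a voxelized
approximation — is deleted.  Coplanar degenerate clouds skip the filter
with a warning.

OA BBs are spaced near the diffraction limit and sit on a homogeneous
bright plateau, whereas cortical BBs are isolated peaks decaying to
cellular background.  A 1 µm² box is centred on each maximum in its z
plane; sample skewness and excess kurtosis (bias-uncorrected moment
definitions, matching histogram-statistics conventions) are computed on
the mean-subtracted plane, and maxima with skew + kurtosis < 1 are moved
to the OA set.  Degenerate uniform boxes are treated as OA and flagged.
The statistics are computed on the raw (not re-smoothed) plane; a
configuration switch could move this to the smoothed plane if a dataset
required it.

## Per-BB photometry

Downstream daughter calling needs intensity *ratios* between neighbouring
BBs that stay meaningful at realistic photon counts.  Intensities are
measured with an anisotropic Gaussian matched filter (sigma 0.15 µm
lateral, 0.30 µm axial) inside a 0.5 µm aperture, orthogonalized against
constant and linear terms over the aperture, which makes the statistic
exactly invariant to any local additive background and to background
ramps (camera offset, diffuse cytoplasmic stain, depth attenuation
gradients).  A flat-aperture integral was measurably noisier and a
background-estimate subtraction systematically compressed ratios near the
two-fold decision boundary; the matched filter is the only photometric
scheme of the three that kept the daughter-calling operating point stable
on synthetic ground truth.

# Axis, polarity, rows

**Poles.**  Each BB's maximum distance to any other BB is ranked; walking
down the ranking, extreme BBs are assigned to the nearer end of the
provisional long axis (the segment realizing the global maximum) until
both clusters hold 10 BBs; poles are the cluster centroids.  A
near-spherical cloud (axis ratio < 1.25 on the covariance spectrum) is
rejected as having no meaningful poles.

**Polarity.**  Marker intensity is integrated in a 5 µm-radius sphere at
each pole — a sphere, not a projected circle, because the data are 3D;
the radius is configurable since no published value exists.  The brighter
pole is anterior (anterior spacing is tighter and the OA adds signal).
When an OA centroid exists it must fall in the anterior half; on
disagreement the OA wins and the decision is flagged `oa-override`.

**Row connection.**  A candidate partner of BB *b* must lie strictly
anterior (greater axial projection — the candidate set is made explicit
here).  Candidate *c* is scored by

```
score(b, c) = ‖b − c‖ + w · dist(c, plane(b, pole_ant, pole_post))
```

with w = 1 by default (the two terms are summed unweighted, in µm; `w`
is exposed as `plane_weight`).  The plane is taken through *b*, matching
the orientation definition below.  Forward and reverse choices are
computed for all unassigned BBs and only reciprocal pairs are accepted —
all pairs of a round simultaneously, which makes the result independent
of BB enumeration order — and rounds repeat until stable.  Remaining BBs
fall back to the closest unassigned anterior candidate within 5 µm.
In/out degrees never exceed one, so links form disjoint
posterior→anterior chains.  Linking failures near the anterior tip,
where rows converge, are accepted behaviour of this construction, not a
defect to be patched.

**Orientation.**  The angular deviation of a link is
`asin(out-of-plane distance / link length)` against the plane through the
BB and both poles, in [0°, 90°].  In a perfect ciliary row every
anterior partner lies in that plane and the statistic is exactly zero —
the analytic limit used as an acceptance anchor.

# Organization metrics

* **Spacing** is the 3D Euclidean link length (curvature between
  partners is below measurement noise at ~1.5 µm spacings); histograms
  use 0.1 µm bins (configurable).  Large gaps are links > 3 µm; close
  pairs are links < 1 µm.
* **Domains.**  The longitudinal coordinate is the Euclidean distance
  from the anterior pole normalized by the pole distance — where the
  normalized-axial-projection and the Euclidean-from-pole definitions
  conflict, the latter (the procedural definition) wins.  Quadrants IV
  (anterior) through I (posterior) split [0, 1] evenly.  The rotational
  coordinate is the azimuth about the axis relative to the OA, folded to
  [0°, 180°] by the cell's mirror symmetry — the fold is the only way to
  obtain exactly four bins labelled 0/45/90/135 — and binned in 45°
  steps.
* **Daughters.**  For each link (posterior p → anterior a), a is a
  daughter and p its mother iff intensity(p)/intensity(a) ≥ 2; the
  boundary is inclusive and configurable (`daughter_ratio`).  Zero
  anterior intensity gives an infinite ratio: called and flagged.  Only
  the first BB of a linear run of dim BBs can be missed by construction;
  this undercount is reproduced, not corrected.  Per-domain pooling
  reports BB-weighted means; cell-weighted pooling can be recovered from
  the per-cell tables.
* **Hull morphometrics.**  Surface area is the facet-area sum and volume
  the signed tetrahedron sum of the cortical-BB convex hull; densities
  are count/area and count per summed link length.

# Cell-cycle kinetics

Stage labels (I–IV, by OA morphogenesis) are inputs — the staging is
morphological and no algorithm for it is published.  Durations multiply
per-stage population frequencies by the doubling time; rates divide the
per-stage parameter change by the duration, with the cycle-start baseline
defined as the mean of the Stage I quartile with fewest BBs.  Reported
rates are rounded to one decimal (the presentation convention); raw
values are also returned.  Note that the printed per-stage cell counts
(127/42/19/11, N = 199) cannot reproduce a Stage I duration of 98 min
out of 180 — the published duration derives from a larger staged
population whose distribution is not printed; the package implements the
formula and leaves that tension unreconciled.

# Particle averaging

Cubes (default 4 µm, chosen so both neighbour peaks are visible at 1–2 µm
spacings) are resampled about each selected BB — by default the medial
quadrants II and III — with the x axis along the cell axis and the
azimuthal frame fixed by the local outward surface normal (the
OA-referenced alternative is possible but the surface normal is defined
for every BB).  Trilinear interpolation at 0.2 µm steps; border-clipped
subvolumes are dropped and counted.  Averages are voxelwise means.  The
linescan is the central x row of the maximum z projection of the cube;
its nine central points are fit to a Gaussian with offset
(Levenberg–Marquardt), and flanking peaks are detected with a 20%
prominence floor and parabola-refined.  Channel registration is
translation-only — both datasets are already in the canonical cell frame
— via the intensity centroid of the fiducial core above half maximum,
which is sub-step accurate for peaked marks.

# The synthetic cell generator

The generator *defines* the study conditions; its defaults are fixed
once:

* Prolate cell 40 × 22 × 22 µm (semi-axes 20, 11, 11 µm); 20 ciliary
  rows as ellipsoid meridians at equal azimuths, spanning polar angles
  13°–167° (rows converge and stop short of the apices).
* Within-row spacing 1.1 µm (anterior) → 1.8 µm (posterior), linear in
  normalized axial position; mean ≈ 1.45 µm, giving ≈ 640 cortical BBs —
  inside the published 550–650 band for interphase cells.
* OA: 150 BBs sunflower-packed at 0.30 µm spacing (near the diffraction
  limit) around azimuth 0°, normalized axial position 0.15, atop a
  super-Gaussian plateau (amplitude 500) — exactly the homogeneous bright
  background the skew/kurtosis filter must reject.
* Optics: Gaussian PSF sigma (0.12, 0.12, 0.25) µm; voxels
  0.125 × 0.125 × 0.30 µm.  The z step is the documented acquisition
  value; the lateral size is the implementer's choice and is set at
  Nyquist-adequate sampling for a ~0.12 µm-sigma spot, typical of a
  100×/1.4NA confocal — lateral undersampling (e.g. 0.25 µm pixels)
  makes single-spot photometry phase-dependent at the ±30% level and is
  not how such data are acquired.
* Depth attenuation: exponential, 0.051 per µm of z, leaving the far
  surface at ~35% of the near surface across the 22 µm cell depth.
* Intensity: spot amplitudes 1100 (centrin-like) and 1000 (Poc1-like)
  with 12% per-BB variation; camera offset 100; diffuse cytoplasmic
  stain of amplitude 80 filling the cell (immunofluorescence always
  carries cytoplasmic signal, and it is what keeps the projected
  footprint a contiguous segmentable object); Poisson shot noise at one
  photon per intensity unit plus Gaussian read noise (sd 6).
* Rows sit on aligned axial stations (no per-row phase stagger).  This
  keeps every anterior partner exactly in its meridian plane — the
  zero-deviation analytic limit — and makes within-row linking provably
  optimal for the scoring metric, at the cost of slightly more regular
  rings than real cells show.

Perturbations model the phenotypes the pipeline must detect: deleted
runs of BBs whose surviving flanks exceed 3 µm (spacing-gap phenotype),
lateral jitter of stated angular sd about the meridian plane
(disorientation phenotype), and channel-2 dimming of selected BBs to
below half of their posterior neighbour (daughter BBs; ground-truth
flags are recomputed from the half-intensity rule after dimming, so the
flags always satisfy their defining invariant).  All randomness flows
from explicit seeds through a scoped RNG; identical (spec, seed) give
bit-identical ground truth and stacks.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: optical aberrations beyond a Gaussian PSF,
spectral bleed-through, debris and neighbouring partial cells in the
field (beyond the shape-filter tests), cilia, and biological row
irregularity beyond the modelled jitter.

# Numerical choices and degenerate inputs

* Hull construction uses a farthest-first initial simplex and a
  tolerance relative to the cloud diameter; collinear/coplanar sets are
  rejected with specific errors.
* The Triangle threshold works on a 256-bin histogram (configurable) and
  mirrors the histogram so the long tail is always to the right.
* Local-maxima plateau ties resolve to the lexicographically smallest
  coordinate; calibration coarser than the search radius is an error,
  not a silent no-op.
* Adaptive-threshold windows with fewer than two maxima fall back to
  whole-stack statistics with a warning.
* Unlinked BBs are a valid row-graph outcome; empty spacing statistics
  are flagged rather than fabricated.
* Disorientation recovery uses the half-normal relation: per-link
  deviations of lateral jitter with sd σ have sd ≈ √2·σ, so
  σ̂ = mean(|deviation|)·√π/2.  Image-based recovery is biased upward by
  detection localization noise (~3–4° at the default preset); the
  recovery tolerance is ±25% at σ = 10°.
* Measured gap frequency on rendered (noisy) cells exceeds the injected
  frequency by up to ~0.007 because missed detections open artificial
  gaps in the posterior half, where 2× spacing crosses 3 µm; the
  recovery tolerance is ±0.015 absolute.

# Problem sizes

Validation uses one rendered default cell per fixture plus ten rendered
cells (four unperturbed, two per perturbation class) in the acceptance
suite, each ≈ 640 cortical BBs in a 361 × 217 × 91 voxel stack — sizes
chosen so the whole battery, including oracle cross-checks at up to
50 points and 100 random row-linking instances, completes in minutes on
one core while still exercising every stage at full cell scale.

# Known limitations

* Reported BB positions are voxel-quantized (sub-voxel localization is
  out of scope); localization error is ~0.1 µm at the default voxel
  size.
* The row metric can misconnect near the anterior tip where meridians
  converge below BB spacing — a documented property of the published
  construction.
* The daughter caller inherits the linear-cluster undercount.
* Global row indexing (assigning every BB a row id) is deliberately not
  implemented; chains are the unit of row structure.
* TIFF metadata is limited to a JSON sidecar; proprietary microscope
  formats are out of scope.
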