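# ciliarray

Automated analysis of cortical basal-body (BB) organization in
*Tetrahymena thermophila* from calibrated multi-channel 3D fluorescence
z-stacks.

Ciliates carry hundreds of BBs arranged in longitudinal ciliary rows whose
spacing, orientation and duplication are under active cell-cycle and
mutant control. Scoring that organization by hand does not scale: a single
interphase cell carries roughly 550–650 cortical BBs, each a
diffraction-limited centrin/Poc1 spot, with the back half of the cell
dimmed several-fold by depth-dependent light scattering. `ciliarray`
implements an end-to-end pipeline for this problem, plus a ground-truthed
synthetic cell-image generator so the whole pipeline can be validated
without original micrographs.

## The method in brief

1. **Cell segmentation** — maximum-intensity projection, mean
   subtraction, 1 µm Gaussian blur, 0.12 µm Laplacian-of-Gaussian edge
   enhancement, Triangle threshold; objects filtered on shape (area ≤
   2000 µm², Feret ≤ 60 µm, circularity ≥ 0.85); mask dilated 5 µm and the
   stack cropped.
2. **BB detection** — 3D local maxima (0.25 µm xy / 0.6 µm z search
   ellipsoid) on a 0.12 µm-smoothed stack, kept when the peak exceeds the
   depth-adaptive threshold

   `((S − I_cv·S) · I_sd) + I_avg`,  S = 6,

   computed over all maxima in a rolling ±0.75 µm z window — the
   threshold scales with the local intensity statistics, so BBs on the
   attenuated far surface survive. Maxima deeper than 2.25 µm inside the
   convex hull of the accepted set are internal BBs and are removed;
   maxima whose 1 µm² box histogram has skewness + kurtosis < 1 sit on
   the oral apparatus' homogeneous bright plateau and are set aside.
3. **Axis, polarity, rows** — poles from the centroids of the 10 most
   extreme BBs at each end; anterior = brighter pole (oral apparatus
   consistency-checked); each BB linked to the anterior partner
   minimizing `‖b−c‖ + dist(c, plane(b, poles))`, accepting only
   reciprocal forward/reverse pairs, with a 5 µm fallback for the rest.
4. **Organization metrics** — spacing (gaps > 3 µm, close pairs < 1 µm),
   angular deviation `asin(out-of-plane / length)` against the BB–pole
   plane, 4 × 4 spatial domains (longitudinal quadrants × OA-referenced
   folded azimuth), hull surface area/volume, and daughter-BB calls
   (anterior BB with ≥ 2-fold dimmer Poc1 than its posterior neighbour).
5. **Kinetics** — stage durations from population frequencies ×
   doubling time, per-stage BB-addition and surface-growth rates,
   predicted-vs-observed counts.
6. **Averaging** — polarity-aligned cubes around medial BBs, voxelwise
   means, Gaussian linescan fits, and translation-only channel
   registration on a fiducial channel.

All tunables live in `pipelineConfig()` with the published values as
defaults; every length is in micrometres.

## Worked example

```r
library(ciliarray)

spec <- cellSpec(seed = 11)          # default mid-cycle Tetrahymena preset
gt   <- placeBasalBodies(spec)       # ground truth: positions, rows, poles
img  <- renderStack(gt)              # two-channel calibrated stack
res  <- runPipeline(img)             # segment -> detect -> rows -> metrics

res$cellModel
res$rowGraph
sp <- res$spacing
cat(sprintf("mean spacing %.2f um, gap frequency %.3f\n",
            sp$meanUm, sp$gapFrequency))

det <- sweep(bbPositions(res$cellModel), 2, res$stack@originUm, "+")
matchToGroundTruth(det, bbPositions(gt), 0.5)[c("recall", "precision")]
```

prints (exact numbers vary slightly with the seed):

```
CellModel: 628 cortical BBs; hull 2383 um^2 / 9983 um^3; polarity via oa-override
  anterior pole (42.0, 13.5, 13.6), posterior pole (3.6, 13.5, 13.3) um
RowGraph: 628 BBs, 608 reciprocal / 0 fallback links, 20 unlinked
mean spacing 1.43 um, gap frequency 0.008
$recall
[1] 0.9796875

$precision
[1] 0.9984076
```

That is: the pipeline re-detects 98% of the 640 generated cortical BBs
with ~0.2% false positives, reconstructs a hull area within 1% of the
generating ellipsoid's analytic surface area (2395 µm²), links
essentially every BB to its within-row anterior neighbour (the 20
unlinked BBs are the row heads, which have no anterior partner by
construction), and recovers the anterior-tight spacing profile mean of
1.45 µm.  The handful of missed detections on the attenuated far surface
open the few >3 µm spacing gaps behind the 0.008 gap frequency.

Perturbed phenotypes are generated the same way:

```r
mut <- injectPerturbations(gt, gapRate = 0.02, disorientSd = 10,
                           daughterRate = 0.15, seed = 99)
```

which deletes runs of BBs until the surviving flanks are > 3 µm apart
(spacing-gap phenotype), jitters BBs laterally about their row plane
(disorientation phenotype), and dims channel-2 intensities of selected
BBs below half of their posterior neighbour (daughter BBs).

Command-line wrappers live in `inst/cli/`:

```sh
Rscript inst/cli/synth-cell.R --preset tetrahymena --n-cells 3 \
    --daughter-rate 0.15 --seed 7 --out synth/
Rscript inst/cli/ciliarray.R run --input synth/cell001.tif --out results/
```

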