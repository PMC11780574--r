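---
title: "Quantifying single extracellular vesicles from correlative super-resolution images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single extracellular vesicles from correlative super-resolution images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Extracellular vesicles (EVs) are membrane-bound nanoparticles, mostly
50-250 nm across, released by essentially all cells. Captured on an
antibody-functionalized coverslip and stained against their tetraspanin
(TSPAN) surface proteins (CD9/CD63/CD81), single EVs appear in
fluorescence microscopy as sub-diffraction spots. Two super-resolution
readouts of the same field carry complementary information:

* **SMLM** (single-molecule localization microscopy, ~28 nm resolution)
  yields a point cloud of fluorophore localizations: the gold standard
  for counting EVs, for their size, and - through the mean number of
  localizations per fluorescent reporter, $\alpha$ - for the number of
  detected TSPAN molecules per EV.
* **SRRF** (super-resolution radial fluctuations, ~70 nm resolution)
  yields a pixel image reconstructed from a short acquisition. It is far
  cheaper to acquire (and works in wide-field mode on a conventional
  microscope), but reports size and molecular content only in image
  units.

`evquant` implements the analysis arm connecting the two: SMLM cluster
detection (ground truth), SRRF segmentation into single-EV regions, the
colocalization that links them, and three calibrations that turn SRRF
segment geometry and intensity into physical diameters and TSPAN counts.
A synthetic-data generator stands in for microscope data, so the whole
chain is testable on any machine.

## SMLM clustering (ground truth)

Each localization's local density is $1/A_i$ with $A_i$ the area of its
Voronoi cell, clipped to the ROI rectangle so border cells stay finite
(`voronoi_densities()`; tessellation by the `deldir` package).
`cluster_localizations()` then applies, in order:

1. **Core threshold.** Points with density at least
   `density_factor` (default 2) times the *global* ROI density
   $n/\mathrm{area}$ are core points. The global density is the uniform
   expectation; the mean of the per-point densities would be dominated by
   the clusters themselves and reject everything.
2. **Merging.** Core points whose Voronoi cells share an edge (Delaunay
   neighbours) merge - but only along edges shorter than
   $1/\sqrt{\texttt{density\_factor} \times n/\mathrm{area}}$, the
   spacing of a point pair *at* the threshold density. Without this cut,
   the thin sliver cells of two clusters' facing hull points can touch
   and bridge clusters micrometres apart.
3. **Boundary recruitment.** The outermost localizations of a dense
   cloud have outward-reaching cells and always fail any density cut, so
   each core recruits non-core localizations Delaunay-adjacent to at
   least two of its members. Molecule counts
   ($M = \mathrm{localizations}/\alpha$) use all members; **area and
   polygon use the core cells only**, so one outsized border cell never
   inflates the geometry. A lone above-threshold point cannot recruit
   (recruitment needs two adjacent core members), which keeps uniform
   noise from seeding clusters.
4. **Molecule cut.** A cluster is a detected EV when it carries at least
   `min_molecules` = 2.5 molecules; this suppresses nonspecific binding
   and free dye.

Cluster diameter is the equivalent-circle diameter
$2\sqrt{\mathrm{area}/\pi}$ (the estimator is not pinned down by the
published method; the equivalent-circle choice is ours and is stated in
the output). The cluster area from summed Voronoi cells systematically
overestimates the true particle cross-section by roughly a third
(localization precision plus cell tiling); this is a stable scale factor
and exactly what the calibrations absorb.

## SRRF segmentation

`segment_pipeline()` runs, per ROI image:

* **Binarization** (`binarize()`). Default: foreground where intensity
  is at least 0.50% of the maximum image intensity
  (`threshold_fraction = 0.005`), which makes the mask - and everything
  downstream - exactly invariant to global intensity rescaling. An
  adaptive local-mean mode serves the sparse single-fluorophore
  calibration surfaces, where a global threshold would be dominated by
  the brightest spot. Its window (default 31 px) must be much wider than
  the PSF: with a window comparable to the spot, the spot raises its own
  local threshold and ~8% of its integral is clipped off.
* **Initial segments** (`label_initial_segments()`): 8-connected
  components of at least `min_segment_area_px` = 4 px, boundaries traced
  along pixel edges.
* **Transform and peaks.** Each segment's intensity patch $i$ is
  transformed to $\nabla^2 i^{1/3}$ (`laplacian_cubicroot()`): the cube
  root compresses the brightness gap between strong and weak partners of
  a merged segment, the 5-point Laplacian (reflect padding) sharpens each
  underlying spot. `detect_peaks()` finds regional maxima of the negated
  transform on the segment foreground, filtered by topographic prominence
  and pairwise separation. Prominence is specified *relative* to the
  patch's value range (default 0.2) - an absolute prominence would break
  the rescaling invariance above.
* **Component count.** Segments with multiple peaks get
  $N = \min(\text{peaks}, 5)$. Single-peak segments whose foreground
  coefficient of variation exceeds `cv_cutoff` = 0.2 are referred to the
  ordinal classifier (below); otherwise $N = 1$. Without a classifier
  (the wide-field-only operating mode) single-peak segments stay whole.
* **Splitting** (`weighted_grid()` + `split_segment_kmeans()`). A grid
  of synthetic localizations is laid over the foreground, each pixel
  receiving $\max(1, \mathrm{round}(\texttt{points\_per\_unit}\cdot w))$
  points with $w$ the pixel's transformed-intensity magnitude rescaled to
  $[0,1]$; k-means with $k = N$ (seeded, 10 restarts) clusters the grid,
  and every pixel joins its nearest centre (ties to the lowest index).
  Pixel sets of the children exactly partition the parent.
* **Intensity integral.** $J$ is the background-subtracted foreground
  sum, clamped at zero *per pixel*, which makes $J$ exactly additive over
  any split. Background is the median intensity outside all segments
  (the published method does not define its background model). The
  normalized integral divides by the ROI maximum (dimensionless,
  illumination-robust; the original normalization constant is not
  recoverable from the main text).

## Ordinal classification of merged segments

A single-peak segment covering two EVs closer than the SRRF resolution
is geometrically near-indistinguishable from a large single EV in peak
count - but differs in area, elongation, integrated intensity and
texture. `train_component_classifier()` fits the ordered three-class
problem (1 < 2 < 3 components) as two cumulative binary questions
("more than one?", "more than two?"), each a Gaussian-kernel soft-margin
SVM on 11 standardized features: area, perimeter, equivalent diameter,
eccentricity, solidity, axis ratio, maximum/mean intensity, intensity
CV, intensity integral, and the dispersion of a 9-bin
histogram-of-oriented-gradients pooled over the patch. (The published
feature list names the three families - morphology, intensity, HOG - but
not the individual features; this realization is ours, and the HOG
descriptor is reduced to one dispersion scalar to fit the 11-feature
budget.) The decode
$N = 1 + [f_1 > 0] + [f_1 > 0 \wedge f_2 > 0]$ is monotone by
construction. The SVM dual is solved exactly with `quadprog`
(deterministic given the data; no SVM package exists in the supported
dependency set), with $C = 10$ and $\gamma = 1/11$ on standardized
features. Training annotations come from colocalization
(`annotate_true_counts()`: overlapping SMLM clusters per initial
segment) on real data, or from `annotate_with_ground_truth()` on
synthetic data - see the generator notes below for why.

## Colocalization

All overlaps are computed on the shared ROI pixel raster. A segment
carries its pixel set natively; a cluster's region (union of its member
Voronoi cells) is rasterized exactly by nearest-localization assignment.
The overlap statistic is
$\mathrm{area}(s \cap c)/\min(\mathrm{area}(s), \mathrm{area}(c))$ with
a passing threshold of 0.25 - intersection over the *smaller* area
tolerates the modalities' different effective resolutions, and the
published method states colocalization without an explicit overlap rule.
`match_segments_to_clusters()` records passing pairs, resolves a
one-to-one assignment greedily by descending overlap, and categorizes
segments (`one_to_one` / `multi` / `srrf_only`) and clusters
(`matched` / `smlm_only`); `confusion()` tabulates true vs predicted
component counts; `channel_positivity()` reports the fraction of
red-channel EVs with a passing overlap in the green channel (GFP or RNA
stain).

## Calibration

Three schemes convert SRRF readouts to physical units
(`apply_calibration()` tags every EV record with its scheme):

* **Regression** (`fit_linear()`): OLS with intercept of the
  SMLM-measured quantity on the SRRF quantity over colocalized single
  EVs - diameter on segment diameter, molecule count on the *square
  root* of the normalized intensity integral (the square-root input
  empirically linearizes the content relation; mechanistically
  $J \propto M$ makes $\sqrt J \propto \sqrt M$). Whether the published
  fits include an intercept is unstated; we keep and report it.
* **Single-fluorophore** (`sami_calibrate()` / `tspan_from_sami()`):
  on a surface of sparse covalently attached antibodies each spot is one
  reporter; $\langle J_1 \rangle$ is the mean spot integral (per ROI,
  then across ROIs), and $M_{EV} = J / \langle J_1 \rangle$. This ratio
  is exactly invariant to global intensity rescaling.
* **Sensitivity** (`sensitivity_calibrate()`): with a reference EV
  standard of known mean size (106 nm) and content (21 molecules/EV),
  the sensitivity is the mean over ROIs of (SRRF per-ROI mean metric /
  reference value); applying the calibration divides by it. The phrasing
  of the source supports either mean-of-ratios or ratio-of-means; the
  default is mean-of-ratios and both are available.
  `crossvalidate_sensitivity()` validates by seeded k-fold partition of
  the ROIs (33 ROIs at k = 5 gives folds {7,7,7,6,6}); with noiseless
  inputs every fold reproduces the reference exactly.

Per-ROI averaging precedes all group statistics, and grand results are
reported as mean +- SEM across ROIs (`summarize_rois()`,
`grand_summary()`): the ROI is the unit of replication.

## The synthetic world

`simulation_config()` defaults encode the stated experimental
conditions: 0.5 detected EVs per um^2; lognormal diameters
(meanlog = log 100, sdlog = 0.35; mean ~106 nm, bulk 50-250 nm);
molecule content $M \sim \mathrm{Poisson}(21\,(d/106)^2)$, anchored to
21 molecules at the 106 nm reference size and scaling with membrane
area; PSF sigma 30 nm (~70 nm FWHM); localization precision 7.5 nm;
$\alpha = 10$ localizations per fluorophore (a typical dSTORM value; the
measured value is not printed in the source's main text); constant
background 2 with 0.5 Gaussian read noise; 2000 intensity units per
molecule. ROIs default to 12 x 12 um so a full tessellation stays below
~20k localizations; the experiment-scale 1,678 um^2 ROI is reachable by
config. EVs render as isotropic Gaussians with
$\sigma_{\mathrm{eff}} = \sqrt{\sigma_{PSF}^2 + (d/4)^2}$ - the PSF
broadened in quadrature by the particle's physical extent, which gives
the monotone size-to-width relation the diameter regression needs - and
integral $M \times 2000$. SMLM sees $M$ fluorophores uniform on the
particle disc, each emitting Poisson($\alpha$) localizations with
Gaussian jitter. `render_sami_surface()` builds single-fluorophore
surfaces with at least 5 PSF-sigma spacing and known per-spot integrals.

What the generator does **not** emulate: nonspecific background
localizations, fluorophore blinking kinetics and dark-state merging,
camera-specific noise, drift, chromatic offsets, or aberrated PSFs. A
green test therefore establishes that the algorithms recover what this
idealized world programs - not that they would survive every pathology
of real data.

**Merged pairs and annotation.** A configurable fraction of EVs is
placed as close pairs at 2.5 PSF sigma (75 nm) to exercise splitting.
At that separation two ~106 nm EVs physically interpenetrate and their
localization clouds merge into a single Voronoi cluster, so SMLM-based
annotation undercounts exactly the class the classifier must learn; for
synthetic training `annotate_with_ground_truth()` (true EV centres per
segment) is used instead. Segments that merge a placed pair with a
*third* EV by spatial coincidence show two peaks and are resolved to
N = 2 by the peak rule - the same failure mode the published method
documents for 3-overlap segments - so the splitting check is scored on
pure pairs, and the all-merged accuracy (~79% in the default world) is a
known limitation.

## Numerical choices and degenerate inputs

* Coordinates: one convention everywhere - origin at the image top-left,
  units nm, pixel (row, col) centred at
  $((\mathrm{col}-0.5)\,s, (\mathrm{row}-0.5)\,s)$ for pixel size $s$,
  y increasing downward.
* Coincident localizations are jittered deterministically by ~0.001 nm
  before tessellation (three orders below localization precision);
  fewer than 4 points or a collinear set is a hard error.
* `deldir` rounds coordinates to 6 significant digits internally
  (<= 0.1 nm at ROI scale); cluster outer rings are chained from the
  tessellation's own edge list and fall back to the convex hull of the
  member cells' vertices if the ring does not close (cluster truncated
  by the ROI border).
* k-means ties in pixel assignment go to the lowest cluster index;
  k-means centres are ordered by coordinate so child-segment identity is
  deterministic; every split is seeded per parent segment.
* Peak plateaus (exact value ties) yield no peak - a peak must strictly
  exceed at least one in-patch neighbour, so constant patches are
  peak-free.
* 1-px segments fall back to eccentricity 0 and axis ratio 1; axis
  ratio is capped at 50 for collinear pixel sets.
* An all-zero image yields an empty mask; an empty localization table
  yields an empty cluster list; an empty reference set makes
  `channel_positivity()` error (the fraction is undefined).

## Known limitations

* SMLM cluster diameters carry a ~1.35x scale from Voronoi-cell tiling
  and localization jitter; absolute sizes require one of the
  calibrations (as in the published workflow, where SMLM itself is
  calibrated against reference EVs).
* Thresholded integrals clip PSF tails; with the default adaptive window
  the single-fluorophore integral is recovered to ~97%, and the bias
  largely cancels in the $J/\langle J_1\rangle$ ratio.
* Segments merging more than two EVs are usually resolved as
  two-component (peak rule); accuracy decays with component count,
  mirroring the published confusion matrix.
* The 11-feature list, SVM hyperparameters and integral normalization
  are package choices where the published supplementary material is not
  available; all are config-exposed.

## A worked run

```{r}
library(evquant)

res <- run_ev_pipeline(simulation_config(), analysis_config(),
                       n_rois = 2, seed = 1)
res$grand            # per-ROI means +- SEM
res$sensitivity      # the reference-EV calibration the run fitted
```

The README walks through the same run step by step, with the numbers it
prints.
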