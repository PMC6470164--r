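---
title: "Methods: particle tracking velocimetry and morphometry for OCT imaging of CSF flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: particle tracking velocimetry and morphometry for OCT imaging of CSF flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, numerical
choices and limitations. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` compute at run time.

## The measurement problem

Optical coherence tomography (OCT) B-scan videos of the mid-sagittal
plane of a transparent tadpole brain resolve endogenous free-floating
particles (3.57–3.88 µm diameter) inside the fluid-filled ventricles.
Cilia-driven cerebrospinal fluid (CSF) circulation advects these
particles, so tracking them yields a velocity map of the ventricular
flow network. The biologically meaningful readouts are: the number and
polarity (clockwise vs counter-clockwise) of coherent vortical *flow
fields*; their mean speeds; the spatial particle density; and, from 3D
stacks, ventricle volumes, chamber extents and cerebral-aqueduct
patency. All of these change in ciliopathy and hydrocephalus models,
which makes them phenotyping endpoints.

## Coordinate and polarity conventions

Images are indexed `(row, col)` with row 0 at the top (dorsal) and
columns increasing anterior → posterior. Physical positions are in
micrometres; pixel centres sit at `(i − 0.5)·pitch`. Velocities are
always reported in µm/s (pixel displacements scaled by the pixel pitch
and divided by the frame interval).

Polarity is defined through the discrete circulation in this frame: a
flow field is **CCW** when its circulation is positive and **CW** when
negative. For the rigid rotation used by the generator,
`v_row = ω·(col − col₀)`, `v_col = −ω·(row − row₀)`, the discrete curl
`∂v_row/∂col − ∂v_col/∂row = 2ω`, so curl sign, circulation sign and the
sign of ω agree everywhere by construction.

## The synthetic generator defines the study conditions

No imaging data are distributed, so the generator is the package's
experimental substrate, and its defaults encode the acquisition it
emulates:

* frame interval 0.015 s (≈66.7 fps; 1000 frames per 15 s acquisition),
  with 300-frame videos as the standard tracking run;
* 2.2 µm isotropic pixels after anisotropy correction;
* 220 particles with diameters uniform in 3.57–3.88 µm, rendered as
  Gaussian spots (σ from the diameter combined with a 2 µm PSF);
* a four-chambered mid-sagittal outline (lateral, third, midbrain and
  fourth-ventricle lobes joined by narrow aqueducts) holding five
  vortical fields FF1…FF5 anterior → posterior with polarity
  CW, CCW, CCW, CW, CCW; FF5 has the largest angular speed
  (0.80 rad/s) and FF1/FF2 the smallest (0.25 rad/s);
* Brownian jitter of 0.15 µm/frame and per-particle appearance and
  disappearance probabilities of 0.001/frame;
* additive Gaussian speckle (SD 6 intensity units on a background of 20
  with spot amplitude 120). Real OCT speckle is multiplicative; an
  additive surrogate suffices for exercising the detector, but absolute
  signal-to-noise figures should not be read as instrument performance.

Particle brightness and background noise are not constrained by any
published statistic; they are free parameters chosen once at realistic
values and left alone.

**Vortex profile.** Fields are solid-body cores (`v_t = ω r` inside the
core radius) with either zero exterior (`solid_body`) or a Rankine
`ω R²/r` exterior (`rankine`). The reference five-field scene uses
Rankine profiles: the Rankine exterior is irrotational, whereas a
hard-truncated core carries a ring of opposite-sign curl at its edge
which any curl-based segmentation would (correctly!) report as a
counter-polarized shell. Closed-form velocities make every recovery test
checkable against ground truth.

**Boundary handling.** A particle whose advection step would leave the
outline is reflected through its previous position (and stays put if
the reflection also exits). This conserves particle number exactly,
which the conservation tests rely on. It is a kinematic convenience,
not a physical wall model: real near-wall flow has a ciliary boundary
layer the generator does not attempt to resolve.

## Detection

`detect_particles()` reimplements the intensity-moment feature-point
method: band-pass restoration (Gaussian σ = 1 px minus a boxcar mean
over `2w+1`), candidate local maxima among the top *r*-percentile of
restored intensities, two passes of intensity-centroid refinement within
a disc of radius `w`, and rejection of candidates whose total intensity
m₀ and second moment m₂ fall outside a χ²(2) quantile ellipse of the
per-frame (m₀, m₂) cloud. The covariance of that cloud is
ridge-regularised (10⁻⁴ of the squared mean scale) so that a frame of
identical noiseless spots — zero variance — keeps every detection; only
genuinely aberrant signatures are trimmed. Defaults are `w = 3` px,
`r = 0.5`, trim quantile 0.1.

`detect_particles_hdome()` is the dense-scene alternative: grayscale
geodesic reconstruction-by-dilation of `I − h` under `I`, dome image
`D = I − rec`, connected `D > 0` regions of at least `min_area` px
become detections at their intensity centroids. Reconstruction of a
constant image leaves a uniform pedestal of height `h`; the global
minimum of `D` is subtracted so a featureless frame yields nothing.
`detect_video()` warns when per-frame counts jump by more than 30%
between frames — the symptom of feature-point false negatives in dense
scenes — and suggests the H-dome mode.

**Parameter guidance.** The percentile `r` bounds the number of
candidate maxima at `r%` of the pixel count; with ~200 spots in a
120k-pixel frame the default `r = 0.5` caps detections at about half
the particles, so dense phantoms are analysed with `r = 2`. The
validation studies in `tests/` and `scripts/acceptance.R` use
`r = 2`.

## Linking

`link_tracks()` links detections frame to frame with candidate pairs
gated at `max_disp` px. Per frame, the assignment maximises the number
of links and, among maximal assignments, minimises the total squared
displacement; this is solved exactly as a maximum-weight bipartite
matching with weights `B − cost` for `B` large enough that cardinality
always dominates. Track ends stay open for `link_range` frames, so
occlusions up to `link_range − 1` missing frames are bridged; velocity
extraction later skips those bridged links. A greedy nearest-pair
fallback (`greedy = TRUE`) exists for extremely dense scenes; it is not
used by any validation.

`max_disp` should be a small multiple of the largest expected per-frame
displacement. At 66.7 fps the fastest phantom particles move < 0.5 px
per frame, and a loose 10 px gate lets ends of broken tracks capture
detections of *neighbouring* particles (~9 px away), which injects
large random velocities and biases speed estimates toward zero. The
phantom studies therefore use `max_disp = 3`; the package default stays
at the conventional 10 px, which is appropriate for sparser or faster
scenes.

## Flow maps and field segmentation

Velocity samples (gap-free consecutive track-point pairs, placed at the
pair midpoint) are averaged on non-overlapping windows (default 10 px)
covering the ROI bounding box. Cells record the component-wise mean and
the sample count; count-weighted cell means conserve the global sample
mean exactly, which is asserted in the tests.

**Outliers.** Cell-vector magnitudes above the 97th percentile are
removed as tracking artefacts. The percentile is *nearest-rank*: the
value at index `⌈0.97·N⌉` of the sorted magnitudes, with removal
strictly above it. This gives reproducible integer semantics (exactly
300 of 10,000 distinct magnitudes are removed) and never removes
anything from an all-equal grid. Filtering is applied at the cell level,
after averaging; a per-sample variant can be had by filtering the
sample table before `window_average()`.

**Segmentation.** The discrete curl is computed by central differences
on interior cells only — cells with valid neighbours on both sides along
each axis. One-sided estimates at the ROI rim were tried and rejected:
in narrow aqueducts they measure the unresolved near-wall shear and
produce counter-polarized bands. Four-connected same-sign curl cells
form candidate regions; a region of `k` cells is significant when its
absolute circulation (Σ curl × cell area) is at least `√k` times the
base threshold. The base threshold self-calibrates against a
permutation null — cell vectors shuffled among non-empty cells 1000
times, threshold = 2 × median |circulation| of single-cell regions —
and the `√k` factor accounts for the random-walk growth of a
homogeneous patch's circulation with its size. Regions smaller than 4
cells are never reported (a vortex resolved by fewer windows carries no
meaningful polarity). Fields are numbered FF1, FF2, … by centroid
column (anterior → posterior).

`estimate_angular_velocity()` fits `v_t = ω r` through the origin by
count-weighted least squares over cells within a given radius of a
known centre; its sign is the polarity.

**Heatmaps.** Densities are per-bin detection counts averaged over
frames divided by the physical bin area, `NA` outside the ROI; total
heatmap mass (Σ value × bin area) equals the mean in-ROI count exactly.
The default bin equals the flow-grid window for visual registration.

## Cross-animal registration

Outlines are resampled to `n_points` (default 100) equally spaced by
arc length, starting at the anterior-most vertex and oriented
clockwise; Procrustes alignment then needs point correspondence, which
a circular-shift search over start offsets (minimising SSE) makes
independent of where the sampling begins. Equal-arc resampling of an
already-resampled polygon reproduces it only to O(curvature/n²) — the
chord polygon's perimeter differs from the original's — so idempotence
holds to a tight tolerance rather than exactly.

The similarity fit itself is the closed-form orthogonal Procrustes
solution via SVD with the determinant corrected to +1: reflections are
excluded because left–right anatomy must never be mirrored, even when a
reflected fit would score lower. Scale is estimated jointly; whether to
multiply velocity magnitudes by the scale when transporting a flow grid
into the reference frame is a genuine modelling choice (normalise flow
to the reference anatomy, or keep physical speeds) — both modes exist,
with scaling the default. Heatmaps transport bin *mass* (density × bin
area), which conserves total particle count exactly and is equivalent
to dividing densities by scale². Transformed cells land on the
reference raster by nearest-cell assignment with count-weighted
merging, and `average_group()` averages animals with per-cell count
weights, recording the number of contributing animals.

## Volumetry

`region_grow()` accretes face-connected (6-connectivity by default;
26 available) neighbours whose intensity differs from the running
region mean by at most a tolerance, batch-wise until closure. The
default tolerance is half the distance between the lumen and tissue
intensity modes as split by Otsu's threshold; a seed brighter than the
Otsu threshold plus the tolerance is rejected rather than allowed to
flood the tissue. Six-connectivity is the default to prevent diagonal
leakage through one-voxel aqueduct walls. On noiseless phantoms the
grown region equals the ground-truth lumen mask exactly and is
independent of which interior voxel seeds it.

`interpolate_manual()` reconstructs a volume from sparse manual slice
annotations by linear blending of per-slice signed Euclidean distance
transforms (positive inside), thresholded at zero; outside the
annotated range the nearest slice extends unchanged. Signed-distance
interpolation is this package's choice of interpolant — it is
shape-aware and exact for identical neighbouring slices — not a claim
about how any particular manual workflow interpolates.

`morphometry()` labels chambers as connected components, reports
AP/DV/LR extents from voxel ranges × pitch, the minimum in-mask
cross-section over transverse (constant-y) planes within a stated
aqueduct span, and calls the aqueduct *patent* exactly when mask voxels
anterior and posterior of the span share a connected component — a
binary, reproducible stenosis call made on the segmentation, not on
raw intensities. `compare_methods()` returns the mean and sample SD
(n − 1) of absolute paired differences; absolute rather than signed
errors are used, the natural reading for a validation error magnitude.

## Problem sizes used in validation

The suite and acceptance script run entirely on synthetic data sized
for a desk machine while keeping the study conditions above: 300-frame
wild-type and single-vortex videos with 200–220 particles; twenty
50-frame acquisitions for polarity calls; 100 random linking instances
(≤ 6 particles, ≤ 5 frames) against exhaustive enumeration; 100 random
similarity transforms; 11 jittered phantom animals for the group map
(ideal, noise-free per-animal grids sampled from the analytic velocity
field — registration is being tested there, not tracking); spheres and
two-chamber phantoms at 5 µm voxels, with 20 noisy phantoms for the
patency classifier and 12 automatic-vs-manual pairs for the error
statistic.

## What passing tests do and do not show

The phantoms validate the *algorithms*: detector localisation,
assignment optimality, percentile semantics, curl/polarity sign
conventions, Procrustes recovery, region-growing exactness and the
patency call. They do not certify performance on real OCT data, whose
speckle is multiplicative and spatially correlated, whose particles
vary in brightness and can leave the imaging plane (the velocimetry is
strictly 2D mid-sagittal), and whose flow fields are not ideal
superposed vortices. Near-wall velocities are systematically
unresolved; segmentation deliberately ignores rim cells for this
reason. No Navier–Stokes or ciliary-beat modelling is attempted, and
3D flow reconstruction is out of scope.
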