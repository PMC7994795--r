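---
title: "volstorm: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{volstorm: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Single-molecule localization microscopy resolves presynaptic scaffold
clusters (e.g. Bassoon at active zones) at tens-of-nanometre resolution, but
a single astigmatic focal plane only captures emitters within roughly
±500 nm of focus. To image micrometre-thick structures — an entire
hippocampal mossy fiber bouton can be 10 µm across — the focal plane is
swept continuously through the tissue with a piezo stage, many thousand
camera frames per sweep, and the sweep is repeated (typically ten times,
alternating direction to balance photobleaching across depth). The product
of such an acquisition is not an image but a stack of *localization tables*:
one fitted emitter detection per row, with lateral position, frame number,
intensity, and the fitted PSF widths $w_x, w_y$ that encode the axial
offset.

`volstorm` turns those tables into drift-corrected volumetric point clouds,
segments protein clusters, measures them (localization count, length,
width, volume, density), flags border-truncated objects, quantifies the
robustness of the size measures to reduced localization counts, and assigns
clusters to membrane-labelled boutons imaged in a second staining round.
A simulator generates complete acquisitions with ground truth so that every
stage is testable without the original raw data.

## Coordinate and data conventions

* nanometres everywhere; origin at the field-of-view corner, x right,
  y down, z away from the coverslip;
* frames and scan indices are 0-based;
* spatial bins and voxels are half-open, $[kb, (k+1)b)$;
* record order in a table is acquisition order and is preserved by all I/O.

## Axial calibration and lookup

A bead stack swept at constant speed gives, per localization, a known stage
position and a fitted width pair. `fitCalibration()` fits cubic smoothing
splines ($w_x(z)$, $w_y(z)$; `stats::smooth.spline`, smoothing chosen by
generalized cross-validation unless given) and restricts the validity range
to the largest interval around the focal crossing on which the discriminant
$d(z) = w_x(z) - w_y(z)$ is strictly monotone — outside it the lookup is not
unique. The focal plane is the root of $d$.

`lookupZ()` inverts the calibration by least squares in *width space*:
$\hat z = \arg\min_z (w_x(z)-W_x)^2 + (w_y(z)-W_y)^2$, evaluated on a 1 nm
grid. This is more robust than inverting $d$ when one width is noisy. Pairs
whose width-space residual exceeds 50 nm (default) are flagged rejected —
they are implausible PSF shapes, typically overlapping emitters — and
dropped (with a tally) during assembly.

The simulator generates widths from the standard astigmatic model
$w_{x,y}(\delta) = w_0\sqrt{1 + ((\delta \mp c)/d)^2}$ with
$w_0 = 150$ nm, $c = 400$ nm, $d = 500$ nm. The spline calibration never
assumes this functional form; the model is a simulator convention only.

## Scan model and volume assembly

The piezo position is linear in the frame index with denominator
`framesPerMovie - 1`, so both endpoints of the travel are reached and, with
alternating direction, the end of scan $k$ coincides with the start of scan
$k+1$. A localization's true z is the stage position of its frame plus the
astigmatic offset from the width lookup. Within-frame stage motion
(≈0.7 nm at 100 Hz over 10 µm in 150 s) is ignored.

## Drift correction and round alignment

Coverslip fiducials imaged before and after each measurement are summarized
by single-linkage merging within 500 nm (beads with fewer than 10
localizations are discarded), matched mutually-nearest-neighbour between
epochs, and the translation (optionally an in-plane rotation and uniform
scale, solved by orthogonal Procrustes) is estimated by least squares.
Because beads are recorded only at the start and end, drift is interpolated
*linearly in acquisition time*; no higher-order model is identifiable from
two epochs, and a non-linear drift component leaves the documented residual
of the linear interpolant. Sequential staining rounds are aligned by the
same machinery applied in full (not time-scaled); the rms bead residual is
reported so users can judge whether a rigid model suffices — elastic
warping is out of scope, being ill-constrained by ~10 beads.

## Denoising

Stray background localizations are removed with DBSCAN
(`eps = 100` nm, `minPts = 8`). The neighbourhood is *elliptical* by
default (z divided by 3 before the radius test): astigmatic axial precision
is ~2–3× worse than lateral, so a cloud that is dense in the sample is
smeared into an ellipsoid in the data, and an isotropic ball undercounts
neighbours exactly for dim, elongated clusters. On simulated study
conditions the isotropic metric deleted whole clusters from the low-count
tail of the blinking distribution (~5 % of objects); the elliptical metric
retains them while still removing a uniform background of a few
localizations per µm³ (expected neighbour count « 1). The isotropic
textbook metric remains available (`anisotropy = c(1, 1, 1)`).

## Cluster segmentation

Clusters are segmented from a kernel-density map: every localization
deposits a CDF-integrated anisotropic Gaussian (default σ = 30 nm lateral,
60 nm axial, reflecting the precision anisotropy) on a sparse voxel grid
(20 nm voxels anchored at the coordinate origin so that different channels
share the grid). Voxels at or above the iso-threshold form 26-connected
components; each localization belongs to the component containing its
voxel. This is an open surrogate for commercial isosurface modules.

**Threshold.** The commercial tool's threshold is interactive and
undocumented, so the default here is a stated rule: 0.20 × the median
rendered density at the localizations themselves — a half-maximum-like
convention that places the surface near the object boundary. The fraction
was calibrated once on simulated recovery scenes: 0.25 missed ~5 % of
clusters (the dim tail of the count distribution falls below a global
threshold), 0.10 inflated lengths by ~15 % through the kernel halo; 0.20
gave 96–100 % cluster recovery with +2–4 % median length bias and was
frozen. The value actually used is recorded in every result
(`tallies(cs)$iso_threshold`), and a background-anchored alternative is
available (`autoMethod = "background"`).

**Metrics.**

* `count` — member localizations: the total number of blinking events,
  the relative-protein-content proxy;
* `length` — the 3D Feret diameter of the *isosurface mask* (exact maximum
  pairwise distance over the mask's directional-extreme candidate set).
  The member-point Feret is also reported (`length_member`) but is *not*
  the headline length: the maximum over $n$ sampled points shrinks
  systematically as $n$ drops (≈ $L(1-\sqrt{4/3n})$ for a filled
  ellipsoid), which would destroy the count-reduction stability that the
  length measure is supposed to have, whereas the mask geometry is
  invariant to count when the threshold is scaled proportionally. The mask
  length also reproduces the ~0.16 µm footprint of a single-localization
  artifact that motivates the reduced-data length floor;
* `width` — extent along the second principal axis of the members;
* `volume` — mask voxel count × voxel volume (µm³), exactly;
* `density` — `count / volume`, exactly.

Clusters with fewer than 8 localizations (inclusive: exactly 8 is kept) are
discarded, with full bookkeeping: kept counts + unassigned + dropped always
equals the input count.

**Truncation.** A cluster is flagged truncated when any member lies within
one voxel (default) of a z face of the region of interest; x/y faces are
optional. Border-straddling objects bias size measurements downward, which
is the reason the volumetric scan exists.

## Reduced-localization robustness

`subsampleLocalizations()` reproduces the exact deterministic schemes for
90/80/66/50 % (omit every 10th/5th/3rd/2nd record) and 33/20/10 % (keep
every 3rd/5th/10th record), 1-based positions, order preserved.
`reductionExperiment()` re-segments each reduced table with the isosurface
threshold scaled proportionally to the retained fraction and a 160 nm
length floor (the size of single-localization artifacts that appear at
strong reduction), and compares the length distributions across fractions
with a Kruskal–Wallis omnibus test. On simulated 1 µm-section scenes the
median mask length at 20 % of the data stays within ~3 % of the full-data
value and the omnibus test is non-significant.

## Bouton reconstruction and cluster assignment

The membrane label of a bouton is a hollow shell. Candidate boutons are
isosurface components of the membrane channel (threshold fraction 0.15 —
lower than for clusters because a shell must stay continuous to be
fillable); each component is morphologically closed (box radius 3 voxels),
its cavities filled by border-connected flood fill, and the filled mask
eroded back to the *radial midline* of the shell: the isosurface sits at
the shell's outer halo, so the filled volume is shrunk by the
self-estimated outer half-thickness (difference between the equivalent
filled radius and the mean shell-voxel radius). On simulated shells of
1.3–30 µm³ this recovers enclosed volumes within ~15 %. Manual bouton/axon
separation is replaced by optional seed points: all candidate voxels are
re-assigned to the nearest seed.

A cluster belongs to the bouton whose filled mask contains its
centre-of-mass voxel (boundary voxels count as inside); otherwise it is
unassigned. `perBoutonSummary()` reports per-bouton volume, cluster count
and median cluster metrics, plus the Spearman rank correlation of volume
against cluster count.

## Statistics

Data are summarized as median with 25th/75th percentiles (type-7
linear-interpolation quartiles; published values computed under another
convention may differ in the last digit), with mean ± SD alongside.
Group comparisons are the Mann–Whitney rank-sum test (exact for small
tie-free samples, continuity-corrected normal approximation otherwise) and
the Kruskal–Wallis test (chi-square approximation); correlation is
Spearman's rank with average ranks for ties and a t-approximation p-value.
Significance stars follow the convention *p < 0.05, **p < 0.01,
***p < 0.001. No multiple-testing correction is applied; raw p-values are
reported.

## The simulator: what it emulates, and what it does not

`simulateScene()` generates: prolate ellipsoidal clusters (aspect 0.2)
with lognormal lengths (median 450 nm, log-sd 0.35 — the size and spread
typical of side-view active-zone scaffold measurements; the truncation
scenes use log-sd 0.54, the wider spread seen in volumetric section data);
negative-binomial blinking counts per cluster (mean 139, sd 80, the
typical immunolabelled-scaffold blinking statistics); uniform stray background
(2 per µm³ after the raw-data intensity threshold); ~10 coverslip
fiducials with configurable per-localization spread; astigmatic widths
from the defocus model at the emitter's offset from the travelling focal
plane (visibility within ±500 nm); localization precision 15 nm lateral /
45 nm axial; linear drift over the acquisition (default (50, −30, 20) nm);
and geometric per-scan bleaching (5 %). Emitters beyond the scanned z
window are not emitted — the mechanical-truncation analogue. Which clusters
straddle a border is size-biased (probability ∝ z extent), as it would be
under uniform placement. Intensities are drawn above the 10000 ADU raw-fit
threshold with intensity/background ratios around 11.

Blinking is i.i.d. per event — no dark-state kinetics, no repeated
localization bursts of one fluorophore, no antibody linkage error as a
separate term (it is absorbed into the precision). Passing tests therefore
demonstrate that the *processing* recovers what the acquisition model
contains; they do not validate fluorophore photophysics, labelling
stoichiometry, or tissue aberrations beyond the homogeneity QC that
`depthProfile()` provides.

Scene generation is deterministic: the same `SceneSpec` and seed give
byte-identical tables (counts and labels exact; floats to better than
1e-9 relative), and the generator restores the caller's RNG state.

## Problem sizes and numerical choices

The shipped validation (test suite and `scripts/acceptance.R`) runs, per
stage: calibration sweeps of 2000 bead localizations; a full default scene
of 200 clusters (≈40 000 localizations, ten 15 000-frame scans over
25 × 25 × 10 µm); a 1 µm-section reduction scene of 80 clusters at eight
fractions; a truncation scene of 300 clusters; ten simulated boutons of
1.3–30 µm³; and 1000-replicate null calibration of the rank-sum test.
These sizes keep each validation under a few minutes on one core while
leaving the acceptance margins (e.g. ≥95 % cluster recovery, length error
≪15 %) comfortably resolved.

Numerical details worth knowing:

* density deposition integrates the Gaussian CDF over each voxel and
  truncates at 4σ, conserving counts to <0.1 %;
* the axial lookup grid is 1 nm; ties in the least-squares objective take
  the first (lowest-z) grid point;
* mask Feret diameters are exact maxima over the mask's convex-extreme
  candidates (64 Fibonacci directions), so elongated masks are measured in
  linear time;
* voxel-grid anchoring at the origin makes masks of different channels
  comparable voxel-by-voxel; halving the voxel edge changes simulated
  cluster volumes by <5 %;
* empty inputs propagate as empty outputs everywhere except where the
  operation's contract requires data (e.g. fiducial summarization).

## Known limitations

* The absolute cluster *volume* scale depends on the kernel/threshold
  convention, as it does for any isosurface method (including the
  commercial one it replaces); volumes are comparable within a convention,
  and validation scores volumes against the same measurement applied to
  noise-free ground-truth positions rather than against bare geometric
  ellipsoid volumes.
* The truncation-filter median shift (non-truncated < unfiltered) is a
  size-selection effect; at a few hundred simulated clusters it is small
  (~4 %) and can invert for unlucky seeds; on real sections the comparison
  rests on thousands of clusters and is far better resolved.
* Drift correction is linear in time between two bead epochs by design;
  non-monotone drift leaves a quantified residual.
* Rigid/similarity round alignment only; elastic registration is a
  non-goal.
* The bouton fill rule (closed, filled, midline-eroded shell) is one
  defensible reading of "inside the bouton signal"; alternative enclosure
  conventions shift volumes by roughly the shell thickness.
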