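# volstorm

Processing pipeline for **volumetric scanning 3D-dSTORM**: single-molecule
localization microscopy of thick tissue acquired by sweeping an astigmatic
focal plane repeatedly through the sample with a piezo stage.

Astigmatic 3D localization encodes the axial position of an emitter in the
asymmetry of its PSF widths, but only within ~±500 nm of focus. Imaging a
10 µm-deep region — an entire hippocampal mossy fiber bouton, with all of
its Bassoon-marked active zones — therefore requires continuous axial
scanning over many repeated sweeps, and afterwards a processing chain that
this package provides:

1. **Localization I/O** — rapidSTORM-style text and a canonical CSV
   dialect, with strict (abort-on-malformed-row) parsing, intensity
   filtering (≥10000 ADU) and 2D sub-pixel binning.
2. **Axial calibration** — cubic smoothing splines of the PSF widths
   wx(z), wy(z) from a bead sweep; the validity range is the interval where
   the discriminant wx − wy is strictly monotone, and sample localizations
   get z from a least-squares width-space lookup,
   ẑ = argmin (wx(z)−Wx)² + (wy(z)−Wy)².
3. **Volume assembly** — the true z of each record is the piezo position of
   its frame (linear trajectory, alternating direction) plus the astigmatic
   offset; rejected width pairs are tallied, never silently lost.
4. **Drift correction** — coverslip fiducials imaged before/after each
   measurement give a rigid transform, interpolated linearly in acquisition
   time; the same machinery aligns sequential staining rounds.
5. **Cluster analysis** — DBSCAN denoising (elliptical neighbourhood
   matching the axial/lateral precision ratio), Gaussian kernel-density
   isosurface segmentation (26-connected voxel components), per-cluster
   count / length (mask Feret diameter) / width / volume / density,
   truncation flags at volume borders, and the deterministic
   localization-reduction robustness experiment with proportional
   threshold scaling and a 160 nm length floor.
6. **Bouton mapping** — membrane-shell reconstruction (close, fill, erode
   to the shell midline), optional seed-point separation, centroid-inside
   cluster assignment, per-bouton summaries and the Spearman correlation
   of bouton volume versus cluster count.
7. **Statistics** — median ± quartile summaries, Mann–Whitney,
   Kruskal–Wallis, Spearman, significance stars.
8. **Simulator** — complete synthetic acquisitions (ellipsoidal clusters
   with lognormal lengths and negative-binomial blinking counts, defocus
   widths, fiducials, drift, bleaching, background, border truncation)
   with full ground truth, so every stage is testable end to end.

## Worked example

Simulate a 50-cluster acquisition (ten alternating scans over
15 × 15 × 5 µm), calibrate, assemble, correct drift, and segment:

```r
library(volstorm)

cal <- fitCalibration(simulateCalibrationStack(widthNoise = 2, seed = 2))
cal
#> CalibrationTable: z in [-800, 800] nm, focal plane at -0.8 nm
#>   widths at focus: wx 192.4 nm, wy 192.4 nm

scene <- simulateScene(sceneSpec(nClusters = 50L,
                                 fieldOfView = c(15000, 15000),
                                 zExtent = 5000, seed = 7))
volume <- assembleVolume(scene$movies, scene$scan, cal)
tf <- estimateTransform(summarizeBeads(scene$beadsPre, epoch = "pre"),
                        summarizeBeads(scene$beadsPost, epoch = "post"))
tf
#> RigidTransform: t = (49.4, -29.9, 19.7) nm, rot 0.0000 deg, scale 1.00000
#>   rms residual 1.66 nm over 10 bead pairs

corrected <- correctDrift(volume, tf, scene$scan)
cs <- segmentClusters(denoise(corrected), clusterParams())
cs
#> ClusterSet: 52 clusters from 7844 localizations
#>   median count 144, median length 487 nm, median volume 0.0116 um^3
#>   iso threshold 3398.3 per um^3; unassigned 373, dropped 13 locs

summarizeValues(clusters(cs)$length, "length_nm")
#>       label  n   median      q25      q75     mean       sd
#> 1 length_nm 52 486.8139 422.8443 577.9869 500.9401 145.3237
```

The estimated drift matches the simulated (50, −30, 20) nm to ~1 nm; the
52 recovered clusters (50 simulated, plus occasional splits of dim
objects) have a median of 144 blinking events, and the median mask length
of 487 nm sits a few percent above the simulated median of 450 nm — the
kernel-halo bias discussed in the methods vignette
(`vignettes/volstorm-methods.Rmd`). Bookkeeping is exact: cluster counts +
unassigned + dropped always equal the denoised input.

A thin command-line wrapper around the same functions lives at
`inst/cli/volstorm.R`:

```sh
Rscript inst/cli/volstorm.R simulate --out scene/
Rscript inst/cli/volstorm.R run --config pipeline.yaml --out results/
```

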