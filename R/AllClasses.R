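# S4 containers for the pipeline. All positions in nm, frames 0-based.

#' LocalizationTable: a point cloud of emitter detections
#'
#' Ordered collection of single-molecule localizations with acquisition
#' metadata. Mandatory columns of the underlying data.frame are `x`, `y`
#' and `frame`; recognised optional columns are `z`, `intensity`,
#' `background`, `width_x`, `width_y`, `movie_id` and `channel`.
#'
#' @slot locs data.frame of localizations, one row per detection; row order
#'   is the acquisition order and is preserved by all I/O round trips.
#' @slot fieldOfView numeric(2), lateral extent (x, y) of the imaged window
#'   in nm; the coordinate origin is the field-of-view corner.
#' @slot pixelSize numeric(1), camera pixel size in nm (used when reading
#'   pixel-unit dialects).
#' @slot metadata free-form list of provenance (dialect, source file,
#'   filters applied, bookkeeping tallies).
#' @exportClass LocalizationTable
setClass("LocalizationTable",
  representation(
    locs = "data.frame",
    fieldOfView = "numeric",
    pixelSize = "numeric",
    metadata = "list"
  ),
  prototype(
    locs = data.frame(x = numeric(0), y = numeric(0), frame = integer(0)),
    fieldOfView = c(25000, 25000),
    pixelSize = 100,
    metadata = list()
  )
)

setValidity("LocalizationTable", function(object) {
  df <- object@locs
  msgs <- character(0)
  for (col in c("x", "y", "frame")) {
    if (!col %in% names(df)) msgs <- c(msgs, sprintf("missing column '%s'", col))
  }
  if (length(msgs)) return(msgs)
  if (nrow(df)) {
    if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
      msgs <- c(msgs, "x and y must be finite")
    if (any(df$frame < 0)) msgs <- c(msgs, "frame indices must be >= 0")
    for (w in c("width_x", "width_y")) {
      if (w %in% names(df) && any(df[[w]] <= 0, na.rm = TRUE))
        msgs <- c(msgs, sprintf("%s must be > 0 where present", w))
    }
  }
  if (length(object@fieldOfView) != 2 || any(object@fieldOfView <= 0))
    msgs <- c(msgs, "fieldOfView must be two positive extents (nm)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LocalizationTable
#'
#' @param locs data.frame with at least columns `x`, `y`, `frame` (nm / 0-based).
#' @param fieldOfView numeric(2) lateral extent in nm; defaults to the data
#'   extent rounded up to the next micrometre.
#' @param pixelSize camera pixel size in nm.
#' @param metadata list of provenance entries.
#' @return A [LocalizationTable-class] object.
#' @examples
#' lt <- localizationTable(data.frame(x = c(100, 200), y = c(50, 60), frame = 0:1))
#' nLocs(lt)
#' @export
localizationTable <- function(locs, fieldOfView = NULL, pixelSize = 100,
                              metadata = list()) {
  if (!is.data.frame(locs)) stop("'locs' must be a data.frame")
  if (is.null(fieldOfView)) {
    if (nrow(locs)) {
      fieldOfView <- ceiling(c(max(locs$x), max(locs$y)) / 1000) * 1000
      fieldOfView <- pmax(fieldOfView, 1000)
    } else fieldOfView <- c(25000, 25000)
  }
  if ("frame" %in% names(locs)) locs$frame <- as.integer(round(locs$frame))
  new("LocalizationTable", locs = locs, fieldOfView = as.numeric(fieldOfView),
      pixelSize = pixelSize, metadata = metadata)
}

#' CalibrationTable: astigmatic width-versus-z calibration
#'
#' Smoothed PSF width curves wx(z), wy(z) from a bead sweep, with the axial
#' validity range restricted to where the discriminant wx - wy is strictly
#' monotone (unique lookup), and the focal plane at the curve crossing.
#'
#' @slot zGrid fine axial grid (nm, strictly increasing) spanning zRange.
#' @slot wx,wy smoothed widths (nm) evaluated on zGrid.
#' @slot zRange numeric(2) validity interval (nm, stage coordinates).
#' @slot focalZ stage z where wx = wy (nm).
#' @slot smoothing smoothing parameter passed to the spline fit.
#' @slot fitX,fitY the underlying smoothing-spline fits.
#' @exportClass CalibrationTable
setClass("CalibrationTable",
  representation(zGrid = "numeric", wx = "numeric", wy = "numeric",
                 zRange = "numeric", focalZ = "numeric",
                 smoothing = "numeric", fitX = "ANY", fitY = "ANY"))

setValidity("CalibrationTable", function(object) {
  msgs <- character(0)
  if (is.unsorted(object@zGrid, strictly = TRUE))
    msgs <- c(msgs, "zGrid must be strictly increasing")
  if (any(object@wx <= 0) || any(object@wy <= 0))
    msgs <- c(msgs, "width curves must be positive over the validity range")
  d <- object@wx - object@wy
  dd <- diff(d)
  if (length(dd) && !(all(dd > 0) || all(dd < 0)))
    msgs <- c(msgs, "discriminant wx - wy must be strictly monotone on zRange")
  if (length(msgs)) msgs else TRUE
})

#' ScanSpec: continuous axial piezo-scan geometry
#'
#' @slot nScans number of repeated axial scans (one movie per scan).
#' @slot framesPerMovie frames recorded in one movie.
#' @slot frameRate camera frame rate (Hz); metadata only.
#' @slot zTravel axial scan range in nm.
#' @slot zStart stage position at frame 0 of scan 0 (nm).
#' @slot alternateDirection invert scan direction after each scan, so the end
#'   of scan k coincides with the start of scan k+1.
#' @exportClass ScanSpec
setClass("ScanSpec",
  representation(nScans = "integer", framesPerMovie = "integer",
                 frameRate = "numeric", zTravel = "numeric",
                 zStart = "numeric", alternateDirection = "logical"))

setValidity("ScanSpec", function(object) {
  msgs <- character(0)
  if (object@zTravel <= 0) msgs <- c(msgs, "zTravel must be > 0")
  if (object@framesPerMovie < 2) msgs <- c(msgs, "framesPerMovie must be >= 2")
  if (object@nScans < 1) msgs <- c(msgs, "nScans must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ScanSpec
#'
#' Defaults follow the standard acquisition: ten scans of 15,000 frames at
#' 100 Hz with continuous axial travel over 10 um, inverting the direction
#' after each scan.
#'
#' @param nScans number of repeated scans.
#' @param framesPerMovie frames per movie.
#' @param frameRate frame rate in Hz.
#' @param zTravel axial scan range in nm (6000 for the 6-um protocol).
#' @param zStart stage position at frame 0 of scan 0 (nm).
#' @param alternateDirection invert direction after each scan.
#' @return A [ScanSpec-class] object.
#' @export
scanSpec <- function(nScans = 10L, framesPerMovie = 15000L, frameRate = 100,
                     zTravel = 10000, zStart = 0, alternateDirection = TRUE) {
  new("ScanSpec", nScans = as.integer(nScans),
      framesPerMovie = as.integer(framesPerMovie), frameRate = frameRate,
      zTravel = zTravel, zStart = zStart,
      alternateDirection = alternateDirection)
}

#' FiducialSet: summarized coverslip fiducial beads
#'
#' @slot positions n x 3 matrix of per-bead mean positions (nm).
#' @slot spreads n x 3 matrix of per-bead positional standard deviations (nm).
#' @slot nLocs localizations averaged per bead.
#' @slot epoch acquisition epoch label ("pre" or "post").
#' @exportClass FiducialSet
setClass("FiducialSet",
  representation(positions = "matrix", spreads = "matrix",
                 nLocs = "integer", epoch = "character"))

setValidity("FiducialSet", function(object) {
  msgs <- character(0)
  if (ncol(object@positions) != 3) msgs <- c(msgs, "positions must be n x 3")
  if (any(object@spreads < 0)) msgs <- c(msgs, "spreads must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' RigidTransform: drift / round-alignment transform
#'
#' Maps reference-epoch coordinates to moving-epoch coordinates as
#' y = s * R(theta) * (x - c) + c + t, where R rotates in the xy plane about
#' center c and the translation t acts on all three axes.
#'
#' @slot translation numeric(3) (dx, dy, dz) in nm.
#' @slot rotation in-plane rotation angle in radians.
#' @slot center numeric(2) xy rotation center (nm).
#' @slot scale uniform in-plane scale factor.
#' @slot rmsResidual post-fit residual over matched beads (nm).
#' @slot nPairs matched bead pairs used in the fit.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(translation = "numeric", rotation = "numeric",
                 center = "numeric", scale = "numeric",
                 rmsResidual = "numeric", nPairs = "integer"),
  prototype(translation = c(0, 0, 0), rotation = 0, center = c(0, 0),
            scale = 1, rmsResidual = 0, nPairs = 0L))

#' Construct a RigidTransform
#' @param translation numeric(3) nm.
#' @param rotation in-plane angle, radians.
#' @param center numeric(2) rotation center (nm).
#' @param scale uniform in-plane scale.
#' @param rmsResidual,nPairs fit diagnostics.
#' @return A [RigidTransform-class] object.
#' @export
rigidTransform <- function(translation = c(0, 0, 0), rotation = 0,
                           center = c(0, 0), scale = 1, rmsResidual = 0,
                           nPairs = 0L) {
  new("RigidTransform", translation = as.numeric(translation),
      rotation = rotation, center = as.numeric(center), scale = scale,
      rmsResidual = rmsResidual, nPairs = as.integer(nPairs))
}

#' ClusterParams: segmentation and denoising parameters
#'
#' @slot dbscanEps DBSCAN neighbourhood radius for denoising (nm).
#' @slot dbscanMinPts DBSCAN minimum neighbour count (a point with fewer
#'   than this many points inside eps, itself included, is noise).
#' @slot voxelSize density-map voxel edge (nm).
#' @slot kernelSigma numeric(3) Gaussian rendering sigma per axis (nm);
#'   axial sigma larger than lateral to reflect poorer axial precision.
#' @slot isoThreshold density threshold (localizations per um^3); NA means
#'   auto-selection (see [segmentClusters()]).
#' @slot minCount minimum localizations per cluster, inclusive.
#' @slot minLength minimum cluster length (nm); 160 for reduced-data runs.
#' @slot borderMargin truncation margin (nm); default one voxel.
#' @exportClass ClusterParams
setClass("ClusterParams",
  representation(dbscanEps = "numeric", dbscanMinPts = "integer",
                 voxelSize = "numeric", kernelSigma = "numeric",
                 isoThreshold = "numeric", minCount = "integer",
                 minLength = "numeric", borderMargin = "numeric"))

setValidity("ClusterParams", function(object) {
  msgs <- character(0)
  pos <- c(dbscanEps = object@dbscanEps, voxelSize = object@voxelSize,
           borderMargin = object@borderMargin)
  if (any(pos <= 0)) msgs <- c(msgs, "parameters must be strictly positive")
  if (any(object@kernelSigma <= 0)) msgs <- c(msgs, "kernelSigma must be > 0")
  if (object@minLength < 0) msgs <- c(msgs, "minLength must be >= 0")
  if (object@dbscanMinPts < 1 || object@minCount < 1)
    msgs <- c(msgs, "count parameters must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct ClusterParams
#' @param dbscanEps DBSCAN radius, nm.
#' @param dbscanMinPts DBSCAN minimum neighbours.
#' @param voxelSize voxel edge, nm.
#' @param kernelSigma per-axis Gaussian sigma, nm (length 1 recycled to
#'   lateral, axial doubled; or length 3).
#' @param isoThreshold density threshold, localizations per um^3 (NA = auto).
#' @param minCount minimum localizations per cluster (inclusive).
#' @param minLength minimum cluster length, nm.
#' @param borderMargin truncation margin, nm.
#' @return A [ClusterParams-class] object.
#' @export
clusterParams <- function(dbscanEps = 100, dbscanMinPts = 8L, voxelSize = 20,
                          kernelSigma = c(30, 30, 60), isoThreshold = NA_real_,
                          minCount = 8L, minLength = 0,
                          borderMargin = voxelSize) {
  if (length(kernelSigma) == 1) kernelSigma <- c(kernelSigma, kernelSigma, 2 * kernelSigma)
  new("ClusterParams", dbscanEps = dbscanEps,
      dbscanMinPts = as.integer(dbscanMinPts), voxelSize = voxelSize,
      kernelSigma = as.numeric(kernelSigma), isoThreshold = isoThreshold,
      minCount = as.integer(minCount), minLength = minLength,
      borderMargin = borderMargin)
}

#' ClusterSet: segmented protein clusters
#'
#' @slot clusters data.frame with one row per kept cluster: cluster_id,
#'   count, centroid_x/y/z (nm), length (nm, 3D Feret diameter of the
#'   isosurface mask), length_member (nm, Feret diameter of the member
#'   localizations), width (nm, extent along the second principal axis),
#'   volume_um3 (mask voxels times voxel volume), density_per_um3
#'   (= count / volume exactly), truncated, bouton_id.
#' @slot membership integer vector, one entry per input localization; 0 means
#'   not part of any kept cluster.
#' @slot params the [ClusterParams-class] used.
#' @slot grid list(origin, voxel) describing the shared voxel grid.
#' @slot tallies bookkeeping list: n_input, unassigned, dropped_clusters,
#'   dropped_locs, iso_threshold.
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(clusters = "data.frame", membership = "integer",
                 params = "ClusterParams", grid = "list", tallies = "list"))

#' BoutonSet: reconstructed membrane-labelled bouton surfaces
#'
#' @slot boutons data.frame: bouton_id, volume_um3 (= mask voxels times voxel
#'   volume exactly), centroid_x/y/z (nm), n_clusters.
#' @slot masks list of integer matrices (n x 3 voxel indices, 0-based) of the
#'   filled bouton masks; masks of distinct boutons are disjoint.
#' @slot grid list(origin, voxel): the voxel grid shared with the density map.
#' @exportClass BoutonSet
setClass("BoutonSet",
  representation(boutons = "data.frame", masks = "list", grid = "list"))

#' DensityMap3D: sparse 3D kernel-density rendering
#'
#' Sparse voxel map of localization density (localizations per um^3). Only
#' voxels within the kernel cutoff of at least one localization are stored.
#'
#' @slot i,j,k 0-based voxel indices relative to `offset`.
#' @slot value density values (localizations per um^3).
#' @slot dims extents of the occupied index box.
#' @slot offset global index of the box corner (may be negative).
#' @slot origin numeric(3) world coordinate (nm) of global voxel (0,0,0).
#' @slot voxel numeric(3) voxel edge lengths (nm).
#' @slot sigma numeric(3) kernel sigma (nm).
#' @slot n number of localizations rendered.
#' @exportClass DensityMap3D
setClass("DensityMap3D",
  representation(i = "integer", j = "integer", k = "integer",
                 value = "numeric", dims = "integer", offset = "integer",
                 origin = "numeric", voxel = "numeric", sigma = "numeric",
                 n = "integer"))

#' SceneSpec: parameters of a simulated volumetric acquisition
#'
#' Defaults emulate the study conditions: a 25 x 25 um imaging window scanned
#' over 10 um in z by ten 15,000-frame movies with alternating direction,
#' prolate ellipsoidal clusters with lognormal lengths (median 450 nm),
#' negative-binomial blinking counts (mean 139, sd 80), ~10 coverslip
#' fiducials, uniform stray background, astigmatic defocus widths, slow
#' linear drift, and fractional photobleaching per scan.
#'
#' @slot fieldOfView numeric(2) lateral extent (nm).
#' @slot zExtent axial extent of the scanned volume (nm).
#' @slot nClusters number of ground-truth clusters.
#' @slot clusterLengthMedian median of the lognormal length distribution (nm).
#' @slot clusterLengthSigma log-sd of the length distribution.
#' @slot clusterAspect width/length ratio of the prolate ellipsoids.
#' @slot locsPerCluster mean blinking events per cluster.
#' @slot locsPerClusterSD standard deviation of blinking events per cluster.
#' @slot backgroundDensity stray localizations per um^3 over the acquisition.
#' @slot nBeads coverslip fiducials.
#' @slot beadSpread per-localization positional sd of bead fits (nm).
#' @slot beadLocs localizations per bead per epoch.
#' @slot precision numeric(2) (lateral, axial) localization precision sd (nm).
#' @slot drift numeric(3) linear drift over the acquisition (nm).
#' @slot bleachPerScan fractional emitter loss per scan.
#' @slot captureHalfwidth astigmatic visibility half-range around focus (nm).
#' @slot truncationFraction fraction of clusters straddling a z border.
#' @slot nScans,framesPerMovie scan geometry (see [scanSpec()]).
#' @slot seed random seed; identical spec + seed give identical output.
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(fieldOfView = "numeric", zExtent = "numeric",
                 nClusters = "integer", clusterLengthMedian = "numeric",
                 clusterLengthSigma = "numeric", clusterAspect = "numeric",
                 locsPerCluster = "numeric", locsPerClusterSD = "numeric",
                 backgroundDensity = "numeric", nBeads = "integer",
                 beadSpread = "numeric", beadLocs = "integer",
                 precision = "numeric", drift = "numeric",
                 bleachPerScan = "numeric", captureHalfwidth = "numeric",
                 truncationFraction = "numeric", nScans = "integer",
                 framesPerMovie = "integer", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msgs <- character(0)
  if (object@nClusters < 0 || object@backgroundDensity < 0 ||
      object@nBeads < 0 || object@locsPerCluster < 0)
    msgs <- c(msgs, "densities and counts must be >= 0")
  if (object@bleachPerScan < 0 || object@bleachPerScan >= 1)
    msgs <- c(msgs, "bleachPerScan must be in [0, 1)")
  if (object@truncationFraction < 0 || object@truncationFraction > 1)
    msgs <- c(msgs, "truncationFraction must be in [0, 1]")
  # a typical cluster must fit in the scanned volume (larger-than-section
  # clusters are legitimate -- they come out truncated -- but a median-sized
  # cluster exceeding the volume is an infeasible spec)
  if (object@nClusters > 0 &&
      object@clusterLengthMedian > min(object@fieldOfView, object@zExtent))
    msgs <- c(msgs, "infeasible spec: median cluster length exceeds the scanned volume")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SceneSpec
#'
#' See [SceneSpec-class] for the meaning and provenance of the defaults.
#'
#' @param fieldOfView lateral extent (nm).
#' @param zExtent axial extent (nm).
#' @param nClusters ground-truth cluster count.
#' @param clusterLengthMedian,clusterLengthSigma lognormal length model (nm, log-sd).
#' @param clusterAspect width/length ratio.
#' @param locsPerCluster,locsPerClusterSD blinking counts per cluster (mean, sd).
#' @param backgroundDensity stray localizations per um^3.
#' @param nBeads,beadSpread,beadLocs fiducial model.
#' @param precision (lateral, axial) localization sd (nm).
#' @param drift linear drift (dx, dy, dz) over the acquisition (nm).
#' @param bleachPerScan fractional emitter loss per scan.
#' @param captureHalfwidth astigmatic visibility half-range (nm).
#' @param truncationFraction fraction of clusters straddling a z border.
#' @param nScans,framesPerMovie scan geometry.
#' @param seed random seed.
#' @return A [SceneSpec-class] object.
#' @export
sceneSpec <- function(fieldOfView = c(25000, 25000), zExtent = 10000,
                      nClusters = 200L, clusterLengthMedian = 450,
                      clusterLengthSigma = 0.35, clusterAspect = 0.2,
                      locsPerCluster = 139, locsPerClusterSD = 80,
                      backgroundDensity = 2, nBeads = 10L, beadSpread = 5,
                      beadLocs = 50L, precision = c(15, 45),
                      drift = c(50, -30, 20), bleachPerScan = 0.05,
                      captureHalfwidth = 500, truncationFraction = 0,
                      nScans = 10L, framesPerMovie = 15000L, seed = 1L) {
  new("SceneSpec", fieldOfView = as.numeric(fieldOfView), zExtent = zExtent,
      nClusters = as.integer(nClusters),
      clusterLengthMedian = clusterLengthMedian,
      clusterLengthSigma = clusterLengthSigma, clusterAspect = clusterAspect,
      locsPerCluster = locsPerCluster, locsPerClusterSD = locsPerClusterSD,
      backgroundDensity = backgroundDensity, nBeads = as.integer(nBeads),
      beadSpread = beadSpread, beadLocs = as.integer(beadLocs),
      precision = as.numeric(precision), drift = as.numeric(drift),
      bleachPerScan = bleachPerScan, captureHalfwidth = captureHalfwidth,
      truncationFraction = truncationFraction, nScans = as.integer(nScans),
      framesPerMovie = as.integer(framesPerMovie), seed = as.integer(seed))
}

#' SceneTruth: complete ground truth of a simulated scene
#'
#' @slot clusters data.frame: cluster_id, center x/y/z (nm), length (major
#'   axis, nm), width (nm), axis (orientation, 3 columns), n_locs realized,
#'   feret_true (max pairwise distance of the true member positions, nm),
#'   truncated (straddles a z border by construction).
#' @slot beads n x 3 matrix of true bead positions (nm, pre-drift).
#' @slot drift applied linear drift (nm over the acquisition).
#' @slot labels list with one integer vector per movie: ground-truth cluster
#'   id per emitted localization (0 = background).
#' @slot truePositions n x 3 matrix of the true (noise- and drift-free)
#'   positions of every emitted event, cluster events first then background.
#' @slot trueLabels integer cluster id per row of `truePositions`.
#' @slot eventIndex list with one integer vector per movie mapping each
#'   movie row to its row in `truePositions`.
#' @slot spec the generating [SceneSpec-class].
#' @exportClass SceneTruth
setClass("SceneTruth",
  representation(clusters = "data.frame", beads = "matrix",
                 drift = "numeric", labels = "list",
                 truePositions = "matrix", trueLabels = "integer",
                 eventIndex = "list", spec = "SceneSpec"))
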