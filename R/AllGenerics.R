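# Generics and accessors. Slots are never touched directly by user code.

#' Localization records of a table
#' @param x a [LocalizationTable-class].
#' @return data.frame of localizations in acquisition order.
#' @export
setGeneric("locs", function(x) standardGeneric("locs"))

#' @rdname locs
#' @export
setMethod("locs", "LocalizationTable", function(x) x@locs)

#' Number of localizations
#' @param x a [LocalizationTable-class].
#' @return integer count of records.
#' @export
setGeneric("nLocs", function(x) standardGeneric("nLocs"))

#' @rdname nLocs
#' @export
setMethod("nLocs", "LocalizationTable", function(x) nrow(x@locs))

#' Field of view of a localization table
#' @param x a [LocalizationTable-class].
#' @return numeric(2) lateral extent in nm.
#' @export
setGeneric("fieldOfView", function(x) standardGeneric("fieldOfView"))

#' @rdname fieldOfView
#' @export
setMethod("fieldOfView", "LocalizationTable", function(x) x@fieldOfView)

#' Provenance metadata
#' @param x a [LocalizationTable-class] or [ClusterSet-class].
#' @return list of provenance entries.
#' @export
setGeneric("locMetadata", function(x) standardGeneric("locMetadata"))

#' @rdname locMetadata
#' @export
setMethod("locMetadata", "LocalizationTable", function(x) x@metadata)

#' Replace provenance metadata
#' @param x a [LocalizationTable-class].
#' @param value a list.
#' @return the modified object.
#' @export
setGeneric("locMetadata<-", function(x, value) standardGeneric("locMetadata<-"))

#' @rdname locMetadata-set
#' @export
setMethod("locMetadata<-", "LocalizationTable", function(x, value) {
  x@metadata <- value
  x
})

#' Cluster metric table of a ClusterSet
#' @param x a [ClusterSet-class].
#' @return data.frame with one row per kept cluster.
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname clusters
#' @export
setMethod("clusters", "ClusterSet", function(x) x@clusters)

#' Per-localization cluster membership
#' @param x a [ClusterSet-class].
#' @return integer vector (0 = not in any kept cluster), aligned with the
#'   localization table the set was segmented from.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname membership
#' @export
setMethod("membership", "ClusterSet", function(x) x@membership)

#' Bookkeeping tallies of a segmentation
#' @param x a [ClusterSet-class].
#' @return list with n_input, unassigned, dropped_clusters, dropped_locs and
#'   the iso_threshold used.
#' @export
setGeneric("tallies", function(x) standardGeneric("tallies"))

#' @rdname tallies
#' @export
setMethod("tallies", "ClusterSet", function(x) x@tallies)

#' Bouton summary table of a BoutonSet
#' @param x a [BoutonSet-class].
#' @return data.frame with one row per bouton.
#' @export
setGeneric("boutons", function(x) standardGeneric("boutons"))

#' @rdname boutons
#' @export
setMethod("boutons", "BoutonSet", function(x) x@boutons)

#' Focal plane of a calibration
#' @param x a [CalibrationTable-class].
#' @return stage z (nm) where wx = wy.
#' @export
setGeneric("focalZ", function(x) standardGeneric("focalZ"))

#' @rdname focalZ
#' @export
setMethod("focalZ", "CalibrationTable", function(x) x@focalZ)

#' Axial validity range of a calibration
#' @param x a [CalibrationTable-class].
#' @return numeric(2) stage-z interval (nm) where the discriminant is
#'   strictly monotone.
#' @export
setGeneric("zRange", function(x) standardGeneric("zRange"))

#' @rdname zRange
#' @export
setMethod("zRange", "CalibrationTable", function(x) x@zRange)

setMethod("show", "LocalizationTable", function(object) {
  df <- object@locs
  cat(sprintf("LocalizationTable: %d localizations, FOV %.1f x %.1f um\n",
              nrow(df), object@fieldOfView[1] / 1000,
              object@fieldOfView[2] / 1000))
  cat("  columns:", paste(names(df), collapse = ", "), "\n")
  if ("movie_id" %in% names(df) && nrow(df))
    cat("  movies:", length(unique(df$movie_id)), "\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "CalibrationTable", function(object) {
  cat(sprintf(
    "CalibrationTable: z in [%.0f, %.0f] nm, focal plane at %.1f nm\n",
    object@zRange[1], object@zRange[2], object@focalZ))
  cat(sprintf("  widths at focus: wx %.1f nm, wy %.1f nm\n",
              approx(object@zGrid, object@wx, object@focalZ)$y,
              approx(object@zGrid, object@wy, object@focalZ)$y))
})

setMethod("show", "ScanSpec", function(object) {
  cat(sprintf(
    "ScanSpec: %d scans x %d frames @ %g Hz, z travel %.1f um from %.0f nm%s\n",
    object@nScans, object@framesPerMovie, object@frameRate,
    object@zTravel / 1000, object@zStart,
    if (object@alternateDirection) ", alternating" else ""))
})

setMethod("show", "FiducialSet", function(object) {
  cat(sprintf("FiducialSet (%s): %d beads, median spread %.1f nm\n",
              object@epoch, nrow(object@positions),
              if (nrow(object@spreads)) median(object@spreads) else NA))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf(
    "RigidTransform: t = (%.1f, %.1f, %.1f) nm, rot %.4f deg, scale %.5f\n",
    object@translation[1], object@translation[2], object@translation[3],
    object@rotation * 180 / pi, object@scale))
  cat(sprintf("  rms residual %.2f nm over %d bead pairs\n",
              object@rmsResidual, object@nPairs))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d clusters from %d localizations\n",
              nrow(object@clusters), object@tallies$n_input))
  if (nrow(object@clusters)) {
    cat(sprintf("  median count %.0f, median length %.0f nm, median volume %.4f um^3\n",
                median(object@clusters$count), median(object@clusters$length),
                median(object@clusters$volume_um3)))
  }
  cat(sprintf("  iso threshold %.1f per um^3; unassigned %d, dropped %d locs\n",
              object@tallies$iso_threshold, object@tallies$unassigned,
              object@tallies$dropped_locs))
})

setMethod("show", "BoutonSet", function(object) {
  cat(sprintf("BoutonSet: %d boutons, volumes %s um^3\n",
              nrow(object@boutons),
              if (nrow(object@boutons))
                paste(sprintf("%.1f", sort(object@boutons$volume_um3)),
                      collapse = ", ") else ""))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d clusters in %.0f x %.0f x %.0f um, %d scans, seed %d\n",
    object@nClusters, object@fieldOfView[1] / 1000,
    object@fieldOfView[2] / 1000, object@zExtent / 1000, object@nScans,
    object@seed))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth: %d clusters, %d beads, drift (%.0f, %.0f, %.0f) nm\n",
              nrow(object@clusters), nrow(object@beads), object@drift[1],
              object@drift[2], object@drift[3]))
})

setMethod("show", "DensityMap3D", function(object) {
  cat(sprintf(
    "DensityMap3D: %d occupied voxels (%.0f nm), %d localizations, peak %.1f per um^3\n",
    length(object@value), object@voxel[1], object@n, max(object@value)))
})
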