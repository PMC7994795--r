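# End-to-end orchestration: simulate or ingest movies, assemble, correct
# drift, filter, denoise, segment, flag truncation, optionally map boutons,
# and report. Driven by a YAML configuration with [scan], [calibration],
# [cluster], [bouton] and [simulate] sections.

.cfg <- function(config, section, key, default) {
  v <- config[[section]][[key]]
  if (is.null(v)) default else v
}

#' Run the full volumetric pipeline
#'
#' Either simulates a scene (config section `simulate`) or reads movie and
#' bead tables from disk (section `input`: `movies`, `beads_pre`,
#' `beads_post`, `calibration`), then assembles the volume with true z,
#' corrects drift from the bracketing bead epochs, applies the intensity
#' filter, DBSCAN denoising, isosurface segmentation and truncation
#' flagging, and summarizes cluster metrics.
#'
#' @param config a YAML file path or an equivalent nested list.
#' @param outdir optional directory; when given, the corrected volume and
#'   cluster table are written as canonical CSV.
#' @param seed overrides the configured simulation seed.
#' @return list with the assembled `volume`, `corrected` table, `denoised`
#'   table, `clusterSet`, `summary` (data.frame of median metrics),
#'   `truth` (when simulated) and `provenance`.
#' @export
runPipeline <- function(config = list(), outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  scan <- scanSpec(
    nScans = .cfg(config, "scan", "n_scans", 10L),
    framesPerMovie = .cfg(config, "scan", "frames_per_movie", 15000L),
    frameRate = .cfg(config, "scan", "frame_rate", 100),
    zTravel = .cfg(config, "scan", "z_travel_nm", 10000),
    zStart = .cfg(config, "scan", "z_start_nm", 0))
  params <- clusterParams(
    dbscanEps = .cfg(config, "cluster", "dbscan_eps", 100),
    dbscanMinPts = .cfg(config, "cluster", "dbscan_min_pts", 8L),
    voxelSize = .cfg(config, "cluster", "voxel_size", 20),
    kernelSigma = unlist(.cfg(config, "cluster", "kernel_sigma", c(30, 30, 60))),
    isoThreshold = .cfg(config, "cluster", "iso_threshold", NA_real_),
    minCount = .cfg(config, "cluster", "min_count", 8L),
    minLength = .cfg(config, "cluster", "min_length", 0))

  truth <- NULL
  if (!is.null(config$simulate) || is.null(config$input)) {
    simSeed <- if (!is.null(seed)) seed else .cfg(config, "simulate", "seed", 1L)
    spec <- sceneSpec(
      fieldOfView = unlist(.cfg(config, "simulate", "field_of_view_nm",
                                c(25000, 25000))),
      zExtent = .cfg(config, "simulate", "z_extent_nm", scan@zTravel),
      nClusters = .cfg(config, "simulate", "n_clusters", 200L),
      backgroundDensity = .cfg(config, "simulate", "background_density", 2),
      truncationFraction = .cfg(config, "simulate", "truncation_fraction", 0),
      nScans = scan@nScans, framesPerMovie = scan@framesPerMovie,
      seed = as.integer(simSeed))
    scene <- simulateScene(spec)
    movies <- scene$movies
    beadsPre <- scene$beadsPre
    beadsPost <- scene$beadsPost
    scan <- scene$scan
    truth <- scene$truth
    calib <- fitCalibration(simulateCalibrationStack(
      seed = as.integer(simSeed) + 101L))
  } else {
    movies <- lapply(config$input$movies, readLocalizations,
                     dialect = .cfg(config, "input", "dialect", "canonical_csv"))
    beadsPre <- readLocalizations(config$input$beads_pre)
    beadsPost <- readLocalizations(config$input$beads_post)
    calib <- readCalibration(config$input$calibration)
  }

  volume <- assembleVolume(movies, scan, calib)
  tf <- estimateTransform(summarizeBeads(beadsPre, epoch = "pre"),
                          summarizeBeads(beadsPost, epoch = "post"))
  corrected <- correctDrift(volume, tf, scan)
  if ("intensity" %in% names(locs(corrected)))
    corrected <- filterIntensity(corrected,
                                 .cfg(config, "cluster", "intensity_threshold",
                                      10000))
  den <- denoise(corrected, eps = params@dbscanEps,
                 minPts = params@dbscanMinPts)
  cs <- segmentClusters(den, params)
  roi <- list(x = c(0, fieldOfView(den)[1]), y = c(0, fieldOfView(den)[2]),
              z = c(scan@zStart, scan@zStart + scan@zTravel))
  cs <- flagTruncation(cs, den, roi)
  cl <- clusters(cs)
  summary <- rbind(
    if (nrow(cl)) summarizeValues(cl$count, "count"),
    if (nrow(cl)) summarizeValues(cl$length, "length_nm"),
    if (nrow(cl)) summarizeValues(cl$volume_um3, "volume_um3"),
    if (nrow(cl)) summarizeValues(cl$density_per_um3, "density_per_um3"))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeLocalizations(corrected, file.path(outdir, "volume_corrected.csv"),
                       allowEmpty = TRUE)
    write.csv(cl, file.path(outdir, "clusters.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(parameters = list(scan = list(n_scans = scan@nScans,
                                         frames_per_movie = scan@framesPerMovie,
                                         z_travel_nm = scan@zTravel),
                             iso_threshold = tallies(cs)$iso_threshold,
                             drift_translation_nm = tf@translation),
           version = as.character(utils::packageVersion("volstorm"))),
      file.path(outdir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  list(volume = volume, corrected = corrected, denoised = den,
       clusterSet = cs, summary = summary, truth = truth,
       provenance = list(drift = tf, calibration = calib, scan = scan,
                         params = params))
}
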