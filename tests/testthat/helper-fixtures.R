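# Shared fixtures and independent reference implementations.

# a clean noiseless calibration used across tests (cached per session)
noiseless_calibration <- local({
  cal <- NULL
  function() {
    if (is.null(cal)) cal <<- fitCalibration(
      simulateCalibrationStack(widthNoise = 0, seed = 2))
    cal
  }
})

# tiny localization table builder
loc_table <- function(x, y, z = NULL, frame = seq_along(x) - 1L, ...) {
  df <- data.frame(x = x, y = y, frame = frame, ...)
  if (!is.null(z)) df$z <- z
  localizationTable(df)
}

# brute-force O(n^2) DBSCAN, written independently of the package kernel:
# labels 0 = noise, clusters numbered by discovery order
brute_dbscan <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      for (q in nbrs[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# assembled + drift-corrected + denoised table for a scene, with truth
run_front_end <- function(spec, calib = noiseless_calibration()) {
  scene <- simulateScene(spec)
  vol <- assembleVolume(scene$movies, scene$scan, calib)
  tf <- estimateTransform(summarizeBeads(scene$beadsPre, epoch = "pre"),
                          summarizeBeads(scene$beadsPost, epoch = "post"))
  corrected <- correctDrift(vol, tf, scene$scan)
  list(scene = scene, volume = vol, transform = tf,
       corrected = corrected, denoised = denoise(corrected),
       truth = sceneTruthTable(scene$truth))
}

# match recovered cluster centroids to truth centers (nearest within maxDist)
match_truth <- function(cl, tt, maxDist = 200) {
  d2 <- outer(cl$centroid_x, tt$x, "-")^2 +
    outer(cl$centroid_y, tt$y, "-")^2 +
    outer(cl$centroid_z, tt$z, "-")^2
  dist_min <- apply(d2, 2, function(v) sqrt(min(v)))
  idx <- apply(d2, 2, which.min)
  list(dist = dist_min, idx = idx, matched = dist_min <= maxDist)
}
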