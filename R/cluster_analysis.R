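# Denoising, density rendering, isosurface cluster segmentation, metrics,
# truncation flagging, deterministic subsampling and the reduction experiment.

#' DBSCAN denoising of a volumetric point cloud
#'
#' Runs DBSCAN on the 3D coordinates and removes records labelled noise
#' (fewer than `minPts` neighbours within `eps`, core-unreachable). Used to
#' strip stray background localizations before isosurface segmentation.
#'
#' Astigmatic 3D localization is 2-3x less precise axially than laterally,
#' so a point cloud that is dense in the sample is smeared into an ellipsoid
#' in the data. The neighbourhood is therefore elliptical by default: the
#' `anisotropy` vector divides each coordinate before the radius test, so
#' with the default `c(1, 1, 3)` the neighbourhood reaches `eps` laterally
#' and `3 * eps` axially. Set `anisotropy = c(1, 1, 1)` for the textbook
#' isotropic metric.
#'
#' @param table a [LocalizationTable-class] with z present.
#' @param eps lateral neighbourhood radius (nm).
#' @param minPts minimum points within the neighbourhood (the point itself
#'   counts).
#' @param anisotropy numeric(3) per-axis scaling of the neighbourhood.
#' @return the denoised [LocalizationTable-class]; metadata records the
#'   removed count.
#' @export
denoise <- function(table, eps = 100, minPts = 8L, anisotropy = c(1, 1, 3)) {
  stopifnot(is(table, "LocalizationTable"))
  df <- locs(table)
  if (!nrow(df)) return(table)
  if (!"z" %in% names(df)) stop("denoise needs a z column")
  lab <- cpp_dbscan(df$x / anisotropy[1], df$y / anisotropy[2],
                    df$z / anisotropy[3], eps, as.integer(minPts))
  keep <- lab > 0
  out <- table
  out@locs <- df[keep, , drop = FALSE]
  rownames(out@locs) <- NULL
  meta <- locMetadata(table)
  meta$denoise <- list(eps = eps, min_pts = minPts, anisotropy = anisotropy,
                       removed = sum(!keep))
  out@metadata <- meta
  out
}

#' Render a sparse 3D kernel-density map
#'
#' Each localization deposits a normalized anisotropic Gaussian, integrated
#' per voxel, so the map integral times the voxel volume equals the record
#' count to within the kernel cutoff truncation (< 0.1 % at the default
#' 4-sigma cutoff). The voxel grid is anchored at the coordinate origin so
#' maps of different channels share voxel indices.
#'
#' @param table a [LocalizationTable-class] with z present.
#' @param voxelSize voxel edge (nm).
#' @param kernelSigma per-axis Gaussian sigma (nm), length 1 or 3.
#' @param cutoff kernel support half-width in sigmas.
#' @return A [DensityMap3D-class] (localizations per um^3).
#' @export
renderDensity3D <- function(table, voxelSize = 20, kernelSigma = c(30, 30, 60),
                            cutoff = 4) {
  stopifnot(is(table, "LocalizationTable"))
  df <- locs(table)
  if (!"z" %in% names(df)) stop("renderDensity3D needs a z column")
  if (voxelSize <= 0) stop("voxelSize must be > 0")
  if (length(kernelSigma) == 1) kernelSigma <- rep(kernelSigma, 3)
  if (voxelSize > 2 * min(kernelSigma))
    warning("voxelSize > 2 * kernelSigma: kernel undersampled")
  sp <- cpp_density_sparse(df$x, df$y, df$z, c(0, 0, 0),
                           rep(voxelSize, 3), as.numeric(kernelSigma), cutoff)
  new("DensityMap3D", i = sp$i, j = sp$j, k = sp$k, value = sp$value,
      dims = sp$dims, offset = sp$offset, origin = c(0, 0, 0),
      voxel = rep(voxelSize, 3), sigma = as.numeric(kernelSigma),
      n = nrow(df))
}

#' Dense array view of a density map
#' @param map a [DensityMap3D-class].
#' @param maxCells guard against materializing huge arrays.
#' @return 3D numeric array over the occupied bounding box; attribute
#'   `offset` gives the global voxel index of `[1,1,1]`.
#' @export
densityArray <- function(map, maxCells = 2e8) {
  stopifnot(is(map, "DensityMap3D"))
  if (prod(as.numeric(map@dims)) > maxCells)
    stop("density array too large to materialize; use the sparse form")
  arr <- array(0, dim = map@dims)
  arr[cbind(map@i + 1L, map@j + 1L, map@k + 1L)] <- map@value
  attr(arr, "offset") <- map@offset
  attr(arr, "voxel") <- map@voxel
  arr
}

#' Map integral in localization counts
#' @param map a [DensityMap3D-class].
#' @return sum(values) times the voxel volume (should equal the record count).
#' @export
densityIntegral <- function(map) {
  stopifnot(is(map, "DensityMap3D"))
  sum(map@value) * prod(map@voxel) * 1e-9
}

# Feret diameter of a voxel mask: exact max pairwise distance over the
# convex-hull candidate set (per-direction extremes over a fixed Fibonacci
# sphere of directions), so elongated masks are measured in O(V) + O(c^2).
.mask_feret <- function(vox, voxelSize) {
  if (nrow(vox) == 1) return(0)
  P <- (vox + 0.5) * voxelSize
  ndir <- 64L
  ii <- seq_len(ndir) - 1
  zz <- 1 - 2 * ii / (ndir - 1)
  rr <- sqrt(pmax(1 - zz^2, 0))
  th <- pi * (3 - sqrt(5)) * ii
  D <- cbind(rr * cos(th), rr * sin(th), zz)
  proj <- P %*% t(D)
  idx <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
  C <- P[idx, , drop = FALSE]
  cpp_max_pairwise(C[, 1], C[, 2], C[, 3])
}

# Resolve the iso threshold. "member_density" anchors the threshold at the
# typical rendered density at the localizations themselves (cluster
# interiors) and takes a fixed fraction of it: the half-maximum convention
# that places the isosurface near the true object boundary. "background"
# uses a multiple of the mean density over the data bounding box.
.resolve_iso_threshold <- function(map, df, method, fraction) {
  if (method == "member_density") {
    qi <- as.integer(floor(df$x / map@voxel[1])) - map@offset[1]
    qj <- as.integer(floor(df$y / map@voxel[2])) - map@offset[2]
    qk <- as.integer(floor(df$z / map@voxel[3])) - map@offset[3]
    vals <- cpp_voxel_lookup(qi, qj, qk, map@i, map@j, map@k,
                             seq_along(map@value))
    dens <- numeric(nrow(df))
    dens[vals > 0] <- map@value[vals[vals > 0]]
    fraction * median(dens)
  } else {
    vol_um3 <- prod(pmax(apply(cbind(df$x, df$y, df$z), 2,
                               function(v) diff(range(v))), 1)) * 1e-9
    5 * nrow(df) / vol_um3
  }
}

#' Segment protein clusters by density isosurface
#'
#' Thresholds the kernel-density map and takes 26-connected voxel components
#' as cluster masks (an open surrogate for commercial isosurface modules).
#' Each localization is assigned to the mask containing its voxel;
#' localizations in no mask are excluded and tallied. Per-cluster metrics:
#' count (blinking events), centroid, length (3D Feret diameter of the
#' isosurface mask — stable under localization-count reduction, unlike the
#' member-point Feret which shrinks with sample size and is reported
#' alongside as `length_member`), width (extent along the second principal
#' axis of the members), volume (mask voxels times voxel volume, um^3) and
#' density (count / volume, exact). Clusters below `minCount` (inclusive
#' cut-off: a cluster with exactly `minCount` members is kept) or below
#' `minLength` are dropped with tallies.
#'
#' When `params@isoThreshold` is `NA` the threshold is auto-selected as
#' `autoFraction` times the median rendered density at the localizations
#' (half-maximum convention); the value used is recorded in the tallies.
#'
#' @param table a denoised [LocalizationTable-class] with z.
#' @param params a [ClusterParams-class].
#' @param autoMethod threshold auto-selection rule, `"member_density"` or
#'   `"background"`.
#' @param autoFraction fraction of the member density used by the
#'   half-maximum rule.
#' @return A [ClusterSet-class].
#' @export
segmentClusters <- function(table, params = clusterParams(),
                            autoMethod = c("member_density", "background"),
                            autoFraction = 0.2) {
  stopifnot(is(table, "LocalizationTable"), is(params, "ClusterParams"))
  autoMethod <- match.arg(autoMethod)
  df <- locs(table)
  n <- nrow(df)
  grid <- list(origin = c(0, 0, 0), voxel = rep(params@voxelSize, 3))
  empty <- function(thr) {
    new("ClusterSet",
        clusters = data.frame(cluster_id = integer(0), count = integer(0),
                              centroid_x = numeric(0), centroid_y = numeric(0),
                              centroid_z = numeric(0), length = numeric(0),
                              length_member = numeric(0),
                              width = numeric(0), volume_um3 = numeric(0),
                              density_per_um3 = numeric(0),
                              truncated = logical(0), bouton_id = integer(0)),
        membership = integer(n), params = params, grid = grid,
        tallies = list(n_input = n, unassigned = n, dropped_clusters = 0L,
                       dropped_locs = 0L, iso_threshold = thr))
  }
  if (!n) return(empty(params@isoThreshold))
  map <- renderDensity3D(table, voxelSize = params@voxelSize,
                         kernelSigma = params@kernelSigma)
  thr <- params@isoThreshold
  if (is.na(thr))
    thr <- .resolve_iso_threshold(map, df, autoMethod, autoFraction)
  above <- map@value >= thr
  if (!any(above)) return(empty(thr))
  vi <- map@i[above]
  vj <- map@j[above]
  vk <- map@k[above]
  comp <- cpp_components_sparse(vi, vj, vk)
  voxvol <- prod(rep(params@voxelSize, 3)) * 1e-9

  qi <- as.integer(floor(df$x / params@voxelSize)) - map@offset[1]
  qj <- as.integer(floor(df$y / params@voxelSize)) - map@offset[2]
  qk <- as.integer(floor(df$z / params@voxelSize)) - map@offset[3]
  memb <- cpp_voxel_lookup(qi, qj, qk, vi, vj, vk, comp)

  comp_sizes <- tabulate(comp)
  vox_groups <- split(seq_along(comp), comp)
  groups <- split(seq_len(n), memb)
  groups[["0"]] <- NULL
  ids <- as.integer(names(groups))
  met <- lapply(seq_along(ids), function(g) {
    idx <- groups[[g]]
    cx <- df$x[idx]; cy <- df$y[idx]; cz <- df$z[idx]
    len <- if (length(idx) > 1) cpp_max_pairwise(cx, cy, cz) else 0
    vsel <- vox_groups[[as.character(ids[g])]]
    mlen <- .mask_feret(cbind(vi[vsel], vj[vsel], vk[vsel]), params@voxelSize)
    wid <- 0
    if (length(idx) > 2) {
      pc <- prcomp(cbind(cx, cy, cz), center = TRUE)
      if (ncol(pc$x) >= 2) wid <- diff(range(pc$x[, 2]))
    }
    vol <- comp_sizes[ids[g]] * voxvol
    c(count = length(idx), cx = mean(cx), cy = mean(cy), cz = mean(cz),
      len = len, mlen = mlen, wid = wid, vol = vol)
  })
  met <- do.call(rbind, met)
  cl <- data.frame(cluster_id = seq_along(ids), count = as.integer(met[, "count"]),
                   centroid_x = met[, "cx"], centroid_y = met[, "cy"],
                   centroid_z = met[, "cz"], length = met[, "mlen"],
                   length_member = met[, "len"],
                   width = met[, "wid"], volume_um3 = met[, "vol"],
                   density_per_um3 = met[, "count"] / met[, "vol"],
                   truncated = FALSE, bouton_id = NA_integer_)
  keep <- cl$count >= params@minCount & cl$length >= params@minLength
  dropped_locs <- sum(cl$count[!keep])
  unassigned <- n - sum(cl$count)
  # relabel kept clusters 1..K in the localization membership vector
  relabel <- integer(length(ids))
  relabel[keep] <- seq_len(sum(keep))
  old_of_loc <- match(memb, ids)
  membership <- integer(n)
  hit <- !is.na(old_of_loc)
  membership[hit] <- relabel[old_of_loc[hit]]
  cl <- cl[keep, , drop = FALSE]
  cl$cluster_id <- seq_len(nrow(cl))
  rownames(cl) <- NULL
  new("ClusterSet", clusters = cl, membership = membership, params = params,
      grid = grid,
      tallies = list(n_input = n, unassigned = as.integer(unassigned),
                     dropped_clusters = as.integer(sum(!keep)),
                     dropped_locs = as.integer(dropped_locs),
                     iso_threshold = thr))
}

#' Flag clusters truncated at the imaged-volume border
#'
#' A cluster is truncated iff any member localization lies within `margin`
#' of a face of the region of interest along a checked axis. The default
#' checks z only: axial scans truncate objects at the top and bottom of the
#' scanned volume.
#'
#' @param clusterSet a [ClusterSet-class].
#' @param table the [LocalizationTable-class] the set was segmented from.
#' @param roi list with numeric(2) elements `x`, `y`, `z`: the volume bounds
#'   (nm).
#' @param margin distance to a face that counts as touching (nm); default one
#'   voxel.
#' @param axes subset of c("x", "y", "z") to check.
#' @return the [ClusterSet-class] with the `truncated` column filled in.
#' @export
flagTruncation <- function(clusterSet, table, roi, margin = NULL,
                           axes = "z") {
  stopifnot(is(clusterSet, "ClusterSet"), is(table, "LocalizationTable"))
  if (!all(axes %in% c("x", "y", "z"))) stop("axes must be in {x, y, z}")
  for (ax in axes) {
    if (!ax %in% names(roi) || length(roi[[ax]]) != 2 || diff(roi[[ax]]) <= 0)
      stop(sprintf("roi must contain well-formed bounds for axis '%s'", ax))
  }
  if (is.null(margin)) margin <- clusterSet@params@voxelSize
  df <- locs(table)
  memb <- membership(clusterSet)
  cl <- clusters(clusterSet)
  near <- rep(FALSE, nrow(df))
  for (ax in axes) {
    v <- df[[ax]]
    near <- near | v <= roi[[ax]][1] + margin | v >= roi[[ax]][2] - margin
  }
  touched <- unique(memb[near & memb > 0])
  cl$truncated <- cl$cluster_id %in% touched
  out <- clusterSet
  out@clusters <- cl
  out
}

#' Deterministic subsampling of a localization table
#'
#' Reproduces the exact omission schemes used to create artificially reduced
#' datasets: 90/80/66/50 % keep all but every 10th/5th/3rd/2nd localization;
#' 33/20/10 % keep only every 3rd/5th/10th localization (1-based positions,
#' order preserved).
#'
#' @param table a [LocalizationTable-class] (ordered).
#' @param fraction one of 1, 0.9, 0.8, 0.66, 0.5, 0.33, 0.2, 0.1.
#' @return the subsampled [LocalizationTable-class]; metadata records the
#'   fraction.
#' @export
subsampleLocalizations <- function(table, fraction) {
  stopifnot(is(table, "LocalizationTable"))
  n <- nLocs(table)
  i <- seq_len(n)
  keep <- switch(as.character(fraction),
                 "1" = rep(TRUE, n),
                 "0.9" = i %% 10 != 0,
                 "0.8" = i %% 5 != 0,
                 "0.66" = i %% 3 != 0,
                 "0.5" = i %% 2 != 0,
                 "0.33" = i %% 3 == 1,
                 "0.2" = i %% 5 == 1,
                 "0.1" = i %% 10 == 1,
                 stop(sprintf("unsupported fraction: %s", fraction)))
  out <- table
  out@locs <- locs(table)[keep, , drop = FALSE]
  rownames(out@locs) <- NULL
  meta <- locMetadata(table)
  meta$subsample <- list(fraction = fraction, kept = sum(keep), from = n)
  out@metadata <- meta
  out
}

#' Localization-reduction robustness experiment
#'
#' For each fraction f, deterministically subsamples the table, segments with
#' the isosurface threshold scaled proportionally to f (the threshold for the
#' 80 % dataset is 80 % of the full-data threshold) and a 160 nm minimum
#' cluster length, and collects the cluster length distributions. An omnibus
#' Kruskal-Wallis test compares lengths across fractions.
#'
#' @param table a denoised [LocalizationTable-class].
#' @param params a [ClusterParams-class]; if `isoThreshold` is NA the
#'   full-data auto threshold is resolved once and then scaled.
#' @param fractions subset of c(1, 0.9, 0.8, 0.66, 0.5, 0.33, 0.2, 0.1).
#' @param minLength length floor applied to every fraction (nm).
#' @return list with per-fraction `lengths`, `medians`, `n_clusters`,
#'   `thresholds`, and `kruskal` (statistic, p).
#' @export
reductionExperiment <- function(table, params = clusterParams(),
                                fractions = c(1, 0.9, 0.8, 0.66, 0.5, 0.33,
                                              0.2, 0.1),
                                minLength = 160) {
  stopifnot(is(table, "LocalizationTable"), is(params, "ClusterParams"))
  base <- params
  base@minLength <- max(params@minLength, minLength)
  thr0 <- params@isoThreshold
  if (is.na(thr0)) {
    full <- segmentClusters(table, base)
    thr0 <- tallies(full)$iso_threshold
  }
  lengths <- list()
  thresholds <- numeric(0)
  for (f in fractions) {
    p <- base
    p@isoThreshold <- thr0 * f
    cs <- segmentClusters(subsampleLocalizations(table, f), p)
    lengths[[as.character(f)]] <- clusters(cs)$length
    thresholds[as.character(f)] <- thr0 * f
  }
  kw <- rankTests(lengths, kind = "kruskal_wallis")
  list(lengths = lengths,
       medians = vapply(lengths, median, numeric(1)),
       n_clusters = vapply(lengths, length, integer(1)),
       thresholds = thresholds,
       kruskal = kw)
}

#' Depth homogeneity profile
#'
#' Quality control for aberration-free volumetric imaging: per-z-bin medians
#' of localization intensity, intensity/background ratio, and counts should
#' be flat through the imaging volume.
#'
#' @param table a [LocalizationTable-class] with z, intensity and background.
#' @param nBins number of equal-width z bins.
#' @return data.frame with bin centers, median intensity, median
#'   intensity/background ratio and counts.
#' @export
depthProfile <- function(table, nBins = 10L) {
  stopifnot(is(table, "LocalizationTable"))
  df <- locs(table)
  need <- c("z", "intensity", "background")
  if (!all(need %in% names(df)))
    stop("depthProfile needs z, intensity and background columns")
  rng <- range(df$z)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = nBins + 1)
  bin <- pmin(findInterval(df$z, edges, rightmost.closed = TRUE), nBins)
  centers <- (head(edges, -1) + edges[-1]) / 2
  out <- data.frame(bin_center_nm = centers,
                    median_intensity = NA_real_,
                    median_ratio = NA_real_,
                    count = 0L)
  for (b in seq_len(nBins)) {
    sel <- bin == b
    out$count[b] <- sum(sel)
    if (any(sel)) {
      out$median_intensity[b] <- median(df$intensity[sel])
      out$median_ratio[b] <- median(df$intensity[sel] / df$background[sel])
    }
  }
  out
}
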