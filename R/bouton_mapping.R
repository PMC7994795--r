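# Reconstruction of membrane-labelled bouton surfaces from the second
# staining round, and assignment of protein clusters to boutons by the
# centroid-inside rule.

#' Reconstruct bouton surfaces from a membrane-label point cloud
#'
#' Density-isosurface components of the membrane channel above `minVolume`
#' become candidate boutons. Because the membrane label is a hollow shell,
#' each component mask is morphologically closed (box element, radius
#' `closingRadius` voxels) and its interior cavities filled, so "inside the
#' bouton signal" is well defined for cluster assignment. If seed points are
#' given (the user-in-the-loop surrogate for manual bouton/axon separation),
#' all candidate voxels are re-assigned to the nearest seed, splitting
#' connected structures.
#'
#' @param membraneTable [LocalizationTable-class] of the membrane channel
#'   (z present, ideally denoised).
#' @param params a [ClusterParams-class] (voxel size, kernel, threshold).
#' @param minVolume minimum filled volume per bouton (um^3).
#' @param seeds optional data.frame (bouton_id, x, y, z) in nm.
#' @param closingRadius box closing radius in voxels.
#' @param autoFraction threshold auto-selection fraction (see
#'   [segmentClusters()]).
#' @return A [BoutonSet-class].
#' @export
reconstructBoutons <- function(membraneTable, params = clusterParams(),
                               minVolume = 1, seeds = NULL,
                               closingRadius = 3L, autoFraction = 0.15) {
  stopifnot(is(membraneTable, "LocalizationTable"), is(params, "ClusterParams"))
  df <- locs(membraneTable)
  grid <- list(origin = c(0, 0, 0), voxel = rep(params@voxelSize, 3))
  empty <- new("BoutonSet",
               boutons = data.frame(bouton_id = integer(0),
                                    volume_um3 = numeric(0),
                                    centroid_x = numeric(0),
                                    centroid_y = numeric(0),
                                    centroid_z = numeric(0),
                                    n_clusters = integer(0)),
               masks = list(), grid = grid)
  if (!nrow(df)) return(empty)
  map <- renderDensity3D(membraneTable, voxelSize = params@voxelSize,
                         kernelSigma = params@kernelSigma)
  thr <- params@isoThreshold
  if (is.na(thr))
    thr <- .resolve_iso_threshold(map, df, "member_density", autoFraction)
  above <- map@value >= thr
  if (!any(above)) return(empty)
  vi <- map@i[above]
  vj <- map@j[above]
  vk <- map@k[above]
  comp <- cpp_components_sparse(vi, vj, vk)
  voxvol <- prod(rep(params@voxelSize, 3)) * 1e-9

  # Close + fill each component on a padded dense sub-array, then erode the
  # filled mask back to the radial midline of the membrane shell: the
  # isosurface of a labelled shell sits at its outer halo, so the filled
  # volume is shrunk by the (self-estimated) outer half-thickness so that
  # the reported volume is the membrane-enclosed volume.
  pad <- closingRadius + 1L
  fill_component <- function(sel) {
    ci <- vi[sel]; cj <- vj[sel]; ck <- vk[sel]
    lo <- c(min(ci), min(cj), min(ck)) - pad
    dm <- c(max(ci), max(cj), max(ck)) + pad - lo + 1L
    m <- array(FALSE, dim = dm)
    m[cbind(ci - lo[1] + 1L, cj - lo[2] + 1L, ck - lo[3] + 1L)] <- TRUE
    m[] <- cpp_close_box(as.logical(m), dim(m), closingRadius)
    m[] <- cpp_fill_holes(as.logical(m), dim(m))
    # radial midline correction (in voxels): mean shell radius vs filled radius
    cen <- c(mean(ci), mean(cj), mean(ck)) - lo + 1
    rShell <- mean(sqrt((ci - lo[1] + 1 - cen[1])^2 +
                        (cj - lo[2] + 1 - cen[2])^2 +
                        (ck - lo[3] + 1 - cen[3])^2))
    rFill <- (3 * sum(m) / (4 * pi))^(1 / 3)
    k <- max(0L, as.integer(round(rFill - rShell)))
    if (k > 0) m[] <- cpp_erode_box(as.logical(m), dim(m), k)
    w <- which(m, arr.ind = TRUE)
    # back to global voxel indices (shared grid anchored at the origin)
    cbind(w[, 1] + lo[1] - 1L + map@offset[1],
          w[, 2] + lo[2] - 1L + map@offset[2],
          w[, 3] + lo[3] - 1L + map@offset[3])
  }
  masks <- lapply(seq_len(max(comp)), function(g) fill_component(comp == g))
  vols <- vapply(masks, nrow, integer(1)) * voxvol
  masks <- masks[vols >= minVolume]
  if (!length(masks)) return(empty)

  if (!is.null(seeds)) {
    stopifnot(all(c("bouton_id", "x", "y", "z") %in% names(seeds)))
    allvox <- do.call(rbind, masks)
    allvox <- allvox[!duplicated(allvox), , drop = FALSE]
    centers <- sweep(allvox + 0.5, 2, grid$voxel, "*")
    sd2 <- vapply(seq_len(nrow(seeds)), function(s) {
      rowSums(sweep(centers, 2, c(seeds$x[s], seeds$y[s], seeds$z[s]))^2)
    }, numeric(nrow(allvox)))
    nearest <- max.col(-sd2)
    masks <- lapply(seq_len(nrow(seeds)),
                    function(s) allvox[nearest == s, , drop = FALSE])
    ids <- seeds$bouton_id
    keep <- vapply(masks, nrow, integer(1)) > 0
    masks <- masks[keep]
    ids <- ids[keep]
  } else {
    ids <- seq_along(masks)
  }
  cent <- t(vapply(masks, function(m) {
    colMeans(sweep(m + 0.5, 2, grid$voxel, "*"))
  }, numeric(3)))
  bt <- data.frame(bouton_id = as.integer(ids),
                   volume_um3 = vapply(masks, nrow, integer(1)) * voxvol,
                   centroid_x = cent[, 1], centroid_y = cent[, 2],
                   centroid_z = cent[, 3], n_clusters = 0L)
  names(masks) <- as.character(bt$bouton_id)
  new("BoutonSet", boutons = bt, masks = masks, grid = grid)
}

#' Assign clusters to boutons by the centroid-inside rule
#'
#' A cluster belongs to the bouton whose filled mask contains the voxel of
#' its center of mass (boundary voxels count as inside); clusters whose
#' centroid falls in no mask stay unassigned. Cluster and bouton grids must
#' share the voxel size and origin.
#'
#' @param clusterSet a [ClusterSet-class].
#' @param boutonSet a [BoutonSet-class].
#' @return list with the updated `clusterSet` (bouton_id filled in) and
#'   `boutonSet` (n_clusters updated).
#' @export
assignClusters <- function(clusterSet, boutonSet) {
  stopifnot(is(clusterSet, "ClusterSet"), is(boutonSet, "BoutonSet"))
  if (!isTRUE(all.equal(clusterSet@grid$voxel, boutonSet@grid$voxel)))
    stop("cluster and bouton voxel grids differ")
  cl <- clusters(clusterSet)
  bt <- boutons(boutonSet)
  if (!nrow(cl) || !nrow(bt)) {
    bt$n_clusters <- 0L
    out <- boutonSet
    out@boutons <- bt
    return(list(clusterSet = clusterSet, boutonSet = out))
  }
  vox <- boutonSet@grid$voxel
  allvox <- do.call(rbind, boutonSet@masks)
  lab <- rep(bt$bouton_id, vapply(boutonSet@masks, nrow, integer(1)))
  qi <- as.integer(floor(cl$centroid_x / vox[1]))
  qj <- as.integer(floor(cl$centroid_y / vox[2]))
  qk <- as.integer(floor(cl$centroid_z / vox[3]))
  # shift everything to non-negative indices for the hash lookup
  sh <- c(min(qi, allvox[, 1]), min(qj, allvox[, 2]), min(qk, allvox[, 3]))
  hit <- cpp_voxel_lookup(qi - sh[1], qj - sh[2], qk - sh[3],
                          allvox[, 1] - sh[1], allvox[, 2] - sh[2],
                          allvox[, 3] - sh[3], as.integer(lab))
  cl$bouton_id <- ifelse(hit > 0, hit, NA_integer_)
  tallied <- table(factor(cl$bouton_id, levels = bt$bouton_id))
  bt$n_clusters <- as.integer(tallied)
  csOut <- clusterSet
  csOut@clusters <- cl
  bsOut <- boutonSet
  bsOut@boutons <- bt
  list(clusterSet = csOut, boutonSet = bsOut)
}

#' Per-bouton summary and volume-count correlation
#'
#' One row per bouton with its filled volume, assigned cluster count and
#' median cluster metrics, plus the Spearman rank correlation of bouton
#' volume against cluster count across boutons (the bouton-size scaling of
#' active-zone number).
#'
#' @param clusterSet a [ClusterSet-class] after [assignClusters()].
#' @param boutonSet the matching [BoutonSet-class].
#' @return data.frame with one row per bouton; attribute `spearman` holds
#'   r and the two-tailed p (omitted with a notice when < 3 boutons).
#' @export
perBoutonSummary <- function(clusterSet, boutonSet) {
  stopifnot(is(clusterSet, "ClusterSet"), is(boutonSet, "BoutonSet"))
  cl <- clusters(clusterSet)
  bt <- boutons(boutonSet)
  out <- bt[, c("bouton_id", "volume_um3", "n_clusters")]
  out$median_count <- NA_real_
  out$median_length <- NA_real_
  out$median_cluster_volume <- NA_real_
  for (r in seq_len(nrow(out))) {
    sel <- !is.na(cl$bouton_id) & cl$bouton_id == out$bouton_id[r]
    if (any(sel)) {
      out$median_count[r] <- median(cl$count[sel])
      out$median_length[r] <- median(cl$length[sel])
      out$median_cluster_volume[r] <- median(cl$volume_um3[sel])
    }
  }
  if (nrow(out) >= 3 && sd(out$volume_um3) > 0 && sd(out$n_clusters) > 0) {
    attr(out, "spearman") <- spearmanCorrelation(out$volume_um3,
                                                 out$n_clusters)
  } else {
    attr(out, "spearman_notice") <-
      "correlation omitted: fewer than 3 boutons or constant values"
  }
  out
}
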