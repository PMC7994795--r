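# Fiducial-based drift estimation and correction, and alignment of
# sequential staining rounds. Drift is interpolated linearly in acquisition
# time between the pre and post bead epochs: beads are recorded only at the
# start and end of a measurement, so no higher-order model is identifiable.

#' Summarize bead localizations into fiducials
#'
#' Groups bead localizations by single-linkage clustering at the merge
#' radius; each group is one physical bead whose position is the
#' coordinate-wise mean. Beads supported by fewer than `minLocs`
#' localizations are discarded.
#'
#' @param beadTable a [LocalizationTable-class] of bead localizations (z
#'   column used when present, otherwise 0: coverslip plane).
#' @param mergeRadius single-linkage merge radius in nm.
#' @param minLocs minimum localizations per bead.
#' @param epoch label, "pre" or "post".
#' @return A [FiducialSet-class].
#' @export
summarizeBeads <- function(beadTable, mergeRadius = 500, minLocs = 10L,
                           epoch = "pre") {
  stopifnot(is(beadTable, "LocalizationTable"))
  df <- locs(beadTable)
  if (!nrow(df)) stop("fiducial error: empty bead table")
  z <- if ("z" %in% names(df)) df$z else rep(0, nrow(df))
  coords <- cbind(df$x, df$y, z)
  if (nrow(coords) > 1) {
    hc <- hclust(dist(coords), method = "single")
    grp <- cutree(hc, h = mergeRadius)
  } else grp <- 1L
  sizes <- table(grp)
  keep <- as.integer(names(sizes)[sizes >= minLocs])
  if (!length(keep))
    stop("fiducial error: no bead has enough localizations")
  pos <- t(vapply(keep, function(g) colMeans(coords[grp == g, , drop = FALSE]),
                  numeric(3)))
  spr <- t(vapply(keep, function(g) {
    m <- coords[grp == g, , drop = FALSE]
    if (nrow(m) > 1) apply(m, 2, sd) else c(0, 0, 0)
  }, numeric(3)))
  new("FiducialSet", positions = pos, spreads = spr,
      nLocs = as.integer(sizes[as.character(keep)]), epoch = epoch)
}

# mutual nearest-neighbour bead matching within max_dist; returns index pairs
.match_beads <- function(A, B, maxDist) {
  if (!nrow(A) || !nrow(B)) return(cbind(integer(0), integer(0)))
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d2 <- pmax(d2, 0)
  nnA <- apply(d2, 1, which.min)
  nnB <- apply(d2, 2, which.min)
  ia <- which(nnB[nnA] == seq_len(nrow(A)))
  pairs <- cbind(ia, nnA[ia])
  ok <- sqrt(d2[pairs]) <= maxDist
  pairs[ok, , drop = FALSE]
}

#' Estimate the drift transform between two bead epochs
#'
#' Beads are matched by mutual nearest neighbour within `maxMatchDist`. The
#' translation is the least-squares optimum over matched pairs; with
#' `allowRotation` the in-plane rotation (and optionally a uniform scale) is
#' solved by orthogonal Procrustes about the pre-epoch centroid.
#'
#' @param pre,post [FiducialSet-class] of the bracketing epochs.
#' @param maxMatchDist mutual-nearest-neighbour acceptance distance (nm).
#' @param allowRotation solve an in-plane rotation as well.
#' @param allowScale solve a uniform in-plane scale (for round alignment).
#' @return A [RigidTransform-class] mapping pre coordinates to post
#'   coordinates, with rms residual and pair count.
#' @export
estimateTransform <- function(pre, post, maxMatchDist = 500,
                              allowRotation = FALSE, allowScale = FALSE) {
  stopifnot(is(pre, "FiducialSet"), is(post, "FiducialSet"))
  pairs <- .match_beads(pre@positions, post@positions, maxMatchDist)
  if (nrow(pairs) < 3)
    stop(sprintf("insufficient fiducials: %d matched pairs (need >= 3)",
                 nrow(pairs)))
  A <- pre@positions[pairs[, 1], , drop = FALSE]
  B <- post@positions[pairs[, 2], , drop = FALSE]
  theta <- 0
  s <- 1
  center <- c(0, 0)
  if (allowRotation) {
    center <- colMeans(A[, 1:2, drop = FALSE])
    Ac <- sweep(A[, 1:2, drop = FALSE], 2, center)
    Bc <- sweep(B[, 1:2, drop = FALSE], 2, colMeans(B[, 1:2, drop = FALSE]))
    H <- t(Ac) %*% Bc
    sv <- svd(H)
    R <- sv$v %*% diag(c(1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
    theta <- atan2(R[2, 1], R[1, 1])
    if (allowScale) s <- sum(sv$d) / sum(Ac^2)
  }
  # translation: least squares given rotation/scale about `center`
  Arot <- A
  if (theta != 0 || s != 1) {
    R2 <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    Arot[, 1:2] <- sweep(s * (sweep(A[, 1:2, drop = FALSE], 2, center) %*%
                                t(R2)), 2, center, "+")
  }
  tr <- colMeans(B - Arot)
  resid <- sweep(B - Arot, 2, tr)
  tf <- rigidTransform(translation = tr, rotation = theta, center = center,
                       scale = s, rmsResidual = sqrt(mean(rowSums(resid^2))),
                       nPairs = nrow(pairs))
  tf
}

# affine (3x3 linear + offset) form of a transform; rotation/scale act in xy
.tf_affine <- function(tf, fraction = 1) {
  th <- tf@rotation * fraction
  sc <- tf@scale^fraction
  R2 <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  A <- diag(3)
  A[1:2, 1:2] <- R2
  b <- c(tf@center - R2 %*% tf@center, 0) + tf@translation * fraction
  list(A = A, b = b)
}

#' Apply a transform to coordinates
#'
#' `fraction` scales the transform: the rotation angle and translation are
#' multiplied by it and the scale exponentiated, so `fraction = -t` applies
#' the partial inverse used by time-resolved drift correction.
#'
#' @param coords n x 3 matrix of positions (nm).
#' @param tf a [RigidTransform-class].
#' @param fraction scalar or length-n vector of transform fractions.
#' @return n x 3 matrix of transformed positions.
#' @export
applyTransform <- function(coords, tf, fraction = 1) {
  stopifnot(is(tf, "RigidTransform"))
  coords <- as.matrix(coords)
  if (length(fraction) == 1) {
    af <- .tf_affine(tf, fraction)
    return(sweep(coords %*% t(af$A), 2, af$b, "+"))
  }
  stopifnot(length(fraction) == nrow(coords))
  out <- coords
  if (tf@rotation == 0 && tf@scale == 1) {
    out <- coords + outer(fraction, tf@translation)
  } else {
    for (f in unique(fraction)) {
      sel <- fraction == f
      af <- .tf_affine(tf, f)
      out[sel, ] <- sweep(coords[sel, , drop = FALSE] %*% t(af$A), 2, af$b, "+")
    }
  }
  out
}

#' Invert a transform
#' @param tf a [RigidTransform-class].
#' @return the inverse [RigidTransform-class].
#' @export
invertTransform <- function(tf) {
  stopifnot(is(tf, "RigidTransform"))
  # forward: y = s R(x - c) + c + t; inverse about the same center has
  # angle -theta, scale 1/s and xy translation -(1/s) R(-theta) t_xy
  th <- -tf@rotation
  s <- 1 / tf@scale
  R2 <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rigidTransform(translation = c(-as.numeric(R2 %*% tf@translation[1:2]),
                                 -tf@translation[3]),
                 rotation = th, center = tf@center, scale = s,
                 rmsResidual = tf@rmsResidual, nPairs = tf@nPairs)
}

#' Compose two transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#' The composite is expressed about `first`'s rotation center.
#'
#' @param first,second [RigidTransform-class] objects.
#' @return A [RigidTransform-class].
#' @export
composeTransforms <- function(second, first) {
  a1 <- .tf_affine(first)
  a2 <- .tf_affine(second)
  A <- a2$A %*% a1$A
  b <- as.numeric(a2$A %*% a1$b + a2$b)
  th <- atan2(A[2, 1], A[1, 1])
  s <- sqrt(A[1, 1]^2 + A[2, 1]^2)
  cen <- first@center
  R2 <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tr2 <- b[1:2] - as.numeric(cen - R2 %*% cen)
  rigidTransform(translation = c(tr2, b[3]), rotation = th, center = cen,
                 scale = s, rmsResidual = NA_real_,
                 nPairs = min(first@nPairs, second@nPairs))
}

#' Correct drift across a scanned acquisition
#'
#' Each record is shifted by the inverse transform scaled linearly with its
#' global time fraction t in \[0, 1\] across the measurement (t computed from
#' movie_id and frame), matching the linear interpolation between the pre and
#' post bead epochs. Record order and count are preserved.
#'
#' @param table a [LocalizationTable-class] with `frame` and `movie_id`.
#' @param transform [RigidTransform-class] from the bracketing bead epochs
#'   (pre -> post drift).
#' @param spec the [ScanSpec-class] of the acquisition.
#' @return the drift-corrected [LocalizationTable-class].
#' @export
correctDrift <- function(table, transform, spec) {
  stopifnot(is(table, "LocalizationTable"), is(transform, "RigidTransform"),
            is(spec, "ScanSpec"))
  df <- locs(table)
  if (!nrow(df)) return(table)
  if (!all(c("frame", "movie_id") %in% names(df)))
    stop("drift correction needs frame and movie_id columns")
  tglob <- (df$movie_id * spec@framesPerMovie + df$frame) /
    (spec@nScans * spec@framesPerMovie - 1)
  z <- if ("z" %in% names(df)) df$z else rep(0, nrow(df))
  corrected <- applyTransform(cbind(df$x, df$y, z), transform,
                              fraction = -tglob)
  df$x <- corrected[, 1]
  df$y <- corrected[, 2]
  if ("z" %in% names(df)) df$z <- corrected[, 3]
  out <- table
  out@locs <- df
  meta <- locMetadata(table)
  meta$drift_correction <- list(translation = transform@translation,
                                rotation = transform@rotation,
                                rms_residual = transform@rmsResidual)
  out@metadata <- meta
  out
}

#' Align a second staining round into the reference frame
#'
#' Estimates the transform mapping the second round's fiducials onto the
#' reference fiducials (same physical coverslip beads) and applies it in full
#' to every record of the second round.
#'
#' @param round2 [LocalizationTable-class] of the second round.
#' @param pre2 [FiducialSet-class] recorded with the second round.
#' @param reference [FiducialSet-class] of the reference (first) round.
#' @param allowRotation solve an in-plane rotation.
#' @param allowScale solve a uniform in-plane scale.
#' @param maxMatchDist bead matching distance (nm).
#' @return the aligned [LocalizationTable-class]; metadata records the
#'   transform and its residual.
#' @export
alignRounds <- function(round2, pre2, reference, allowRotation = FALSE,
                        allowScale = FALSE, maxMatchDist = 500) {
  tf <- estimateTransform(pre2, reference, maxMatchDist = maxMatchDist,
                          allowRotation = allowRotation,
                          allowScale = allowScale)
  df <- locs(round2)
  z <- if ("z" %in% names(df)) df$z else rep(0, nrow(df))
  moved <- applyTransform(cbind(df$x, df$y, z), tf)
  df$x <- moved[, 1]
  df$y <- moved[, 2]
  if ("z" %in% names(df)) df$z <- moved[, 3]
  out <- round2
  out@locs <- df
  meta <- locMetadata(round2)
  meta$round_alignment <- list(translation = tf@translation,
                               rotation = tf@rotation, scale = tf@scale,
                               rms_residual = tf@rmsResidual,
                               n_pairs = tf@nPairs)
  out@metadata <- meta
  out
}
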