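# Ground-truth simulator for volumetric scanning acquisitions: ellipsoidal
# clusters with lognormal lengths and negative-binomial blinking counts,
# uniform stray background, coverslip fiducials, astigmatic defocus widths,
# triangular piezo trajectories, linear drift and per-scan photobleaching.
# Blinking is modelled as i.i.d. detections per in-focus pass; it exercises
# counting, it is not photophysics.

# run expr with a fixed seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

#' Astigmatic defocus width model
#'
#' The standard two-branch width model of a cylindrical-lens PSF:
#' \eqn{w_{x,y}(\delta) = w_0 \sqrt{1 + ((\delta \mp c)/d)^2}} with focal
#' offsets of the two axes at +c and -c. Used only by the simulator; the
#' spline calibration never assumes this form.
#'
#' @param defocus axial offset(s) from the focal plane (nm).
#' @param w0 waist width (nm).
#' @param c astigmatic focal offset (nm).
#' @param d depth scale (nm).
#' @return data.frame with `wx` and `wy` (nm).
#' @export
defocusWidths <- function(defocus, w0 = 150, c = 400, d = 500) {
  data.frame(wx = w0 * sqrt(1 + ((defocus - c) / d)^2),
             wy = w0 * sqrt(1 + ((defocus + c) / d)^2))
}

#' Simulate an astigmatic calibration bead stack
#'
#' Beads on a coverslip are swept at constant speed through the focal plane;
#' each frame maps to one stage z. Widths follow [defocusWidths()] plus
#' Gaussian width noise. The returned table carries the known `stage_z`
#' column consumed by [fitCalibration()].
#'
#' @param sweep numeric(2) stage range (nm).
#' @param nFrames frames in the sweep.
#' @param nBeads beads on the coverslip.
#' @param widthNoise Gaussian sd added to each width (nm).
#' @param model list(w0, c, d) of the defocus model (nm).
#' @param seed random seed.
#' @return A [LocalizationTable-class] with width and `stage_z` columns.
#' @export
simulateCalibrationStack <- function(sweep = c(-800, 800), nFrames = 200L,
                                     nBeads = 10L, widthNoise = 2,
                                     model = list(w0 = 150, c = 400, d = 500),
                                     seed = 1L) {
  stopifnot(diff(sweep) > 0)
  .with_seed(seed, {
    bx <- runif(nBeads, 1000, 24000)
    by <- runif(nBeads, 1000, 24000)
    frame <- rep(seq_len(nFrames) - 1L, times = nBeads)
    stage <- sweep[1] + diff(sweep) * frame / (nFrames - 1)
    w <- defocusWidths(stage, model$w0, model$c, model$d)
    df <- data.frame(x = rep(bx, each = nFrames), y = rep(by, each = nFrames),
                     frame = frame,
                     intensity = rlnorm(nFrames * nBeads, log(30000), 0.2),
                     width_x = w$wx + rnorm(nFrames * nBeads, 0, widthNoise),
                     width_y = w$wy + rnorm(nFrames * nBeads, 0, widthNoise),
                     channel = "bead", stage_z = stage)
    localizationTable(df, fieldOfView = c(25000, 25000),
                      metadata = list(kind = "calibration_stack",
                                      sweep = sweep, model = model,
                                      width_noise = widthNoise, seed = seed))
  })
}

# orthonormal basis whose first column is u
.basis_from_axis <- function(u) {
  u <- u / sqrt(sum(u^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u
  v <- v / sqrt(sum(v^2))
  cbind(u, v, c(u[2] * v[3] - u[3] * v[2],
                u[3] * v[1] - u[1] * v[3],
                u[1] * v[2] - u[2] * v[1]))
}

# n uniform points in the solid ellipsoid with semi-axes (a, b, b) along
# basis B, centered at cen
.runif_ellipsoid <- function(n, cen, a, b, B) {
  if (!n) return(matrix(numeric(0), 0, 3))
  g <- matrix(rnorm(3 * n), n, 3)
  g <- g / sqrt(rowSums(g^2))
  r <- runif(n)^(1 / 3)
  p <- g * r
  p <- p %*% diag(c(a, b, b))
  sweep(p %*% t(B), 2, cen, "+")
}

#' Simulate a volumetric scanning acquisition
#'
#' Places prolate ellipsoidal clusters in the scanned volume, emits blinking
#' localizations per scan while the emitter is within the astigmatic capture
#' range of the travelling focal plane, applies localization precision,
#' linear drift and per-scan bleaching, and emits matching pre/post bead
#' tables. Emitter positions outside the scanned z window are not emitted
#' (the mechanical-truncation analogue used by the truncation analysis).
#'
#' @param spec a [SceneSpec-class].
#' @return list with `movies` (one [LocalizationTable-class] per scan),
#'   `beadsPre`, `beadsPost`, `scan` (the [ScanSpec-class]) and `truth`
#'   (a [SceneTruth-class]).
#' @export
simulateScene <- function(spec = sceneSpec()) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  .with_seed(spec@seed, {
    scan <- scanSpec(nScans = spec@nScans,
                     framesPerMovie = spec@framesPerMovie,
                     zTravel = spec@zExtent, zStart = 0)
    Fm <- spec@framesPerMovie
    S <- spec@nScans
    zE <- spec@zExtent
    nC <- spec@nClusters

    # --- ground-truth cluster geometry -----------------------------------
    L <- rlnorm(nC, log(spec@clusterLengthMedian), spec@clusterLengthSigma)
    a <- L / 2
    b <- a * spec@clusterAspect
    axis <- matrix(rnorm(3 * max(nC, 1)), ncol = 3)
    axis <- axis / sqrt(rowSums(axis^2))
    hz <- sqrt(a^2 * axis[, 3]^2 + b^2 * (1 - axis[, 3]^2)) # z half-extent
    nTrunc <- round(spec@truncationFraction * nC)
    # which clusters straddle is size-biased, as under uniform placement:
    # the chance of crossing a section border scales with the z extent
    truncated <- rep(FALSE, nC)
    if (nTrunc > 0)
      truncated[sample.int(nC, nTrunc, prob = hz)] <- TRUE
    cz <- numeric(nC)
    if (nTrunc > 0) {
      border <- rep(c(0, zE), length.out = nTrunc)
      inward <- ifelse(border == 0, 1, -1)
      # center close enough to the border that the ellipsoid straddles it
      cz[truncated] <- border + inward * runif(nTrunc, 0.1, 0.9) * hz[truncated]
    }
    free <- !truncated
    cz[free] <- runif(sum(free), hz[free], pmax(zE - hz[free], hz[free]))
    cx <- runif(nC, a, pmax(spec@fieldOfView[1] - a, a))
    cy <- runif(nC, a, pmax(spec@fieldOfView[2] - a, a))

    nEv <- if (nC) {
      mu <- spec@locsPerCluster
      v <- spec@locsPerClusterSD^2
      if (v > mu) rnbinom(nC, mu = mu, size = mu^2 / (v - mu)) else rpois(nC, mu)
    } else integer(0)

    pts <- vector("list", nC)
    feret <- numeric(nC)
    nReal <- integer(nC)
    for (i in seq_len(nC)) {
      p <- .runif_ellipsoid(nEv[i], c(cx[i], cy[i], cz[i]), a[i], b[i],
                            .basis_from_axis(axis[i, ]))
      p <- p[p[, 3] >= 0 & p[, 3] <= zE, , drop = FALSE] # truncation
      pts[[i]] <- p
      nReal[i] <- nrow(p)
      feret[i] <- if (nrow(p) > 1)
        cpp_max_pairwise(p[, 1], p[, 2], p[, 3]) else 0
    }

    # --- background strays ------------------------------------------------
    volUm3 <- prod(spec@fieldOfView) * zE * 1e-9
    nBg <- rpois(1, spec@backgroundDensity * volUm3)
    bg <- cbind(runif(nBg, 0, spec@fieldOfView[1]),
                runif(nBg, 0, spec@fieldOfView[2]),
                runif(nBg, 0, zE))

    allPts <- rbind(do.call(rbind, pts), bg)
    labels <- c(rep(seq_len(nC), nReal), rep(0L, nBg))
    nTot <- nrow(allPts)

    # --- emission times: scan (bleaching-weighted), frame in capture window
    wScan <- (1 - spec@bleachPerScan)^(seq_len(S) - 1)
    sIdx <- sample.int(S, nTot, replace = TRUE, prob = wScan) - 1L
    zT <- allPts[, 3]
    fLo <- (zT - spec@captureHalfwidth) * (Fm - 1) / zE
    fHi <- (zT + spec@captureHalfwidth) * (Fm - 1) / zE
    fLo <- pmax(ceiling(fLo), 0)
    fHi <- pmin(floor(fHi), Fm - 1)
    frame <- fLo + floor(runif(nTot) * (fHi - fLo + 1))
    desc <- scan@alternateDirection & (sIdx %% 2 == 1)
    frame[desc] <- (Fm - 1) - frame[desc] # mirrored trajectory, same stage z
    tGlob <- (sIdx * Fm + frame) / (S * Fm - 1)

    # --- observation model ------------------------------------------------
    stage <- stageZ(frame, sIdx, scan)
    defocus <- (zT + spec@drift[3] * tGlob) - stage +
      rnorm(nTot, 0, spec@precision[2])
    w <- defocusWidths(defocus)
    obs <- data.frame(
      x = allPts[, 1] + spec@drift[1] * tGlob + rnorm(nTot, 0, spec@precision[1]),
      y = allPts[, 2] + spec@drift[2] * tGlob + rnorm(nTot, 0, spec@precision[1]),
      frame = frame,
      movie_id = sIdx,
      # emitted tables mimic raw-fit output already filtered at the 10000 ADU
      # intensity threshold, with intensity/background ratios around 11
      intensity = 10000 + rlnorm(nTot, log(3000), 0.7),
      background = rlnorm(nTot, log(1180), 0.25),
      width_x = w$wx, width_y = w$wy,
      channel = rep("bassoon", nTot))
    # clip rare jittered positions to the field of view
    obs$x <- pmin(pmax(obs$x, 0), spec@fieldOfView[1])
    obs$y <- pmin(pmax(obs$y, 0), spec@fieldOfView[2])

    movies <- vector("list", S)
    movieLabels <- vector("list", S)
    movieEvents <- vector("list", S)
    for (s in seq_len(S)) {
      sel <- which(obs$movie_id == s - 1L)
      sel <- sel[order(obs$frame[sel])]
      movieEvents[[s]] <- sel
      movies[[s]] <- localizationTable(
        obs[sel, setdiff(names(obs), "movie_id"), drop = FALSE],
        fieldOfView = spec@fieldOfView,
        metadata = list(kind = "simulated_movie", scan_index = s - 1L,
                        seed = spec@seed))
      movies[[s]]@locs <- `rownames<-`(movies[[s]]@locs, NULL)
      movieLabels[[s]] <- labels[sel]
    }

    # --- fiducials --------------------------------------------------------
    beads <- cbind(runif(spec@nBeads, 500, spec@fieldOfView[1] - 500),
                   runif(spec@nBeads, 500, spec@fieldOfView[2] - 500),
                   rep(0, spec@nBeads))
    beadTable <- function(shift, epoch) {
      nb <- spec@nBeads * spec@beadLocs
      df <- data.frame(
        x = rep(beads[, 1] + shift[1], each = spec@beadLocs) +
          rnorm(nb, 0, spec@beadSpread),
        y = rep(beads[, 2] + shift[2], each = spec@beadLocs) +
          rnorm(nb, 0, spec@beadSpread),
        z = rep(beads[, 3] + shift[3], each = spec@beadLocs) +
          rnorm(nb, 0, spec@beadSpread),
        frame = rep(seq_len(spec@beadLocs) - 1L, times = spec@nBeads),
        intensity = rlnorm(nb, log(40000), 0.2),
        channel = "bead")
      localizationTable(df, fieldOfView = spec@fieldOfView,
                        metadata = list(kind = "bead_epoch", epoch = epoch))
    }
    beadsPre <- beadTable(c(0, 0, 0), "pre")
    beadsPost <- beadTable(spec@drift, "post")

    axisC <- axis[seq_len(nC), , drop = FALSE]
    truthClusters <- data.frame(
      cluster_id = seq_len(nC), x = cx, y = cy, z = cz,
      length = L, width = L * spec@clusterAspect,
      axis_x = axisC[, 1], axis_y = axisC[, 2], axis_z = axisC[, 3],
      n_locs = nReal, feret_true = feret,
      truncated = truncated | nReal < nEv) # any member beyond a z border
    truth <- new("SceneTruth", clusters = truthClusters, beads = beads,
                 drift = spec@drift, labels = movieLabels,
                 truePositions = allPts, trueLabels = as.integer(labels),
                 eventIndex = movieEvents, spec = spec)
    list(movies = movies, beadsPre = beadsPre, beadsPost = beadsPost,
         scan = scan, truth = truth)
  })
}

#' Ground-truth metric table of a simulated scene
#'
#' @param truth a [SceneTruth-class].
#' @return data.frame aligned by cluster id with the true center, length,
#'   width, realized member count, member Feret diameter and truncation flag,
#'   for recovery scoring against segmented clusters.
#' @export
sceneTruthTable <- function(truth) {
  stopifnot(is(truth, "SceneTruth"))
  truth@clusters
}

#' Simulate membrane-labelled boutons with internal protein clusters
#'
#' Generates hollow spherical membrane shells (the bouton surface label) and
#' ellipsoidal protein clusters inside each bouton, with the expected number
#' of clusters proportional to bouton volume. Coordinates carry z directly:
#' this emulates an already assembled and drift-corrected two-round
#' acquisition for the bouton reconstruction and assignment stages.
#'
#' @param nBoutons number of boutons.
#' @param volumeRange numeric(2) bouton volume range (um^3).
#' @param clustersPerUm3 expected clusters per um^3 of bouton volume.
#' @param membranePerUm2 membrane localizations per um^2 of surface.
#' @param locsPerCluster mean blinking events per cluster.
#' @param jitter membrane/member localization noise sd (nm).
#' @param seed random seed.
#' @return list with `membrane` and `clusters` ([LocalizationTable-class])
#'   and `truth` (data.frames `boutons` and `clusterCenters`).
#' @export
simulateBoutonScene <- function(nBoutons = 8L, volumeRange = c(2, 30),
                                clustersPerUm3 = 1.1, membranePerUm2 = 400,
                                locsPerCluster = 139, jitter = 15,
                                seed = 1L) {
  .with_seed(seed, {
    vols <- exp(runif(nBoutons, log(volumeRange[1]), log(volumeRange[2])))
    radii <- (3 * vols / (4 * pi))^(1 / 3) * 1000 # nm
    # place boutons on a jittered grid so shells never touch
    ncol_ <- ceiling(sqrt(nBoutons))
    pitch <- 2 * max(radii) + 2000
    cx <- (((seq_len(nBoutons) - 1) %% ncol_) + 0.5) * pitch
    cy <- (((seq_len(nBoutons) - 1) %/% ncol_) + 0.5) * pitch
    czc <- max(radii) + 500 + runif(nBoutons, 0, 500)

    memb <- vector("list", nBoutons)
    clLocs <- list()
    clCenters <- list()
    nClTrue <- integer(nBoutons)
    for (i in seq_len(nBoutons)) {
      area <- 4 * pi * (radii[i] / 1000)^2
      nm_ <- rpois(1, membranePerUm2 * area)
      g <- matrix(rnorm(3 * nm_), ncol = 3)
      g <- g / sqrt(rowSums(g^2))
      memb[[i]] <- cbind(cx[i] + radii[i] * g[, 1] + rnorm(nm_, 0, jitter),
                         cy[i] + radii[i] * g[, 2] + rnorm(nm_, 0, jitter),
                         czc[i] + radii[i] * g[, 3] + rnorm(nm_, 0, jitter))
      nClTrue[i] <- max(rpois(1, clustersPerUm3 * vols[i]), 1L)
      for (j in seq_len(nClTrue[i])) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        rad <- runif(1)^(1 / 3) * 0.75 * radii[i]
        cen <- c(cx[i], cy[i], czc[i]) + rad * u
        Lj <- rlnorm(1, log(450), 0.3)
        nj <- rpois(1, locsPerCluster)
        p <- .runif_ellipsoid(nj, cen, Lj / 2, Lj * 0.1,
                              .basis_from_axis(rnorm(3)))
        p <- p + matrix(rnorm(3 * nrow(p), 0, jitter), ncol = 3)
        clLocs[[length(clLocs) + 1]] <- p
        clCenters[[length(clCenters) + 1]] <-
          data.frame(bouton_id = i, x = cen[1], y = cen[2], z = cen[3],
                     length = Lj, n_locs = nj)
      }
    }
    mk <- function(mat, channel) {
      df <- data.frame(x = mat[, 1], y = mat[, 2], z = mat[, 3],
                       frame = seq_len(nrow(mat)) - 1L, channel = channel)
      localizationTable(df, fieldOfView = c(max(mat[, 1]) + 1000,
                                            max(mat[, 2]) + 1000))
    }
    membMat <- do.call(rbind, memb)
    clMat <- do.call(rbind, clLocs)
    list(membrane = mk(membMat, "gfp"),
         clusters = mk(clMat, "bassoon"),
         truth = list(boutons = data.frame(bouton_id = seq_len(nBoutons),
                                           x = cx, y = cy, z = czc,
                                           radius = radii, volume_um3 = vols,
                                           n_clusters_true = nClTrue),
                      clusterCenters = do.call(rbind, clCenters)))
  })
}
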