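test_that("DBSCAN denoising matches a brute-force reference", {
  set.seed(20)
  n <- 300
  coords <- cbind(runif(n, 0, 3000), runif(n, 0, 3000), runif(n, 0, 1500))
  tab <- loc_table(coords[, 1], coords[, 2], z = coords[, 3])
  for (minPts in c(4L, 8L)) {
    ref <- brute_dbscan(coords, eps = 250, min_pts = minPts)
    out <- denoise(tab, eps = 250, minPts = minPts, anisotropy = c(1, 1, 1))
    expect_equal(nLocs(out), sum(ref > 0))
    kept <- locs(out)
    expect_equal(sort(kept$x), sort(coords[ref > 0, 1]))
  }
  # the default elliptical neighbourhood equals DBSCAN on scaled coordinates
  ref3 <- brute_dbscan(sweep(coords, 2, c(1, 1, 3), "/"), eps = 250,
                       min_pts = 8L)
  out3 <- denoise(tab, eps = 250, minPts = 8L)
  expect_equal(nLocs(out3), sum(ref3 > 0))
})

test_that("denoising removes isolated points and exact constructed strays", {
  one <- loc_table(100, 100, z = 100)
  expect_equal(nLocs(denoise(one, eps = 100, minPts = 8)), 0)

  set.seed(21)
  dense <- cbind(rnorm(100, 5000, 25), rnorm(100, 5000, 25), rnorm(100, 500, 25))
  ang <- runif(20, 0, 2 * pi)
  strays <- cbind(5000 + cos(ang) * runif(20, 1.5e3, 3e3) * 2,
                  5000 + sin(ang) * runif(20, 1.5e3, 3e3) * 2,
                  runif(20, 0, 1000))
  tab <- loc_table(c(dense[, 1], strays[, 1]), c(dense[, 2], strays[, 2]),
                   z = c(dense[, 3], strays[, 3]))
  out <- denoise(tab, eps = 100, minPts = 8)
  expect_equal(nLocs(out), 100)
  expect_equal(locMetadata(out)$denoise$removed, 20)

  empty <- localizationTable(data.frame(x = numeric(0), y = numeric(0),
                                        frame = integer(0), z = numeric(0)))
  expect_equal(nLocs(denoise(empty)), 0)
})

test_that("density maps are normalized, linear, and honour level sets", {
  one <- loc_table(1000, 1000, z = 500)
  m1 <- renderDensity3D(one, voxelSize = 10, kernelSigma = c(50, 50, 50))
  expect_lt(abs(densityIntegral(m1) - 1), 0.001)

  two <- loc_table(c(1000, 1000), c(1000, 1000), z = c(500, 500))
  m2 <- renderDensity3D(two, voxelSize = 10, kernelSigma = c(50, 50, 50))
  expect_lt(abs(densityIntegral(m2) - 2), 0.002)
  expect_equal(max(m2@value), 2 * max(m1@value), tolerance = 1e-9)

  # the level set of one isotropic Gaussian is a sphere of known radius
  sigma <- 50
  peak <- 1 / ((2 * pi)^1.5 * sigma^3) * 1e9 # per um^3
  level <- peak / 4
  r <- sigma * sqrt(2 * log(peak / level))
  vol_analytic <- 4 / 3 * pi * r^3 * 1e-9
  vol_measured <- sum(m1@value >= level) * 10^3 * 1e-9
  expect_lt(abs(vol_measured / vol_analytic - 1), 0.1)

  expect_warning(renderDensity3D(one, voxelSize = 200), "undersampled")
})

test_that("two distant synthetic clusters segment into exactly two objects", {
  set.seed(22)
  unif_ellipsoid <- function(cen, a, b) {
    g <- matrix(rnorm(300), 100, 3)
    g <- g / sqrt(rowSums(g^2))
    p <- g * runif(100)^(1 / 3)
    sweep(p %*% diag(c(a, b, b)), 2, cen, "+")
  }
  c1 <- unif_ellipsoid(c(2000, 2000, 1000), 250, 60)
  c2 <- unif_ellipsoid(c(4000, 4000, 1000), 250, 60)
  tab <- loc_table(c(c1[, 1], c2[, 1]), c(c1[, 2], c2[, 2]),
                   z = c(c1[, 3], c2[, 3]))
  cs <- segmentClusters(tab, clusterParams())
  cl <- clusters(cs)
  expect_equal(nrow(cl), 2)
  expect_true(all(abs(cl$count - 100) <= 2)) # boundary-voxel losses only
  tal <- tallies(cs)
  expect_equal(sum(cl$count) + tal$unassigned + tal$dropped_locs, 200)
})

test_that("member Feret of a two-point cluster is their distance", {
  tab <- loc_table(c(1000, 1000), c(1000, 1300), z = c(500, 500))
  # a broad kernel and a low threshold connect the two blobs into one object
  cs <- segmentClusters(tab, clusterParams(kernelSigma = c(100, 100, 100),
                                           isoThreshold = 1, minCount = 1L))
  cl <- clusters(cs)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$length_member, 300)
})

test_that("the minimum-count cut-off is inclusive", {
  set.seed(23)
  mk <- function(cx, n) cbind(rnorm(n, cx, 30), rnorm(n, 2000, 30),
                              rnorm(n, 800, 30))
  pts <- rbind(mk(2000, 5), mk(6000, 8), mk(10000, 20))
  tab <- loc_table(pts[, 1], pts[, 2], z = pts[, 3])
  cs <- segmentClusters(tab, clusterParams(minCount = 8L, isoThreshold = 100))
  cl <- clusters(cs)
  expect_equal(sort(cl$count), c(8, 20))
  expect_equal(tallies(cs)$dropped_clusters, 1)
  expect_equal(tallies(cs)$dropped_locs, 5)
})

test_that("density equals count over volume exactly for every cluster", {
  spec <- sceneSpec(nClusters = 25L, fieldOfView = c(10000, 10000),
                    zExtent = 3000, backgroundDensity = 1, seed = 24)
  fe <- run_front_end(spec)
  cl <- clusters(segmentClusters(fe$denoised, clusterParams()))
  expect_gt(nrow(cl), 10)
  expect_equal(cl$density_per_um3, cl$count / cl$volume_um3)
  expect_true(all(cl$volume_um3 > 0))
  expect_true(all(cl$length >= cl$width | cl$count < 3))
})

test_that("localization bookkeeping is conserved through segmentation", {
  spec <- sceneSpec(nClusters = 25L, fieldOfView = c(10000, 10000),
                    zExtent = 3000, backgroundDensity = 3, seed = 25)
  fe <- run_front_end(spec)
  cs <- segmentClusters(fe$denoised, clusterParams())
  tal <- tallies(cs)
  expect_equal(sum(clusters(cs)$count) + tal$unassigned + tal$dropped_locs,
               nLocs(fe$denoised))
  expect_equal(tal$n_input, nLocs(fe$denoised))
  # membership agrees with the per-cluster counts
  expect_equal(as.integer(table(membership(cs)[membership(cs) > 0])),
               clusters(cs)$count)
})

test_that("cluster volumes converge as the voxel grid is refined", {
  set.seed(26)
  mk <- function(cen) cbind(rnorm(300, cen[1], 120), rnorm(300, cen[2], 60),
                            rnorm(300, cen[3], 60))
  pts <- rbind(mk(c(2000, 2000, 1000)), mk(c(5000, 5000, 1500)))
  tab <- loc_table(pts[, 1], pts[, 2], z = pts[, 3])
  v20 <- clusters(segmentClusters(tab, clusterParams(voxelSize = 20)))$volume_um3
  v10 <- clusters(segmentClusters(tab, clusterParams(voxelSize = 10)))$volume_um3
  expect_equal(length(v20), 2)
  expect_true(all(abs(v10 / v20 - 1) < 0.05))
})

test_that("truncation flags respect the margin and the checked axes", {
  set.seed(27)
  near <- cbind(rnorm(50, 1000, 30), rnorm(50, 1000, 30),
                pmax(rnorm(50, 30, 15), 0))
  inner <- cbind(rnorm(50, 3000, 30), rnorm(50, 3000, 30), rnorm(50, 500, 30))
  tab <- loc_table(c(near[, 1], inner[, 1]), c(near[, 2], inner[, 2]),
                   z = c(near[, 3], inner[, 3]))
  cs <- segmentClusters(tab, clusterParams())
  roi <- list(x = c(0, 5000), y = c(0, 5000), z = c(0, 1000))
  fl <- clusters(flagTruncation(cs, tab, roi, margin = 20))
  byz <- setNames(fl$truncated, round(fl$centroid_z, -2))
  expect_true(fl$truncated[which.min(fl$centroid_z)])
  expect_false(fl$truncated[which.max(fl$centroid_z)])
  # clusters comfortably inside never get flagged whatever the axes
  fl2 <- clusters(flagTruncation(cs, tab, roi, margin = 20,
                                 axes = c("x", "y", "z")))
  expect_false(fl2$truncated[which.max(fl2$centroid_z)])
})

test_that("deterministic subsampling reproduces the exact schemes", {
  tab <- loc_table(1:10 * 1.0, 1:10 * 1.0, z = 1:10 * 1.0)
  keep0 <- function(f) locs(subsampleLocalizations(tab, f))$x - 1 # 0-based ids
  expect_equal(keep0(0.5), c(0, 2, 4, 6, 8))
  expect_equal(keep0(0.9), 0:8)
  expect_equal(keep0(0.2), c(0, 5))
  expect_equal(keep0(0.8), c(0, 1, 2, 3, 5, 6, 7, 8))
  expect_equal(keep0(0.66), c(0, 1, 3, 4, 6, 7, 9))
  expect_equal(keep0(0.33), c(0, 3, 6, 9))
  expect_equal(keep0(0.1), 0)
  expect_equal(keep0(1), 0:9)
  expect_error(subsampleLocalizations(tab, 0.42), "unsupported")
  # deterministic, order-preserving, idempotent at fraction 1
  expect_identical(locs(subsampleLocalizations(tab, 0.66)),
                   locs(subsampleLocalizations(tab, 0.66)))
  # sizes are the exact floor implied by each scheme for any n
  set.seed(28)
  big <- loc_table(runif(1234), runif(1234), z = runif(1234))
  sizes <- vapply(c(0.9, 0.8, 0.66, 0.5, 0.33, 0.2, 0.1), function(f)
    nLocs(subsampleLocalizations(big, f)), numeric(1))
  expect_equal(sizes, c(1234 - floor(1234 / 10), 1234 - floor(1234 / 5),
                        1234 - floor(1234 / 3), 1234 - floor(1234 / 2),
                        ceiling(1234 / 3), ceiling(1234 / 5),
                        ceiling(1234 / 10)))
})

test_that("identical reduction groups give a Kruskal-Wallis p of 1", {
  set.seed(29)
  x <- rlnorm(40, log(400), 0.3)
  kw <- rankTests(list(a = x, b = x, c = x), "kruskal_wallis")
  expect_equal(kw$p, 1, tolerance = 1e-9)
})

test_that("depth profile reports flat medians for depth-independent data", {
  set.seed(30)
  n <- 4000
  tab <- loc_table(runif(n, 0, 10000), runif(n, 0, 10000),
                   z = runif(n, 0, 5000),
                   intensity = rlnorm(n, log(13000), 0.3),
                   background = rlnorm(n, log(1180), 0.2))
  prof <- depthProfile(tab, nBins = 8L)
  expect_equal(nrow(prof), 8)
  expect_equal(sum(prof$count), n)
  groups <- split(locs(tab)$intensity, cut(locs(tab)$z, 8))
  kw <- rankTests(groups, "kruskal_wallis")
  expect_gt(kw$p, 0.05)
  # single bin = global medians; the ratio column is intensity / background
  g <- depthProfile(tab, nBins = 1L)
  expect_equal(g$median_intensity, median(locs(tab)$intensity))
  one <- depthProfile(loc_table(1, 1, z = 1, intensity = 11000,
                                background = 1000), 1L)
  expect_equal(one$median_ratio, 11)
})
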