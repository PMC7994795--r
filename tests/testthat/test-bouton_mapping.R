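test_that("a hollow membrane shell reconstructs with its enclosed volume", {
  bs <- simulateBoutonScene(nBoutons = 1L, volumeRange = c(8, 8), seed = 41)
  bset <- reconstructBoutons(bs$membrane, clusterParams(), minVolume = 1)
  bt <- boutons(bset)
  expect_equal(nrow(bt), 1)
  expect_lt(abs(bt$volume_um3 / bs$truth$boutons$volume_um3 - 1), 0.2)
  tr <- bs$truth$boutons
  expect_lt(sqrt((bt$centroid_x - tr$x)^2 + (bt$centroid_y - tr$y)^2 +
                   (bt$centroid_z - tr$z)^2), 200)
})

test_that("filled bouton volumes are recovered within 20% across sizes", {
  bs <- simulateBoutonScene(nBoutons = 6L, volumeRange = c(1.3, 30), seed = 8)
  bset <- reconstructBoutons(bs$membrane, clusterParams(), minVolume = 1)
  bt <- boutons(bset)
  tr <- bs$truth$boutons
  expect_equal(nrow(bt), nrow(tr))
  relerr <- vapply(seq_len(nrow(tr)), function(i) {
    d <- sqrt((bt$centroid_x - tr$x[i])^2 + (bt$centroid_y - tr$y[i])^2 +
                (bt$centroid_z - tr$z[i])^2)
    j <- which.min(d)
    abs(bt$volume_um3[j] - tr$volume_um3[i]) / tr$volume_um3[i]
  }, numeric(1))
  expect_true(all(relerr < 0.2))
})

test_that("seed points split connected structures by nearest seed", {
  # two shells joined by a thin tube of membrane label
  set.seed(42)
  shell <- function(cen, r, n) {
    g <- matrix(rnorm(3 * n), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    sweep(r * g, 2, cen, "+") + matrix(rnorm(3 * n, 0, 15), ncol = 3)
  }
  c1 <- c(3000, 3000, 2000)
  c2 <- c(8000, 3000, 2000)
  tube_t <- runif(1500)
  tube <- cbind(3000 + 5000 * tube_t, 3000 + rnorm(1500, 0, 60),
                2000 + rnorm(1500, 0, 60))
  mat <- rbind(shell(c1, 1200, 6000), shell(c2, 1000, 5000), tube)
  memb <- loc_table(mat[, 1], mat[, 2], z = mat[, 3])
  seeds <- data.frame(bouton_id = c(1L, 2L), x = c(3000, 8000),
                      y = c(3000, 3000), z = c(2000, 2000))
  bset <- reconstructBoutons(memb, clusterParams(), minVolume = 1,
                             seeds = seeds)
  bt <- boutons(bset)
  expect_equal(sort(bt$bouton_id), c(1L, 2L))
  # the larger shell must come out larger, and the masks stay disjoint
  expect_gt(bt$volume_um3[bt$bouton_id == 1], bt$volume_um3[bt$bouton_id == 2])
  vox <- do.call(rbind, bset@masks)
  expect_equal(nrow(vox), nrow(unique(vox)))
})

test_that("an empty membrane table yields an empty bouton set", {
  empty <- localizationTable(data.frame(x = numeric(0), y = numeric(0),
                                        frame = integer(0), z = numeric(0)))
  expect_equal(nrow(boutons(reconstructBoutons(empty, clusterParams()))), 0)
})

test_that("clusters are assigned by the centroid-inside rule", {
  bs <- simulateBoutonScene(nBoutons = 3L, volumeRange = c(6, 20), seed = 43)
  bset <- reconstructBoutons(bs$membrane, clusterParams(), minVolume = 1)
  cs <- segmentClusters(bs$clusters, clusterParams())
  res <- assignClusters(cs, bset)
  cl <- clusters(res$clusterSet)
  bt <- boutons(res$boutonSet)
  expect_gt(sum(bt$n_clusters), 0)
  # conservation: per-bouton tallies plus unassigned equals total clusters
  expect_equal(sum(bt$n_clusters) + sum(is.na(cl$bouton_id)), nrow(cl))
  # assignment matches the generating bouton for the assigned clusters,
  # after mapping reconstructed bouton ids to truth by centroid proximity
  truth_ctr <- bs$truth$boutons
  to_truth <- vapply(seq_len(nrow(bt)), function(b) {
    d <- sqrt((truth_ctr$x - bt$centroid_x[b])^2 +
                (truth_ctr$y - bt$centroid_y[b])^2 +
                (truth_ctr$z - bt$centroid_z[b])^2)
    truth_ctr$bouton_id[which.min(d)]
  }, integer(1))
  names(to_truth) <- as.character(bt$bouton_id)
  for (r in which(!is.na(cl$bouton_id))) {
    d <- sqrt((truth_ctr$x - cl$centroid_x[r])^2 +
                (truth_ctr$y - cl$centroid_y[r])^2 +
                (truth_ctr$z - cl$centroid_z[r])^2)
    expect_equal(truth_ctr$bouton_id[which.min(d)],
                 unname(to_truth[as.character(cl$bouton_id[r])]))
  }
  # determinism
  res2 <- assignClusters(cs, bset)
  expect_equal(clusters(res2$clusterSet)$bouton_id, cl$bouton_id)
})

test_that("a centroid outside all masks stays unassigned", {
  bs <- simulateBoutonScene(nBoutons = 1L, volumeRange = c(8, 8), seed = 44)
  bset <- reconstructBoutons(bs$membrane, clusterParams(), minVolume = 1)
  far <- loc_table(rnorm(60, 50, 20) + 200, rnorm(60, 200, 20), z = rnorm(60, 200, 20))
  cs <- segmentClusters(far, clusterParams())
  res <- assignClusters(cs, bset)
  expect_true(all(is.na(clusters(res$clusterSet)$bouton_id)))
})

test_that("per-bouton summaries carry the volume-count correlation", {
  mk_cs <- function(vols, counts) {
    # construct a ClusterSet/BoutonSet pair directly with known tallies
    bt <- data.frame(bouton_id = seq_along(vols), volume_um3 = vols,
                     centroid_x = 0, centroid_y = 0, centroid_z = 0,
                     n_clusters = counts)
    bset <- new("BoutonSet", boutons = bt, masks = list(),
                grid = list(origin = c(0, 0, 0), voxel = rep(20, 3)))
    ncl <- sum(counts)
    cl <- data.frame(cluster_id = seq_len(ncl), count = 10L,
                     centroid_x = 0, centroid_y = 0, centroid_z = 0,
                     length = 300, length_member = 280, width = 80,
                     volume_um3 = 0.005, density_per_um3 = 10 / 0.005,
                     truncated = FALSE,
                     bouton_id = rep(seq_along(vols), counts))
    cs <- new("ClusterSet", clusters = cl, membership = integer(0),
              params = clusterParams(), grid = bset@grid,
              tallies = list(n_input = ncl * 10L, unassigned = 0L,
                             dropped_clusters = 0L, dropped_locs = 0L,
                             iso_threshold = 1))
    list(cs = cs, bset = bset)
  }
  mono <- mk_cs(vols = c(2, 5, 9, 14, 20), counts = c(2L, 4L, 7L, 9L, 13L))
  s1 <- perBoutonSummary(mono$cs, mono$bset)
  expect_equal(attr(s1, "spearman")$r, 1)
  anti <- mk_cs(vols = c(2, 5, 9, 14, 20), counts = c(13L, 9L, 7L, 4L, 2L))
  s2 <- perBoutonSummary(anti$cs, anti$bset)
  expect_equal(attr(s2, "spearman")$r, -1)
  two <- mk_cs(vols = c(2, 5), counts = c(2L, 4L))
  s3 <- perBoutonSummary(two$cs, two$bset)
  expect_null(attr(s3, "spearman", exact = TRUE))
  expect_match(attr(s3, "spearman_notice"), "fewer than 3")
})
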