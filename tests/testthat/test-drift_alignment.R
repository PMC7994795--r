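make_bead_table <- function(centers, n_per = 50, sd = 10, seed = 1) {
  set.seed(seed)
  df <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    data.frame(x = rnorm(n_per, centers[i, 1], sd),
               y = rnorm(n_per, centers[i, 2], sd),
               z = rnorm(n_per, centers[i, 3], sd),
               frame = seq_len(n_per) - 1L)
  }))
  localizationTable(df)
}

fidset <- function(positions, epoch = "pre") {
  new("FiducialSet", positions = as.matrix(positions),
      spreads = matrix(0, nrow(positions), 3),
      nLocs = rep(50L, nrow(positions)), epoch = epoch)
}

test_that("bead summarization merges localizations into fiducials", {
  centers <- matrix(c(1000, 1000, 0, 8000, 2000, 0, 4000, 9000, 0),
                    ncol = 3, byrow = TRUE)
  fs <- summarizeBeads(make_bead_table(centers, sd = 10, seed = 3),
                       mergeRadius = 500)
  expect_equal(nrow(fs@positions), 3)
  ord <- order(fs@positions[, 1])
  expect_lt(max(abs(fs@positions[ord, ] - centers[order(centers[, 1]), ])), 5)
  expect_true(all(fs@nLocs == 50))
})

test_that("beads separated by twice the merge radius stay distinct", {
  centers <- matrix(c(1000, 1000, 0, 2000, 1000, 0), ncol = 3, byrow = TRUE)
  fs <- summarizeBeads(make_bead_table(centers, sd = 5, seed = 4),
                       mergeRadius = 500)
  expect_equal(nrow(fs@positions), 2)
})

test_that("too few bead localizations raise a fiducial error", {
  tab <- loc_table(1:5, 1:5, z = rep(0, 5))
  expect_error(summarizeBeads(tab), "fiducial error")
})

test_that("exact shifts are recovered exactly; identity gives zero", {
  set.seed(7)
  pre <- matrix(runif(30, 0, 20000), 10, 3)
  shift <- c(50, -30, 20)
  tf <- estimateTransform(fidset(pre), fidset(sweep(pre, 2, -shift), "post"))
  expect_equal(tf@translation, shift, tolerance = 1e-9)
  expect_lt(tf@rmsResidual, 1e-9)
  expect_equal(tf@nPairs, 10L)
  tf0 <- estimateTransform(fidset(pre), fidset(pre, "post"))
  expect_equal(tf0@translation, c(0, 0, 0), tolerance = 1e-12)
})

test_that("noisy bead matches recover the shift within standard error", {
  set.seed(8)
  pre <- matrix(runif(60, 0, 20000), 20, 3)
  shift <- c(50, -30, 20)
  noise <- matrix(rnorm(60, 0, 10), 20, 3)
  tf <- estimateTransform(fidset(pre),
                          fidset(sweep(pre, 2, -shift) + noise, "post"))
  se <- 10 / sqrt(20)
  expect_true(all(abs(tf@translation - shift) < 3 * se))
})

test_that("fewer than three matched beads is an error", {
  pre <- matrix(c(0, 0, 0, 5000, 5000, 0), 2, 3, byrow = TRUE)
  expect_error(estimateTransform(fidset(pre), fidset(pre, "post")),
               "insufficient fiducials")
  # disjoint sets: no mutual neighbours within the match distance
  far <- pre + 1e6
  p3 <- rbind(pre, c(2500, 9000, 0))
  expect_error(estimateTransform(fidset(p3), fidset(p3 + 1e6, "post")),
               "insufficient fiducials")
})

test_that("transform estimation is shift-equivariant", {
  set.seed(9)
  pre <- matrix(runif(30, 0, 10000), 10, 3)
  post <- sweep(pre, 2, c(-40, 25, -10)) + matrix(rnorm(30, 0, 5), 10, 3)
  tf1 <- estimateTransform(fidset(pre), fidset(post, "post"))
  common <- c(1234, -567, 89)
  tf2 <- estimateTransform(fidset(sweep(pre, 2, -common)),
                           fidset(sweep(post, 2, -common), "post"))
  expect_equal(tf1@translation, tf2@translation, tolerance = 1e-9)
})

test_that("transforms compose and invert to the identity", {
  tf <- rigidTransform(translation = c(30, -20, 10), rotation = 0.01,
                       center = c(5000, 5000), scale = 1.001)
  pts <- matrix(runif(30, 0, 10000), 10, 3)
  back <- applyTransform(applyTransform(pts, tf), invertTransform(tf))
  expect_lt(max(abs(back - pts)), 1e-6)
  comp <- composeTransforms(invertTransform(tf), tf)
  moved <- applyTransform(pts, comp)
  expect_lt(max(abs(moved - pts)), 1e-6)
})

test_that("zero transform leaves a table unchanged", {
  tab <- loc_table(1:10 * 100, 1:10 * 100, z = 1:10 * 10,
                   movie_id = rep(0L, 10))
  out <- correctDrift(tab, rigidTransform(), scanSpec(nScans = 1L))
  expect_equal(locs(out)$x, locs(tab)$x)
  expect_equal(locs(out)$z, locs(tab)$z)
})

test_that("injected linear drift is removed to a few nm RMS end to end", {
  spec <- sceneSpec(nClusters = 30L, fieldOfView = c(12000, 12000),
                    zExtent = 4000, backgroundDensity = 0, beadSpread = 0,
                    precision = c(0, 0), drift = c(60, 0, -40), seed = 12)
  fe <- run_front_end(spec)
  expect_true(all(abs(fe$transform@translation - c(60, 0, -40)) < 1))
  # residual of corrected records against their true drift-free positions
  truth <- fe$scene$truth
  true_pos <- truth@truePositions[do.call(c, truth@eventIndex), , drop = FALSE]
  df <- locs(fe$corrected)
  expect_equal(nrow(df), nrow(true_pos))
  res <- cbind(df$x, df$y, df$z) - true_pos
  expect_lt(sqrt(mean(rowSums(res^2))), 5)
})

test_that("a mid-acquisition jump leaves the documented linear-model residual", {
  # drift that is a step, corrected with the linear interpolant: the
  # correction at the jump time removes exactly half the step
  tab <- loc_table(rep(1000, 3), rep(1000, 3), z = rep(500, 3),
                   frame = c(0L, 50L, 99L), movie_id = rep(0L, 3))
  spec <- scanSpec(nScans = 1L, framesPerMovie = 100L, zTravel = 1000)
  jump <- 40
  shifted <- tab
  # record at t >= 0.5 experienced the full jump in x
  sh <- locs(shifted)
  sh$x <- sh$x + ifelse(sh$frame >= 50, jump, 0)
  shifted@locs <- sh
  tf <- rigidTransform(translation = c(jump, 0, 0)) # pre/post beads see it all
  out <- locs(correctDrift(shifted, tf, spec))
  t_mid <- (50 / 99)
  expect_equal(out$x[2] - 1000, jump - t_mid * jump, tolerance = 1e-9)
  expect_equal(out$x[1], 1000)              # t = 0: no correction applied
  expect_equal(out$x[3], 1000, tolerance = 1e-9) # t = 1: fully corrected
})

test_that("round alignment recovers translation and small rotations", {
  set.seed(13)
  ref <- matrix(runif(30, 0, 20000), 10, 3)
  ref[, 3] <- 0
  # pure translation
  moved <- sweep(ref, 2, -c(100, 100, 0))
  tab <- loc_table(moved[, 1], moved[, 2], z = moved[, 3])
  aligned <- alignRounds(tab, fidset(moved, "pre2"), fidset(ref))
  expect_lt(max(abs(cbind(locs(aligned)$x, locs(aligned)$y) - ref[, 1:2])),
            1e-6)
  # rotation of 0.5 degrees about the field center plus a shift
  th <- 0.5 * pi / 180
  ctr <- colMeans(ref[, 1:2])
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- sweep(sweep(ref[, 1:2], 2, ctr) %*% t(R), 2, ctr + c(40, -25), "+")
  moved2 <- cbind(rot, 0)
  tf <- estimateTransform(fidset(moved2, "pre2"), fidset(ref),
                          allowRotation = TRUE)
  expect_lt(abs(abs(tf@rotation) - th), 0.01 * pi / 180)
  back <- applyTransform(moved2, tf)
  expect_lt(max(abs(back[, 1:2] - ref[, 1:2])), 2)
})
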