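test_that("canonical CSV round trip preserves order and coordinates", {
  set.seed(1)
  n <- 1000
  tab <- localizationTable(data.frame(
    x = runif(n, 0, 20000), y = runif(n, 0, 20000), z = runif(n, 0, 5000),
    frame = sample(0:14999, n, replace = TRUE),
    movie_id = sample(0:9, n, replace = TRUE),
    intensity = runif(n, 10000, 60000), background = runif(n, 800, 2000),
    width_x = runif(n, 140, 350), width_y = runif(n, 140, 350),
    channel = "bassoon"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLocalizations(tab, path, "canonical_csv")
  back <- readLocalizations(path, "canonical_csv")
  expect_equal(nLocs(back), n)
  for (col in c("x", "y", "z", "width_x", "width_y"))
    expect_true(max(abs(locs(back)[[col]] - locs(tab)[[col]])) < 0.01)
  expect_identical(locs(back)$frame, locs(tab)$frame)
  expect_identical(locs(back)$channel, locs(tab)$channel)
})

test_that("rapidSTORM dialect round trips and carries unknown columns", {
  set.seed(2)
  n <- 200
  tab <- localizationTable(data.frame(
    x = runif(n, 0, 10000), y = runif(n, 0, 10000),
    frame = sort(sample(0:5000, n, replace = TRUE)),
    intensity = runif(n, 9000, 40000),
    width_x = runif(n, 150, 300), width_y = runif(n, 150, 300)))
  path <- withr::local_tempfile(fileext = ".txt")
  writeLocalizations(tab, path, "rapidstorm")
  expect_true(startsWith(readLines(path, 1), "#"))
  back <- readLocalizations(path, "rapidstorm")
  expect_equal(nLocs(back), n)
  expect_true(max(abs(locs(back)$x - locs(tab)$x)) < 0.01)
  expect_true(max(abs(locs(back)$width_y - locs(tab)$width_y)) < 0.01)
  expect_identical(locs(back)$frame, locs(tab)$frame)

  # a header without width fields yields a table without widths, and the
  # assembler then refuses the z lookup
  txt <- c('# <localizations><field identifier="Position-0-0" unit="nanometer" /><field identifier="Position-1-0" unit="nanometer" /><field identifier="ImageNumber-0-0" unit="frame" /></localizations>',
           "100.5 200.5 0", "300.25 400.75 1")
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(txt, p2)
  nw <- readLocalizations(p2, "rapidstorm")
  expect_false("width_x" %in% names(locs(nw)))
  expect_error(
    assembleVolume(list(nw), scanSpec(nScans = 1L, framesPerMovie = 2L),
                   noiseless_calibration()),
    "widths absent")
})

test_that("missing mandatory columns and malformed rows abort with context", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_nm,intensity", "1,2"), p)
  expect_error(readLocalizations(p, "canonical_csv"), "y_nm")

  rows <- c("x_nm,y_nm,frame", sprintf("%d,%d,%d", 1:100, 1:100, 0:99))
  rows[43] <- "41,notanumber,41"
  writeLines(rows, p)
  expect_error(readLocalizations(p, "canonical_csv"), "line 43")
})

test_that("empty-table writes require the explicit flag", {
  tab <- localizationTable(data.frame(x = numeric(0), y = numeric(0),
                                      frame = integer(0)))
  p <- withr::local_tempfile(fileext = ".csv")
  expect_error(writeLocalizations(tab, p), "allowEmpty")
  writeLocalizations(tab, p, allowEmpty = TRUE)
  expect_equal(nLocs(readLocalizations(p)), 0)
})

test_that("z column appears in output iff present in the table", {
  tab <- loc_table(c(1, 2), c(3, 4))
  p <- withr::local_tempfile(fileext = ".csv")
  writeLocalizations(tab, p)
  expect_false(grepl("z_nm", readLines(p, 1)))
  tab2 <- loc_table(c(1, 2), c(3, 4), z = c(5, 6))
  writeLocalizations(tab2, p)
  expect_true(grepl("z_nm", readLines(p, 1)))
})

test_that("intensity filter is inclusive, idempotent, and tallied", {
  tab <- loc_table(1:3, 1:3, intensity = c(9999, 10000, 20000))
  kept <- filterIntensity(tab, 10000)
  expect_equal(nLocs(kept), 2)
  expect_equal(locs(kept)$intensity, c(10000, 20000))
  expect_equal(locMetadata(kept)$intensity_filter$removed, 1)
  expect_equal(locs(filterIntensity(kept, 10000)), locs(kept))  # idempotent
  expect_equal(nLocs(filterIntensity(tab, 0)), 3)               # identity
  expect_equal(nLocs(filterIntensity(tab, 1e9)), 0)             # all removed
  expect_error(filterIntensity(tab, -1), ">= 0")
})

test_that("2D histogram uses half-open bins and conserves counts", {
  tab <- localizationTable(data.frame(x = 15, y = 15, frame = 0L),
                           fieldOfView = c(100, 100))
  img <- renderHistogram2D(tab, 10)
  expect_equal(dim(img), c(10, 10))
  expect_equal(img[2, 2], 1)
  expect_equal(sum(img), 1)

  set.seed(5)
  n <- 5000
  tab2 <- localizationTable(data.frame(x = runif(n, 0, 1000),
                                       y = runif(n, 0, 1000), frame = 0L),
                            fieldOfView = c(1000, 1000))
  img2 <- renderHistogram2D(tab2, 10)
  expect_equal(sum(img2), n)
  expect_equal(sum(renderHistogram2D(tab2, 37)), n) # any bin size conserves

  # uniform field: per-pixel counts Poisson(lambda), chi-square GOF
  lambda <- n / length(img2)
  counts <- table(factor(pmin(as.vector(img2), 4), levels = 0:4))
  p_exp <- c(dpois(0:3, lambda), 1 - ppois(3, lambda))
  gof <- suppressWarnings(chisq.test(as.vector(counts), p = p_exp))
  expect_gt(gof$p.value, 0.01)
})
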