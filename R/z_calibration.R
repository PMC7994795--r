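# Astigmatic width-vs-z calibration: cubic smoothing splines of wx and wy
# against the known stage position of a bead sweep, and least-squares axial
# lookup of sample localizations against the paired curves.

#' Fit an astigmatic z calibration from a bead sweep
#'
#' The calibration stack is a [LocalizationTable-class] whose `locs` carry a
#' `stage_z` column: the known piezo position for each localization (the bead
#' stack is swept at constant speed, so each frame maps to one stage z).
#' Cubic smoothing splines of `width_x` and `width_y` against stage z form
#' the calibration curves; the validity range is trimmed to the largest
#' interval around the focal plane on which the discriminant
#' \eqn{d(z) = w_x(z) - w_y(z)} is strictly monotone (required for a unique
#' axial lookup), and the focal plane is the root of d.
#'
#' @param stack [LocalizationTable-class] with `width_x`, `width_y` and
#'   `stage_z` columns; at least 50 localizations spanning >= 1 um in z.
#' @param smoothing spline smoothing parameter (`spar` of
#'   [stats::smooth.spline()]); `NULL` selects it by generalized
#'   cross-validation.
#' @param gridStep evaluation grid step in nm for the stored curves.
#' @return A [CalibrationTable-class].
#' @seealso [lookupZ()], [simulateCalibrationStack()]
#' @export
fitCalibration <- function(stack, smoothing = NULL, gridStep = 1) {
  stopifnot(is(stack, "LocalizationTable"))
  df <- locs(stack)
  need <- c("width_x", "width_y", "stage_z")
  if (!all(need %in% names(df)))
    stop("calibration stack needs width_x, width_y and stage_z columns")
  ok <- complete.cases(df[, need])
  df <- df[ok, ]
  if (nrow(df) < 50) stop("too few calibration localizations (need >= 50)")
  if (diff(range(df$stage_z)) < 1000)
    stop("calibration sweep must span at least 1 um in z")

  args_x <- list(x = df$stage_z, y = df$width_x)
  args_y <- list(x = df$stage_z, y = df$width_y)
  if (!is.null(smoothing)) {
    args_x$spar <- smoothing
    args_y$spar <- smoothing
  }
  fit_x <- do.call(smooth.spline, args_x)
  fit_y <- do.call(smooth.spline, args_y)
  spar <- c(fit_x$spar, fit_y$spar)

  zg <- seq(min(df$stage_z), max(df$stage_z), by = gridStep)
  wx <- predict(fit_x, zg)$y
  wy <- predict(fit_y, zg)$y
  d <- wx - wy

  if (max(abs(d)) < 1) # widths coincide everywhere: no astigmatism encoded
    stop("astigmatism not resolvable: wx and wy coincide over the sweep")
  cross <- which(diff(sign(d)) != 0)
  if (!length(cross))
    stop("astigmatism not resolvable: discriminant has no focal crossing")
  # focal plane: linear interpolation at the sign change nearest mid-sweep
  ci <- cross[which.min(abs(zg[cross] - mean(range(zg))))]
  focal <- zg[ci] - d[ci] * gridStep / (d[ci + 1] - d[ci])

  # largest strictly monotone run of d containing the focal crossing
  s <- sign(diff(d))
  s[s == 0] <- NA
  lo <- ci
  while (lo > 1 && !is.na(s[lo - 1]) && s[lo - 1] == s[ci]) lo <- lo - 1
  hi <- ci
  while (hi < length(s) && !is.na(s[hi + 1]) && s[hi + 1] == s[ci]) hi <- hi + 1
  keep <- lo:(hi + 1)
  if (length(keep) < 10)
    stop("astigmatism not resolvable: discriminant not monotone around focus")
  zg <- zg[keep]
  wx <- wx[keep]
  wy <- wy[keep]
  if (any(wx <= 0) || any(wy <= 0))
    stop("calibration curves not positive over the validity range")

  new("CalibrationTable", zGrid = zg, wx = wx, wy = wy,
      zRange = range(zg), focalZ = focal, smoothing = spar,
      fitX = fit_x, fitY = fit_y)
}

#' Evaluate calibration curves
#'
#' @param calib a [CalibrationTable-class].
#' @param z stage positions (nm) inside the validity range.
#' @return data.frame with columns `z`, `wx`, `wy` (nm).
#' @export
evalCalibration <- function(calib, z) {
  stopifnot(is(calib, "CalibrationTable"))
  if (any(z < calib@zRange[1] - 1e-9 | z > calib@zRange[2] + 1e-9))
    stop("z outside the calibrated range")
  data.frame(z = z,
             wx = approx(calib@zGrid, calib@wx, z, rule = 2)$y,
             wy = approx(calib@zGrid, calib@wy, z, rule = 2)$y)
}

#' Look up axial position from fitted PSF widths
#'
#' For each (width_x, width_y) pair, finds the stage offset minimizing the
#' squared width-space distance to the paired calibration curves,
#' \eqn{(w_x(z) - W_x)^2 + (w_y(z) - W_y)^2}, over the validity range. The
#' result is reported relative to the focal plane. Pairs whose width-space
#' residual exceeds the rejection ceiling are flagged rejected, not dropped.
#'
#' @param widthX,widthY fitted PSF widths (nm), vectors of equal length.
#' @param calib a [CalibrationTable-class].
#' @param rejectCeiling residual ceiling in width space (nm).
#' @return data.frame with `z` (nm, relative to the focal plane), `residual`
#'   (nm, width-space distance) and `rejected` (logical).
#' @export
lookupZ <- function(widthX, widthY, calib, rejectCeiling = 50) {
  stopifnot(is(calib, "CalibrationTable"), length(widthX) == length(widthY))
  if (!length(widthX))
    return(data.frame(z = numeric(0), residual = numeric(0),
                      rejected = logical(0)))
  if (any(widthX <= 0 | widthY <= 0, na.rm = TRUE))
    stop("widths must be positive")
  G <- cbind(calib@wx, calib@wy)           # m x 2 curve samples
  cst <- rowSums(G^2)
  n <- length(widthX)
  z <- numeric(n)
  res <- numeric(n)
  chunk <- 4000L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    W <- rbind(widthX[idx], widthY[idx])   # 2 x b
    score <- cst - 2 * (G %*% W)           # m x b (+ const per column)
    amin <- max.col(-t(score), ties.method = "first")
    z[idx] <- calib@zGrid[amin]
    ss <- score[cbind(amin, seq_along(idx))] + widthX[idx]^2 + widthY[idx]^2
    res[idx] <- sqrt(pmax(ss, 0))
  }
  data.frame(z = z - calib@focalZ, residual = res,
             rejected = res > rejectCeiling)
}

#' Write a calibration to disk
#'
#' CSV of the sampled curves (`z_nm, wx_nm, wy_nm`) plus a JSON sidecar with
#' the validity range, focal plane and smoothing parameter.
#'
#' @param calib a [CalibrationTable-class].
#' @param path CSV output path; the sidecar is `<path>.json`.
#' @return invisibly, the CSV path.
#' @export
writeCalibration <- function(calib, path) {
  stopifnot(is(calib, "CalibrationTable"))
  write.csv(data.frame(z_nm = calib@zGrid, wx_nm = calib@wx,
                       wy_nm = calib@wy),
            path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(z_range = calib@zRange, focal_z = calib@focalZ,
                            smoothing = calib@smoothing),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a calibration written by [writeCalibration()]
#' @param path CSV path (with `<path>.json` sidecar next to it).
#' @return A [CalibrationTable-class].
#' @export
readCalibration <- function(path) {
  tab <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("CalibrationTable", zGrid = tab$z_nm, wx = tab$wx_nm, wy = tab$wy_nm,
      zRange = as.numeric(side$z_range), focalZ = as.numeric(side$focal_z),
      smoothing = as.numeric(side$smoothing),
      fitX = NULL, fitY = NULL)
}
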