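# Continuous piezo scan model and assembly of repeated-scan movies into one
# volumetric localization table with true z.

#' Stage position during a continuous axial scan
#'
#' The piezo moves linearly in frame index, reaching both endpoints:
#' ascending scans return \code{zStart + zTravel * frame / (framesPerMovie - 1)};
#' with alternating direction, descending scans mirror the trajectory so the
#' end of scan k equals the start of scan k+1.
#'
#' @param frame frame index (0-based), vectorized.
#' @param scanIndex scan index (0-based), vectorized or scalar.
#' @param spec a [ScanSpec-class].
#' @return stage position(s) in nm.
#' @export
stageZ <- function(frame, scanIndex, spec) {
  stopifnot(is(spec, "ScanSpec"))
  if (any(frame < 0 | frame >= spec@framesPerMovie))
    stop("frame out of range [0, framesPerMovie)")
  if (any(scanIndex < 0 | scanIndex >= spec@nScans))
    stop("scanIndex out of range [0, nScans)")
  pos <- frame / (spec@framesPerMovie - 1)
  descending <- spec@alternateDirection & (scanIndex %% 2 == 1)
  n <- max(length(pos), length(descending))
  pos <- rep_len(pos, n)
  descending <- rep_len(descending, n)
  pos[descending] <- 1 - pos[descending]
  spec@zStart + spec@zTravel * pos
}

#' Assemble repeated-scan movies into a volumetric table
#'
#' Concatenates one localization table per scan and computes the true z of
#' each record as the piezo stage position of its frame plus the astigmatic
#' offset looked up from its PSF widths. Records whose width pair is rejected
#' by the lookup (residual above the ceiling) are dropped and counted, so
#' kept + rejected equals the input count.
#'
#' @param movies list of [LocalizationTable-class], one per scan, in scan
#'   order; widths must be present.
#' @param spec a [ScanSpec-class]; its `nScans` must equal `length(movies)`.
#' @param calib a [CalibrationTable-class].
#' @param rejectCeiling width-space residual ceiling (nm) for [lookupZ()].
#' @return A [LocalizationTable-class] with a `z` column and `movie_id` set;
#'   metadata reports per-movie kept/rejected tallies.
#' @export
assembleVolume <- function(movies, spec, calib, rejectCeiling = 50) {
  stopifnot(is(spec, "ScanSpec"), is(calib, "CalibrationTable"))
  if (length(movies) != spec@nScans)
    stop(sprintf("spec mismatch: %d movies but nScans = %d", length(movies),
                 spec@nScans))
  pieces <- vector("list", length(movies))
  rejected <- integer(length(movies))
  for (s in seq_along(movies)) {
    tab <- movies[[s]]
    stopifnot(is(tab, "LocalizationTable"))
    df <- locs(tab)
    if (!all(c("width_x", "width_y") %in% names(df)))
      stop("z lookup refused: widths absent from movie table")
    if (!nrow(df)) {
      df$z <- numeric(0)
      df$movie_id <- integer(0)
      pieces[[s]] <- df
      next
    }
    lk <- lookupZ(df$width_x, df$width_y, calib, rejectCeiling = rejectCeiling)
    df$z <- stageZ(df$frame, s - 1L, spec) + lk$z
    df$movie_id <- s - 1L
    rejected[s] <- sum(lk$rejected)
    pieces[[s]] <- df[!lk$rejected, , drop = FALSE]
  }
  common <- Reduce(intersect, lapply(pieces, names))
  out <- do.call(rbind, lapply(pieces, function(p) p[, common, drop = FALSE]))
  rownames(out) <- NULL
  localizationTable(out,
                    fieldOfView = fieldOfView(movies[[1]]),
                    pixelSize = movies[[1]]@pixelSize,
                    metadata = list(
                      n_input = sum(vapply(movies, nLocs, integer(1))),
                      n_kept = nrow(out),
                      n_rejected = sum(rejected),
                      rejected_per_movie = rejected,
                      scan_spec = list(n_scans = spec@nScans,
                                       frames_per_movie = spec@framesPerMovie,
                                       z_travel = spec@zTravel,
                                       z_start = spec@zStart)))
}
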