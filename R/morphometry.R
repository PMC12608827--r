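## Per-image vascular metrics from a SkeletonGraph and LabelMask.

#' Weighted centerline path length
#'
#' Length of an 8-connected pixel polyline as the sum over consecutive
#' pixel pairs of 1 (axial step) or sqrt(2) (diagonal step), times the
#' pixel size. This step metric is unbiased for diagonal runs, unlike
#' pixel counting.
#'
#' @param polyline 2-column matrix of (row, col) pixel coordinates with at
#'   least two rows, consecutive rows 8-adjacent.
#' @param pixelSize micrometers per pixel (default 1: pixel units).
#' @return Length (um, or px when `pixelSize = 1`).
#' @export
#' @examples
#' pathLength(cbind(1, 1:11))            # 10
#' pathLength(cbind(1:6, 1:6))           # 5 * sqrt(2)
pathLength <- function(polyline, pixelSize = 1) {
  if (!is.matrix(polyline) || nrow(polyline) < 2L)
    stop("polyline needs at least 2 pixels")
  dr <- abs(diff(polyline[, 1L]))
  dc <- abs(diff(polyline[, 2L]))
  if (any(dr > 1L) || any(dc > 1L) || any(dr + dc == 0L))
    stop("consecutive polyline pixels must be distinct 8-neighbours")
  sum(ifelse(dr == 1L & dc == 1L, sqrt(2), 1)) * pixelSize
}

chordLength <- function(polyline, pixelSize = 1) {
  n <- nrow(polyline)
  sqrt(sum((polyline[n, ] - polyline[1L, ])^2)) * pixelSize
}

#' Arc-chord tortuosity of a centerline segment
#'
#' The ratio of the actual vessel path length to the straight-line
#' distance between the segment endpoints; 1 for a straight vessel.
#' Discretization can produce values marginally below 1; values in
#' `[1 - 1e-9, 1)` are clamped to 1. A zero chord (closed loop) yields
#' `NA` with a reason attribute rather than an error: such segments are
#' excluded from tortuosity statistics.
#'
#' @inheritParams pathLength
#' @return Dimensionless ratio >= 1, or `NA` for zero-chord segments.
#' @export
#' @examples
#' tortuosity(cbind(1, 1:11))                             # 1
#' tortuosity(rbind(cbind(1, 1:6), cbind(2:6, 6)))        # ~ sqrt(2)
tortuosity <- function(polyline, pixelSize = 1) {
  p <- pathLength(polyline, pixelSize)
  ch <- chordLength(polyline, pixelSize)
  if (ch == 0) {
    return(structure(NA_real_, reason = "zero chord (closed loop)"))
  }
  t <- p / ch
  if (t < 1 && t >= 1 - 1e-9) t <- 1
  t
}

#' Total vessel length per class
#'
#' Sums the weighted centerline length over *all* segments (complete and
#' incomplete), grouped by vessel class: total network length is a network
#' property, so unlike segment-level statistics it is not restricted to
#' complete segments. The total includes undetermined-class vessels; a
#' determined-only total is also returned.
#'
#' @param graph a [SkeletonGraph-class].
#' @param pixelSize micrometers per pixel (default: the graph's).
#' @return Named numeric vector: `total`, `total_determined`, `arteriole`,
#'   `venule`, `undetermined`, `lymphatic`.
#' @export
totalVesselLength <- function(graph, pixelSize = NULL) {
  if (is.null(pixelSize)) pixelSize <- graph@pixelSize
  stopifnot(is(graph, "SkeletonGraph"))
  segs <- graph@segments
  out <- c(total = 0, total_determined = 0, arteriole = 0, venule = 0,
           undetermined = 0, lymphatic = 0)
  if (!nrow(segs)) return(out)
  len <- vapply(graph@polylines, function(p) {
    if (nrow(p) < 2L) 0 else pathLength(p, pixelSize)
  }, 0)
  byClass <- tapply(len, segs$class, sum)
  for (cl in names(byClass)) out[tolower(cl)] <- byClass[[cl]]
  out["total"] <- sum(len)
  out["total_determined"] <- out["total"] - out["undetermined"]
  out
}

#' Segment-level statistics over complete segments
#'
#' Mean and median length and tortuosity, computed *exclusively over
#' complete segments* (both ends bounded by branching or transition
#' points). The `OVERALL` row pools all vessel classes including
#' undetermined; arteriole- and venule-specific rows exclude undetermined
#' segments. Zero-chord (loop) segments are excluded from tortuosity with
#' their count reported. Classes with no complete segments yield `NA`.
#'
#' @inheritParams totalVesselLength
#' @return data.frame with one row per class (`OVERALL`, `ARTERIOLE`,
#'   `VENULE`, `UNDETERMINED`, `LYMPHATIC`): `n_complete`, `mean_length`,
#'   `median_length`, `mean_tortuosity`, `median_tortuosity`,
#'   `n_tortuosity_excluded`.
#' @export
segmentStatistics <- function(graph, pixelSize = NULL) {
  if (is.null(pixelSize)) pixelSize <- graph@pixelSize
  stopifnot(is(graph, "SkeletonGraph"))
  segs <- graph@segments
  classesOut <- c("OVERALL", "ARTERIOLE", "VENULE", "UNDETERMINED",
                  "LYMPHATIC")
  rows <- lapply(classesOut, function(cl) {
    sel <- if (cl == "OVERALL") segs$complete else
      segs$complete & segs$class == cl
    idx <- which(sel)
    if (!length(idx)) {
      return(data.frame(class = cl, n_complete = 0L, mean_length = NA_real_,
                        median_length = NA_real_, mean_tortuosity = NA_real_,
                        median_tortuosity = NA_real_,
                        n_tortuosity_excluded = 0L,
                        stringsAsFactors = FALSE))
    }
    len <- vapply(idx, function(i) pathLength(graph@polylines[[i]], pixelSize), 0)
    tor <- vapply(idx, function(i)
      as.numeric(tortuosity(graph@polylines[[i]], pixelSize)), 0)
    data.frame(class = cl, n_complete = length(idx),
               mean_length = mean(len), median_length = median(len),
               mean_tortuosity = if (all(is.na(tor))) NA_real_
                                 else mean(tor, na.rm = TRUE),
               median_tortuosity = if (all(is.na(tor))) NA_real_
                                   else median(tor, na.rm = TRUE),
               n_tortuosity_excluded = sum(is.na(tor)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Vessel area fraction of a label mask
#'
#' Fraction of image pixels occupied by vessels: count of non-background
#' pixels over height x width, plus per-class fractions.
#'
#' @param mask a [LabelMask-class].
#' @return Named numeric vector: `vessel`, `arteriole`, `venule`,
#'   `undetermined`, `lymphatic`, all in `[0, 1]`.
#' @export
#' @examples
#' g <- matrix(0L, 100, 100); g[1:10, 1:100] <- 1L
#' vesselAreaFraction(LabelMask(g))["vessel"]   # 0.1
vesselAreaFraction <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  g <- mask@grid
  n <- length(g)
  lv <- maskLabels()
  c(vessel = sum(g != lv["BACKGROUND"]) / n,
    arteriole = sum(g == lv["ARTERIOLE"]) / n,
    venule = sum(g == lv["VENULE"]) / n,
    undetermined = sum(g == lv["UNDETERMINED"]) / n,
    lymphatic = sum(g == lv["LYMPHATIC"]) / n)
}

#' Per-segment metric table
#'
#' One row per segment: class, completeness, weighted length, chord and
#' tortuosity (NA for zero-chord loops). The unit follows the graph's
#' pixel size.
#'
#' @inheritParams totalVesselLength
#' @return data.frame.
#' @export
segmentTable <- function(graph, pixelSize = NULL) {
  if (is.null(pixelSize)) pixelSize <- graph@pixelSize
  stopifnot(is(graph, "SkeletonGraph"))
  segs <- graph@segments
  if (!nrow(segs)) {
    return(data.frame(id = integer(), class = character(),
                      complete = logical(), length = numeric(),
                      chord = numeric(), tortuosity = numeric()))
  }
  data.frame(
    id = segs$id, class = segs$class, complete = segs$complete,
    length = vapply(graph@polylines, function(p)
      if (nrow(p) < 2L) 0 else pathLength(p, pixelSize), 0),
    chord = vapply(graph@polylines, function(p)
      chordLength(p, pixelSize), 0),
    tortuosity = vapply(graph@polylines, function(p)
      if (nrow(p) < 2L) NA_real_
      else as.numeric(tortuosity(p, pixelSize)), 0),
    stringsAsFactors = FALSE)
}

#' Assemble the per-image morphometry record
#'
#' One row holding the image's vascular metrics: total and per-class
#' vessel length, complete-segment counts, mean/median segment length and
#' tortuosity (overall and per class), and vessel area fractions. The
#' graph must derive from the given mask (matching image ids).
#'
#' @param graph a [SkeletonGraph-class].
#' @param mask the [LabelMask-class] the graph was built from.
#' @param pixelSize micrometers per pixel (default: the mask's).
#' @return One-row data.frame (a morphometry record).
#' @export
summarizeImage <- function(graph, mask, pixelSize = NULL) {
  if (is.null(pixelSize)) pixelSize <- mask@pixelSize
  stopifnot(is(graph, "SkeletonGraph"), is(mask, "LabelMask"))
  if (!identical(graph@sourceMaskId, mask@imageId))
    stop(sprintf("graph derives from '%s', not from mask '%s'",
                 graph@sourceMaskId, mask@imageId))
  tot <- totalVesselLength(graph, pixelSize)
  st <- segmentStatistics(graph, pixelSize)
  af <- vesselAreaFraction(mask)
  pick <- function(cl, fld) st[[fld]][st$class == cl]
  data.frame(
    image_id = mask@imageId, animal_id = mask@animalId, group = mask@group,
    unit = if (pixelSize == 1) "px" else "um",
    pixel_size = pixelSize,
    total_length = unname(tot["total"]),
    total_length_determined = unname(tot["total_determined"]),
    arteriole_length = unname(tot["arteriole"]),
    venule_length = unname(tot["venule"]),
    undetermined_length = unname(tot["undetermined"]),
    n_complete_segments = pick("OVERALL", "n_complete"),
    n_complete_arteriole = pick("ARTERIOLE", "n_complete"),
    n_complete_venule = pick("VENULE", "n_complete"),
    mean_segment_length = pick("OVERALL", "mean_length"),
    mean_segment_length_arteriole = pick("ARTERIOLE", "mean_length"),
    mean_segment_length_venule = pick("VENULE", "mean_length"),
    median_segment_length = pick("OVERALL", "median_length"),
    mean_tortuosity = pick("OVERALL", "mean_tortuosity"),
    mean_tortuosity_arteriole = pick("ARTERIOLE", "mean_tortuosity"),
    mean_tortuosity_venule = pick("VENULE", "mean_tortuosity"),
    median_tortuosity = pick("OVERALL", "median_tortuosity"),
    vessel_area_fraction = unname(af["vessel"]),
    arteriole_area_fraction = unname(af["arteriole"]),
    venule_area_fraction = unname(af["venule"]),
    stringsAsFactors = FALSE)
}
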