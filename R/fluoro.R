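## Fluorescence-derived measures: classical vessel segmentation, alpha-SMA
## coverage and stromal signal, PDPL lymphatic fraction and cell counting.

#' Separable Gaussian smoothing
#'
#' @param mat numeric matrix.
#' @param sigma standard deviation in pixels; 0 returns the input.
#' @return Smoothed matrix (reflective boundary).
#' @noRd
gaussianBlur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(v, r) c(rev(v[seq_len(r)]), v, rev(v[(length(v) - r + 1L):length(v)]))
  conv1 <- function(v) {
    p <- pad(v, r)
    vapply(seq_along(v), function(i) sum(p[i:(i + 2L * r)] * k), 0)
  }
  tmp <- apply(mat, 2L, conv1)
  t(apply(tmp, 1L, conv1))
}

#' Otsu threshold
#'
#' Global threshold maximizing between-class variance over a 256-bin
#' histogram of the intensity range. Returns `NA` for constant images.
#'
#' @param mat non-negative numeric matrix.
#' @return Threshold on the intensity scale of `mat`, or `NA`.
#' @export
otsuThreshold <- function(mat) {
  lo <- min(mat); hi <- max(mat)
  if (hi <= lo) return(NA_real_)
  nb <- 256L
  brk <- seq(lo, hi, length.out = nb + 1L)
  h <- tabulate(pmin(nb, findInterval(mat, brk, rightmost.closed = TRUE)), nb)
  p <- h / sum(h)
  mids <- (brk[-1L] + brk[-(nb + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nb]
  w0c <- w0[-nb]; muc <- mu[-nb]
  valid <- w0c > 0 & w0c < 1
  bcv <- rep(-Inf, nb - 1L)
  bcv[valid] <- (muT * w0c[valid] - muc[valid])^2 /
    (w0c[valid] * (1 - w0c[valid]))
  brk[which.max(bcv) + 1L]
}

#' Classical intensity-based vessel segmentation
#'
#' Deterministic stand-in for learned vessel segmentation: the channel is
#' Gaussian-smoothed, thresholded (Otsu by default, or a fixed value) and
#' objects smaller than `minObjectPx` are removed. A constant-intensity
#' image under the automatic threshold yields an empty mask flagged
#' degenerate (attribute `degenerate = TRUE`).
#'
#' @param channel non-negative numeric intensity matrix.
#' @param smoothingScale Gaussian sigma in pixels (default 2).
#' @param thresholdRule `"otsu"` or a fixed numeric threshold.
#' @param minObjectPx minimum connected-component size kept (default 20).
#' @return Logical vessel mask of the channel's shape.
#' @export
segmentVesselsClassical <- function(channel, smoothingScale = 2,
                                    thresholdRule = "otsu",
                                    minObjectPx = 20) {
  stopifnot(is.matrix(channel), all(channel >= 0))
  sm <- gaussianBlur(channel, smoothingScale)
  thr <- if (identical(thresholdRule, "otsu")) otsuThreshold(sm)
         else as.numeric(thresholdRule)
  if (is.na(thr)) {
    out <- matrix(FALSE, nrow(channel), ncol(channel))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  bin <- sm > thr
  if (minObjectPx > 1 && any(bin)) {
    lab <- cpp_label_components(bin, 8L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= minObjectPx)
    bin <- matrix(lab %in% keep, nrow(bin), ncol(bin))
  }
  bin
}

#' Alpha-SMA vessel coverage
#'
#' Sums the alpha-SMA signal over the vessel mask and divides by the
#' vessel area (mask pixel count): the signal-to-area ratio indexes
#' vascular smooth-muscle coverage. A zero-area mask yields an `NA` ratio
#' flagged missing.
#'
#' @param asmaChannel non-negative numeric matrix.
#' @param vesselMask logical matrix of the same shape.
#' @return Named numeric vector: `vessel_area` (px), `signal`, `ratio`.
#' @export
asmaCoverage <- function(asmaChannel, vesselMask) {
  stopifnot(is.matrix(asmaChannel), is.matrix(vesselMask))
  if (!identical(dim(asmaChannel), dim(vesselMask)))
    stop("channel and mask shapes differ")
  area <- sum(vesselMask)
  sig <- sum(asmaChannel[vesselMask])
  c(vessel_area = area, signal = sig,
    ratio = if (area > 0) sig / area else NA_real_)
}

#' Stromal (non-vessel) alpha-SMA signal
#'
#' The difference between total alpha-SMA signal in the image and the
#' vessel-associated signal. By construction vessel + stromal = total,
#' exactly.
#'
#' @inheritParams asmaCoverage
#' @return Non-negative scalar.
#' @export
stromalAsma <- function(asmaChannel, vesselMask) {
  stopifnot(is.matrix(asmaChannel), is.matrix(vesselMask))
  if (!identical(dim(asmaChannel), dim(vesselMask)))
    stop("channel and mask shapes differ")
  sum(asmaChannel) - sum(asmaChannel[vesselMask])
}

#' Fraction of PDPL-positive lymphatic vessels per image area
#'
#' Lymphatic pixels over total pixels, from a binary mask or a
#' [LabelMask-class] using the `LYMPHATIC` label.
#'
#' @param lymphMask logical matrix or [LabelMask-class].
#' @return Fraction in `[0, 1]`.
#' @export
pdplVesselFraction <- function(lymphMask) {
  m <- if (is(lymphMask, "LabelMask")) {
    lymphMask@grid == maskLabels()["LYMPHATIC"]
  } else lymphMask
  stopifnot(is.matrix(m), is.logical(m))
  sum(m) / length(m)
}

#' Count PDPL-positive cells
#'
#' Podoplanin-positive cells (putative lymphatic endothelial progenitors)
#' are detected as connected components of the thresholded PDPL channel
#' that fall within an area range and do not overlap the lymphatic vessel
#' mask (cells are vessel-external puncta). Deterministic.
#'
#' @param pdplChannel non-negative numeric matrix.
#' @param lymphMask logical matrix or [LabelMask-class] of the same shape.
#' @param intensityThreshold numeric, or `"otsu"` (default).
#' @param areaRange integer pair `[min_px, max_px]`, default `c(10, 400)`.
#' @return Non-negative integer count.
#' @export
countPdplCells <- function(pdplChannel, lymphMask,
                           intensityThreshold = "otsu",
                           areaRange = c(10, 400)) {
  stopifnot(is.matrix(pdplChannel), length(areaRange) == 2L)
  if (areaRange[1L] > areaRange[2L])
    stop("areaRange minimum exceeds maximum")
  lm <- if (is(lymphMask, "LabelMask")) {
    lymphMask@grid == maskLabels()["LYMPHATIC"]
  } else lymphMask
  if (!identical(dim(pdplChannel), dim(lm)))
    stop("channel and mask shapes differ")
  thr <- if (identical(intensityThreshold, "otsu")) otsuThreshold(pdplChannel)
         else as.numeric(intensityThreshold)
  if (is.na(thr)) return(0L)
  bin <- pdplChannel > thr
  if (!any(bin)) return(0L)
  lab <- cpp_label_components(bin, 8L)
  k <- max(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  onVessel <- unique(lab[lm & lab > 0L])
  sum(sizes >= areaRange[1L] & sizes <= areaRange[2L] &
        !(seq_len(k) %in% onVessel))
}

#' Lymphatic morphometry
#'
#' Skeletonizes the lymphatic mask and reuses the segment machinery to
#' report the mean complete-segment length of the lymphatic network
#' (`NA` when no complete segment exists).
#'
#' @param lymphMask a [LabelMask-class] (LYMPHATIC on background) or
#'   logical matrix.
#' @param minSpurLength spur-pruning threshold, default 5.
#' @param pixelSize micrometers per pixel (default: mask's, or 1).
#' @return Named numeric vector: `mean_segment_length`, `n_complete`,
#'   `total_length`, `area_fraction`.
#' @export
lymphaticMorphometry <- function(lymphMask, minSpurLength = 5,
                                 pixelSize = NULL) {
  if (!is(lymphMask, "LabelMask")) {
    stopifnot(is.matrix(lymphMask), is.logical(lymphMask))
    g <- matrix(maskLabels()["BACKGROUND"], nrow(lymphMask), ncol(lymphMask))
    g[lymphMask] <- maskLabels()["LYMPHATIC"]
    lymphMask <- LabelMask(g, pixelSize = if (is.null(pixelSize)) 1
                                          else pixelSize)
  }
  ps <- if (is.null(pixelSize)) lymphMask@pixelSize else pixelSize
  graph <- maskToGraph(lymphMask, minSpurLength = minSpurLength)
  st <- segmentStatistics(graph, ps)
  tot <- totalVesselLength(graph, ps)
  c(mean_segment_length = st$mean_length[st$class == "LYMPHATIC"],
    n_complete = st$n_complete[st$class == "LYMPHATIC"],
    total_length = unname(tot["lymphatic"]),
    area_fraction = pdplVesselFraction(lymphMask))
}

#' Assemble the per-image fluorescence record
#'
#' Combines [segmentVesselsClassical()] (or a supplied vessel mask),
#' [asmaCoverage()], [stromalAsma()], [pdplVesselFraction()] and
#' [countPdplCells()] into one row.
#'
#' @param img a [MultiChannelImage-class] with channels among `vessel`,
#'   `asma`, `pdpl`.
#' @param lymphMask logical matrix or [LabelMask-class]; optional.
#' @param vesselMask optional precomputed logical vessel mask; otherwise
#'   segmented from the `vessel` channel.
#' @param ... passed to [segmentVesselsClassical()].
#' @return One-row data.frame (a fluorescence quantification record).
#' @export
quantifyFluorescence <- function(img, lymphMask = NULL, vesselMask = NULL,
                                 ...) {
  stopifnot(is(img, "MultiChannelImage"))
  if (is.null(vesselMask)) {
    if (!"vessel" %in% channelNames(img))
      stop("no vessel channel and no precomputed vessel mask")
    vesselMask <- segmentVesselsClassical(getChannel(img, "vessel"), ...)
  }
  rec <- data.frame(image_id = img@imageId, animal_id = img@animalId,
                    group = img@group, stringsAsFactors = FALSE)
  if ("asma" %in% channelNames(img)) {
    cov <- asmaCoverage(getChannel(img, "asma"), vesselMask)
    rec$vessel_area <- unname(cov["vessel_area"])
    rec$asma_vessel_signal <- unname(cov["signal"])
    rec$asma_coverage_ratio <- unname(cov["ratio"])
    rec$asma_stromal_signal <- stromalAsma(getChannel(img, "asma"),
                                           vesselMask)
  }
  if (!is.null(lymphMask)) {
    rec$pdpl_vessel_fraction <- pdplVesselFraction(lymphMask)
    if ("pdpl" %in% channelNames(img)) {
      rec$pdpl_cell_count <- countPdplCells(getChannel(img, "pdpl"),
                                            lymphMask)
    }
  }
  rec
}
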