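## Skeletonization of vessel masks.

#' Skeletonize a vessel mask
#'
#' Reduces the union of all vessel classes of a [LabelMask-class] (or a
#' logical matrix) to a one-pixel-wide, topology-preserving centerline via
#' sequential thinning: simple, non-endpoint pixels are deleted one at a
#' time in four directional subpasses (so 8-connectivity of the foreground
#' and the component count are preserved exactly), followed by a cleanup
#' pass that removes residual two-pixel-wide blocks. An empty foreground
#' yields an empty skeleton.
#'
#' @param mask a [LabelMask-class] or logical matrix (TRUE = foreground).
#' @return Logical matrix, TRUE on skeleton pixels.
#' @export
#' @examples
#' m <- matrix(FALSE, 9, 24); m[4:6, 3:22] <- TRUE
#' sum(skeletonizeMask(m))
skeletonizeMask <- function(mask) {
  fg <- if (is(mask, "LabelMask")) mask@grid != maskLabels()["BACKGROUND"]
        else mask
  stopifnot(is.matrix(fg), is.logical(fg))
  cpp_thin(fg)
}

#' Prune short terminal spurs from a skeleton
#'
#' Thinning leaves short terminal branches at vessel-wall irregularities.
#' Every terminal branch whose weighted centerline length from its tip to
#' the first junction pixel is shorter than `minSpurLength` is deleted;
#' branches whose removal would disconnect the skeleton (bare paths with
#' two free ends) are kept. The operation is idempotent at a fixed
#' threshold, and a threshold of 0 is the identity.
#'
#' @param skeleton logical matrix as from [skeletonizeMask()].
#' @param minSpurLength pruning threshold in pixels (weighted steps:
#'   1 axial, sqrt(2) diagonal). Default 5.
#' @return Logical matrix.
#' @export
pruneSpurs <- function(skeleton, minSpurLength = 5) {
  stopifnot(is.matrix(skeleton), is.logical(skeleton), minSpurLength >= 0)
  cpp_prune_spurs(skeleton, as.numeric(minSpurLength))
}

#' Classify skeleton pixels by the underlying mask label
#'
#' Each skeleton pixel carries the vessel-class label of the mask at its
#' own coordinate. A skeleton pixel over background is an internal
#' consistency error (the skeleton must be a subset of the foreground).
#'
#' @param skeleton logical matrix.
#' @param mask a [LabelMask-class] of the same shape.
#' @return Integer matrix of label codes at skeleton pixels, `NA` elsewhere.
#' @export
classifySkeletonPixels <- function(skeleton, mask) {
  stopifnot(is(mask, "LabelMask"))
  g <- mask@grid
  stopifnot(identical(dim(skeleton), dim(g)))
  on <- which(skeleton)
  if (any(g[on] == maskLabels()["BACKGROUND"])) {
    bad <- on[g[on] == maskLabels()["BACKGROUND"]][1L]
    rc <- arrayInd(bad, dim(g))
    stop(sprintf("skeleton pixel over BACKGROUND at (row %d, col %d)",
                 rc[1L], rc[2L]))
  }
  out <- matrix(NA_integer_, nrow(g), ncol(g))
  out[on] <- g[on]
  out
}

#' Label connected components
#'
#' 4- or 8-connected component labelling of a logical matrix; labels
#' 1..K, background 0.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of component labels.
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask), connectivity %in% c(4, 8))
  cpp_label_components(mask, as.integer(connectivity))
}
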