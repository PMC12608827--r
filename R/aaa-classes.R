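#' duravasc: skeleton-graph morphometry of dural microvascular networks
#'
#' Tools to quantify 2D microvascular architecture in the cranial dura
#' mater: class-labelled vessel masks are reduced to one-pixel-wide
#' centerline graphs with typed nodes (branching, transition, endpoint),
#' from which total and per-class vessel lengths, complete-segment lengths
#' and arc-chord tortuosities, and vessel area fractions are computed.
#' Fluorescence channels yield alpha-SMA vessel coverage, stromal alpha-SMA,
#' podoplanin-positive lymphatic vessel fractions and cell counts.
#' Per-image records are averaged per animal and compared between two
#' groups with an unpaired t-test. A synthetic confocal-scene generator
#' with exact analytic ground truth supports validation end to end.
#'
#' @useDynLib duravasc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats aggregate integrate median pt qt rbinom rlnorm rnorm
#'   rpois runif sd setNames t.test quantile
#' @importFrom utils read.csv write.csv packageVersion head tail
#' @keywords internal
"_PACKAGE"

## ---- vessel class labels -------------------------------------------------

#' Vessel class labels
#'
#' Integer codes used in [LabelMask] grids. `BACKGROUND = 0`,
#' `ARTERIOLE = 1`, `VENULE = 2`, `UNDETERMINED = 3`, `LYMPHATIC = 4`.
#' Undetermined regions are vessel areas that could not be attributed to
#' either class due to visual ambiguity; they count towards network totals
#' but not towards arteriole- or venule-specific statistics.
#'
#' @return Named integer vector of label codes.
#' @export
#' @examples
#' maskLabels()
maskLabels <- function() {
  c(BACKGROUND = 0L, ARTERIOLE = 1L, VENULE = 2L,
    UNDETERMINED = 3L, LYMPHATIC = 4L)
}

#' Default mask colour palette
#'
#' The fixed RGB convention for label-mask images: black background, red
#' arterioles, green venules, blue undetermined regions, white lymphatics.
#' Matching is exact (no tolerance); masks are written losslessly.
#'
#' @return data.frame with columns `label`, `code`, `r`, `g`, `b` (0-255).
#' @export
defaultPalette <- function() {
  data.frame(
    label = c("BACKGROUND", "ARTERIOLE", "VENULE", "UNDETERMINED", "LYMPHATIC"),
    code  = c(0L, 1L, 2L, 3L, 4L),
    r = c(0L, 255L, 0L, 0L, 255L),
    g = c(0L, 0L, 255L, 0L, 255L),
    b = c(0L, 0L, 0L, 255L, 255L),
    stringsAsFactors = FALSE
  )
}

labelName <- function(code) {
  lv <- maskLabels()
  names(lv)[match(code, lv)]
}

## ---- S4 classes ----------------------------------------------------------

#' LabelMask: a class-labelled 2D vessel mask
#'
#' The unit of annotation: a 2D grid of integer vessel-class labels (see
#' [maskLabels()]) with pixel-size metadata. When `pixelSize` is 1 (the
#' default) all downstream lengths are in pixel units; otherwise in
#' micrometers.
#'
#' @slot grid integer matrix of label codes.
#' @slot pixelSize micrometers per pixel (> 0).
#' @slot imageId,animalId,group identifier strings.
#' @export
setClass("LabelMask",
  representation(grid = "matrix", pixelSize = "numeric",
                 imageId = "character", animalId = "character",
                 group = "character"))

setValidity("LabelMask", function(object) {
  msg <- character()
  g <- object@grid
  if (!is.numeric(g) && !is.integer(g)) msg <- c(msg, "grid must be numeric")
  if (nrow(g) < 1L || ncol(g) < 1L) msg <- c(msg, "grid must be at least 1x1")
  if (!all(g %in% maskLabels())) {
    msg <- c(msg, "grid contains values outside the label set 0..4")
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) {
    msg <- c(msg, "pixelSize must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMask
#'
#' @param grid integer matrix of label codes (see [maskLabels()]).
#' @param pixelSize micrometers per pixel; default 1 means pixel units.
#' @param imageId,animalId,group identifier strings.
#' @return A [LabelMask-class] object.
#' @export
#' @examples
#' m <- LabelMask(matrix(0L, 16, 16))
#' vesselAreaFraction(m)
LabelMask <- function(grid, pixelSize = 1, imageId = "image",
                      animalId = "animal", group = "GROUP") {
  storage.mode(grid) <- "integer"
  new("LabelMask", grid = grid, pixelSize = as.numeric(pixelSize),
      imageId = as.character(imageId), animalId = as.character(animalId),
      group = as.character(group))
}

#' MultiChannelImage: co-registered fluorescence intensity channels
#'
#' A named set of non-negative 2D intensity grids sharing one shape.
#' Channel names are drawn from `vessel` (blood-vessel marker), `asma`
#' (alpha smooth-muscle actin) and `pdpl` (podoplanin).
#'
#' @slot channels named list of numeric matrices.
#' @slot pixelSize micrometers per pixel.
#' @slot imageId,animalId,group identifier strings.
#' @export
setClass("MultiChannelImage",
  representation(channels = "list", pixelSize = "numeric",
                 imageId = "character", animalId = "character",
                 group = "character"))

setValidity("MultiChannelImage", function(object) {
  msg <- character()
  ch <- object@channels
  if (length(ch) < 1L) msg <- c(msg, "at least one channel required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    msg <- c(msg, "channels must be named")
  if (!all(names(ch) %in% c("vessel", "asma", "pdpl")))
    msg <- c(msg, "channel names must be among vessel, asma, pdpl")
  dims <- lapply(ch, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1L)
    msg <- c(msg, "all channels must share one shape")
  for (nm in names(ch)) {
    if (!is.matrix(ch[[nm]]) || !is.numeric(ch[[nm]]))
      msg <- c(msg, sprintf("channel '%s' must be a numeric matrix", nm))
    else if (any(ch[[nm]] < 0))
      msg <- c(msg, sprintf("channel '%s' has negative intensities", nm))
  }
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a MultiChannelImage
#'
#' @param channels named list of non-negative numeric matrices sharing one
#'   shape; names among `vessel`, `asma`, `pdpl`.
#' @inheritParams LabelMask
#' @return A [MultiChannelImage-class] object.
#' @export
MultiChannelImage <- function(channels, pixelSize = 1, imageId = "image",
                              animalId = "animal", group = "GROUP") {
  new("MultiChannelImage", channels = channels,
      pixelSize = as.numeric(pixelSize), imageId = as.character(imageId),
      animalId = as.character(animalId), group = as.character(group))
}

#' ZStack: an ordered stack of MultiChannelImage planes
#'
#' @slot planes list of [MultiChannelImage-class] sharing shape and
#'   channel names.
#' @slot planeSpacing micrometers between planes.
#' @export
setClass("ZStack",
  representation(planes = "list", planeSpacing = "numeric"))

setValidity("ZStack", function(object) {
  msg <- character()
  pl <- object@planes
  if (length(pl) < 1L) msg <- c(msg, "a z-stack needs at least one plane")
  if (!all(vapply(pl, is, TRUE, "MultiChannelImage")))
    msg <- c(msg, "planes must be MultiChannelImage objects")
  if (length(pl) >= 1L && all(vapply(pl, is, TRUE, "MultiChannelImage"))) {
    sig <- vapply(pl, function(p) {
      paste(paste(dim(p@channels[[1L]]), collapse = "x"),
            paste(sort(names(p@channels)), collapse = ","))
    }, "")
    if (length(unique(sig)) > 1L)
      msg <- c(msg, "planes must share shape and channel names")
  }
  if (length(object@planeSpacing) != 1L || object@planeSpacing <= 0)
    msg <- c(msg, "planeSpacing must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a ZStack
#'
#' @param planes list of [MultiChannelImage-class] objects sharing shape
#'   and channel names.
#' @param planeSpacing micrometers between consecutive planes (default 1).
#' @return A [ZStack-class] object.
#' @export
ZStack <- function(planes, planeSpacing = 1) {
  new("ZStack", planes = planes, planeSpacing = as.numeric(planeSpacing))
}

#' SkeletonGraph: a typed centerline graph of a vessel network
#'
#' One-pixel-wide centerlines decomposed into class-labelled segments
#' bounded by typed nodes. Node kinds: `BRANCHING` (a vessel splits into
#' two or more branches, at least 3 incident segments), `TRANSITION`
#' (anatomical arteriole/venule transition, exactly 2 incident segments of
#' different classes) and `ENDPOINT` (exactly 1). A segment is *complete*
#' when both its end nodes are branching or transition points; segment-level
#' statistics are computed exclusively over complete segments. Artificial
#' nodes (anchors of node-free cycles, isolated pixels, degenerate junction
#' clusters) are flagged and exempt from the degree invariants.
#'
#' @slot nodes data.frame: `id`, `row`, `col`, `kind`, `artificial`.
#' @slot segments data.frame: `id`, `class`, `from`, `to`, `complete`,
#'   `n_interior`.
#' @slot polylines list of 2-column integer matrices (row, col), one per
#'   segment, ordered 8-connected, ends at the end-node positions.
#' @slot nodePixels list of 2-column integer matrices, the pixel set of
#'   each node (junction clusters can span several pixels).
#' @slot sourceMaskId id of the mask the graph was derived from.
#' @slot pixelSize micrometers per pixel, copied from the mask.
#' @export
setClass("SkeletonGraph",
  representation(nodes = "data.frame", segments = "data.frame",
                 polylines = "list", nodePixels = "list",
                 sourceMaskId = "character", pixelSize = "numeric"))

setValidity("SkeletonGraph", function(object) {
  msg <- character()
  nd <- object@nodes
  sg <- object@segments
  if (nrow(sg) && !all(c(sg$from, sg$to) %in% nd$id))
    msg <- c(msg, "segment end nodes must exist")
  if (length(object@polylines) != nrow(sg))
    msg <- c(msg, "one polyline per segment required")
  # degree consistency (artificial nodes exempt)
  if (nrow(nd)) {
    inc <- tabulate(c(sg$from, sg$to), nbins = max(nd$id))
    for (i in seq_len(nrow(nd))) {
      if (nd$artificial[i]) next
      k <- inc[nd$id[i]]
      if (nd$kind[i] == "BRANCHING" && k < 3L)
        msg <- c(msg, sprintf("branching node %d has %d < 3 incident segments",
                              nd$id[i], k))
      if (nd$kind[i] == "ENDPOINT" && k != 1L)
        msg <- c(msg, sprintf("endpoint node %d has %d != 1 incident segments",
                              nd$id[i], k))
      if (nd$kind[i] == "TRANSITION") {
        if (k != 2L)
          msg <- c(msg, sprintf("transition node %d has %d != 2 incident segments",
                                nd$id[i], k))
        cls <- sg$class[sg$from == nd$id[i] | sg$to == nd$id[i]]
        if (k == 2L && length(unique(cls)) != 2L)
          msg <- c(msg, sprintf("transition node %d joins same-class segments",
                                nd$id[i]))
      }
    }
  }
  if (length(msg)) msg else TRUE
})
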