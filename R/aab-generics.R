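## Accessor generics and show methods.

#' @rdname LabelMask-class
#' @param object,x a duravasc object
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))
#' @rdname LabelMask-class
#' @export
setMethod("maskGrid", "LabelMask", function(x) x@grid)

#' @rdname LabelMask-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname LabelMask-class
#' @export
setMethod("pixelSize", "LabelMask", function(x) x@pixelSize)
#' @rdname MultiChannelImage-class
#' @export
setMethod("pixelSize", "MultiChannelImage", function(x) x@pixelSize)
#' @rdname SkeletonGraph-class
#' @export
setMethod("pixelSize", "SkeletonGraph", function(x) x@pixelSize)

#' @rdname LabelMask-class
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname LabelMask-class
#' @export
setMethod("imageId", "LabelMask", function(x) x@imageId)
#' @rdname MultiChannelImage-class
#' @export
setMethod("imageId", "MultiChannelImage", function(x) x@imageId)

#' @rdname LabelMask-class
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))
#' @rdname LabelMask-class
#' @export
setMethod("animalId", "LabelMask", function(x) x@animalId)
#' @rdname MultiChannelImage-class
#' @export
setMethod("animalId", "MultiChannelImage", function(x) x@animalId)

#' @rdname LabelMask-class
#' @export
setGeneric("groupName", function(x) standardGeneric("groupName"))
#' @rdname LabelMask-class
#' @export
setMethod("groupName", "LabelMask", function(x) x@group)
#' @rdname MultiChannelImage-class
#' @export
setMethod("groupName", "MultiChannelImage", function(x) x@group)

#' @rdname MultiChannelImage-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname MultiChannelImage-class
#' @export
setMethod("channelNames", "MultiChannelImage", function(x) names(x@channels))

#' @rdname MultiChannelImage-class
#' @param name channel name (`vessel`, `asma` or `pdpl`)
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))
#' @rdname MultiChannelImage-class
#' @export
setMethod("getChannel", "MultiChannelImage", function(x, name) {
  if (!name %in% names(x@channels))
    stop(sprintf("no channel '%s' (have: %s)", name,
                 paste(names(x@channels), collapse = ", ")))
  x@channels[[name]]
})

#' @rdname ZStack-class
#' @param x a ZStack
#' @export
setGeneric("nPlanes", function(x) standardGeneric("nPlanes"))
#' @rdname ZStack-class
#' @export
setMethod("nPlanes", "ZStack", function(x) length(x@planes))

#' @rdname ZStack-class
#' @export
setGeneric("planeSpacing", function(x) standardGeneric("planeSpacing"))
#' @rdname ZStack-class
#' @export
setMethod("planeSpacing", "ZStack", function(x) x@planeSpacing)

#' @rdname SkeletonGraph-class
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname SkeletonGraph-class
#' @export
setMethod("graphNodes", "SkeletonGraph", function(x) x@nodes)

#' @rdname SkeletonGraph-class
#' @export
setGeneric("graphSegments", function(x) standardGeneric("graphSegments"))
#' @rdname SkeletonGraph-class
#' @export
setMethod("graphSegments", "SkeletonGraph", function(x) x@segments)

#' @rdname SkeletonGraph-class
#' @export
setGeneric("segmentPolylines", function(x) standardGeneric("segmentPolylines"))
#' @rdname SkeletonGraph-class
#' @export
setMethod("segmentPolylines", "SkeletonGraph", function(x) x@polylines)

#' @rdname SkeletonGraph-class
#' @export
setGeneric("nodePixelSets", function(x) standardGeneric("nodePixelSets"))
#' @rdname SkeletonGraph-class
#' @export
setMethod("nodePixelSets", "SkeletonGraph", function(x) x@nodePixels)

setMethod("show", "LabelMask", function(object) {
  g <- object@grid
  counts <- table(factor(labelName(g), levels = names(maskLabels())))
  cat(sprintf("LabelMask '%s' (%d x %d px, %.3g um/px)\n",
              object@imageId, nrow(g), ncol(g), object@pixelSize))
  cat(sprintf("  animal '%s', group '%s'\n", object@animalId, object@group))
  cat("  ", paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                  collapse = " "), "\n", sep = "")
})

setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object@channels[[1L]])
  cat(sprintf("MultiChannelImage '%s' (%d x %d px): channels %s\n",
              object@imageId, d[1L], d[2L],
              paste(names(object@channels), collapse = ", ")))
})

setMethod("show", "ZStack", function(object) {
  d <- dim(object@planes[[1L]]@channels[[1L]])
  cat(sprintf("ZStack: %d planes of %d x %d px (%g um spacing), channels %s\n",
              length(object@planes), d[1L], d[2L], object@planeSpacing,
              paste(names(object@planes[[1L]]@channels), collapse = ", ")))
})

setMethod("show", "SkeletonGraph", function(object) {
  nd <- object@nodes; sg <- object@segments
  cat(sprintf("SkeletonGraph of '%s': %d nodes, %d segments (%d complete)\n",
              object@sourceMaskId, nrow(nd), nrow(sg), sum(sg$complete)))
  if (nrow(nd)) {
    kt <- table(factor(nd$kind, c("BRANCHING", "TRANSITION", "ENDPOINT")))
    cat("  nodes: ", paste(sprintf("%s=%d", names(kt), as.integer(kt)),
                           collapse = " "), "\n", sep = "")
  }
  if (nrow(sg)) {
    ct <- table(sg$class)
    cat("  segment classes: ",
        paste(sprintf("%s=%d", names(ct), as.integer(ct)), collapse = " "),
        "\n", sep = "")
  }
})
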