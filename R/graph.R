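## Skeleton-to-graph extraction: typed nodes, class-labelled segments.

KIND_NAMES <- c("BRANCHING", "TRANSITION", "ENDPOINT")

#' Build a typed skeleton graph from a classified skeleton
#'
#' Converts a pruned, classified skeleton into a [SkeletonGraph-class]:
#'
#' * pixels with three or more skeleton neighbours are junction pixels;
#'   8-adjacent junction pixels are merged into one `BRANCHING` node placed
#'   at the cluster pixel nearest the cluster centroid (thinning produces
#'   two-pixel junction clusters that would otherwise double-count nodes);
#' * pixels with exactly one neighbour become `ENDPOINT` nodes;
#' * maximal centerline walks between node pixels become segments, and a
#'   `TRANSITION` node is inserted wherever consecutive centerline pixels
#'   change vessel class, placed at the first pixel of the new class and
#'   shared by both resulting segments;
#' * a segment is `complete` when both end nodes are branching or
#'   transition points (segments reaching the image border end at an
#'   endpoint and are therefore never complete);
#' * node-free cycles receive one artificial anchor node at their
#'   lexicographically smallest pixel; the cycle segment has zero chord
#'   and is excluded from tortuosity statistics downstream.
#'
#' @param skeleton logical matrix (will be pruned with `minSpurLength`).
#' @param mask the [LabelMask-class] the skeleton was derived from (gives
#'   pixel classes, pixel size and identifiers).
#' @param minSpurLength spur-pruning threshold in pixels, default 5; use 0
#'   to skip pruning. Recorded in the run manifest by the pipeline.
#' @return A [SkeletonGraph-class].
#' @export
#' @examples
#' m <- matrix(0L, 21, 21)
#' m[11, 2:20] <- 1L; m[2:10, 11] <- 1L  # a T of arterioles
#' g <- buildGraph(matrix(m > 0, 21, 21), LabelMask(m), minSpurLength = 0)
#' graphNodes(g)
buildGraph <- function(skeleton, mask, minSpurLength = 5) {
  stopifnot(is(mask, "LabelMask"))
  skeleton <- pruneSpurs(skeleton, minSpurLength)
  classes <- classifySkeletonPixels(skeleton, mask)
  traced <- cpp_trace_graph(skeleton)

  nodes <- data.frame(
    id = traced$node_id, row = traced$node_row, col = traced$node_col,
    kind = KIND_NAMES[traced$node_kind],
    artificial = traced$node_artificial,
    stringsAsFactors = FALSE)
  nodePixels <- as.list(traced$node_pixels)
  polys <- as.list(traced$seg_polyline)
  from <- traced$seg_from
  to <- traced$seg_to

  isNodePixel <- matrix(FALSE, nrow(classes), ncol(classes))
  for (np in nodePixels) isNodePixel[np] <- TRUE

  ## split segments at class changes, inserting TRANSITION nodes
  outPolys <- list(); outClass <- character(); outFrom <- integer()
  outTo <- integer()
  nextId <- if (nrow(nodes)) max(nodes$id) else 0L
  transAt <- new.env(parent = emptyenv())  # "row,col" -> node id

  segClassOf <- function(poly) {
    ## majority class over interior (non-node, non-terminal) pixels;
    ## fall back to the first pixel's class
    n <- nrow(poly)
    cand <- if (n > 2L) 2:(n - 1L) else integer()
    if (length(cand)) {
      keep <- !isNodePixel[poly[cand, , drop = FALSE]]
      cand <- cand[keep]
    }
    cls <- if (length(cand)) classes[poly[cand, , drop = FALSE]]
           else classes[poly[1L, 1L], poly[1L, 2L]]
    tab <- sort(table(cls), decreasing = TRUE)
    as.integer(names(tab)[1L])
  }

  for (i in seq_along(polys)) {
    poly <- polys[[i]]
    n <- nrow(poly)
    cls <- classes[poly]
    ## candidate cut positions: class differs from the previous pixel and
    ## the pixel is not part of a node cluster (class changes inside a
    ## junction cluster need no transition node)
    cuts <- integer()
    if (n >= 3L) {
      chg <- which(cls[-1L] != cls[-n]) + 1L          # first px of new class
      chg <- chg[chg >= 2L & chg <= n - 1L]
      chg <- chg[!isNodePixel[poly[chg, , drop = FALSE]]]
      cuts <- chg
    }
    bounds <- c(1L, cuts, n)
    nsub <- length(bounds) - 1L
    for (j in seq_len(nsub)) {
      a <- bounds[j]; b <- bounds[j + 1L]
      sub <- poly[a:b, , drop = FALSE]
      ## class from the run structure: a sub ending at a transition cut
      ## takes the class just before the cut; a sub starting at a cut
      ## takes the cut pixel's (new) class; an uncut segment uses the
      ## majority over its interior. This keeps the two segments at a
      ## transition on the two classes that triggered the cut, even when
      ## a sub-segment has no interior pixels (mixed-class junction
      ## clusters).
      subClass <- if (j < nsub) cls[bounds[j + 1L] - 1L]
                  else if (nsub > 1L) cls[bounds[j]]
                  else segClassOf(sub)
      fromId <- if (j == 1L) from[i] else {
        get(sprintf("%d,%d", poly[a, 1L], poly[a, 2L]), envir = transAt)
      }
      toId <- if (j == length(bounds) - 1L) to[i] else {
        key <- sprintf("%d,%d", poly[b, 1L], poly[b, 2L])
        if (!exists(key, envir = transAt)) {
          nextId <- nextId + 1L
          assign(key, nextId, envir = transAt)
          nodes <- rbind(nodes, data.frame(
            id = nextId, row = poly[b, 1L], col = poly[b, 2L],
            kind = "TRANSITION", artificial = FALSE,
            stringsAsFactors = FALSE))
          nodePixels[[nextId]] <- matrix(poly[b, ], 1L, 2L)
          isNodePixel[poly[b, 1L], poly[b, 2L]] <- TRUE
        }
        get(key, envir = transAt)
      }
      outPolys[[length(outPolys) + 1L]] <- sub
      outClass <- c(outClass, labelName(subClass))
      outFrom <- c(outFrom, fromId)
      outTo <- c(outTo, toId)
    }
  }

  ## reconcile node kinds with realized incidence (degenerate junction
  ## clusters on unusual thinned shapes are demoted / flagged artificial)
  inc <- tabulate(c(outFrom, outTo),
                  nbins = if (nrow(nodes)) max(nodes$id) else 0L)
  for (k in seq_len(nrow(nodes))) {
    if (nodes$artificial[k]) next
    d <- inc[nodes$id[k]]
    if (nodes$kind[k] == "BRANCHING" && d < 3L) {
      if (d == 1L) nodes$kind[k] <- "ENDPOINT"
      nodes$artificial[k] <- d != 1L
    }
    if (nodes$kind[k] == "ENDPOINT" && d != 1L) nodes$artificial[k] <- TRUE
  }

  kindOf <- setNames(nodes$kind, nodes$id)
  complete <- kindOf[as.character(outFrom)] %in% c("BRANCHING", "TRANSITION") &
              kindOf[as.character(outTo)]   %in% c("BRANCHING", "TRANSITION")

  nInterior <- vapply(seq_along(outPolys), function(i) {
    p <- outPolys[[i]]
    sum(!isNodePixel[p])
  }, 0L)

  segs <- data.frame(
    id = seq_along(outPolys), class = outClass, from = outFrom, to = outTo,
    complete = as.logical(complete), n_interior = nInterior,
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL

  new("SkeletonGraph", nodes = nodes, segments = segs, polylines = outPolys,
      nodePixels = nodePixels, sourceMaskId = mask@imageId,
      pixelSize = mask@pixelSize)
}

#' Mask to graph in one step
#'
#' Convenience composition: [skeletonizeMask()] then [buildGraph()].
#'
#' @inheritParams buildGraph
#' @param mask a [LabelMask-class].
#' @return A [SkeletonGraph-class].
#' @export
maskToGraph <- function(mask, minSpurLength = 5) {
  buildGraph(skeletonizeMask(mask), mask, minSpurLength = minSpurLength)
}

#' Export a skeleton graph
#'
#' Writes the graph as JSON (nodes and segments with polylines) and a
#' per-segment CSV (`id`, `class`, `complete`, `length`, `chord`,
#' `tortuosity`).
#'
#' @param graph a [SkeletonGraph-class].
#' @param jsonPath,csvPath output paths (either may be `NULL` to skip).
#' @return Invisibly, the per-segment data.frame.
#' @export
exportGraph <- function(graph, jsonPath = NULL, csvPath = NULL) {
  stopifnot(is(graph, "SkeletonGraph"))
  segs <- segmentTable(graph)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(source_mask_id = graph@sourceMaskId,
           pixel_size = graph@pixelSize,
           nodes = graph@nodes,
           segments = segs,
           polylines = lapply(graph@polylines, function(p) {
             list(row = p[, 1L], col = p[, 2L])
           })),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csvPath)) write.csv(segs, csvPath, row.names = FALSE)
  invisible(segs)
}
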