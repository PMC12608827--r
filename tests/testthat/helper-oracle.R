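# Brute-force oracles, written independently of the package internals:
# plain-R neighbour walking on the pixel grid, quadratic scans, no shared
# code with the C++ core. Used on small inputs only.

oracleMaxProject <- function(planes) {
  out <- planes[[1]]
  for (r in seq_len(nrow(out))) for (c in seq_len(ncol(out))) {
    for (p in planes) if (p[r, c] > out[r, c]) out[r, c] <- p[r, c]
  }
  out
}

oracleLabelComponents <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 8) {
    cbind(rep(-1:1, each = 3), rep(-1:1, 3))[-5, ]
  } else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0)); lab[r0, c0] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
        if (r < 1 || c < 1 || r > nr || c > nc) next
        if (mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# ---- full graph-extraction oracle ---------------------------------------
# Implements the stated rules by naive enumeration:
#  * junction pixels: >= 3 skeleton 8-neighbours; 8-adjacent junction
#    pixels merge into one BRANCHING node at the centroid-nearest pixel
#    (ties: smallest (row, col));
#  * endpoints: exactly 1 neighbour; isolated pixels: degenerate nodes;
#  * segments: maximal walks between node pixels; node-free cycles get an
#    anchor at their lexicographically smallest pixel;
#  * transition nodes at the first pixel of a new class (non-node pixels
#    only); completeness = both ends BRANCHING or TRANSITION;
#  * nodes are reconciled against realized incidence as the package
#    documents (degenerate junctions demoted/flagged).
# Returns canonical node and segment keys for comparison.

oracleGraph <- function(skel, classes) {
  nr <- nrow(skel); nc <- ncol(skel)
  isOn <- function(r, c) r >= 1 && c >= 1 && r <= nr && c <= nc && skel[r, c]
  # canonical neighbour order N, NE, E, SE, S, SW, W, NW (the package's
  # documented tie-break for cycle traversal)
  DRC <- cbind(c(-1, -1, 0, 1, 1, 1, 0, -1), c(0, 1, 1, 1, 0, -1, -1, -1))
  nbrs <- function(r, c) {
    out <- list()
    for (k in 1:8) {
      if (isOn(r + DRC[k, 1], c + DRC[k, 2]))
        out[[length(out) + 1L]] <- c(r + DRC[k, 1], c + DRC[k, 2])
    }
    out
  }
  deg <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (skel[r, c]) deg[r, c] <- length(nbrs(r, c))
  }

  nodeOf <- matrix(0L, nr, nc)
  nodes <- list()   # each: list(pixels (kx2), pos, kind, artificial)
  addNode <- function(pixels, kind, artificial) {
    id <- length(nodes) + 1L
    ctr <- colMeans(pixels)
    d2 <- (pixels[, 1] - ctr[1])^2 + (pixels[, 2] - ctr[2])^2
    best <- which(d2 <= min(d2) + 1e-12)
    best <- best[order(pixels[best, 1], pixels[best, 2])][1]
    nodes[[id]] <<- list(pixels = pixels, pos = pixels[best, ],
                         kind = kind, artificial = artificial)
    nodeOf[pixels] <<- id
    id
  }

  # junction clusters via flood fill over junction pixels
  seen <- matrix(FALSE, nr, nc)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!skel[r0, c0] || deg[r0, c0] < 3L || seen[r0, c0]) next
    comp <- matrix(c(r0, c0), 1); seen[r0, c0] <- TRUE
    stack <- list(c(r0, c0))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (q in nbrs(p[1], p[2])) {
        if (deg[q[1], q[2]] >= 3L && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          comp <- rbind(comp, q)
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    addNode(comp, "BRANCHING", FALSE)
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!skel[r, c] || nodeOf[r, c] != 0L) next
    if (deg[r, c] == 1L) addNode(matrix(c(r, c), 1), "ENDPOINT", FALSE)
    if (deg[r, c] == 0L) addNode(matrix(c(r, c), 1), "ENDPOINT", TRUE)
  }

  visited <- matrix(FALSE, nr, nc)
  segs <- list()   # list(chain = kx2 interior pixels, a = id, b = id)
  directSeen <- character()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    nid <- nodeOf[r, c]
    if (nid == 0L) next
    for (q in nbrs(r, c)) {
      qid <- nodeOf[q[1], q[2]]
      if (qid == nid) next
      if (qid != 0L) {
        key <- paste(sort(c(paste(r, c), paste(q[1], q[2]))), collapse = "|")
        if (key %in% directSeen) next
        directSeen <- c(directSeen, key)
        segs[[length(segs) + 1L]] <- list(
          chain = matrix(numeric(), 0, 2), a = nid, b = qid,
          aPix = c(r, c), bPix = q)
        next
      }
      if (visited[q[1], q[2]]) next
      chain <- matrix(q, 1); visited[q[1], q[2]] <- TRUE
      prev <- c(r, c); cur <- q; endId <- 0L
      repeat {
        nxt <- NULL
        for (x in nbrs(cur[1], cur[2])) {
          if (x[1] == prev[1] && x[2] == prev[2]) next
          nxt <- x; break
        }
        if (is.null(nxt)) break
        xid <- nodeOf[nxt[1], nxt[2]]
        if (xid != 0L) { endId <- xid; break }
        prev <- cur; cur <- nxt
        chain <- rbind(chain, cur); visited[cur[1], cur[2]] <- TRUE
      }
      if (endId == 0L) next
      segs[[length(segs) + 1L]] <- list(chain = chain, a = nid, b = endId,
                                        aPix = c(r, c), bPix = cur)
    }
  }
  # node-free cycles
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!skel[r, c] || nodeOf[r, c] != 0L || visited[r, c]) next
    id <- addNode(matrix(c(r, c), 1), "BRANCHING", TRUE)
    start <- c(r, c)
    first <- nbrs(r, c)[[1]]
    chain <- matrix(first, 1); visited[first[1], first[2]] <- TRUE
    prev <- start; cur <- first
    repeat {
      nxt <- NULL
      for (x in nbrs(cur[1], cur[2])) {
        if (x[1] == prev[1] && x[2] == prev[2]) next
        if (!(x[1] == start[1] && x[2] == start[2]) && visited[x[1], x[2]])
          next
        nxt <- x; break
      }
      if (is.null(nxt) || (nxt[1] == start[1] && nxt[2] == start[2])) break
      prev <- cur; cur <- nxt
      chain <- rbind(chain, cur); visited[cur[1], cur[2]] <- TRUE
    }
    segs[[length(segs) + 1L]] <- list(chain = chain, a = id, b = id,
                                      aPix = start, bPix = start)
  }

  # transition splitting: cuts wherever consecutive pixels of the walk
  # (attachment node pixel, chain pixels, end node pixel) change class
  # and the new-class pixel is a chain (non-node) pixel
  finalSegs <- list()
  transAt <- list()
  sliceChain <- function(chain, lo, hi) {
    if (hi < lo) matrix(numeric(), 0, 2) else chain[lo:hi, , drop = FALSE]
  }
  for (s in segs) {
    nch <- nrow(s$chain)
    if (nch == 0L) {
      finalSegs[[length(finalSegs) + 1L]] <- s
      next
    }
    ext <- c(classes[s$aPix[1], s$aPix[2]],
             apply(s$chain, 1, function(p) classes[p[1], p[2]]),
             classes[s$bPix[1], s$bPix[2]])
    extCuts <- which(diff(ext) != 0) + 1L      # ext index of new class
    extCuts <- extCuts[extCuts >= 2L & extCuts <= nch + 1L]
    cuts <- extCuts - 1L                       # chain indices
    if (!length(cuts)) {
      finalSegs[[length(finalSegs) + 1L]] <- s
      next
    }
    prevId <- s$a; prevPix <- s$aPix; lo <- 1L
    for (j in seq_along(cuts)) {
      px <- s$chain[cuts[j], ]
      key <- paste(px, collapse = ",")
      if (is.null(transAt[[key]])) {
        transAt[[key]] <- addNode(matrix(px, 1), "TRANSITION", FALSE)
      }
      tid <- transAt[[key]]
      finalSegs[[length(finalSegs) + 1L]] <- list(
        chain = sliceChain(s$chain, lo, cuts[j] - 1L),
        a = prevId, b = tid, aPix = prevPix, bPix = px)
      prevId <- tid; prevPix <- px; lo <- cuts[j] + 1L
    }
    finalSegs[[length(finalSegs) + 1L]] <- list(
      chain = sliceChain(s$chain, lo, nch),
      a = prevId, b = s$b, aPix = prevPix, bPix = s$bPix)
  }

  # reconciliation against realized incidence
  inc <- integer(length(nodes))
  for (s in finalSegs) { inc[s$a] <- inc[s$a] + 1L; inc[s$b] <- inc[s$b] + 1L }
  for (i in seq_along(nodes)) {
    if (nodes[[i]]$artificial) next
    if (nodes[[i]]$kind == "BRANCHING" && inc[i] < 3L) {
      if (inc[i] == 1L) nodes[[i]]$kind <- "ENDPOINT"
      else nodes[[i]]$artificial <- TRUE
    }
    if (nodes[[i]]$kind == "ENDPOINT" && inc[i] != 1L)
      nodes[[i]]$artificial <- TRUE
  }

  bounded <- c("BRANCHING", "TRANSITION")
  segKeys <- vapply(finalSegs, function(s) {
    interior <- s$chain
    cls <- if (nrow(interior)) {
      v <- apply(interior, 1, function(p) classes[p[1], p[2]])
      tb <- sort(table(v), decreasing = TRUE)
      as.integer(names(tb)[1])
    } else NA_integer_
    complete <- nodes[[s$a]]$kind %in% bounded &&
      nodes[[s$b]]$kind %in% bounded
    ends <- sort(c(paste(nodes[[s$a]]$pos, collapse = ","),
                   paste(nodes[[s$b]]$pos, collapse = ",")))
    ik <- if (nrow(interior)) {
      paste(sort(paste(interior[, 1], interior[, 2], sep = ",")),
            collapse = ";")
    } else ""
    paste(ik, cls, complete, paste(ends, collapse = "~"), sep = "#")
  }, "")

  nodeKeys <- vapply(nodes, function(nd) {
    paste(nd$kind, nd$pos[1], nd$pos[2], nd$artificial, sep = "#")
  }, "")

  list(nodeKeys = sort(nodeKeys), segKeys = sort(segKeys))
}

# the same canonical keys computed from a package SkeletonGraph
graphKeys <- function(graph, classes) {
  nodes <- graphNodes(graph)
  isNode <- matrix(FALSE, nrow(classes), ncol(classes))
  for (np in nodePixelSets(graph)) isNode[np] <- TRUE
  bounded <- c("BRANCHING", "TRANSITION")
  kindOf <- setNames(nodes$kind, nodes$id)
  posOf <- setNames(paste(nodes$row, nodes$col, sep = ","), nodes$id)
  segs <- graphSegments(graph)
  polys <- segmentPolylines(graph)
  segKeys <- vapply(seq_len(nrow(segs)), function(i) {
    p <- polys[[i]]
    keep <- !isNode[p]
    interior <- p[keep, , drop = FALSE]
    cls <- if (nrow(interior)) {
      v <- classes[interior]
      tb <- sort(table(v), decreasing = TRUE)
      as.integer(names(tb)[1])
    } else NA_integer_
    ends <- sort(c(posOf[[as.character(segs$from[i])]],
                   posOf[[as.character(segs$to[i])]]))
    ik <- if (nrow(interior)) {
      paste(sort(paste(interior[, 1], interior[, 2], sep = ",")),
            collapse = ";")
    } else ""
    paste(ik, cls, segs$complete[i], paste(ends, collapse = "~"), sep = "#")
  }, "")
  nodeKeys <- paste(nodes$kind, nodes$row, nodes$col, nodes$artificial,
                    sep = "#")
  list(nodeKeys = sort(nodeKeys), segKeys = sort(segKeys))
}
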