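# Skeleton-to-graph extraction: node taxonomy, segments, completeness.

test_that("a Y-shaped skeleton gives 1 branching node, 3 endpoints, 3 segments", {
  m <- yMask()
  g <- buildGraph(maskGrid(m) > 0, m, minSpurLength = 0)
  nd <- graphNodes(g)
  expect_equal(sum(nd$kind == "BRANCHING"), 1L)
  expect_equal(sum(nd$kind == "ENDPOINT"), 3L)
  expect_equal(nrow(graphSegments(g)), 3L)
  expect_equal(sum(graphSegments(g)$complete), 0L)   # each arm ends free
  expect_true(validObject(g))
})

test_that("an H-shaped skeleton has exactly one complete segment (the crossbar)", {
  m <- hMask()
  g <- buildGraph(maskGrid(m) > 0, m, minSpurLength = 0)
  nd <- graphNodes(g)
  expect_equal(sum(nd$kind == "BRANCHING"), 2L)
  expect_equal(sum(nd$kind == "ENDPOINT"), 4L)
  segs <- graphSegments(g)
  expect_equal(nrow(segs), 5L)
  expect_equal(sum(segs$complete), 1L)
  # the complete one is the crossbar: bounded by the two branching nodes
  cb <- segs[segs$complete, ]
  k <- setNames(nd$kind, nd$id)
  expect_true(all(k[as.character(c(cb$from, cb$to))] == "BRANCHING"))
})

test_that("a class switch mid-path inserts one transition node", {
  # bare path: ARTERIOLE then VENULE
  g <- matrix(0L, 9, 30)
  g[5, 2:15] <- LBL[["ARTERIOLE"]]
  g[5, 16:29] <- LBL[["VENULE"]]
  m <- LabelMask(g)
  gr <- buildGraph(g > 0, m, minSpurLength = 0)
  nd <- graphNodes(gr)
  segs <- graphSegments(gr)
  expect_equal(sum(nd$kind == "TRANSITION"), 1L)
  expect_equal(nrow(segs), 2L)
  expect_setequal(segs$class, c("ARTERIOLE", "VENULE"))
  expect_false(any(segs$complete))             # free ends on both sides
  # transition node sits at the first pixel of the new class
  tn <- nd[nd$kind == "TRANSITION", ]
  expect_equal(c(tn$row, tn$col), c(5, 16))

  # same path embedded between two junctions: both halves complete
  g2 <- matrix(0L, 11, 30)
  g2[6, 2:15] <- LBL[["ARTERIOLE"]]
  g2[6, 16:29] <- LBL[["VENULE"]]
  g2[4:8, 2] <- LBL[["ARTERIOLE"]]     # vertical bar crossing left end
  g2[4:8, 29] <- LBL[["VENULE"]]       # vertical bar crossing right end
  m2 <- LabelMask(g2)
  gr2 <- buildGraph(g2 > 0, m2, minSpurLength = 0)
  segs2 <- graphSegments(gr2)
  main <- segs2[segs2$n_interior > 5, ]
  expect_equal(nrow(main), 2L)
  expect_true(all(main$complete))
  expect_setequal(main$class, c("ARTERIOLE", "VENULE"))
})

test_that("pixel conservation: node pixels + segment interiors = skeleton", {
  for (seed in 1:5) {
    sc <- simulateScene(smallSceneParams(), seed = seed,
                        withChannels = FALSE)
    sk <- pruneSpurs(skeletonizeMask(sc$bloodMask), 5)
    gr <- buildGraph(skeletonizeMask(sc$bloodMask), sc$bloodMask,
                     minSpurLength = 5)
    isNode <- matrix(FALSE, nrow(sk), ncol(sk))
    for (np in nodePixelSets(gr)) isNode[np] <- TRUE
    seen <- matrix(0L, nrow(sk), ncol(sk))
    for (p in segmentPolylines(gr)) {
      keep <- !isNode[p]
      pi <- p[keep, , drop = FALSE]
      seen[pi] <- seen[pi] + 1L
    }
    # every interior pixel belongs to exactly one segment
    expect_true(all(seen[seen > 0] == 1L), info = sprintf("seed %d", seed))
    covered <- isNode | seen == 1L
    expect_identical(unname(which(covered)), unname(which(sk)),
                     info = sprintf("seed %d", seed))
    expect_true(validObject(gr))
  }
})

test_that("graph extraction matches the brute-force oracle on small masks", {
  # a slice of the acceptance suite; the full >= 500-case run lives in
  # the acceptance tests
  nbad <- 0
  for (seed in 1:80) {
    fg <- randomBlobMask(12, seed)
    m <- randomClassMask(fg, seed)
    sk <- skeletonizeMask(m)
    if (!any(sk)) next
    gr <- buildGraph(sk, m, minSpurLength = 0)
    classes <- matrix(NA_integer_, 12, 12)
    classes[sk] <- maskGrid(m)[sk]
    want <- oracleGraph(sk, classes)
    got <- graphKeys(gr, classes)
    if (!identical(got, want)) nbad <- nbad + 1
    expect_identical(got, want, info = sprintf("seed %d", seed))
  }
  expect_equal(nbad, 0)
})

test_that("rasterized synthetic trees recover the true branching count", {
  p <- smallSceneParams(transitionRate = 0, undeterminedRate = 0,
                        branchingProb = 0.5)
  for (seed in 1:4) {
    net <- sampleNetwork(p, seed)
    segs <- net$segments
    # true branch points: interior tree points where >= 2 segments start
    starts <- paste(round(segs$r0, 1), round(segs$c0, 1), segs$tree)
    trueBranches <- sum(table(starts) >= 2)
    sc <- rasterizeNetwork(net, p)
    gr <- maskToGraph(sc$bloodMask, minSpurLength = 5)
    nd <- graphNodes(gr)
    measured <- sum(nd$kind == "BRANCHING" & !nd$artificial)
    expect_equal(measured, trueBranches, info = sprintf("seed %d", seed))
  }
})
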