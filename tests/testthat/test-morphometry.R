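# Path length, tortuosity, totals, segment statistics, area fractions.

test_that("path length follows the weighted step metric", {
  expect_equal(pathLength(cbind(1, 1:11)), 10)
  expect_equal(pathLength(cbind(1:6, 1:6)), 5 * sqrt(2))
  expect_equal(pathLength(cbind(1, 1:11), pixelSize = 0.5), 5)
  expect_error(pathLength(cbind(1, 1)), "2 pixels")
  expect_error(pathLength(cbind(c(1, 3), c(1, 1))), "8-neighbours")
})

test_that("tortuosity is the arc-chord ratio with unit clamp and loop guard", {
  expect_equal(tortuosity(cbind(1, 1:11)), 1)
  # L-path (0,0)->(0,5)->(5,5): path 10, chord 5 sqrt 2
  L <- rbind(cbind(1, 1:6), cbind(2:6, 6))
  expect_equal(tortuosity(L), sqrt(2), tolerance = 1e-12)
  # closed loop: flagged NA, not an error
  loop <- rbind(c(1, 1), c(1, 2), c(2, 2), c(2, 1), c(1, 1))
  tl <- tortuosity(loop)
  expect_true(is.na(tl))
  expect_match(attr(tl, "reason"), "loop")
})

test_that("tortuosity and area fraction are isometry invariant", {
  set.seed(5)
  for (rep in 1:10) {
    fg <- randomBlobMask(12, rep + 300)
    m <- maskFromLogical(fg)
    af <- vesselAreaFraction(m)[["vessel"]]
    g <- maskGrid(m)
    expect_equal(vesselAreaFraction(LabelMask(t(g)))[["vessel"]], af)
    expect_equal(vesselAreaFraction(LabelMask(g[nrow(g):1, ]))[["vessel"]], af)
    rot90 <- t(g)[ncol(g):1, , drop = FALSE]
    expect_equal(vesselAreaFraction(LabelMask(rot90))[["vessel"]], af)
  }
  # 90-degree rotation and flips are exact on the grid for tortuosity
  poly <- rbind(cbind(3, 3:9), cbind(4:8, 9))
  t0 <- tortuosity(poly)
  rot <- cbind(poly[, 2], 20 - poly[, 1])
  flip <- cbind(poly[, 1], 20 - poly[, 2])
  expect_equal(tortuosity(rot), t0)
  expect_equal(tortuosity(flip), t0)
})

test_that("rasterized semicircle: step-metric path length carries the known
           digitization bias over the analytic arc length", {
  # independent oracle: analytic arc length pi * r; the (1, sqrt 2) step
  # metric over-measures 8-connected digitizations by up to ~8%
  fg <- semicircleBand(40, 1.5)
  m <- maskFromLogical(fg)
  gr <- maskToGraph(m, minSpurLength = 5)
  st <- segmentTable(gr)
  expect_equal(nrow(st), 1L)
  expect_gt(st$length, 0.97 * pi * 40)
  expect_lt(st$length, 1.10 * pi * 40)
  expect_gt(st$tortuosity, 1.50)
  expect_lt(st$tortuosity, 1.72)
})

test_that("total vessel length sums all segments per class", {
  # empty graph -> zeros
  empty <- maskToGraph(LabelMask(matrix(0L, 10, 10)))
  expect_true(all(totalVesselLength(empty) == 0))

  # H-skeleton: total equals the sum of the 5 segment lengths
  m <- hMask()
  g <- buildGraph(maskGrid(m) > 0, m, minSpurLength = 0)
  st <- segmentTable(g)
  expect_equal(nrow(st), 5L)
  expect_equal(unname(totalVesselLength(g)["total"]), sum(st$length))

  # additivity over disjoint subgraphs
  g1 <- maskGrid(yMask()); g2 <- matrix(0L, 21, 21)
  g2[cbind(2:20, 2)] <- 1L
  both <- LabelMask(pmax(g1, g2))
  tA <- totalVesselLength(buildGraph(g1 > 0, LabelMask(g1), 0))
  tB <- totalVesselLength(buildGraph(g2 > 0, LabelMask(g2), 0))
  tAB <- totalVesselLength(buildGraph(pmax(g1, g2) > 0, both, 0))
  expect_equal(unname(tAB["total"]), unname(tA["total"] + tB["total"]))
})

test_that("segment statistics cover complete segments only", {
  # one complete segment of known length: H crossbar
  m <- hMask()
  g <- buildGraph(maskGrid(m) > 0, m, minSpurLength = 0)
  st <- segmentStatistics(g)
  ov <- st[st$class == "OVERALL", ]
  expect_equal(ov$n_complete, 1L)
  expect_equal(ov$mean_length, 10)            # crossbar cols 5..15
  expect_equal(ov$mean_tortuosity, 1)

  # Y graph: no complete segments -> flagged missing
  y <- yMask()
  gy <- buildGraph(maskGrid(y) > 0, y, minSpurLength = 0)
  sty <- segmentStatistics(gy)
  expect_equal(sty$n_complete[sty$class == "OVERALL"], 0L)
  expect_true(is.na(sty$mean_length[sty$class == "OVERALL"]))

  # recomputation oracle from the per-segment table on a random scene
  sc <- simulateScene(smallSceneParams(), seed = 31, withChannels = FALSE)
  gr <- maskToGraph(sc$bloodMask)
  st <- segmentStatistics(gr)
  tab <- segmentTable(gr)
  cmp <- tab[tab$complete, ]
  expect_equal(st$mean_length[st$class == "OVERALL"], mean(cmp$length))
  expect_equal(st$median_length[st$class == "OVERALL"], median(cmp$length))
  expect_equal(st$mean_tortuosity[st$class == "OVERALL"],
               mean(cmp$tortuosity, na.rm = TRUE))
  art <- cmp[tab$class[tab$complete] == "ARTERIOLE", ]
  expect_equal(st$mean_length[st$class == "ARTERIOLE"], mean(art$length))
})

test_that("vessel area fraction is non-background count over image area", {
  expect_equal(unname(vesselAreaFraction(
    LabelMask(matrix(0L, 8, 8)))["vessel"]), 0)
  g <- matrix(0L, 100, 100); g[1:10, ] <- LBL[["ARTERIOLE"]]
  expect_equal(unname(vesselAreaFraction(LabelMask(g))["vessel"]), 0.1)
  expect_equal(unname(vesselAreaFraction(LabelMask(g))["arteriole"]), 0.1)
  full <- matrix(LBL[["VENULE"]], 5, 5)
  expect_equal(unname(vesselAreaFraction(LabelMask(full))["vessel"]), 1)
})

test_that("summarizeImage assembles the per-image record consistently", {
  # empty mask -> all-zero record
  em <- LabelMask(matrix(0L, 16, 16), imageId = "empty")
  rec <- summarizeImage(maskToGraph(em), em)
  expect_equal(rec$total_length, 0)
  expect_equal(rec$n_complete_segments, 0L)
  expect_equal(rec$vessel_area_fraction, 0)

  # all-arteriole H: arteriole length is the whole network, tortuosity 1
  m <- hMask()
  gr <- buildGraph(maskGrid(m) > 0, m, minSpurLength = 0)
  rec <- summarizeImage(gr, m)
  expect_equal(rec$arteriole_length, rec$total_length)
  expect_equal(rec$mean_tortuosity, 1)
  expect_equal(rec$unit, "px")

  # id mismatch is an error
  other <- LabelMask(maskGrid(m), imageId = "other")
  expect_error(summarizeImage(gr, other), "derives from")

  # recomputation oracle on a synthetic scene
  sc <- simulateScene(smallSceneParams(), seed = 9, withChannels = FALSE)
  gg <- maskToGraph(sc$bloodMask)
  rec <- summarizeImage(gg, sc$bloodMask)
  tot <- totalVesselLength(gg)
  expect_equal(rec$total_length, unname(tot["total"]))
  expect_equal(rec$arteriole_length, unname(tot["arteriole"]))
  expect_gte(rec$total_length,
             rec$arteriole_length + rec$venule_length - 1e-9)
  af <- vesselAreaFraction(sc$bloodMask)
  expect_equal(rec$vessel_area_fraction, unname(af["vessel"]))
  expect_true(all(segmentTable(gg)$tortuosity >= 1, na.rm = TRUE))
})
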