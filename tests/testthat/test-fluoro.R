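# Fluorescence quantification: segmentation, alpha-SMA, PDPL measures.

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

test_that("classical vessel segmentation finds bright objects deterministically", {
  # zeros -> empty mask flagged degenerate
  z <- segmentVesselsClassical(matrix(0, 32, 32))
  expect_false(any(z))
  expect_true(isTRUE(attr(z, "degenerate")))

  # two bright bars on dim background
  set.seed(21)
  ch <- matrix(10, 64, 64)
  truthMask <- matrix(FALSE, 64, 64)
  truthMask[10:15, 5:60] <- TRUE
  truthMask[40:46, 5:60] <- TRUE
  ch[truthMask] <- 200
  ch <- ch + matrix(rnorm(64 * 64, 0, 2), 64, 64)
  got <- segmentVesselsClassical(pmax(ch, 0), smoothingScale = 1,
                                 minObjectPx = 5)
  expect_gte(dice(got, truthMask), 0.9)

  # determinism
  got2 <- segmentVesselsClassical(pmax(ch, 0), smoothingScale = 1,
                                  minObjectPx = 5)
  expect_identical(got, got2)

  # small objects removed
  ch2 <- matrix(0, 32, 32); ch2[5, 5] <- 100; ch2[20:28, 10:12] <- 100
  seg <- segmentVesselsClassical(ch2, smoothingScale = 0,
                                 thresholdRule = 50, minObjectPx = 5)
  expect_false(seg[5, 5])
  expect_true(any(seg[20:28, 10:12]))
})

test_that("alpha-SMA coverage is signal over vessel area", {
  mask <- matrix(FALSE, 20, 20); mask[1:10, 1:10] <- TRUE
  ch <- matrix(0, 20, 20); ch[mask] <- 10
  cov <- asmaCoverage(ch, mask)
  expect_equal(unname(cov["vessel_area"]), 100)
  expect_equal(unname(cov["ratio"]), 10)
  expect_equal(unname(asmaCoverage(matrix(0, 20, 20), mask)["ratio"]), 0)
  # zero-area mask: ratio flagged missing
  none <- asmaCoverage(ch, matrix(FALSE, 20, 20))
  expect_true(is.na(none["ratio"]))
  expect_error(asmaCoverage(ch, matrix(TRUE, 5, 5)), "shape")

  # brute-force summation oracle on random inputs
  set.seed(3)
  for (rep in 1:5) {
    ch <- matrix(runif(400, 0, 50), 20, 20)
    mk <- matrix(runif(400) < 0.3, 20, 20)
    s <- 0
    for (r in 1:20) for (c in 1:20) if (mk[r, c]) s <- s + ch[r, c]
    cov <- asmaCoverage(ch, mk)
    expect_equal(unname(cov["signal"]), s)
    expect_equal(unname(cov["ratio"]), s / sum(mk))
  }
})

test_that("vessel plus stromal signal equals total, exactly", {
  set.seed(4)
  for (rep in 1:10) {
    ch <- matrix(runif(900, 0, 80), 30, 30)
    mk <- matrix(runif(900) < runif(1, 0.1, 0.6), 30, 30)
    expect_equal(unname(asmaCoverage(ch, mk)["signal"]) +
                   stromalAsma(ch, mk), sum(ch), tolerance = 1e-12)
  }
  ch <- matrix(runif(100, 1, 5), 10, 10)
  expect_equal(stromalAsma(ch, matrix(FALSE, 10, 10)), sum(ch))
  expect_equal(stromalAsma(ch, matrix(TRUE, 10, 10)), 0)
})

test_that("coverage ratio is intensive under tile duplication", {
  set.seed(6)
  ch <- matrix(runif(100, 0, 30), 10, 10)
  mk <- matrix(runif(100) < 0.4, 10, 10)
  ch2 <- rbind(cbind(ch, ch), cbind(ch, ch))
  mk2 <- rbind(cbind(mk, mk), cbind(mk, mk))
  a <- asmaCoverage(ch, mk); b <- asmaCoverage(ch2, mk2)
  expect_equal(unname(b["ratio"]), unname(a["ratio"]))
  expect_equal(unname(b["signal"]), 4 * unname(a["signal"]))
  expect_equal(unname(b["vessel_area"]), 4 * unname(a["vessel_area"]))
})

test_that("PDPL vessel fraction is lymphatic pixels over image area", {
  expect_equal(pdplVesselFraction(matrix(FALSE, 10, 10)), 0)
  half <- matrix(FALSE, 10, 10); half[1:5, ] <- TRUE
  expect_equal(pdplVesselFraction(half), 0.5)
  g <- matrix(0L, 10, 10); g[2:4, ] <- LBL[["LYMPHATIC"]]
  expect_equal(pdplVesselFraction(LabelMask(g)), 0.3)
})

test_that("PDPL cell counting: threshold, area gate, vessel exclusion", {
  expect_equal(countPdplCells(matrix(0, 40, 40), matrix(FALSE, 40, 40),
                              intensityThreshold = 50), 0L)

  # 7 disjoint disks off-vessel
  ch <- matrix(0, 80, 80)
  lymph <- matrix(FALSE, 80, 80); lymph[35:45, ] <- TRUE
  ctrs <- cbind(c(8, 8, 8, 20, 20, 60, 70), c(10, 30, 55, 10, 70, 20, 60))
  for (i in 1:7) {
    for (dr in -3:3) for (dc in -3:3) {
      if (dr^2 + dc^2 <= 9) ch[ctrs[i, 1] + dr, ctrs[i, 2] + dc] <- 200
    }
  }
  expect_equal(countPdplCells(ch, lymph, intensityThreshold = 100,
                              areaRange = c(5, 100)), 7L)

  # a disk fully inside the vessel mask is not counted
  ch2 <- ch
  for (dr in -3:3) for (dc in -3:3) {
    if (dr^2 + dc^2 <= 9) ch2[40 + dr, 40 + dc] <- 200
  }
  expect_equal(countPdplCells(ch2, lymph, intensityThreshold = 100,
                              areaRange = c(5, 100)), 7L)

  # sub-threshold background noise does not change the count
  set.seed(12)
  noisy <- pmax(ch + matrix(rnorm(6400, 0, 5), 80, 80), 0)
  expect_equal(countPdplCells(noisy, lymph, intensityThreshold = 100,
                              areaRange = c(5, 100)), 7L)

  expect_error(countPdplCells(ch, lymph, areaRange = c(10, 5)), "exceeds")
})

test_that("lymphatic morphometry reuses the skeleton machinery", {
  # thick lymphatic H (width 3): the crossbar between the two junctions
  # is the one complete segment, of about the centerline length 20
  fg <- matrix(FALSE, 41, 41)
  fg[5:35, 9:11] <- TRUE
  fg[5:35, 29:31] <- TRUE
  fg[19:21, 9:31] <- TRUE
  g <- matrix(0L, 41, 41); g[fg] <- LBL[["LYMPHATIC"]]
  lm <- lymphaticMorphometry(LabelMask(g), minSpurLength = 4)
  expect_equal(unname(lm["n_complete"]), 1)
  # junction nodes sit inside the crossing area, so the measured crossbar
  # is the 20 px centerline distance minus up to ~1 px at each junction
  expect_gte(unname(lm["mean_segment_length"]), 17.5)
  expect_lte(unname(lm["mean_segment_length"]), 21)

  # empty mask -> missing value
  le <- lymphaticMorphometry(matrix(FALSE, 16, 16))
  expect_true(is.na(le["mean_segment_length"]))
  expect_equal(unname(le["total_length"]), 0)
})

test_that("quantifyFluorescence assembles a conserving record", {
  sc <- simulateScene(sceneParams(size = 256, noiseSigma = 0),
                      seed = 5, withChannels = TRUE)
  lymphFg <- maskGrid(sc$lymphMask) == LBL[["LYMPHATIC"]]
  rec <- quantifyFluorescence(sc$channels, lymphMask = lymphFg)
  expect_equal(rec$asma_vessel_signal + rec$asma_stromal_signal,
               sum(getChannel(sc$channels, "asma")))
  expect_equal(rec$pdpl_vessel_fraction, pdplVesselFraction(lymphFg))
  expect_true(rec$pdpl_cell_count >= 0)
})
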