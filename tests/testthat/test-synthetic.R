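# Synthetic scene generator: determinism, analytic truth, rasterization,
# channels, cohorts.

test_that("networks are reproducible and truth is self-consistent", {
  p <- smallSceneParams()
  n1 <- sampleNetwork(p, seed = 17)
  n2 <- sampleNetwork(p, seed = 17)
  expect_identical(n1$segments, n2$segments)
  n3 <- sampleNetwork(p, seed = 18)
  expect_false(identical(n1$segments, n3$segments))
  # per-class totals equal sums of per-segment truth lengths, exactly
  for (cl in names(n1$truth$perClassLength)) {
    expect_identical(unname(n1$truth$perClassLength[[cl]]),
                     sum(n1$segments$trueLength[n1$segments$class == cl]))
  }
})

test_that("zero curvature gives straight chords with tortuosity exactly 1", {
  p <- smallSceneParams(curvatureAmplitude = c(arteriole = 0, venule = 0))
  net <- sampleNetwork(p, seed = 4)
  expect_true(all(net$segments$trueTortuosity == 1))
  expect_equal(net$segments$trueLength, net$segments$trueChord)
})

test_that("analytic arc lengths match dense polygonal quadrature", {
  p <- smallSceneParams()
  net <- sampleNetwork(p, seed = 23)
  segs <- net$segments[sample(nrow(net$segments), 8), ]
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    # oracle: polygonal length at 10x the rasterizer's sampling density
    d <- c(s$r1 - s$r0, s$c1 - s$c0)
    L <- sqrt(sum(d^2)); nh <- c(-d[2], d[1]) / L
    t <- seq(0, 1, length.out = 10 * ceiling(s$trueLength / 0.4))
    off <- s$amp * sin(pi * s$halfWaves * t)
    pts <- cbind(s$r0 + t * d[1] + off * nh[1],
                 s$c0 + t * d[2] + off * nh[2])
    poly <- sum(sqrt(rowSums(diff(pts)^2)))
    expect_equal(s$trueLength, poly, tolerance = 1e-6,
                 info = sprintf("segment %d", s$id))
    expect_gte(s$trueTortuosity, 1)
  }
})

test_that("rasterization realizes the recorded pixel counts exactly", {
  p <- smallSceneParams(includeLymphatics = TRUE)
  sc <- simulateScene(p, seed = 6, withChannels = FALSE)
  counts <- sc$truth$pixelCounts
  g <- maskGrid(sc$bloodMask)
  expect_identical(unname(counts[["arteriole"]]),
                   sum(g == LBL[["ARTERIOLE"]]))
  expect_identical(unname(counts[["venule"]]), sum(g == LBL[["VENULE"]]))
  af <- vesselAreaFraction(sc$bloodMask)
  expect_identical(
    unname(af["vessel"]),
    unname((counts[["arteriole"]] + counts[["venule"]] +
              counts[["undetermined"]]) / sc$truth$imageArea))
  expect_identical(pdplVesselFraction(sc$lymphMask),
                   unname(counts[["lymphatic"]] / sc$truth$imageArea))

  # a single straight bar, width 3, length 50: about 150 vessel pixels
  seg <- data.frame(class = "ARTERIOLE", underlying = "ARTERIOLE",
                    tree = 1, depth = 1, r0 = 40, c0 = 20, r1 = 40,
                    c1 = 70, amp = 0, halfWaves = 1, width = 3,
                    trueChord = 50, trueLength = 50, trueTortuosity = 1,
                    id = 1, terminal = FALSE)
  net <- list(segments = seg, truth = list(perClassLength =
                c(ARTERIOLE = 50)))
  bar <- rasterizeNetwork(net, smallSceneParams(size = 128))
  nv <- sum(maskGrid(bar$bloodMask) > 0)
  expect_gte(nv, 135); expect_lte(nv, 175)

  # empty network -> all background
  empt <- rasterizeNetwork(list(segments = data.frame(),
                                truth = list(perClassLength = numeric())),
                           smallSceneParams())
  expect_true(all(maskGrid(empt$bloodMask) == LBL[["BACKGROUND"]]))
})

test_that("rendered channels carry exact noiseless truth", {
  p <- sceneParams(size = 256, noiseSigma = 0, stromalPatchCount = 0)
  sc <- simulateScene(p, seed = 13, withChannels = TRUE)
  # no patches, no noise: stromal signal is exactly zero
  expect_equal(sc$truth$asmaStromalSignal, 0)
  bloodFg <- maskGrid(sc$bloodMask) != LBL[["BACKGROUND"]]
  expect_equal(sc$truth$asmaVesselSignal,
               sum(getChannel(sc$channels, "asma")[bloodFg]))
  # cell count recovered exactly at zero noise
  lymphFg <- maskGrid(sc$lymphMask) == LBL[["LYMPHATIC"]]
  got <- countPdplCells(getChannel(sc$channels, "pdpl"), lymphFg,
                        intensityThreshold = 100, areaRange = c(5, 200))
  expect_equal(got, sc$truth$cellCount)

  # doubling the gain doubles the true vessel signal
  p2 <- sceneParams(size = 256, noiseSigma = 0, stromalPatchCount = 0,
                    asmaGain = 2)
  sc2 <- simulateScene(p2, seed = 13, withChannels = TRUE)
  expect_equal(sc2$truth$asmaVesselSignal, 2 * sc$truth$asmaVesselSignal)
})

test_that("cohorts are reproducible and carry the injected effect in truth", {
  p <- smallSceneParams()
  co1 <- makeCohort(p, effectSpec(), nAnimals = c(2, 2),
                    imagesPerAnimal = 2, seed = 5)
  co2 <- makeCohort(p, effectSpec(), nAnimals = c(2, 2),
                    imagesPerAnimal = 2, seed = 5)
  expect_identical(co1$plan, co2$plan)
  s1 <- cohortScene(co1, 3); s2 <- cohortScene(co2, 3)
  expect_identical(maskGrid(s1$bloodMask), maskGrid(s2$bloodMask))

  # arteriolar shortening shows up in the ground truth at the right size
  eff <- effectSpec(arterioleLengthFactor = 0.75)
  co <- makeCohort(smallSceneParams(size = 320), eff, nAnimals = c(5, 5),
                   imagesPerAnimal = 8, seed = 11)
  tr <- cohortTruth(co)
  gm <- tapply(tr$true_arteriole_length, tr$group, mean)
  ratio <- gm[["OVX"]] / gm[["CONTROL"]]
  expect_gt(ratio, 0.65); expect_lt(ratio, 0.85)
  # venules carry no injected effect; the band reflects sampling noise
  # (about 6% SE on each group mean at 4 animals x 6 images)
  gv <- tapply(tr$true_venule_length, tr$group, mean)
  expect_gt(gv[["OVX"]] / gv[["CONTROL"]], 0.8)
  expect_lt(gv[["OVX"]] / gv[["CONTROL"]], 1.2)
})

test_that("parameter validation rejects nonsense", {
  expect_error(sceneParams(size = 32), "size")
  expect_error(sceneParams(branchingProb = 1.5))
  expect_error(sceneParams(vesselWidth = c(arteriole = 0, venule = 4)))
  expect_error(effectSpec(arterioleLengthFactor = 0))
  expect_error(effectSpec(lymphaticAreaFactor = -1))
})
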