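## Synthetic dural vascular scenes with exact analytic ground truth.
##
## Centerlines are analytic curves (a chord plus a perpendicular
## sinusoidal perturbation), so true path length and tortuosity come from
## quadrature, independent of the pipeline's discrete estimators. All
## randomness flows from one master seed via counter-based derivation.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

deriveSeed <- function(master, counter) {
  ((as.numeric(master) * 48271 + as.numeric(counter) * 7919) %%
     2147483629) + 1
}

#' Scene generator parameters
#'
#' The stated world of the synthetic generator: 512 x 512 maximum-
#' projection-style fields with interdigitating arteriolar and venular
#' trees anchored on the image border, curved centerlines with
#' controllable tortuosity, a lymphatic network along a virtual suture
#' band, an alpha-SMA channel concentrated on vessels plus stromal
#' patches, and PDPL-positive vessels plus isolated cell puncta.
#'
#' @param size image side in pixels (square), >= 64. Default 512.
#' @param nTrees named integer vector, trees per blood class.
#' @param branchingProb probability that a growing tip splits in two.
#' @param maxDepth maximum tree depth.
#' @param segmentLengthMedian named numeric (px): log-normal median of
#'   segment length per class.
#' @param segmentLengthSigma log-sd of segment length.
#' @param curvatureAmplitude named numeric: perpendicular sinusoidal
#'   amplitude as a fraction of the chord (0 = straight). Default 0.15
#'   per class, giving baseline tortuosities around 1.05.
#' @param vesselWidth named numeric (px), >= 1.
#' @param transitionRate probability a continuing path switches class
#'   (creates a transition point).
#' @param undeterminedRate probability a segment is annotated
#'   undetermined (visual ambiguity).
#' @param lymphNPaths,lymphWidth,lymphLengthMedian,lymphCurvature,
#'   lymphBandFraction,lymphBranchProb lymphatic network along the suture
#'   band: path count, width (px), segment length median, curvature,
#'   band height fraction, side-branch probability.
#' @param vesselChannelIntensity,asmaVesselIntensity,asmaGain vessel
#'   marker and alpha-SMA band intensities (arbitrary units).
#' @param stromalPatchCount,stromalPatchIntensity,stromalPatchRadius
#'   Poisson mean count, intensity and radius range (px) of stromal
#'   alpha-SMA patches.
#' @param pdplVesselIntensity,pdplCellRate,pdplCellRadius,
#'   pdplCellIntensity PDPL channel: vessel intensity, Poisson mean cell
#'   count, cell radius (px) and intensity.
#' @param noiseSigma additive Gaussian noise sd (clipped at 0);
#'   `poissonNoise` replaces it with Poisson shot noise.
#' @param poissonNoise logical toggle.
#' @param includeLymphatics grow the lymphatic network (default TRUE);
#'   blood-vessel draws are unaffected by this switch, so blood masks are
#'   reproducible either way.
#' @return A validated parameter list of class `duravascSceneParams`.
#' @export
sceneParams <- function(size = 512,
                        nTrees = c(arteriole = 3, venule = 3),
                        branchingProb = 0.35,
                        maxDepth = 4,
                        segmentLengthMedian = c(arteriole = 60, venule = 60),
                        segmentLengthSigma = 0.3,
                        curvatureAmplitude = c(arteriole = 0.15,
                                               venule = 0.15),
                        vesselWidth = c(arteriole = 4, venule = 5),
                        transitionRate = 0.12,
                        undeterminedRate = 0.05,
                        lymphNPaths = 3,
                        lymphWidth = 8,
                        lymphLengthMedian = 110,
                        lymphCurvature = 0.10,
                        lymphBandFraction = 0.4,
                        lymphBranchProb = 0.6,
                        vesselChannelIntensity = 180,
                        asmaVesselIntensity = 120,
                        asmaGain = 1,
                        stromalPatchCount = 6,
                        stromalPatchIntensity = 60,
                        stromalPatchRadius = c(8, 20),
                        pdplVesselIntensity = 150,
                        pdplCellRate = 12,
                        pdplCellRadius = 3,
                        pdplCellIntensity = 200,
                        noiseSigma = 5,
                        poissonNoise = FALSE,
                        includeLymphatics = TRUE) {
  p <- list(size = size, nTrees = nTrees, branchingProb = branchingProb,
            maxDepth = maxDepth, segmentLengthMedian = segmentLengthMedian,
            segmentLengthSigma = segmentLengthSigma,
            curvatureAmplitude = curvatureAmplitude,
            vesselWidth = vesselWidth, transitionRate = transitionRate,
            undeterminedRate = undeterminedRate, lymphNPaths = lymphNPaths,
            lymphWidth = lymphWidth, lymphLengthMedian = lymphLengthMedian,
            lymphCurvature = lymphCurvature,
            lymphBandFraction = lymphBandFraction,
            lymphBranchProb = lymphBranchProb,
            vesselChannelIntensity = vesselChannelIntensity,
            asmaVesselIntensity = asmaVesselIntensity, asmaGain = asmaGain,
            stromalPatchCount = stromalPatchCount,
            stromalPatchIntensity = stromalPatchIntensity,
            stromalPatchRadius = stromalPatchRadius,
            pdplVesselIntensity = pdplVesselIntensity,
            pdplCellRate = pdplCellRate, pdplCellRadius = pdplCellRadius,
            pdplCellIntensity = pdplCellIntensity, noiseSigma = noiseSigma,
            poissonNoise = poissonNoise,
            includeLymphatics = includeLymphatics)
  stopifnot(size >= 64,
            all(c("arteriole", "venule") %in% names(nTrees)),
            branchingProb >= 0, branchingProb <= 1,
            transitionRate >= 0, transitionRate <= 1,
            undeterminedRate >= 0, undeterminedRate <= 1,
            lymphBranchProb >= 0, lymphBranchProb <= 1,
            all(vesselWidth >= 1), lymphWidth >= 1,
            all(segmentLengthMedian > 0), segmentLengthSigma >= 0,
            all(curvatureAmplitude >= 0), noiseSigma >= 0,
            all(vesselWidth < size), lymphWidth < size)
  class(p) <- "duravascSceneParams"
  p
}

#' Group-level effect specification
#'
#' Multiplicative / additive effects injected into a group's scene
#' parameters, encoding directions of microvascular remodeling:
#' arteriolar shortening (`arterioleLengthFactor < 1`), raised arteriolar
#' curvature (higher tortuosity), lymphatic expansion
#' (`lymphaticAreaFactor > 1`), more PDPL-positive cells, elevated
#' alpha-SMA.
#'
#' @param arterioleLengthFactor,venuleLengthFactor multiply the class's
#'   segment-length median (< 1 shortens). Default 1.
#' @param arterioleCurvatureDelta,venuleCurvatureDelta added to the
#'   class's curvature amplitude. Default 0.
#' @param lymphaticAreaFactor multiplies lymphatic vessel width (> 1
#'   expands area). Default 1.
#' @param pdplCellRateFactor multiplies the PDPL cell Poisson mean.
#' @param asmaGainFactor multiplies alpha-SMA gain.
#' @return A list of class `duravascEffectSpec`.
#' @export
effectSpec <- function(arterioleLengthFactor = 1, venuleLengthFactor = 1,
                       arterioleCurvatureDelta = 0,
                       venuleCurvatureDelta = 0,
                       lymphaticAreaFactor = 1, pdplCellRateFactor = 1,
                       asmaGainFactor = 1) {
  e <- list(arterioleLengthFactor = arterioleLengthFactor,
            venuleLengthFactor = venuleLengthFactor,
            arterioleCurvatureDelta = arterioleCurvatureDelta,
            venuleCurvatureDelta = venuleCurvatureDelta,
            lymphaticAreaFactor = lymphaticAreaFactor,
            pdplCellRateFactor = pdplCellRateFactor,
            asmaGainFactor = asmaGainFactor)
  stopifnot(arterioleLengthFactor > 0, venuleLengthFactor > 0,
            lymphaticAreaFactor > 0, pdplCellRateFactor > 0,
            asmaGainFactor > 0,
            arterioleCurvatureDelta >= 0, venuleCurvatureDelta >= 0)
  class(e) <- "duravascEffectSpec"
  e
}

applyEffect <- function(params, effect) {
  stopifnot(inherits(effect, "duravascEffectSpec"))
  params$segmentLengthMedian["arteriole"] <-
    params$segmentLengthMedian["arteriole"] * effect$arterioleLengthFactor
  params$segmentLengthMedian["venule"] <-
    params$segmentLengthMedian["venule"] * effect$venuleLengthFactor
  params$curvatureAmplitude["arteriole"] <-
    params$curvatureAmplitude["arteriole"] + effect$arterioleCurvatureDelta
  params$curvatureAmplitude["venule"] <-
    params$curvatureAmplitude["venule"] + effect$venuleCurvatureDelta
  params$lymphWidth <- params$lymphWidth * effect$lymphaticAreaFactor
  params$pdplCellRate <- params$pdplCellRate * effect$pdplCellRateFactor
  params$asmaGain <- params$asmaGain * effect$asmaGainFactor
  params
}

## true arc length of P(t) = p0 + t d + A sin(pi h t) n_hat, t in [0, 1]
arcLengthQuad <- function(chord, amp, halfWaves) {
  if (amp == 0) return(chord)
  f <- function(t) sqrt(chord^2 + (amp * pi * halfWaves *
                                     cos(pi * halfWaves * t))^2)
  integrate(f, 0, 1, rel.tol = 1e-10)$value
}

## dense analytic centerline points of one segment (continuous coords)
segmentPoints <- function(seg, spacing = 0.4) {
  d <- c(seg$r1 - seg$r0, seg$c1 - seg$c0)
  L <- sqrt(sum(d^2))
  nhat <- c(-d[2L], d[1L]) / L
  n <- max(2L, ceiling(seg$trueLength / spacing))
  t <- seq(0, 1, length.out = n)
  off <- seg$amp * sin(pi * seg$halfWaves * t)
  cbind(seg$r0 + t * d[1L] + off * nhat[1L],
        seg$c0 + t * d[2L] + off * nhat[2L])
}

## Occupancy-aware growth: a shared logical grid records already-placed
## vessel corridors. A proposed segment is rejected when its test corridor
## (half-width + 2.5 px clearance) hits occupied pixels outside the
## junction vicinity of its start point, and the tip redraws (up to 4
## attempts). Accepted segments mark a slightly narrower corridor
## (half-width + 1 px), so distinct vessels keep a >= 2 px gap and the
## rasterized classes never touch or merge. This emulates the largely
## non-overlapping, interdigitating arteriolar/venular territories of 2D
## projections and keeps measured skeleton length close to analytic truth.

.diskCache <- new.env(parent = emptyenv())

diskOffsets <- function(rho) {
  key <- sprintf("%.4f", rho)
  if (!is.null(.diskCache[[key]])) return(.diskCache[[key]])
  rr <- seq(-ceiling(rho), ceiling(rho))
  off <- as.matrix(expand.grid(dr = rr, dc = rr))
  off <- off[off[, 1L]^2 + off[, 2L]^2 <= rho^2 + 1e-9, , drop = FALSE]
  .diskCache[[key]] <- off
  off
}

segmentPixels <- function(seg, rho, size, spacing = 1) {
  pts <- segmentPoints(seg, spacing = spacing)
  off <- diskOffsets(rho)
  pr <- rep(round(pts[, 1L]), each = nrow(off)) + off[, 1L]
  pc <- rep(round(pts[, 2L]), each = nrow(off)) + off[, 2L]
  ok <- pr >= 1 & pr <= size & pc >= 1 & pc <= size
  cbind(pr[ok], pc[ok])
}

proposeSegment <- function(pt, theta, len, relAmp, width, size) {
  p1 <- pt + len * c(cos(theta), sin(theta))
  p1 <- pmin(pmax(p1, 6), size - 5)
  d <- p1 - pt
  chord <- sqrt(sum(d^2))
  if (chord < 12) return(NULL)
  amp <- sample(c(-1, 1), 1L) * min(relAmp * chord, 12)
  halfWaves <- sample(1:2, 1L, prob = c(0.7, 0.3))
  arc <- arcLengthQuad(chord, amp, halfWaves)
  list(r0 = pt[1L], c0 = pt[2L], r1 = p1[1L], c1 = p1[2L], amp = amp,
       halfWaves = halfWaves, width = width, trueChord = chord,
       trueLength = arc, p1 = p1, theta = atan2(d[2L], d[1L]))
}

## Try to place a segment against the occupancy grid held in `env$occ`.
## A colliding proposal is retried with a fresh direction and a
## progressively shorter length (a vessel stops short of an obstacle
## rather than vanishing): discarding blocked tips outright would delete
## whole subtrees preferentially in the *less* crowded group and distort
## injected group effects away from their nominal factors.
placeSegment <- function(pt, theta0, relAmp, med, sigma, width, size, env) {
  lenScale <- c(1, 1, 0.7, 0.55, 0.4, 0.3)
  len0 <- rlnorm(1L, log(med), sigma)
  len0 <- min(max(len0, 15), 2.5 * med)
  for (attempt in seq_along(lenScale)) {
    len <- max(len0 * lenScale[attempt], 13)
    theta <- theta0 + rnorm(1L, 0, 0.18)
    cand <- proposeSegment(pt, theta, len, relAmp, width, size)
    if (is.null(cand)) next
    test <- segmentPixels(cand, width / 2 + 2.5, size, spacing = 1.5)
    nearStart <- (test[, 1L] - pt[1L])^2 + (test[, 2L] - pt[2L])^2 <=
      (width + 4)^2
    if (any(env$occ[test[!nearStart, , drop = FALSE]])) next
    env$occ[segmentPixels(cand, width / 2 + 1, size, spacing = 1.5)] <- TRUE
    return(cand)
  }
  NULL
}

## assemble collected per-segment lists into one data.frame
mkSegDF <- function(rows) {
  if (!length(rows)) return(NULL)
  f <- function(nm, typ) vapply(rows, function(r) r[[nm]], typ)
  data.frame(class = f("class", ""), underlying = f("underlying", ""),
             tree = f("tree", 0), depth = f("depth", 0),
             r0 = f("r0", 0), c0 = f("c0", 0), r1 = f("r1", 0),
             c1 = f("c1", 0), amp = f("amp", 0),
             halfWaves = f("halfWaves", 0), width = f("width", 0),
             trueChord = f("trueChord", 0), trueLength = f("trueLength", 0),
             trueTortuosity = f("trueLength", 0) / f("trueChord", 0),
             stringsAsFactors = FALSE)
}

## grow one tree; returns a data.frame of segment rows
growTree <- function(root, theta0, class0, treeId, params, env) {
  size <- params$size
  rows <- list()
  tips <- list(list(pt = root, theta = theta0, depth = 1L, class = class0))
  while (length(tips)) {
    tip <- tips[[1L]]; tips <- tips[-1L]
    if (tip$depth > params$maxDepth) next
    cand <- placeSegment(tip$pt, tip$theta,
                         params$curvatureAmplitude[[tip$class]],
                         params$segmentLengthMedian[[tip$class]],
                         params$segmentLengthSigma,
                         params$vesselWidth[[tip$class]], size, env)
    if (is.null(cand)) next
    annotated <- if (runif(1L) < params$undeterminedRate) "UNDETERMINED"
                 else toupper(tip$class)
    rows[[length(rows) + 1L]] <- list(
      class = annotated, underlying = toupper(tip$class),
      tree = as.numeric(treeId), depth = as.numeric(tip$depth),
      r0 = cand$r0, c0 = cand$c0, r1 = cand$r1, c1 = cand$c1,
      amp = cand$amp, halfWaves = as.numeric(cand$halfWaves),
      width = cand$width, trueChord = cand$trueChord,
      trueLength = cand$trueLength)
    if (tip$depth < params$maxDepth) {
      if (runif(1L) < params$branchingProb) {
        spread <- runif(1L, 0.35, 0.8)
        tips <- c(tips, list(
          list(pt = cand$p1, theta = cand$theta + spread,
               depth = tip$depth + 1L, class = tip$class),
          list(pt = cand$p1, theta = cand$theta - spread,
               depth = tip$depth + 1L, class = tip$class)))
      } else {
        cls <- tip$class
        if (runif(1L) < params$transitionRate) {
          cls <- if (cls == "arteriole") "venule" else "arteriole"
        }
        tips <- c(tips, list(
          list(pt = cand$p1, theta = cand$theta + rnorm(1L, 0, 0.25),
               depth = tip$depth + 1L, class = cls)))
      }
    }
  }
  mkSegDF(rows)
}

growLymphatics <- function(params, env) {
  size <- params$size
  band <- params$lymphBandFraction * size / 2
  rows <- list()
  asRow <- function(cand, treeId, depth) {
    list(class = "LYMPHATIC", underlying = "LYMPHATIC",
         tree = as.numeric(treeId), depth = as.numeric(depth),
         r0 = cand$r0, c0 = cand$c0, r1 = cand$r1, c1 = cand$c1,
         amp = cand$amp, halfWaves = as.numeric(cand$halfWaves),
         width = cand$width, trueChord = cand$trueChord,
         trueLength = cand$trueLength)
  }
  for (i in seq_len(params$lymphNPaths)) {
    r <- size / 2 + runif(1L, -band, band)
    pt <- c(r, 8)
    theta <- pi / 2                         # along the suture band
    depth <- 1L
    while (pt[2L] < size - 20 && depth <= 5L) {
      cand <- placeSegment(pt, theta, params$lymphCurvature,
                           params$lymphLengthMedian, 0.25,
                           params$lymphWidth, size, env)
      if (is.null(cand)) break
      rows[[length(rows) + 1L]] <- asRow(cand, 1000L + i, depth)
      if (runif(1L) < params$lymphBranchProb) {
        bth <- cand$theta + sample(c(-1, 1), 1L) * runif(1L, 0.7, 1.2)
        bc <- placeSegment(cand$p1, bth, params$lymphCurvature,
                           params$lymphLengthMedian / 2.5, 0.3,
                           params$lymphWidth, size, env)
        if (!is.null(bc)) {
          rows[[length(rows) + 1L]] <- asRow(bc, 1000L + i, depth + 1L)
        }
      }
      pt <- cand$p1
      ## keep heading along the band, re-centering drifting paths
      theta <- pi / 2 + 0.3 * (size / 2 - pt[1L]) / max(band, 1) +
        rnorm(1L, 0, 0.1)
      depth <- depth + 1L
    }
  }
  mkSegDF(rows)
}

#' Sample a synthetic vascular network
#'
#' Grows planar arteriolar and venular trees from border-anchored roots
#' (alternating classes and borders, so the trees interdigitate), plus a
#' lymphatic network along the suture band. Each segment's centerline is
#' a chord with a perpendicular sinusoidal perturbation; its true arc
#' length is computed by quadrature. Class transitions are inserted along
#' continuing paths at the configured rate. Fully reproducible for a
#' fixed seed.
#'
#' @param params a [sceneParams()] list.
#' @param seed integer seed.
#' @return List with `segments` (data.frame of analytic segment records:
#'   class, endpoints, amplitude, width, `trueChord`, `trueLength`,
#'   `trueTortuosity`) and `truth` (per-class true total lengths).
#' @export
sampleNetwork <- function(params, seed = 1) {
  stopifnot(inherits(params, "duravascSceneParams"))
  withSeed(seed, {
    size <- params$size
    nA <- params$nTrees[["arteriole"]]; nV <- params$nTrees[["venule"]]
    classes <- rep(c("arteriole", "venule"), length.out = nA + nV)
    ntot <- length(classes)
    segs <- list()
    ## blood vessels and lymphatics live on separate occupancy grids:
    ## they are different stains and may overlap in projection
    envB <- new.env(); envB$occ <- matrix(FALSE, size, size)
    ## root positions interleave classes along the borders, but venule
    ## trees are *placed* first: placement on the shared occupancy grid
    ## must not let arteriolar parameters influence venular geometry
    ## (class-specific effects act on their own class only)
    roots <- lapply(seq_len(ntot), function(i) {
      frac <- (i - 0.5) / ntot_safe(ntot)
      col0 <- min(max(frac * size + runif(1L, -12, 12), 14), size - 13)
      top <- (i %% 2L == 1L)
      list(root = c(if (top) 1 else size, col0),
           theta0 = (if (top) 0 else pi) + rnorm(1L, 0, 0.15),
           class = classes[i], id = i)
    })
    for (rt in roots[order(match(classes, c("venule", "arteriole")))]) {
      tr <- growTree(rt$root, rt$theta0, rt$class, rt$id, params, envB)
      if (!is.null(tr)) segs[[length(segs) + 1L]] <- tr
    }
    if (isTRUE(params$includeLymphatics)) {
      envL <- new.env(); envL$occ <- matrix(FALSE, size, size)
      ly <- growLymphatics(params, envL)
      if (!is.null(ly)) segs[[length(segs) + 1L]] <- ly
    }
    segments <- if (length(segs)) do.call(rbind, segs) else
      data.frame()
    if (nrow(segments)) {
      segments$id <- seq_len(nrow(segments))
      ## terminal tips (no child segment starts at this segment's end):
      ## rasterized with butt ends so the painted vessel's centerline
      ## extent matches the recorded analytic length
      segments$terminal <- vapply(seq_len(nrow(segments)), function(i) {
        same <- segments$tree == segments$tree[i]
        !any(same & abs(segments$r0 - segments$r1[i]) < 0.5 &
               abs(segments$c0 - segments$c1[i]) < 0.5)
      }, TRUE)
    }
    perClass <- if (nrow(segments))
      tapply(segments$trueLength, segments$class, sum) else numeric()
    list(segments = segments,
         truth = list(perClassLength = perClass,
                      nSegments = nrow(segments)))
  })
}

ntot_safe <- function(n) if (n > 0) n else 1

#' Rasterize a synthetic network into label masks
#'
#' Dilates each analytic centerline to its class width and paints it into
#' a blood-vessel [LabelMask-class] (and a separate lymphatic mask).
#' Overlaps are resolved arteriole-over-venule (painting order:
#' undetermined, venule, arteriole), recorded in the returned truth.
#' Realized per-class pixel counts are exact by construction, so
#' [vesselAreaFraction()] of the mask equals the truth count ratio
#' exactly.
#'
#' @param network from [sampleNetwork()].
#' @param params the same [sceneParams()].
#' @param imageId,animalId,group identifiers for the masks.
#' @param pixelSize micrometers per pixel.
#' @return List: `bloodMask`, `lymphMask` ([LabelMask-class]), `truth`
#'   (segment records, per-class true lengths, realized pixel counts,
#'   overlap policy).
#' @export
rasterizeNetwork <- function(network, params, imageId = "scene",
                             animalId = "animal", group = "GROUP",
                             pixelSize = 1) {
  size <- params$size
  lv <- maskLabels()
  blood <- matrix(lv[["BACKGROUND"]], size, size)
  lymph <- matrix(lv[["BACKGROUND"]], size, size)
  segs <- network$segments
  paint <- function(grid, seg, code) {
    pts <- segmentPoints(seg, spacing = 0.6)
    if (isTRUE(seg$terminal)) {
      ## butt cap: stop the stamp half a width before the analytic tip
      keep <- ceiling(nrow(pts) * max(0, 1 - (seg$width / 2) /
                                        seg$trueLength))
      pts <- pts[seq_len(max(2L, keep)), , drop = FALSE]
    }
    rho <- seg$width / 2
    off <- diskOffsets(rho)
    pr <- rep(round(pts[, 1L]), each = nrow(off)) + off[, 1L]
    pc <- rep(round(pts[, 2L]), each = nrow(off)) + off[, 2L]
    ok <- pr >= 1 & pr <= size & pc >= 1 & pc <= size
    grid[cbind(pr[ok], pc[ok])] <- code
    grid
  }
  if (nrow(segs)) {
    for (cl in c("UNDETERMINED", "VENULE", "ARTERIOLE")) {
      for (i in which(segs$class == cl)) {
        blood <- paint(blood, segs[i, ], lv[[cl]])
      }
    }
    for (i in which(segs$class == "LYMPHATIC")) {
      lymph <- paint(lymph, segs[i, ], lv[["LYMPHATIC"]])
    }
  }
  storage.mode(blood) <- "integer"
  storage.mode(lymph) <- "integer"
  counts <- c(arteriole = sum(blood == lv[["ARTERIOLE"]]),
              venule = sum(blood == lv[["VENULE"]]),
              undetermined = sum(blood == lv[["UNDETERMINED"]]),
              lymphatic = sum(lymph == lv[["LYMPHATIC"]]))
  truth <- network$truth
  truth$segments <- segs
  truth$pixelCounts <- counts
  truth$imageArea <- size * size
  truth$overlapPolicy <- "arteriole over venule over undetermined"
  list(bloodMask = LabelMask(blood, pixelSize, imageId, animalId, group),
       lymphMask = LabelMask(lymph, pixelSize,
                             paste0(imageId, "_lymph"), animalId, group),
       truth = truth)
}

#' Render fluorescence channels for a rasterized scene
#'
#' Builds the `vessel`, `asma` and `pdpl` channels: the vessel marker on
#' blood vessels; alpha-SMA as a vessel-band intensity (times gain) plus
#' random stromal patches; PDPL on lymphatic vessels plus isolated
#' off-vessel cell disks (count Poisson-distributed, positions rejected
#' against the lymphatic mask). Additive Gaussian noise (clipped at 0) or
#' Poisson shot noise is applied last. The returned truth records the
#' noiseless vessel/stromal alpha-SMA signals (which sum exactly to the
#' noiseless total) and the realized cell count and positions.
#'
#' @param scene from [rasterizeNetwork()].
#' @param params the same [sceneParams()].
#' @param seed integer seed (channel noise and cell placement).
#' @return List: `channels` ([MultiChannelImage-class]), `truth` (scene
#'   truth extended with channel ground truth).
#' @export
renderChannels <- function(scene, params, seed = 1) {
  size <- params$size
  lv <- maskLabels()
  bloodFg <- maskGrid(scene$bloodMask) != lv[["BACKGROUND"]]
  lymphFg <- maskGrid(scene$lymphMask) == lv[["LYMPHATIC"]]
  withSeed(seed + 1, {
    vessel0 <- matrix(0, size, size)
    vessel0[bloodFg] <- params$vesselChannelIntensity
    asma0 <- matrix(0, size, size)
    asma0[bloodFg] <- params$asmaGain * params$asmaVesselIntensity
    nPatch <- rpois(1L, params$stromalPatchCount)
    diskAt <- function(grid, center, radius, intensity) {
      rr <- seq(-ceiling(radius), ceiling(radius))
      off <- expand.grid(dr = rr, dc = rr)
      off <- off[off$dr^2 + off$dc^2 <= radius^2, , drop = FALSE]
      pr <- round(center[1L]) + off$dr
      pc <- round(center[2L]) + off$dc
      ok <- pr >= 1 & pr <= size & pc >= 1 & pc <= size
      idx <- cbind(pr[ok], pc[ok])
      grid[idx] <- grid[idx] + intensity
      grid
    }
    for (i in seq_len(nPatch)) {
      asma0 <- diskAt(asma0, runif(2L, 1, size),
                      runif(1L, params$stromalPatchRadius[1L],
                            params$stromalPatchRadius[2L]),
                      params$stromalPatchIntensity)
    }
    pdpl0 <- matrix(0, size, size)
    pdpl0[lymphFg] <- params$pdplVesselIntensity
    nCells <- rpois(1L, params$pdplCellRate)
    placed <- 0L
    cellPos <- matrix(numeric(), ncol = 2L)
    tries <- 0L
    rad <- params$pdplCellRadius
    ## cells must stay clear of lymphatic vessels and of each other by at
    ## least one pixel so each renders as its own connected component
    blocked <- lymphFg
    while (placed < nCells && tries < 50L * max(nCells, 1L)) {
      tries <- tries + 1L
      ctr <- runif(2L, rad + 3, size - rad - 2)
      ext <- ceiling(rad) + 1L
      rr <- round(ctr[1L]) + seq(-ext, ext)
      cc <- round(ctr[2L]) + seq(-ext, ext)
      rr <- rr[rr >= 1 & rr <= size]; cc <- cc[cc >= 1 & cc <= size]
      if (any(blocked[rr, cc])) next
      pdpl0 <- diskAt(pdpl0, ctr, rad, params$pdplCellIntensity)
      blocked[rr, cc] <- TRUE
      cellPos <- rbind(cellPos, ctr)
      placed <- placed + 1L
    }
    addNoise <- function(m) {
      if (params$poissonNoise) {
        matrix(rpois(length(m), lambda = m), nrow(m), ncol(m))
      } else if (params$noiseSigma > 0) {
        pmax(m + matrix(rnorm(length(m), 0, params$noiseSigma),
                        nrow(m), ncol(m)), 0)
      } else m
    }
    channels <- MultiChannelImage(
      list(vessel = addNoise(vessel0), asma = addNoise(asma0),
           pdpl = addNoise(pdpl0)),
      pixelSize = pixelSize(scene$bloodMask),
      imageId = imageId(scene$bloodMask),
      animalId = animalId(scene$bloodMask),
      group = groupName(scene$bloodMask))
    truth <- scene$truth
    truth$asmaVesselSignal <- sum(asma0[bloodFg])
    truth$asmaStromalSignal <- sum(asma0) - truth$asmaVesselSignal
    truth$asmaTotalSignal <- sum(asma0)
    truth$cellCount <- placed
    truth$cellPositions <- cellPos
    list(channels = channels, truth = truth)
  })
}

#' Simulate one complete scene
#'
#' [sampleNetwork()] then [rasterizeNetwork()] and optionally
#' [renderChannels()], under one seed.
#'
#' @inheritParams rasterizeNetwork
#' @param params a [sceneParams()] list.
#' @param seed integer seed.
#' @param withChannels render fluorescence channels (default TRUE).
#' @return List: `bloodMask`, `lymphMask`, `channels` (or `NULL`),
#'   `truth`.
#' @export
simulateScene <- function(params = sceneParams(), seed = 1,
                          withChannels = TRUE, imageId = "scene",
                          animalId = "animal", group = "GROUP",
                          pixelSize = 1) {
  net <- sampleNetwork(params, seed)
  scene <- rasterizeNetwork(net, params, imageId = imageId,
                            animalId = animalId, group = group,
                            pixelSize = pixelSize)
  if (withChannels) {
    rc <- renderChannels(scene, params, seed)
    scene$channels <- rc$channels
    scene$truth <- rc$truth
  } else {
    scene$channels <- NULL
  }
  scene
}

#' Assemble a two-group synthetic cohort
#'
#' Builds a control and an effect group of animals with
#' `imagesPerAnimal` scenes each, mirroring the study design (default 4
#' control and 5 treated animals, 10 images per animal). Each animal
#' receives small log-normal random effects (sd `animalSigma`, default
#' 0.05): a size factor on segment-length medians and lymphatic width,
#' and an intensity factor on alpha-SMA gain and PDPL cell rate — this
#' makes per-animal averaging consequential. The group effect is applied
#' on top via [effectSpec()]. Per-image seeds derive deterministically
#' from the master seed, so a fixed master seed reproduces the cohort
#' exactly. Scenes are materialized lazily via [cohortScene()] to keep
#' memory flat.
#'
#' @param controlParams baseline [sceneParams()].
#' @param effect an [effectSpec()] applied to the second group.
#' @param nAnimals integer pair `c(control, treated)`, each >= 2.
#' @param imagesPerAnimal images per animal (default 10).
#' @param seed master seed.
#' @param groupNames labels, default `c("CONTROL", "OVX")`.
#' @param animalSigma log-sd of animal random effects.
#' @return A `duravascCohort`: `plan` data.frame (image_id, animal_id,
#'   group, seed), `paramsByAnimal`, plus the inputs.
#' @export
makeCohort <- function(controlParams = sceneParams(),
                       effect = effectSpec(),
                       nAnimals = c(4, 5), imagesPerAnimal = 10,
                       seed = 1, groupNames = c("CONTROL", "OVX"),
                       animalSigma = 0.05) {
  stopifnot(length(nAnimals) == 2L, all(nAnimals >= 2L),
            imagesPerAnimal >= 1L)
  animals <- c(sprintf("%s_%d", groupNames[1L], seq_len(nAnimals[1L])),
               sprintf("%s_%d", groupNames[2L], seq_len(nAnimals[2L])))
  groupOf <- rep(groupNames, nAnimals)
  paramsByAnimal <- withSeed(deriveSeed(seed, 0), {
    lapply(seq_along(animals), function(i) {
      p <- controlParams
      if (groupOf[i] == groupNames[2L]) p <- applyEffect(p, effect)
      sizeF <- rlnorm(1L, 0, animalSigma)
      intF <- rlnorm(1L, 0, animalSigma)
      p$segmentLengthMedian <- p$segmentLengthMedian * sizeF
      p$lymphLengthMedian <- p$lymphLengthMedian * sizeF
      p$lymphWidth <- p$lymphWidth * sizeF
      p$asmaGain <- p$asmaGain * intF
      p$pdplCellRate <- p$pdplCellRate * intF
      p
    })
  })
  names(paramsByAnimal) <- animals
  plan <- do.call(rbind, lapply(seq_along(animals), function(i) {
    data.frame(
      image_id = sprintf("%s_img%02d", animals[i], seq_len(imagesPerAnimal)),
      animal_id = animals[i], group = groupOf[i],
      seed = vapply(seq_len(imagesPerAnimal), function(k)
        deriveSeed(seed, (i - 1L) * imagesPerAnimal + k), 0),
      stringsAsFactors = FALSE)
  }))
  rownames(plan) <- NULL
  structure(list(plan = plan, paramsByAnimal = paramsByAnimal,
                 effect = effect, masterSeed = seed,
                 groupNames = groupNames, animalSigma = animalSigma),
            class = "duravascCohort")
}

#' Materialize one cohort scene
#'
#' @param cohort a [makeCohort()] object.
#' @param i row index into `cohort$plan`.
#' @param withChannels render fluorescence channels (default FALSE).
#' @return A scene list as from [simulateScene()].
#' @export
cohortScene <- function(cohort, i, withChannels = FALSE) {
  stopifnot(inherits(cohort, "duravascCohort"))
  row <- cohort$plan[i, ]
  simulateScene(cohort$paramsByAnimal[[row$animal_id]], seed = row$seed,
                withChannels = withChannels, imageId = row$image_id,
                animalId = row$animal_id, group = row$group)
}

#' Ground-truth table for a cohort
#'
#' Regenerates each scene's analytic network (no rasterization) and
#' returns per-image true per-class total lengths.
#'
#' @param cohort a [makeCohort()] object.
#' @return data.frame: image_id, animal_id, group, true lengths per class.
#' @export
cohortTruth <- function(cohort) {
  stopifnot(inherits(cohort, "duravascCohort"))
  rows <- lapply(seq_len(nrow(cohort$plan)), function(i) {
    row <- cohort$plan[i, ]
    net <- sampleNetwork(cohort$paramsByAnimal[[row$animal_id]],
                         seed = row$seed)
    pc <- net$truth$perClassLength
    g <- function(cl) if (cl %in% names(pc)) unname(pc[[cl]]) else 0
    data.frame(image_id = row$image_id, animal_id = row$animal_id,
               group = row$group,
               true_arteriole_length = g("ARTERIOLE"),
               true_venule_length = g("VENULE"),
               true_undetermined_length = g("UNDETERMINED"),
               true_lymphatic_length = g("LYMPHATIC"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.duravascCohort <- function(x, ...) {
  cat(sprintf("duravascCohort: %d images, %d animals, groups %s (seed %d)\n",
              nrow(x$plan), length(x$paramsByAnimal),
              paste(x$groupNames, collapse = " vs "), x$masterSeed))
  invisible(x)
}
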