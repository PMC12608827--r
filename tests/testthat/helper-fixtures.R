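# Shared fixtures: tiny deterministic masks, a vessel-like semicircular
# band, and reduced-size scene parameters used to keep simulation-heavy
# tests inside the suite's runtime budget (the generator defaults are the
# full 512 px stated world; these shrink the canvas, not the science).

LBL <- maskLabels()

# reduced scene for cohort-scale simulations (overridable defaults)
smallSceneParams <- function(...) {
  args <- list(size = 256, nTrees = c(arteriole = 3, venule = 3),
               maxDepth = 3,
               segmentLengthMedian = c(arteriole = 45, venule = 45),
               includeLymphatics = FALSE)
  over <- list(...)
  for (nm in names(over)) args[[nm]] <- over[[nm]]
  do.call(sceneParams, args)
}

maskFromLogical <- function(fg, class = "ARTERIOLE", ...) {
  g <- matrix(LBL[["BACKGROUND"]], nrow(fg), ncol(fg))
  g[fg] <- LBL[[class]]
  LabelMask(g, ...)
}

# Y: three arms meeting at (11, 11)
yMask <- function() {
  g <- matrix(0L, 21, 21)
  g[11, 2:11] <- 1L
  for (k in 0:9) { g[11 - k, 11 + k] <- 1L; g[11 + k, 11 + k] <- 1L }
  LabelMask(g)
}

# H: two vertical bars joined by a crossbar
hMask <- function() {
  g <- matrix(0L, 21, 21)
  g[2:20, 5] <- 1L
  g[2:20, 15] <- 1L
  g[11, 5:15] <- 1L
  LabelMask(g)
}

# vessel-like semicircular band: arc of radius r stamped with disks
semicircleBand <- function(r = 40, diskRadius = 1.5) {
  th <- seq(0, pi, length.out = 4000)
  h <- 2 * r + 60
  fg <- matrix(FALSE, h, 2 * r + 100)
  pr <- (r + 35) - r * sin(th)
  pc <- (r + 50) + r * cos(th)
  rr <- seq(-ceiling(diskRadius), ceiling(diskRadius))
  off <- as.matrix(expand.grid(rr, rr))
  off <- off[off[, 1]^2 + off[, 2]^2 <= diskRadius^2 + 1e-9, , drop = FALSE]
  prr <- rep(round(pr), each = nrow(off)) + off[, 1]
  pcc <- rep(round(pc), each = nrow(off)) + off[, 2]
  fg[cbind(prr, pcc)] <- TRUE
  fg
}

# random blob mask on a small canvas (rectangles + disks + strokes)
randomBlobMask <- function(n = 12, seed = 1) {
  set.seed(seed)
  fg <- matrix(FALSE, n, n)
  for (k in seq_len(sample(1:3, 1))) {
    shape <- sample(c("rect", "disk", "stroke"), 1)
    if (shape == "rect") {
      r0 <- sample(n, 1); c0 <- sample(n, 1)
      r1 <- min(n, r0 + sample(0:4, 1)); c1 <- min(n, c0 + sample(0:4, 1))
      fg[r0:r1, c0:c1] <- TRUE
    } else if (shape == "disk") {
      ctr <- sample(n, 2); rad <- sample(1:3, 1)
      for (r in 1:n) for (c in 1:n) {
        if ((r - ctr[1])^2 + (c - ctr[2])^2 <= rad^2) fg[r, c] <- TRUE
      }
    } else {
      r <- sample(n, 1); c <- sample(n, 1)
      for (s in 1:sample(3:8, 1)) {
        fg[r, c] <- TRUE
        r <- min(n, max(1, r + sample(-1:1, 1)))
        c <- min(n, max(1, c + sample(-1:1, 1)))
      }
    }
  }
  fg
}

# random two-class labelling of a foreground: split by a random line
randomClassMask <- function(fg, seed = 1) {
  set.seed(seed + 999)
  g <- matrix(LBL[["BACKGROUND"]], nrow(fg), ncol(fg))
  th <- runif(1, 0, pi)
  b <- runif(1, -nrow(fg) / 2, nrow(fg) / 2)
  for (r in seq_len(nrow(fg))) for (c in seq_len(ncol(fg))) {
    if (!fg[r, c]) next
    side <- (r - nrow(fg) / 2) * cos(th) + (c - ncol(fg) / 2) * sin(th) > b
    g[r, c] <- if (side) LBL[["ARTERIOLE"]] else LBL[["VENULE"]]
  }
  LabelMask(g)
}
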