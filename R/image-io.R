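## Reading and writing label masks, multi-channel images and z-stacks.
##
## Conventions owned here:
##  * coordinates are 0-based (row, col) in the C++ core and 1-based in R,
##    row-major, origin top-left (the raster convention);
##  * label masks are RGB PNG with an exact palette (defaultPalette());
##  * multi-channel images are one PNG per channel (16-bit precision via
##    high/low bytes in the R and G planes) plus a
##    JSON sidecar recording channel names, per-channel intensity scale,
##    pixel size and identifiers (no TIFF dependency is available);
##  * z-stacks are channel files per plane with the spacing in the sidecar.

sidecarPath <- function(path) paste0(path, ".json")

#' Read a label mask from a palette PNG
#'
#' Maps each pixel of an RGB (or grayscale) PNG to a vessel-class label by
#' exact colour match against `palette`. Any off-palette pixel is an error
#' reporting its coordinate and colour. A JSON sidecar (`<path>.json`),
#' written by [writeLabelMask()], restores pixel size and identifiers.
#'
#' @param path PNG file path.
#' @param palette palette data.frame as from [defaultPalette()].
#' @param pixelSize,imageId,animalId,group metadata used when no sidecar
#'   is present.
#' @return A [LabelMask-class].
#' @export
readLabelMask <- function(path, palette = defaultPalette(), pixelSize = 1,
                          imageId = basename(path), animalId = "animal",
                          group = "GROUP") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {      # grayscale: replicate to RGB
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  d <- dim(img)[1:2]
  r <- matrix(round(img[, , 1L] * 255), d[1L], d[2L])
  g <- matrix(round(img[, , 2L] * 255), d[1L], d[2L])
  b <- matrix(round(img[, , 3L] * 255), d[1L], d[2L])
  key <- r * 65536 + g * 256 + b
  palKey <- palette$r * 65536 + palette$g * 256 + palette$b
  idx <- match(key, palKey)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    rc <- arrayInd(bad, dim(key))
    stop(sprintf(
      "off-palette pixel at (row %d, col %d): rgb(%d, %d, %d) in %s",
      rc[1L], rc[2L], r[bad], g[bad], b[bad], path))
  }
  grid <- matrix(palette$code[idx], nrow(key), ncol(key))
  sc <- sidecarPath(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$pixel_size)) pixelSize <- meta$pixel_size
    if (!is.null(meta$image_id))   imageId <- meta$image_id
    if (!is.null(meta$animal_id))  animalId <- meta$animal_id
    if (!is.null(meta$group))      group <- meta$group
  }
  LabelMask(grid, pixelSize = pixelSize, imageId = imageId,
            animalId = animalId, group = group)
}

#' Write a label mask as a palette PNG (with JSON sidecar)
#'
#' Lossless inverse of [readLabelMask()]: the round trip reproduces the
#' grid bit-exactly and the sidecar preserves pixel size and identifiers.
#'
#' @param mask a [LabelMask-class].
#' @param path output PNG path.
#' @param palette palette data.frame as from [defaultPalette()].
#' @return `path`, invisibly.
#' @export
writeLabelMask <- function(mask, path, palette = defaultPalette()) {
  stopifnot(is(mask, "LabelMask"))
  g <- mask@grid
  idx <- match(g, palette$code)
  arr <- array(0, dim = c(nrow(g), ncol(g), 3L))
  arr[, , 1L] <- palette$r[idx] / 255
  arr[, , 2L] <- palette$g[idx] / 255
  arr[, , 3L] <- palette$b[idx] / 255
  png::writePNG(arr, target = path)
  jsonlite::write_json(
    list(pixel_size = mask@pixelSize, image_id = mask@imageId,
         animal_id = mask@animalId, group = mask@group),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## one PNG per channel with 16-bit precision: the normalized intensity is
## split into high/low bytes stored in the R and G planes (the installed
## png writer is 8-bit per plane), with the per-channel scale recorded in
## the sidecar, so arbitrary dynamic range survives to ~1/65535
writeChannelPNG <- function(mat, path) {
  mx <- max(mat)
  scale <- if (mx > 0) mx else 1
  q <- round(mat / scale * 65535)
  arr <- array(0, dim = c(nrow(mat), ncol(mat), 3L))
  arr[, , 1L] <- (q %/% 256) / 255
  arr[, , 2L] <- (q %% 256) / 255
  png::writePNG(arr, target = path)
  scale
}

readChannelPNG <- function(path, scale) {
  a <- png::readPNG(path)
  d <- dim(a)[1:2]
  hi <- matrix(round(a[, , 1L] * 255), d[1L], d[2L])
  lo <- matrix(round(a[, , 2L] * 255), d[1L], d[2L])
  (hi * 256 + lo) / 65535 * scale
}

#' Write / read a multi-channel image
#'
#' `writeMultiChannelImage()` stores each channel as
#' `<prefix>_<channel>.png` (16-bit precision: normalized intensity split
#' into high/low bytes in the R and G planes, divided by a
#' recorded per-channel scale) and a sidecar `<prefix>.json` naming the
#' channels, scales, pixel size and identifiers.
#' `readMultiChannelImage()` restores the object (intensities to within
#' 16-bit quantisation).
#'
#' @param img a [MultiChannelImage-class].
#' @param prefix path prefix for the channel files and sidecar.
#' @return The sidecar path (write) or a [MultiChannelImage-class] (read).
#' @export
writeMultiChannelImage <- function(img, prefix) {
  stopifnot(is(img, "MultiChannelImage"))
  scales <- list()
  for (nm in names(img@channels)) {
    scales[[nm]] <- writeChannelPNG(img@channels[[nm]],
                                    sprintf("%s_%s.png", prefix, nm))
  }
  sc <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(channels = names(img@channels), scales = scales,
         pixel_size = img@pixelSize, image_id = img@imageId,
         animal_id = img@animalId, group = img@group),
    sc, auto_unbox = TRUE, digits = NA)
  invisible(sc)
}

#' @rdname writeMultiChannelImage
#' @export
readMultiChannelImage <- function(prefix) {
  sc <- paste0(prefix, ".json")
  if (!file.exists(sc)) stop(sprintf("sidecar not found: %s", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  ch <- lapply(seq_along(meta$channels), function(i) {
    nm <- meta$channels[[i]]
    readChannelPNG(sprintf("%s_%s.png", prefix, nm), meta$scales[[nm]])
  })
  names(ch) <- unlist(meta$channels)
  MultiChannelImage(ch, pixelSize = meta$pixel_size, imageId = meta$image_id,
                    animalId = meta$animal_id, group = meta$group)
}

#' Write / read a z-stack
#'
#' Planes are stored as `<prefix>_p###_<channel>.png` with one sidecar
#' `<prefix>.json` recording plane count, channel names, per-plane scales
#' and plane spacing.
#'
#' @param zstack a [ZStack-class].
#' @param prefix path prefix.
#' @return The sidecar path (write) or a [ZStack-class] (read).
#' @export
writeZStack <- function(zstack, prefix) {
  stopifnot(is(zstack, "ZStack"))
  p1 <- zstack@planes[[1L]]
  scales <- list()
  for (i in seq_along(zstack@planes)) {
    for (nm in names(p1@channels)) {
      f <- sprintf("%s_p%03d_%s.png", prefix, i, nm)
      scales[[sprintf("p%03d_%s", i, nm)]] <-
        writeChannelPNG(zstack@planes[[i]]@channels[[nm]], f)
    }
  }
  sc <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(n_planes = length(zstack@planes), channels = names(p1@channels),
         scales = scales, plane_spacing = zstack@planeSpacing,
         pixel_size = p1@pixelSize, image_id = p1@imageId,
         animal_id = p1@animalId, group = p1@group),
    sc, auto_unbox = TRUE, digits = NA)
  invisible(sc)
}

#' @rdname writeZStack
#' @export
readZStack <- function(prefix) {
  sc <- paste0(prefix, ".json")
  if (!file.exists(sc)) stop(sprintf("sidecar not found: %s", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  planes <- lapply(seq_len(meta$n_planes), function(i) {
    ch <- lapply(unlist(meta$channels), function(nm) {
      readChannelPNG(sprintf("%s_p%03d_%s.png", prefix, i, nm),
                     meta$scales[[sprintf("p%03d_%s", i, nm)]])
    })
    names(ch) <- unlist(meta$channels)
    MultiChannelImage(ch, pixelSize = meta$pixel_size,
                      imageId = meta$image_id, animalId = meta$animal_id,
                      group = meta$group)
  })
  ZStack(planes, planeSpacing = meta$plane_spacing)
}

#' Maximum-intensity projection of a z-stack
#'
#' Fuses a z-stack into a single [MultiChannelImage-class] by the per-pixel
#' maximum over planes, channel by channel. Identity on single-plane
#' stacks, idempotent and invariant to plane reordering.
#'
#' @param zstack a [ZStack-class] with at least one plane.
#' @return A [MultiChannelImage-class].
#' @export
#' @examples
#' p <- MultiChannelImage(list(vessel = matrix(3, 2, 2)))
#' q <- MultiChannelImage(list(vessel = matrix(7, 2, 2)))
#' maxProject(ZStack(list(p, q)))
maxProject <- function(zstack) {
  stopifnot(is(zstack, "ZStack"))
  if (length(zstack@planes) < 1L) stop("empty stack")
  p1 <- zstack@planes[[1L]]
  out <- p1@channels
  for (i in seq_along(zstack@planes)[-1L]) {
    for (nm in names(out)) {
      out[[nm]] <- pmax(out[[nm]], zstack@planes[[i]]@channels[[nm]])
    }
  }
  MultiChannelImage(out, pixelSize = p1@pixelSize, imageId = p1@imageId,
                    animalId = p1@animalId, group = p1@group)
}
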