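## Colourimetric image pipeline: segmentation, centre-region selection,
## channel statistics, capsule sizing.

#' Construct a CapsuleImage
#'
#' @param pixels numeric H x W x 3 array of channel intensities in
#'   [0, 2^bitDepth - 1].
#' @param sampleId sample identifier.
#' @param conc CaCl2 soaking concentration, millimolar.
#' @param scale micrometres per pixel.
#' @param bitDepth bits per channel.
#' @return a [CapsuleImage-class].
#' @export
capsuleImage <- function(pixels, sampleId = NA_character_, conc = NA_real_,
                         scale = NA_real_, bitDepth = 8L) {
  new("CapsuleImage", pixels = pixels, sampleId = as.character(sampleId),
      conc = as.numeric(conc), scale = as.numeric(scale),
      bitDepth = as.integer(bitDepth))
}

#' Read a capsule image from PNG or TIFF
#'
#' Greyscale images are expanded to three identical channels; an alpha
#' channel, if present, is dropped. Intensities are rescaled to [0, 255].
#'
#' @param path file path (.png, .tif or .tiff).
#' @inheritParams capsuleImage
#' @return a [CapsuleImage-class].
#' @export
readCapsuleImage <- function(path, sampleId = basename(path),
                             conc = NA_real_, scale = NA_real_) {
  if (!file.exists(path))
    csStop(sprintf("image not found: %s", path), "coreshell_io")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    csStop(sprintf("unsupported image format '.%s'", ext), "coreshell_io"))
  if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 2L) raw <- array(raw[, , 1L], c(dim(raw)[1:2], 3L))
  capsuleImage(raw * 255, sampleId = sampleId, conc = conc, scale = scale)
}

setMethod("show", "CapsuleImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CapsuleImage '%s': %d x %d px, %d-bit RGB\n",
              object@sampleId, d[1], d[2], object@bitDepth))
  cat(sprintf("  conc: %s mM, scale: %s um/px\n",
              format(object@conc), format(object@scale)))
  invisible(NULL)
})

#' @rdname SegmentationResult-class
#' @export
setMethod("capsuleMask", "SegmentationResult",
          function(object) object@capsuleMask)

#' @rdname SegmentationResult-class
#' @export
setMethod("backgroundMask", "SegmentationResult",
          function(object) object@backgroundMask)

setMethod("show", "SegmentationResult", function(object) {
  n <- length(object@capsuleMask)
  cat(sprintf("SegmentationResult: %d / %d px capsule (%.1f%%)\n",
              sum(object@capsuleMask), n,
              100 * sum(object@capsuleMask) / n))
  invisible(NULL)
})

## Deterministic initial centers for 2-means: a double-sweep approximation of
## the two most-distant pixel values. Anchor at the darkest pixel, take the
## farthest value from it, then the farthest value from that one.
.initCenters <- function(px) {
  lum <- rowMeans(px)
  a <- px[which.min(lum), ]
  d2 <- (px[, 1] - a[1])^2 + (px[, 2] - a[2])^2 + (px[, 3] - a[3])^2
  u1 <- px[which.max(d2), ]
  d2 <- (px[, 1] - u1[1])^2 + (px[, 2] - u1[2])^2 + (px[, 3] - u1[3])^2
  u2 <- px[which.max(d2), ]
  rbind(u1, u2, deparse.level = 0)
}

#' Segment a capsule image into capsule and background
#'
#' Two-cluster (k = 2) partition of the pixels in RGB space, Lloyd's
#' algorithm with deterministic initialisation (double-sweep approximation of
#' the two most-distant pixel values, anchored at the darkest pixel). Under
#' transmitted illumination the background is bright, so the cluster with the
#' lower mean luminance is the capsule. The largest connected component of
#' that cluster is retained and its holes are filled; if more than one
#' substantial component is present (multiple capsules in frame) the largest
#' is used and a warning is issued.
#'
#' @param image a [CapsuleImage-class].
#' @param ... unused.
#' @return a [SegmentationResult-class].
#' @section Errors: a \code{coreshell_no_capsule} error is raised for images
#'   with a single uniform colour or when the capsule cluster holds less than
#'   0.5\% of the pixels.
#' @export
setMethod("segmentCapsule", "CapsuleImage", function(image, ...) {
  p <- image@pixels
  n <- prod(dim(p)[1:2])
  px <- cbind(as.vector(p[, , 1]), as.vector(p[, , 2]), as.vector(p[, , 3]))
  centers <- .initCenters(px)
  if (sum((centers[1, ] - centers[2, ])^2) == 0)
    csStop("no capsule detected: image has a single uniform colour",
           "coreshell_no_capsule")
  km <- suppressWarnings(
    stats::kmeans(px, centers = centers, iter.max = 100L,
                  algorithm = "Lloyd"))
  dark <- which.min(rowMeans(km$centers))
  cap <- km$cluster == dark
  if (sum(cap) < 0.005 * n)
    csStop("no capsule detected: capsule cluster below 0.5% of pixels",
           "coreshell_no_capsule")
  m <- matrix(as.numeric(cap), nrow = dim(p)[1])
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  if (length(sizes) > 1L && sort(sizes, decreasing = TRUE)[2] >=
        0.1 * sizes[keep])
    warning("multiple capsule-sized components; keeping the largest",
            call. = FALSE)
  filled <- EBImage::fillHull(matrix(as.numeric(lab == keep),
                                     nrow = dim(p)[1]))
  capMask <- matrix(as.logical(filled > 0), nrow = dim(p)[1])
  if (sum(capMask) < 0.005 * n)
    csStop("no capsule detected: largest component below 0.5% of pixels",
           "coreshell_no_capsule")
  new("SegmentationResult", capsuleMask = capMask,
      backgroundMask = !capMask)
})

#' Select the centre sampling region of a segmented capsule
#'
#' A disc centred on the capsule-mask centroid with radius equal to
#' \code{fraction} times the equivalent-circle radius of the capsule mask.
#' The default fraction (0.1) keeps the disc safely over the optically clear
#' core for every shell thickness the fabrication process produces.
#'
#' @param seg a [SegmentationResult-class].
#' @param fraction disc radius as a fraction of the equivalent radius,
#'   in (0, 0.5].
#' @return logical matrix mask of the centre disc.
#' @section Errors: \code{coreshell_region} if the capsule mask is empty or
#'   the disc would extend outside it (highly eccentric mask).
#' @export
setMethod("centreRegion", "SegmentationResult",
  function(seg, fraction = 0.1) {
    if (fraction <= 0 || fraction > 0.5)
      csStop("'fraction' must lie in (0, 0.5]", "coreshell_domain")
    m <- seg@capsuleMask
    if (!any(m))
      csStop("capsule mask is empty", "coreshell_region")
    idx <- which(m, arr.ind = TRUE)
    ctr <- colMeans(idx)
    re <- sqrt(nrow(idx) / pi)
    r <- fraction * re
    rows <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
    cols <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
    disc <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= r^2
    if (!any(disc))  # degenerate tiny mask: keep the centroid pixel
      disc[round(ctr[1]), round(ctr[2])] <- TRUE
    if (any(disc & !m))
      csStop("centre disc extends outside the capsule mask",
             "coreshell_region")
    disc
  })

#' Extract centre-region and background colour statistics
#'
#' Channel means over the centre region and over the background, the latter
#' kept away from the capsule boundary by dilating the capsule mask by
#' \code{backgroundErosion} pixels (halo exclusion). Means are computed in
#' floating point. The derived metrics are filled by construction:
#' \code{metricR = RMean}, \code{metricRMinusBg = RMean - RBg},
#' \code{metricRMinusB = RMean - BMean}.
#'
#' @param image a [CapsuleImage-class].
#' @param centre logical centre-region mask (from [centreRegion()]).
#' @param seg the [SegmentationResult-class] for the image.
#' @param backgroundErosion margin, in pixels, between the capsule boundary
#'   and the sampled background.
#' @return a [ColourStats-class].
#' @export
extractColourStats <- function(image, centre, seg, backgroundErosion = 5) {
  if (!any(centre))
    csStop("centre mask is empty", "coreshell_region")
  bg <- seg@backgroundMask
  if (backgroundErosion > 0) {
    brush <- EBImage::makeBrush(2 * round(backgroundErosion) + 1, "disc")
    grown <- EBImage::dilate(matrix(as.numeric(seg@capsuleMask),
                                    nrow = nrow(bg)), brush)
    bg <- bg & !(as.matrix(grown) > 0)
  }
  if (!any(bg))
    csStop("background mask is empty after erosion", "coreshell_region")
  p <- image@pixels
  chan <- function(i, mask) mean(p[, , i][mask])
  RMean <- chan(1, centre); GMean <- chan(2, centre); BMean <- chan(3, centre)
  RBg <- chan(1, bg); GBg <- chan(2, bg); BBg <- chan(3, bg)
  new("ColourStats", RMean = RMean, GMean = GMean, BMean = BMean,
      RBg = RBg, GBg = GBg, BBg = BBg,
      metricR = RMean, metricRMinusBg = RMean - RBg,
      metricRMinusB = RMean - BMean)
}

#' @rdname ColourStats-class
#' @export
setMethod("metricRMinusB", "ColourStats",
          function(object) object@metricRMinusB)

setMethod("show", "ColourStats", function(object) {
  cat("ColourStats\n")
  cat(sprintf("  centre RGB: (%.1f, %.1f, %.1f)\n",
              object@RMean, object@GMean, object@BMean))
  cat(sprintf("  background RGB: (%.1f, %.1f, %.1f)\n",
              object@RBg, object@GBg, object@BBg))
  cat(sprintf("  R = %.2f, R-bg = %.2f, R-B = %.2f\n",
              object@metricR, object@metricRMinusBg, object@metricRMinusB))
  invisible(NULL)
})

#' @describeIn extractColourStats flatten a ColourStats into a one-row
#'   data.frame (columns R_mean, G_mean, B_mean, R_bg, G_bg, B_bg, metric_R,
#'   metric_R_minus_bg, R_minus_B).
#' @param x a \code{ColourStats}
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @export
as.data.frame.ColourStats <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
  data.frame(R_mean = x@RMean, G_mean = x@GMean, B_mean = x@BMean,
             R_bg = x@RBg, G_bg = x@GBg, B_bg = x@BBg,
             metric_R = x@metricR, metric_R_minus_bg = x@metricRMinusBg,
             R_minus_B = x@metricRMinusB)
}

#' Equivalent-circle outer radius of a segmented capsule
#'
#' \eqn{r = \sqrt{area/\pi} \times scale}. This is the outer radius (core
#' plus shell); the core radius used by the gelation model comes from the
#' direct measurements table.
#'
#' @param seg a [SegmentationResult-class].
#' @param scale micrometres per pixel (> 0).
#' @return outer radius in micrometres.
#' @export
setMethod("measureRadius", "SegmentationResult", function(seg, scale) {
  if (missing(scale) || length(scale) != 1L || is.na(scale))
    csStop("a micrometres-per-pixel scale is required", "coreshell_units")
  if (scale <= 0)
    csStop("'scale' must be positive", "coreshell_units")
  area <- sum(seg@capsuleMask)
  if (area == 0L)
    csStop("capsule mask is empty", "coreshell_region")
  sqrt(area / pi) * scale
})

#' Write a mask as a single-channel PNG for visual inspection
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow = nrow(mask)), path)
  invisible(path)
}
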