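# Segmentation, centre-region selection, colour statistics, sizing.

test_that("segmentation recovers a synthetic disc to within 2% area", {
  img <- discImage(side = 256, discs = list(
    list(row = 128, col = 128, radius = 80, rgb = c(150, 140, 130))),
    noise = 2, seed = 5)
  seg <- segmentCapsule(img)
  expect_lt(abs(sum(capsuleMask(seg)) - pi * 80^2) / (pi * 80^2), 0.02)
  expect_true(validObject(seg))
})

test_that("a single uniform colour raises no-capsule-detected", {
  img <- capsuleImage(array(200, c(64, 64, 3)))
  expect_error(segmentCapsule(img), class = "coreshell_no_capsule")
})

test_that("with two capsules in frame only the larger is kept", {
  img <- discImage(side = 300, discs = list(
    list(row = 110, col = 100, radius = 70, rgb = c(150, 140, 130)),
    list(row = 230, col = 230, radius = 40, rgb = c(150, 140, 130))))
  expect_warning(seg <- segmentCapsule(img), "largest")
  m <- capsuleMask(seg)
  rows <- matrix(seq_len(300), 300, 300); cols <- t(rows)
  small <- (rows - 230)^2 + (cols - 230)^2 <= 40^2
  expect_equal(sum(m & small), 0L)
  expect_lt(abs(sum(m) - pi * 70^2) / (pi * 70^2), 0.02)
})

test_that("segmentation masks are invariant to a global brightness offset", {
  base <- discImage(side = 160, bg = c(200, 198, 195), discs = list(
    list(row = 80, col = 80, radius = 50, rgb = c(140, 130, 120))),
    noise = 2, seed = 8)
  shifted <- capsuleImage(base@pixels + 20)
  expect_identical(capsuleMask(segmentCapsule(base)),
                   capsuleMask(segmentCapsule(shifted)))
})

test_that("segmentation fills interior holes of the capsule", {
  # bright core, dark shell ring: the filled mask must cover the core
  img <- discImage(side = 200, discs = list(
    list(row = 100, col = 100, radius = 60, rgb = c(150, 140, 130)),
    list(row = 100, col = 100, radius = 40, rgb = c(230, 228, 225))))
  seg <- segmentCapsule(img)
  expect_true(capsuleMask(seg)[100, 100])
  expect_lt(abs(sum(capsuleMask(seg)) - pi * 60^2) / (pi * 60^2), 0.02)
})

test_that("centreRegion selects a concentric disc of the right size", {
  img <- discImage(side = 256, discs = list(
    list(row = 128, col = 128, radius = 100, rgb = c(150, 140, 130))))
  seg <- segmentCapsule(img)
  ctr <- centreRegion(seg, fraction = 0.1)
  expect_lt(abs(sum(ctr) - pi * 10^2) / (pi * 10^2), 0.1)
  expect_true(all(capsuleMask(seg)[ctr]))
  # fraction 0.5: concentric discs, area ratio 25%
  half <- centreRegion(seg, fraction = 0.5)
  expect_lt(abs(sum(half) / sum(capsuleMask(seg)) - 0.25), 0.02)
})

test_that("centreRegion rejects bad fractions, empty and eccentric masks", {
  img <- discImage(side = 128, discs = list(
    list(row = 64, col = 64, radius = 40, rgb = c(150, 140, 130))))
  seg <- segmentCapsule(img)
  expect_error(centreRegion(seg, fraction = 0), class = "coreshell_domain")
  expect_error(centreRegion(seg, fraction = 0.6),
               class = "coreshell_domain")
  empty <- new("SegmentationResult",
               capsuleMask = matrix(FALSE, 64, 64),
               backgroundMask = matrix(TRUE, 64, 64))
  expect_error(centreRegion(empty), class = "coreshell_region")
  strip <- matrix(FALSE, 64, 64); strip[31:34, 5:60] <- TRUE
  eccentric <- new("SegmentationResult", capsuleMask = strip,
                   backgroundMask = !strip)
  expect_error(centreRegion(eccentric, fraction = 0.5),
               class = "coreshell_region")
})

test_that("colour statistics satisfy their defining identities", {
  img <- discImage(side = 200, bg = c(230, 228, 225), discs = list(
    list(row = 100, col = 100, radius = 60, rgb = c(180, 120, 60))))
  seg <- segmentCapsule(img)
  ctr <- centreRegion(seg)
  cs <- extractColourStats(img, ctr, seg)
  expect_lt(abs(cs@RMean - 180), 1)
  expect_lt(abs(cs@metricRMinusB - 120), 2)
  expect_lt(abs(cs@metricRMinusBg - (-50)), 2)
  # identities hold exactly by construction
  expect_identical(cs@metricR, cs@RMean)
  expect_identical(cs@metricRMinusBg, cs@RMean - cs@RBg)
  expect_identical(cs@metricRMinusB, cs@RMean - cs@BMean)
  expect_true(validObject(cs))
})

test_that("uniform colour over both masks gives the trivial metrics", {
  img <- capsuleImage(array(rep(c(200, 150, 100), each = 64 * 64),
                            c(64, 64, 3)))
  m <- matrix(FALSE, 64, 64); m[20:44, 20:44] <- TRUE
  seg <- new("SegmentationResult", capsuleMask = m, backgroundMask = !m)
  ctr <- matrix(FALSE, 64, 64); ctr[30:34, 30:34] <- TRUE
  cs <- extractColourStats(img, ctr, seg, backgroundErosion = 2)
  expect_equal(cs@metricRMinusB, 100)
  expect_equal(cs@metricRMinusBg, 0)
})

test_that("empty masks are rejected by extractColourStats", {
  img <- discImage(side = 128, discs = list(
    list(row = 64, col = 64, radius = 40, rgb = c(150, 140, 130))))
  seg <- segmentCapsule(img)
  none <- matrix(FALSE, 128, 128)
  expect_error(extractColourStats(img, none, seg),
               class = "coreshell_region")
  # erosion so large it consumes the whole background
  expect_error(extractColourStats(img, centreRegion(seg), seg,
                                  backgroundErosion = 70),
               class = "coreshell_region")
})

test_that("measureRadius returns the equivalent-circle outer radius", {
  img <- discImage(side = 256, discs = list(
    list(row = 128, col = 128, radius = 100, rgb = c(150, 140, 130))))
  seg <- segmentCapsule(img)
  expect_lt(abs(measureRadius(seg, 2) - 200) / 200, 0.02)
  one <- matrix(FALSE, 64, 64); one[32, 32] <- TRUE
  segOne <- new("SegmentationResult", capsuleMask = one,
                backgroundMask = !one)
  expect_equal(measureRadius(segOne, 3), sqrt(1 / pi) * 3)
  empty <- new("SegmentationResult", capsuleMask = matrix(FALSE, 64, 64),
               backgroundMask = matrix(TRUE, 64, 64))
  expect_error(measureRadius(empty, 2), class = "coreshell_region")
  expect_error(measureRadius(segOne, NA), class = "coreshell_units")
})

test_that("images round-trip through PNG and masks are writable", {
  img <- discImage(side = 64, discs = list(
    list(row = 32, col = 32, radius = 20, rgb = c(150, 140, 130))))
  p <- tempfile(fileext = ".png")
  png::writePNG(img@pixels / 255, p)
  back <- readCapsuleImage(p, conc = 10, scale = 4)
  expect_equal(back@pixels, img@pixels)
  expect_equal(back@conc, 10)
  mp <- tempfile(fileext = ".png")
  writeMask(capsuleMask(segmentCapsule(img)), mp)
  expect_true(file.exists(mp))
})
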