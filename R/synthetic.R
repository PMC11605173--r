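## Synthetic capsule-image generator: the in-package stand-in for the
## deposited microscopy data, with the statistical and optical structure the
## analysis pipeline assumes.

#' Construct optics parameters for the synthetic renderer
#'
#' The defaults are the package's study conditions. They were derived from
#' the model's own requirements rather than fitted to data: the scattering
#' term saturates the red channel within the first tens of micrometres of
#' shell (so the raw R metric flattens across the upper concentration range),
#' the blue absorption coefficient is small enough that R-B keeps growing,
#' monotonically and near-linearly, over the whole thickness range the
#' fabrication process produces, and the interface particle load reproduces
#' the threshold-like colour onset that makes extrapolated thickness negative
#' for shell-less capsules. See the methods vignette for the derivation.
#'
#' @param backgroundRGB background intensities (transmitted illumination,
#'   slightly warm white).
#' @param mu per-channel absorption, per micrometre of optical path;
#'   must satisfy mu_R < mu_G < mu_B.
#' @param noiseSigma Gaussian pixel noise, intensity units.
#' @param bitDepth bits per channel.
#' @param scatterCoef achromatic scattering, per micrometre of path.
#' @param diffuseFraction diffuse transmitted fraction in [0, 1].
#' @param surfaceLoad equivalent thickness of the interface particle layer,
#'   micrometres.
#' @param surfaceScale build-up scale of the interface layer, micrometres.
#' @param rimWidth refraction-rim width, micrometres.
#' @param rimDarkening colour-neutral multiplicative rim attenuation.
#' @return an [OpticsParams-class].
#' @export
opticsParams <- function(backgroundRGB = c(240, 238, 235),
                         mu = c(5e-6, 1e-4, 4e-4),
                         noiseSigma = 2, bitDepth = 8L,
                         scatterCoef = 0.015, diffuseFraction = 0.6,
                         surfaceLoad = 20, surfaceScale = 5,
                         rimWidth = 20, rimDarkening = 0.8) {
  new("OpticsParams", backgroundRGB = backgroundRGB, mu = mu,
      noiseSigma = noiseSigma, bitDepth = as.integer(bitDepth),
      scatterCoef = scatterCoef, diffuseFraction = diffuseFraction,
      surfaceLoad = surfaceLoad, surfaceScale = surfaceScale,
      rimWidth = rimWidth, rimDarkening = rimDarkening)
}

setMethod("show", "OpticsParams", function(object) {
  cat("OpticsParams (transmitted-light stand-in)\n")
  cat(sprintf("  background RGB: (%g, %g, %g), noise sigma %g, %d-bit\n",
              object@backgroundRGB[1], object@backgroundRGB[2],
              object@backgroundRGB[3], object@noiseSigma, object@bitDepth))
  cat(sprintf("  absorption mu (R,G,B): (%g, %g, %g) /um\n",
              object@mu[1], object@mu[2], object@mu[3]))
  cat(sprintf("  scattering %g /um, diffuse fraction %g\n",
              object@scatterCoef, object@diffuseFraction))
  cat(sprintf("  interface load %g um (scale %g um), rim %g um x %g\n",
              object@surfaceLoad, object@surfaceScale,
              object@rimWidth, object@rimDarkening))
  invisible(NULL)
})

## Per-channel transmittance along an optical path of length L (um).
.transmittance <- function(optics, L, channel) {
  mu <- optics@mu[channel]
  s <- optics@diffuseFraction
  (1 - s) * exp(-(mu + optics@scatterCoef) * L) + s * exp(-mu * L)
}

## Effective absorber thickness seen at the capsule centre: geometric shell
## thickness plus the saturating interface particle layer.
.effectiveThickness <- function(optics, h) {
  h + optics@surfaceLoad * (1 - exp(-h / optics@surfaceScale))
}

#' Closed-form centre colour of a rendered capsule
#'
#' The noiseless RGB intensity at the exact centre of a capsule of shell
#' thickness \code{h}: light crosses the shell twice (entering and leaving),
#' so the optical path is \eqn{L = 2 h_{eff}} with the interface layer
#' included in the effective thickness. This is the analytic ground truth
#' against which the image pipeline's centre-region means are validated.
#'
#' @param optics an [OpticsParams-class].
#' @param h shell thickness, micrometres (vectorized).
#' @return matrix with columns R, G, B (one row per h).
#' @export
centreColour <- function(optics, h) {
  stopifnot(is(optics, "OpticsParams"))
  L <- 2 * .effectiveThickness(optics, h)
  out <- sapply(1:3, function(ch)
    optics@backgroundRGB[ch] * .transmittance(optics, L, ch))
  out <- matrix(out, ncol = 3)
  colnames(out) <- c("R", "G", "B")
  out
}

#' Render a synthetic transmitted-light capsule image
#'
#' Spherical core-shell geometry projected onto the image plane. For a pixel
#' at lateral distance r from the capsule centre the line of sight traverses
#' a shell chord of length
#' \deqn{L(r) = 2\left(\sqrt{R_o^2 - r^2} - \sqrt{\max(R_c^2 - r^2, 0)}\right)}
#' with \eqn{R_o = R_c + h}, which reduces to 2h at the centre; sight lines
#' crossing the core (r < R_c) additionally pass the interface particle layer
#' twice. The optically clear core itself does not absorb. A colour-neutral
#' refraction rim darkens the outermost \code{rimWidth} micrometres of the
#' bead. Gaussian noise is added per pixel and channel, then values are
#' clipped to the bit range and rounded.
#'
#' @param Rc core radius, micrometres (> 0).
#' @param h shell thickness, micrometres (>= 0).
#' @param optics an [OpticsParams-class].
#' @param scale micrometres per pixel.
#' @param seed integer seed; renders are bit-identical for a fixed seed.
#' @param canvas optional canvas side in pixels (odd values centre the
#'   capsule on a pixel); defaults to 1.15 times the outer diameter.
#' @param sampleId,conc metadata stored on the returned image.
#' @return a [CapsuleImage-class].
#' @section Errors: \code{coreshell_geometry} if the capsule does not fit the
#'   requested canvas.
#' @export
renderCapsule <- function(Rc, h, optics = opticsParams(), scale = 8,
                          seed = 1L, canvas = NULL,
                          sampleId = NA_character_, conc = NA_real_) {
  if (Rc <= 0 || h < 0)
    csStop("need Rc > 0 and h >= 0", "coreshell_domain")
  Ro <- Rc + h
  if (is.null(canvas)) canvas <- 2L * ceiling(1.15 * Ro / scale) + 1L
  canvas <- as.integer(canvas)
  if (canvas * scale < 2 * Ro)
    csStop("capsule larger than the canvas", "coreshell_geometry")
  ctr <- (canvas + 1) / 2
  ix <- matrix(seq_len(canvas), canvas, canvas)
  r <- scale * sqrt((ix - ctr)^2 + (t(ix) - ctr)^2)
  inside <- r < Ro
  outer2 <- pmax(Ro^2 - r^2, 0)
  inner2 <- pmax(Rc^2 - r^2, 0)
  L <- 2 * (sqrt(outer2) - sqrt(inner2))
  surf <- 2 * optics@surfaceLoad * (1 - exp(-h / optics@surfaceScale))
  L <- L + surf * (r < Rc)
  L[!inside] <- 0
  rim <- inside & (r > Ro - optics@rimWidth)
  top <- 2^optics@bitDepth - 1
  img <- array(0, c(canvas, canvas, 3L))
  for (ch in 1:3) {
    plane <- optics@backgroundRGB[ch] * .transmittance(optics, L, ch)
    plane[rim] <- plane[rim] * optics@rimDarkening
    img[, , ch] <- plane
  }
  if (optics@noiseSigma > 0) {
    set.seed(as.integer(seed))
    img <- img + stats::rnorm(length(img), sd = optics@noiseSigma)
  }
  img <- round(pmin(pmax(img, 0), top))
  capsuleImage(img, sampleId = sampleId, conc = conc, scale = scale,
               bitDepth = optics@bitDepth)
}

#' Construct a scenario specification
#'
#' The defaults reproduce the shape of the fabrication experiment the
#' package analyses: soaking concentrations 0.1-100 mM on the standard grid,
#' four replicates per concentration, alpha = 0.033 per mM, no shell at or
#' below 2 mM, core radii uniform between 500 and 800 micrometres.
#'
#' @param alphaTrue generating proportionality constant, per millimolar.
#' @param concentrations CaCl2 soaking concentrations, millimolar.
#' @param replicates replicates per concentration.
#' @param RcRange core-radius range (min, max), micrometres.
#' @param formationThreshold no shell forms at conc <= this, millimolar.
#' @param scale micrometres per pixel.
#' @param seed root seed.
#' @return a [ScenarioSpec-class].
#' @export
scenarioSpec <- function(alphaTrue = 0.033,
                         concentrations = c(0.1, 1, 2, 5, 10, 15, 20,
                                            30, 50, 100),
                         replicates = 4L, RcRange = c(500, 800),
                         formationThreshold = 2, scale = 8, seed = 1L) {
  new("ScenarioSpec", alphaTrue = alphaTrue,
      concentrations = as.numeric(concentrations),
      replicates = as.integer(replicates), RcRange = as.numeric(RcRange),
      formationThreshold = formationThreshold, scale = scale,
      seed = as.integer(seed))
}

setMethod("show", "ScenarioSpec", function(object) {
  cat("ScenarioSpec\n")
  cat(sprintf("  alpha = %g /mM, formation threshold = %g mM\n",
              object@alphaTrue, object@formationThreshold))
  cat(sprintf("  %d concentrations x %d replicates, Rc ~ U(%g, %g) um\n",
              length(object@concentrations), object@replicates,
              object@RcRange[1], object@RcRange[2]))
  cat(sprintf("  scale %g um/px, seed %d\n", object@scale, object@seed))
  invisible(NULL)
})

#' Generate a full synthetic capsule dataset
#'
#' For every concentration and replicate: draw a core radius uniformly from
#' the scenario range, compute the true shell thickness from the gelation
#' model (zero at or below the formation threshold), render the capsule and
#' write it as PNG. Produces a manifest CSV (image_path, sample_id, conc_mM,
#' scale_um_per_px), a ground-truth CSV (sample_id, conc_mM, R_c_um,
#' h_true_um) and the scenario as YAML. Fully reproducible: all radii are
#' drawn from the root seed and each image gets a seed derived by counter.
#'
#' @param spec a [ScenarioSpec-class].
#' @param optics an [OpticsParams-class].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with elements \code{manifest},
#'   \code{groundTruth} (data.frames) and \code{dir}.
#' @export
generateDataset <- function(spec, optics = opticsParams(), outDir) {
  stopifnot(is(spec, "ScenarioSpec"), is(optics, "OpticsParams"))
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    csStop(sprintf("cannot create output directory '%s'", outDir),
           "coreshell_io")
  conc <- rep(spec@concentrations, each = spec@replicates)
  repl <- rep(seq_len(spec@replicates), times = length(spec@concentrations))
  n <- length(conc)
  set.seed(spec@seed)
  Rc <- stats::runif(n, spec@RcRange[1], spec@RcRange[2])
  h <- ifelse(conc > spec@formationThreshold,
              predictThickness(spec@alphaTrue, conc, Rc), 0)
  sampleId <- sprintf("c%s_r%02d", gsub("\\.", "p", format(conc,
                      trim = TRUE, scientific = FALSE)), repl)
  imagePath <- paste0(sampleId, ".png")
  for (i in seq_len(n)) {
    img <- renderCapsule(Rc[i], h[i], optics = optics, scale = spec@scale,
                         seed = spec@seed + i, sampleId = sampleId[i],
                         conc = conc[i])
    png::writePNG(img@pixels / (2^optics@bitDepth - 1),
                  file.path(outDir, imagePath[i]))
  }
  manifest <- data.frame(image_path = imagePath, sample_id = sampleId,
                         conc_mM = conc, scale_um_per_px = spec@scale)
  groundTruth <- data.frame(sample_id = sampleId, conc_mM = conc,
                            R_c_um = Rc, h_true_um = h)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(groundTruth, file.path(outDir, "ground_truth.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(
    alpha_true = spec@alphaTrue, concentrations = spec@concentrations,
    replicates_per_conc = spec@replicates, R_c_range_um = spec@RcRange,
    formation_threshold_mM = spec@formationThreshold,
    scale_um_per_px = spec@scale, seed = spec@seed),
    file.path(outDir, "scenario.yaml"))
  invisible(list(manifest = manifest, groundTruth = groundTruth,
                 dir = outDir))
}
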