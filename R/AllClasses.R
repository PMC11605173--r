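#' @import methods
NULL

## Internal helper: structured errors so callers/tests can dispatch on class.
csStop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "coreshell_error")))
}

#' ShellModel: the volumetric gelation model
#'
#' Holds the proportionality constant \eqn{\alpha} of the volumetric
#' ionotropic-gelation model, in which the alginate shell volume is
#' proportional to the moles of calcium loaded into the core,
#' \eqn{V_s = \alpha\, n_{Ca^{2+}}}, giving the thickness law
#' \eqn{h = R_c\left((\alpha\,[Ca^{2+}] + 1)^{1/3} - 1\right)}.
#'
#' @slot alpha proportionality constant, per millimolar; strictly positive.
#' @slot rss residual sum of squares of the through-origin fit on the
#'   linearized scale (NA for models not obtained by fitting).
#' @slot n number of observations used in the fit (NA if not fitted).
#'
#' @seealso [fitAlpha()], [predictThickness()]
#' @export
setClass("ShellModel",
  representation(alpha = "numeric", rss = "numeric", n = "integer"),
  prototype(rss = NA_real_, n = NA_integer_),
  validity = function(object) {
    if (length(object@alpha) != 1L || !is.finite(object@alpha))
      return("'alpha' must be a single finite number")
    if (object@alpha <= 0)
      return("'alpha' must be strictly positive")
    TRUE
  }
)

#' CapsuleImage: an RGB microscope image of one capsule
#'
#' 8-bit RGB pixel data (stored as numeric intensities in [0, 255]) plus the
#' acquisition metadata the pipeline needs: a sample identifier, the CaCl2
#' soaking concentration of the capsule core, and the spatial scale.
#'
#' @slot pixels numeric array H x W x 3, values in [0, 2^bitDepth - 1].
#' @slot sampleId character identifier.
#' @slot conc CaCl2 soaking concentration, millimolar (NA if unknown).
#' @slot scale micrometres per pixel (NA if unknown).
#' @slot bitDepth bits per channel (8 by default).
#'
#' @export
setClass("CapsuleImage",
  representation(pixels = "array", sampleId = "character", conc = "numeric",
                 scale = "numeric", bitDepth = "integer"),
  prototype(sampleId = NA_character_, conc = NA_real_, scale = NA_real_,
            bitDepth = 8L),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("'pixels' must be an H x W x 3 array")
    if (d[1] < 32L || d[2] < 32L)
      return("image must be at least 32 x 32 pixels")
    top <- 2^object@bitDepth - 1
    if (anyNA(object@pixels) ||
        min(object@pixels) < 0 || max(object@pixels) > top)
      return(sprintf("channel values must lie in [0, %d]", top))
    TRUE
  }
)

#' SegmentationResult: capsule/background partition of an image
#'
#' Two disjoint boolean masks jointly covering the image. After cleanup the
#' capsule mask is the largest connected component of the darker cluster,
#' with holes filled.
#'
#' @slot capsuleMask logical matrix H x W.
#' @slot backgroundMask logical matrix H x W, the complement of the capsule.
#'
#' @seealso [segmentCapsule()]
#' @export
setClass("SegmentationResult",
  representation(capsuleMask = "matrix", backgroundMask = "matrix"),
  validity = function(object) {
    cm <- object@capsuleMask; bm <- object@backgroundMask
    if (!is.logical(cm) || !is.logical(bm))
      return("masks must be logical matrices")
    if (!identical(dim(cm), dim(bm)))
      return("masks must have identical dimensions")
    if (any(cm & bm))
      return("capsule and background masks must be disjoint")
    if (!all(cm | bm))
      return("masks must jointly cover the image")
    TRUE
  }
)

#' ColourStats: centre-region and background colour statistics
#'
#' Channel means over the selected centre region of the capsule and over the
#' (eroded) background, together with the derived colour metrics used for
#' thickness calibration: R, R - background and R - B.
#'
#' @slot RMean,GMean,BMean centre-region channel means, intensity units.
#' @slot RBg,GBg,BBg background channel means, intensity units.
#' @slot metricR the red metric (equals RMean).
#' @slot metricRMinusBg red minus red-background.
#' @slot metricRMinusB red minus blue, the saturation-resistant metric.
#'
#' @seealso [extractColourStats()]
#' @export
setClass("ColourStats",
  representation(RMean = "numeric", GMean = "numeric", BMean = "numeric",
                 RBg = "numeric", GBg = "numeric", BBg = "numeric",
                 metricR = "numeric", metricRMinusBg = "numeric",
                 metricRMinusB = "numeric"),
  validity = function(object) {
    means <- c(object@RMean, object@GMean, object@BMean,
               object@RBg, object@GBg, object@BBg)
    if (any(!is.finite(means)) || any(means < 0) || any(means > 255))
      return("channel means must lie in [0, 255]")
    if (!isTRUE(all.equal(object@metricR, object@RMean)) ||
        !isTRUE(all.equal(object@metricRMinusBg, object@RMean - object@RBg)) ||
        !isTRUE(all.equal(object@metricRMinusB, object@RMean - object@BMean)))
      return("derived metrics do not satisfy their defining identities")
    TRUE
  }
)

#' ColourCalibration: linear map from R-B intensity to shell thickness
#'
#' Ordinary least squares with intercept, \eqn{h = slope \cdot (R-B) +
#' intercept}. The intercept is essential: extrapolating the fitted line to
#' the background-level colour of shell-less capsules yields negative
#' predicted thicknesses, which is the no-shell signature.
#'
#' @slot slope micrometres per intensity unit; positive for any valid
#'   calibration (thicker shells are redder).
#' @slot intercept micrometres.
#' @slot rSquared coefficient of determination in [0, 1].
#' @slot n number of calibration pairs (>= 2).
#'
#' @seealso [fitColourCalibration()], [predictThicknessFromColour()]
#' @export
setClass("ColourCalibration",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", n = "integer"),
  validity = function(object) {
    if (object@n < 2L) return("a calibration needs at least 2 pairs")
    if (!is.finite(object@slope) || object@slope <= 0)
      return("'slope' must be positive (thicker shells are redder)")
    if (!is.finite(object@rSquared) ||
        object@rSquared < 0 || object@rSquared > 1)
      return("'rSquared' must lie in [0, 1]")
    TRUE
  }
)

#' OpticsParams: the synthetic transmitted-light image-formation model
#'
#' Parameters of the optical stand-in used by [renderCapsule()]. Light
#' crossing a shell path of length L is attenuated per channel c as
#' \deqn{T_c(L) = (1-s)\,e^{-(\mu_c+\mu_{sc})L} + s\,e^{-\mu_c L}}
#' where \eqn{\mu_c} is channel-specific absorption by the iron-oxide stain
#' (\eqn{\mu_R < \mu_G < \mu_B}: the particles transmit red preferentially),
#' \eqn{\mu_{sc}} is achromatic scattering that rapidly extinguishes the
#' direct beam, and s is the diffuse transmitted fraction that survives
#' scattering. The direct term saturates within the first tens of micrometres
#' of shell, so the red channel flattens to a diffuse floor while continued
#' blue absorption keeps the R-B metric growing -- the saturation contrast
#' that makes R-B the calibration metric of choice.
#'
#' Two further stand-in features: \code{surfaceLoad}/\code{surfaceScale}
#' model particle enrichment at the core-shell interface (any shell carries a
#' near-fixed surface dose of stain, producing the threshold-like colour
#' onset at low thickness), and \code{rimWidth}/\code{rimDarkening} render the
#' colour-neutral refraction rim at the bead boundary that makes even an
#' unstained bead visible under transmitted light.
#'
#' Setting \code{scatterCoef = 0} and \code{surfaceLoad = 0} reduces the model
#' to pure Beer-Lambert attenuation.
#'
#' @slot backgroundRGB background intensities, length 3.
#' @slot mu per-channel absorption coefficients, per micrometre of path.
#' @slot noiseSigma Gaussian pixel noise, intensity units.
#' @slot bitDepth bits per channel.
#' @slot scatterCoef achromatic scattering coefficient, per micrometre.
#' @slot diffuseFraction diffuse transmitted fraction in [0, 1].
#' @slot surfaceLoad equivalent shell thickness of the interface particle
#'   layer, micrometres.
#' @slot surfaceScale thickness scale over which the interface layer builds
#'   up, micrometres.
#' @slot rimWidth width of the refraction rim, micrometres.
#' @slot rimDarkening multiplicative (colour-neutral) rim attenuation in
#'   (0, 1].
#'
#' @seealso [opticsParams()], [centreColour()]
#' @export
setClass("OpticsParams",
  representation(backgroundRGB = "numeric", mu = "numeric",
                 noiseSigma = "numeric", bitDepth = "integer",
                 scatterCoef = "numeric", diffuseFraction = "numeric",
                 surfaceLoad = "numeric", surfaceScale = "numeric",
                 rimWidth = "numeric", rimDarkening = "numeric"),
  validity = function(object) {
    if (length(object@backgroundRGB) != 3L || length(object@mu) != 3L)
      return("'backgroundRGB' and 'mu' must have length 3")
    top <- 2^object@bitDepth - 1
    if (any(object@backgroundRGB < 0) || any(object@backgroundRGB > top))
      return("background intensities out of range")
    m <- object@mu
    if (any(m <= 0) || !(m[1] < m[2] && m[2] < m[3]))
      return("need 0 < mu_R < mu_G < mu_B (stained shell transmits red best)")
    if (object@noiseSigma < 0) return("'noiseSigma' must be >= 0")
    if (object@scatterCoef < 0) return("'scatterCoef' must be >= 0")
    if (object@diffuseFraction < 0 || object@diffuseFraction > 1)
      return("'diffuseFraction' must lie in [0, 1]")
    if (object@surfaceLoad < 0 || object@surfaceScale <= 0)
      return("invalid interface-layer parameters")
    if (object@rimWidth < 0 || object@rimDarkening <= 0 ||
        object@rimDarkening > 1)
      return("invalid rim parameters")
    TRUE
  }
)

#' ScenarioSpec: shape of a synthetic capsule-fabrication experiment
#'
#' Describes one soaking-concentration series: the true model constant, the
#' concentration grid, replicates, the core-radius distribution, the
#' no-formation threshold (no continuous shell forms at or below it), the
#' imaging scale and the root seed.
#'
#' @slot alphaTrue generating proportionality constant, per millimolar.
#' @slot concentrations CaCl2 soaking concentrations, millimolar.
#' @slot replicates replicates per concentration.
#' @slot RcRange min and max core radius, micrometres (uniform draw).
#' @slot formationThreshold millimolar; shells do not form at conc <= this.
#' @slot scale micrometres per pixel of the rendered images.
#' @slot seed integer root seed; per-image seeds are derived by counter.
#'
#' @seealso [scenarioSpec()], [generateDataset()]
#' @export
setClass("ScenarioSpec",
  representation(alphaTrue = "numeric", concentrations = "numeric",
                 replicates = "integer", RcRange = "numeric",
                 formationThreshold = "numeric", scale = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@alphaTrue <= 0) return("'alphaTrue' must be positive")
    if (length(object@concentrations) < 1L || any(object@concentrations < 0))
      return("concentrations must be non-negative")
    if (object@replicates < 1L) return("need at least one replicate")
    if (length(object@RcRange) != 2L || any(object@RcRange <= 0) ||
        object@RcRange[1] > object@RcRange[2])
      return("'RcRange' must be positive (min, max)")
    if (object@formationThreshold < 0)
      return("'formationThreshold' must be >= 0")
    if (object@scale <= 0) return("'scale' must be positive")
    TRUE
  }
)

#' PipelineConfig: tunable parameters of the end-to-end analysis
#'
#' @slot centreFraction radius of the centre sampling disc as a fraction of
#'   the capsule's equivalent radius, in (0, 0.5].
#' @slot backgroundErosion pixels by which the background is kept away from
#'   the capsule boundary (halo exclusion).
#' @slot absenceTolerance micrometres; predictions at or below it are
#'   classified shell-absent.
#' @slot calibrationMinConc millimolar; samples at or above are
#'   calibration-eligible (direct thickness measurement is only feasible for
#'   sufficiently concentrated, i.e. thick-shelled, samples).
#' @slot columnMap named list mapping the canonical measurement columns
#'   (sample_id, conc_mM, R_c_um, h_um) onto external CSV headers.
#' @slot seed integer seed recorded with the run.
#'
#' @seealso [pipelineConfig()], [runPipeline()]
#' @export
setClass("PipelineConfig",
  representation(centreFraction = "numeric", backgroundErosion = "numeric",
                 absenceTolerance = "numeric", calibrationMinConc = "numeric",
                 columnMap = "list", seed = "integer"),
  validity = function(object) {
    if (object@centreFraction <= 0 || object@centreFraction > 0.5)
      return("'centreFraction' must lie in (0, 0.5]")
    if (object@backgroundErosion < 0)
      return("'backgroundErosion' must be >= 0")
    if (object@calibrationMinConc < 0)
      return("'calibrationMinConc' must be >= 0")
    need <- c("sample_id", "conc_mM", "R_c_um", "h_um")
    if (!all(need %in% names(object@columnMap)))
      return(paste("'columnMap' must name:", paste(need, collapse = ", ")))
    TRUE
  }
)

#' AnalysisReport: results of one end-to-end pipeline run
#'
#' @slot alphaModel fitted [ShellModel-class].
#' @slot calibration fitted [ColourCalibration-class].
#' @slot perSample data.frame, one row per manifest row (skipped images keep
#'   their row with NA metrics).
#' @slot aggregates data.frame of per-concentration means and standard
#'   deviations of the colour metric and the predicted thickness.
#' @slot formationThreshold millimolar, or NA when no concentration has all
#'   replicates shell-absent.
#' @slot measurements data.frame of the direct measurements used for the
#'   model and calibration fits.
#' @slot skipped data.frame (sample_id, reason) of images that failed.
#' @slot config the [PipelineConfig-class] used.
#'
#' @seealso [runPipeline()], [writeReport()]
#' @export
setClass("AnalysisReport",
  representation(alphaModel = "ShellModel", calibration = "ColourCalibration",
                 perSample = "data.frame", aggregates = "data.frame",
                 formationThreshold = "numeric", measurements = "data.frame",
                 skipped = "data.frame", config = "PipelineConfig"))
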