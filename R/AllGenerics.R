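#' @rdname ShellModel-class
#' @param object a \code{ShellModel}
#' @export
setGeneric("alphaCoef", function(object) standardGeneric("alphaCoef"))

#' Predict shell thickness from soaking concentration
#'
#' Forward evaluation of the thickness law
#' \eqn{h = R_c\left((\alpha\,[Ca^{2+}] + 1)^{1/3} - 1\right)}.
#'
#' @param model a [ShellModel-class] (or a bare positive numeric alpha).
#' @param conc CaCl2 soaking concentration, millimolar (vectorized).
#' @param Rc core radius, micrometres (vectorized, recycled against conc).
#' @return shell thickness in micrometres; 0 at zero concentration and
#'   strictly increasing in concentration, alpha and core radius.
#' @examples
#' m <- shellModel(0.033)
#' predictThickness(m, 100, 1000)   # ~626 um
#' @export
setGeneric("predictThickness",
           function(model, conc, Rc) standardGeneric("predictThickness"))

#' Invert the thickness law: concentration from an observed thickness
#'
#' @param model a [ShellModel-class] (or bare numeric alpha).
#' @param h shell thickness, micrometres.
#' @param Rc core radius, micrometres.
#' @return soaking concentration in millimolar; exact round trip with
#'   [predictThickness()].
#' @export
setGeneric("invertConcentration",
           function(model, h, Rc) standardGeneric("invertConcentration"))

#' @rdname segmentCapsule
#' @export
setGeneric("segmentCapsule",
           function(image, ...) standardGeneric("segmentCapsule"))

#' @rdname centreRegion
#' @export
setGeneric("centreRegion",
           function(seg, fraction = 0.1) standardGeneric("centreRegion"))

#' @rdname measureRadius
#' @export
setGeneric("measureRadius",
           function(seg, scale) standardGeneric("measureRadius"))

#' @rdname SegmentationResult-class
#' @param object a \code{SegmentationResult}
#' @export
setGeneric("capsuleMask", function(object) standardGeneric("capsuleMask"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("backgroundMask",
           function(object) standardGeneric("backgroundMask"))

#' @rdname ColourStats-class
#' @param object a \code{ColourStats}
#' @export
setGeneric("metricRMinusB",
           function(object) standardGeneric("metricRMinusB"))

#' @rdname AnalysisReport-class
#' @param object an \code{AnalysisReport}
#' @export
setGeneric("perSampleTable",
           function(object) standardGeneric("perSampleTable"))

#' @rdname AnalysisReport-class
#' @export
setGeneric("formationThreshold",
           function(object) standardGeneric("formationThreshold"))
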