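## Geometry of a core-shell capsule and the volumetric gelation model.
##
## All lengths in micrometres, concentrations in millimolar, alpha in mM^-1.

#' Core and shell volumes of a spherical core-shell capsule
#'
#' \code{coreVolume} returns \eqn{V_c = \frac{4}{3}\pi R_c^3};
#' \code{shellVolume} returns
#' \eqn{V_s = \frac{4}{3}\pi\left[(R_c + h)^3 - R_c^3\right]}, which is zero
#' exactly when the shell thickness is zero.
#'
#' @param Rc core radius, micrometres (> 0).
#' @param h shell thickness, micrometres (>= 0).
#' @return volume in cubic micrometres.
#' @export
coreVolume <- function(Rc) {
  if (any(!is.finite(Rc)) || any(Rc <= 0))
    csStop("core radius must be positive", "coreshell_domain")
  (4 / 3) * pi * Rc^3
}

#' @rdname coreVolume
#' @export
shellVolume <- function(Rc, h) {
  if (any(!is.finite(Rc)) || any(Rc <= 0))
    csStop("core radius must be positive", "coreshell_domain")
  if (any(!is.finite(h)) || any(h < 0))
    csStop("shell thickness must be non-negative", "coreshell_domain")
  (4 / 3) * pi * ((Rc + h)^3 - Rc^3)
}

#' Moles of calcium loaded into a capsule core
#'
#' The core soaked in a CaCl2 solution of concentration \code{conc} (assumed
#' fully equilibrated, so the core concentration equals the bath
#' concentration) carries \eqn{n = V_c \cdot [Ca^{2+}]} moles. With the core
#' volume in cubic micrometres (1 um^3 = 1e-15 L) and the concentration in
#' millimolar (1e-3 mol/L), the conversion factor is 1e-18.
#'
#' @param conc CaCl2 concentration, millimolar (>= 0).
#' @param Rc core radius, micrometres.
#' @return moles of Ca2+ in the core.
#' @export
calciumMoles <- function(conc, Rc) {
  if (any(!is.finite(conc)) || any(conc < 0))
    csStop("concentration must be non-negative", "coreshell_domain")
  coreVolume(Rc) * conc * 1e-18
}

#' Construct a ShellModel
#'
#' @param alpha proportionality constant, per millimolar (> 0).
#' @param rss,n optional fit diagnostics.
#' @return a [ShellModel-class].
#' @export
shellModel <- function(alpha, rss = NA_real_, n = NA_integer_) {
  new("ShellModel", alpha = as.numeric(alpha), rss = as.numeric(rss),
      n = as.integer(n))
}

#' @rdname ShellModel-class
#' @export
setMethod("alphaCoef", "ShellModel", function(object) object@alpha)

setMethod("show", "ShellModel", function(object) {
  cat("ShellModel (volumetric ionotropic-gelation model)\n")
  cat(sprintf("  alpha: %.6g mM^-1\n", object@alpha))
  if (!is.na(object@n))
    cat(sprintf("  fitted on %d observations, RSS = %.6g\n",
                object@n, object@rss))
  invisible(NULL)
})

.predictThickness <- function(alpha, conc, Rc) {
  if (any(!is.finite(conc)) || any(conc < 0))
    csStop("concentration must be non-negative", "coreshell_domain")
  if (any(!is.finite(Rc)) || any(Rc <= 0))
    csStop("core radius must be positive", "coreshell_domain")
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    csStop("alpha must be positive", "coreshell_domain")
  Rc * ((alpha * conc + 1)^(1 / 3) - 1)
}

#' @rdname predictThickness
#' @export
setMethod("predictThickness", signature(model = "ShellModel"),
  function(model, conc, Rc) .predictThickness(model@alpha, conc, Rc))

#' @rdname predictThickness
#' @export
setMethod("predictThickness", signature(model = "numeric"),
  function(model, conc, Rc) .predictThickness(model, conc, Rc))

#' Linearize an observed thickness
#'
#' The thickness law rearranges to the through-origin form \eqn{y = \alpha x}
#' with \eqn{x = [Ca^{2+}]} and response
#' \deqn{y = \left(\frac{h}{R_c} + 1\right)^3 - 1.}
#'
#' @param h shell thickness, micrometres (>= 0).
#' @param Rc core radius, micrometres (> 0).
#' @return the dimensionless linearized response; 0 at h = 0 and strictly
#'   increasing in h.
#' @export
linearizedResponse <- function(h, Rc) {
  if (any(!is.finite(h)) || any(h < 0))
    csStop("shell thickness must be non-negative", "coreshell_domain")
  if (any(!is.finite(Rc)) || any(Rc <= 0))
    csStop("core radius must be positive", "coreshell_domain")
  (h / Rc + 1)^3 - 1
}

#' @rdname invertConcentration
#' @export
setMethod("invertConcentration", signature(model = "ShellModel"),
  function(model, h, Rc) linearizedResponse(h, Rc) / model@alpha)

#' @rdname invertConcentration
#' @export
setMethod("invertConcentration", signature(model = "numeric"),
  function(model, h, Rc) {
    if (any(!is.finite(model)) || any(model <= 0))
      csStop("alpha must be positive", "coreshell_domain")
    linearizedResponse(h, Rc) / model
  })

#' Estimate the gelation constant alpha from thickness observations
#'
#' Through-origin ordinary least squares on the linearized scale:
#' \eqn{\hat\alpha = \sum x_i y_i / \sum x_i^2} with \eqn{x_i} the soaking
#' concentration and \eqn{y_i} the linearized response of the i-th capsule.
#' This is the exact global minimiser of \eqn{\sum (y_i - \alpha x_i)^2}.
#' No intercept is used (the model passes through the origin: zero calcium,
#' zero shell) and no weights are applied.
#'
#' Observations at zero concentration are accepted; they carry no leverage
#' (x = 0) and only contribute to the residual sum of squares.
#'
#' @param observations data.frame with columns \code{conc_mM},
#'   \code{R_c_um} and \code{h_um}; each capsule carries its own core radius.
#' @param pool \code{"pooled"} fits all replicates individually (default);
#'   \code{"byConcentration"} averages the linearized response per
#'   concentration first.
#' @return a fitted [ShellModel-class] with diagnostics \code{rss} and
#'   \code{n}.
#' @examples
#' obs <- data.frame(conc_mM = c(10, 20), R_c_um = 700,
#'                   h_um = predictThickness(0.05, c(10, 20), 700))
#' alphaCoef(fitAlpha(obs))   # 0.05, exactly
#' @export
fitAlpha <- function(observations, pool = c("pooled", "byConcentration")) {
  pool <- match.arg(pool)
  need <- c("conc_mM", "R_c_um", "h_um")
  if (!is.data.frame(observations) || !all(need %in% names(observations)))
    csStop(paste("observations must contain columns:",
                 paste(need, collapse = ", ")), "coreshell_schema")
  x <- as.numeric(observations$conc_mM)
  y <- linearizedResponse(observations$h_um, observations$R_c_um)
  if (sum(x > 0) < 2L)
    csStop("need at least 2 observations with positive concentration",
           "coreshell_degenerate")
  if (pool == "byConcentration") {
    y <- as.numeric(tapply(y, x, mean))
    x <- sort(unique(x))
  }
  alpha <- sum(x * y) / sum(x^2)
  rss <- sum((y - alpha * x)^2)
  shellModel(alpha, rss = rss, n = length(x))
}
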