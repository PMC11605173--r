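## Colour-to-thickness calibration and no-shell inference.

#' Fit the linear colour-to-thickness calibration
#'
#' Ordinary least squares with intercept of measured shell thickness on the
#' R-B colour metric: \eqn{h = slope\,(R-B) + intercept}. Fitted only on
#' capsules whose shell was thick enough to measure directly; the line is
#' then extrapolated to all samples, and samples whose colour sits at the
#' background level extrapolate to negative thickness -- the no-shell
#' signature.
#'
#' @param RminusB R-B colour intensities of the calibration capsules.
#' @param h directly measured shell thicknesses, micrometres.
#' @return a [ColourCalibration-class] with slope, intercept, r-squared and
#'   the number of pairs.
#' @section Errors: \code{coreshell_degenerate} with fewer than 2 pairs or
#'   when all R-B values are identical.
#' @export
fitColourCalibration <- function(RminusB, h) {
  keep <- is.finite(RminusB) & is.finite(h)
  x <- as.numeric(RminusB[keep]); y <- as.numeric(h[keep])
  if (length(x) < 2L)
    csStop("calibration needs at least 2 pairs", "coreshell_degenerate")
  if (diff(range(x)) == 0)
    csStop("all R-B values identical: degenerate calibration design",
           "coreshell_degenerate")
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  slope <- sum((x - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  sst <- sum((y - ym)^2)
  r2 <- if (sst == 0) 1 else 1 - sum((y - slope * x - intercept)^2) / sst
  new("ColourCalibration", slope = slope, intercept = intercept,
      rSquared = min(max(r2, 0), 1), n = length(x))
}

setMethod("show", "ColourCalibration", function(object) {
  cat("ColourCalibration: h = slope * (R-B) + intercept\n")
  cat(sprintf("  slope: %.4g um per intensity unit\n", object@slope))
  cat(sprintf("  intercept: %.4g um\n", object@intercept))
  cat(sprintf("  r-squared: %.4f (n = %d)\n", object@rSquared, object@n))
  invisible(NULL)
})

#' Predict shell thickness (and presence) from colour
#'
#' Affine prediction \eqn{\hat h = slope\,(R-B) + intercept}. Negative
#' predictions are valid outputs: they indicate that the capsule's colour is
#' incompatible with any continuous shell, and the sample is classified
#' \code{absent}. The classification cut is \eqn{\hat h \le} tolerance.
#'
#' @param cal a [ColourCalibration-class].
#' @param RminusB colour metric values (vectorized).
#' @param tolerance micrometres; default 0 classifies exactly the
#'   non-positive predictions as shell-absent.
#' @return data.frame with columns \code{h_pred_um} and \code{status}
#'   (factor, levels \code{continuous}/\code{absent}).
#' @export
predictThicknessFromColour <- function(cal, RminusB, tolerance = 0) {
  stopifnot(is(cal, "ColourCalibration"))
  h <- cal@slope * as.numeric(RminusB) + cal@intercept
  status <- factor(ifelse(h <= tolerance, "absent", "continuous"),
                   levels = c("continuous", "absent"))
  data.frame(h_pred_um = h, status = status)
}

#' Per-concentration mean and standard deviation
#'
#' Sample mean and sample standard deviation (n - 1 denominator; 0 for
#' singleton groups) of a per-capsule quantity, grouped by soaking
#' concentration and sorted by ascending concentration.
#'
#' @param conc soaking concentrations, millimolar.
#' @param value per-capsule values (same length).
#' @return data.frame with columns \code{conc_mM}, \code{n}, \code{mean},
#'   \code{sd}.
#' @export
aggregateByConcentration <- function(conc, value) {
  keep <- is.finite(conc) & is.finite(value)
  conc <- conc[keep]; value <- value[keep]
  if (length(conc) == 0L)
    csStop("no values to aggregate", "coreshell_degenerate")
  groups <- sort(unique(conc))
  out <- data.frame(
    conc_mM = groups,
    n = as.integer(tapply(value, factor(conc, levels = groups), length)),
    mean = as.numeric(tapply(value, factor(conc, levels = groups), mean)),
    sd = as.numeric(tapply(value, factor(conc, levels = groups), stats::sd)))
  out$sd[is.na(out$sd)] <- 0
  rownames(out) <- NULL
  out
}

#' Detect the shell-formation threshold concentration
#'
#' The experiment's qualitative conclusion -- below some soaking
#' concentration no continuous shell forms -- is formalised as: the largest
#' tested concentration at which ALL replicates are classified shell-absent.
#' Returns NA when no concentration qualifies. A warning is issued when the
#' absent/continuous pattern is non-monotone (a qualifying concentration
#' above one that already has continuous shells).
#'
#' @param conc per-sample soaking concentrations, millimolar.
#' @param status per-sample classification, \code{"absent"} or
#'   \code{"continuous"} (character or factor).
#' @return the threshold concentration in millimolar, or NA.
#' @export
detectFormationThreshold <- function(conc, status) {
  status <- as.character(status)
  keep <- is.finite(conc) & !is.na(status)
  conc <- conc[keep]; status <- status[keep]
  if (length(unique(conc)) < 2L)
    csStop("need samples at two or more distinct concentrations",
           "coreshell_degenerate")
  groups <- sort(unique(conc))
  allAbsent <- vapply(groups,
                      function(g) all(status[conc == g] == "absent"),
                      logical(1))
  anyCont <- vapply(groups,
                    function(g) any(status[conc == g] == "continuous"),
                    logical(1))
  if (!any(allAbsent)) return(NA_real_)
  thr <- max(groups[allAbsent])
  if (any(anyCont & groups < thr))
    warning(sprintf(paste("non-monotone formation pattern: all replicates",
                          "absent at %g mM above a concentration with",
                          "continuous shells"), thr), call. = FALSE)
  thr
}
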