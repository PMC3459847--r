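#' @name accessors
#' @title Accessors for omgrowth classes
#' @description Small accessor generics: geometry (`radius`,
#'   `circumference`, `surfaceArea`, `axialLimits`), kinetics (`kOn`,
#'   `kIns`, `tau`, `doublingTime`, `meanEventArea`), and image data
#'   (`intensity`, `pixelSize`).
#' @param object an omgrowth S4 object.
#' @return the corresponding slot or derived scalar.
NULL

#' @rdname accessors
#' @export
setGeneric("radius", function(object) standardGeneric("radius"))
#' @rdname accessors
#' @export
setMethod("radius", "CylinderGeom", function(object) object@R)

#' @rdname accessors
#' @export
setGeneric("circumference", function(object) standardGeneric("circumference"))
#' @rdname accessors
#' @export
setMethod("circumference", "CylinderGeom", function(object) 2 * pi * object@R)

#' @rdname accessors
#' @export
setGeneric("axialLimits", function(object) standardGeneric("axialLimits"))
#' @rdname accessors
#' @export
setMethod("axialLimits", "CylinderGeom",
          function(object) c(object@xLeft, object@xRight))

#' @rdname accessors
#' @export
setGeneric("surfaceArea", function(object) standardGeneric("surfaceArea"))
#' @rdname accessors
#' @export
setMethod("surfaceArea", "CylinderGeom", function(object)
  2 * pi * object@R * (object@xRight - object@xLeft))
#' @rdname accessors
#' @export
setMethod("surfaceArea", "SimulationState",
          function(object) surfaceArea(object@geom))

#' @rdname accessors
#' @export
setGeneric("kOn", function(object) standardGeneric("kOn"))
#' @rdname accessors
#' @export
setMethod("kOn", "KineticParams", function(object) object@kOn)

#' @rdname accessors
#' @export
setGeneric("kIns", function(object) standardGeneric("kIns"))
#' @rdname accessors
#' @export
setMethod("kIns", "KineticParams", function(object) object@kIns)

#' @rdname accessors
#' @export
setGeneric("tau", function(object) standardGeneric("tau"))
#' @rdname accessors
#' @export
setMethod("tau", "KineticParams", function(object) object@tau)

#' @rdname accessors
#' @export
setGeneric("doublingTime", function(object) standardGeneric("doublingTime"))
#' @rdname accessors
#' @export
setMethod("doublingTime", "KineticParams", function(object) object@tDouble)

#' @rdname accessors
#' @export
setGeneric("meanEventArea", function(object) standardGeneric("meanEventArea"))
#' @rdname accessors
#' @export
setMethod("meanEventArea", "KineticParams",
          function(object) object@tau * object@kIns)

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setMethod("intensity", "Micrograph", function(object) object@intensity)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "Micrograph", function(object) object@pixelSize)

#' @rdname accessors
#' @param state a [SimulationState-class].
#' @export
patches <- function(state) state@patches

#' @rdname accessors
#' @export
sources <- function(state) state@sources

#' @rdname accessors
#' @export
simTime <- function(state) state@t

setMethod("show", "CylinderGeom", function(object) {
  cat(sprintf("CylinderGeom: R = %.3g um, x in [%.3g, %.3g] um (P = %.3g um)\n",
              object@R, object@xLeft, object@xRight, circumference(object)))
})

setMethod("show", "KineticParams", function(object) {
  cat(sprintf(paste0(
    "KineticParams: kOn = %.3g um^-2 s^-1, kIns = %.3g um^2 s^-1,\n",
    "  tau = %.4g s, tDouble = %.4g s (mean event area %.3g um^2)\n"),
    object@kOn, object@kIns, object@tau, object@tDouble,
    meanEventArea(object)))
})

setMethod("show", "LabelSchedule", function(object) {
  cat("LabelSchedule:",
      paste(sprintf("%s (%g s)", object@labels, object@durations),
            collapse = " -> "), "\n")
})

setMethod("show", "SimulationState", function(object) {
  nAct <- sum(object@sources$active)
  cat(sprintf(paste0(
    "SimulationState at t = %.4g s\n  area %.4g um^2 (initial %.4g),",
    " %d patches, %d sources (%d active)\n"),
    object@t, surfaceArea(object), object@initialArea,
    length(object@patches), nrow(object@sources), nAct))
})

setMethod("show", "OpticsConfig", function(object) {
  cat(sprintf(paste0(
    "OpticsConfig: %gx / NA %g at %g nm, camera pixel %g um ",
    "(sample %g nm), PSF %s, %d z-layers\n"),
    object@magnification, object@na, object@wavelength, object@cameraPixel,
    1000 * object@cameraPixel / object@magnification, object@psfModel,
    object@zLayers))
})

setMethod("show", "Micrograph", function(object) {
  cat(sprintf("Micrograph: %d x %d px (%.3g nm/px) at t = %.4g s\n",
              nrow(object@intensity), ncol(object@intensity),
              object@pixelSize, object@time))
})

setMethod("show", "PunctaCurve", function(object) {
  cat(sprintf("PunctaCurve: %d frames, %d replicates (%s)\n",
              length(object@times), object@nReplicates,
              object@normalization))
})

setMethod("show", "SigmoidFit", function(object) {
  if (object@converged)
    cat(sprintf(
      "SigmoidFit: nMax = %.3g, rate = %.3g s^-1, midpoint = %.4g s\n",
      object@nMax, object@rate, object@midpoint))
  else
    cat("SigmoidFit: NOT converged --", object@message, "\n")
})

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult: %d parameter sets, %d replicates each\n",
              nrow(object@table), object@meta$replicates))
})
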