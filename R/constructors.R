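#' Create a cylinder geometry
#'
#' @param R cylinder radius (um).
#' @param length initial axial length of the growing region (um); ignored if
#'   `xLeft`/`xRight` are given.
#' @param xLeft,xRight explicit axial limits (um).
#' @return a [CylinderGeom-class].
#' @examples
#' g <- cylinderGeom(R = 0.5, length = 2)
#' circumference(g)   # 2*pi*R
#' surfaceArea(g)     # cylindrical area, ~6.283 um^2
#' @export
cylinderGeom <- function(R = 0.5, length = 2,
                         xLeft = -length / 2, xRight = length / 2) {
  new("CylinderGeom", R = as.numeric(R), xLeft = as.numeric(xLeft),
      xRight = as.numeric(xRight))
}

#' Create a kinetic parameter set
#'
#' Exactly one of `tau` and `tDouble` may be omitted; the other is then
#' derived from the mean-field growth law (see [solveTau()] and
#' [growthRate()]). If both are given they must be consistent.
#'
#' @param kOn event initiation rate per area (um^-2 s^-1).
#' @param kIns area insertion rate per active event (um^2 s^-1).
#' @param tau mean event duration (s), or `NULL` to derive from `tDouble`.
#' @param tDouble doubling time (s), or `NULL` to derive from `tau`.
#' @return a [KineticParams-class].
#' @examples
#' p <- kineticParams(0.004, 0.00064, tDouble = 90 * 60)
#' tau(p)            # ~50 s
#' meanEventArea(p)  # tau * kIns, ~0.032 um^2
#' @export
kineticParams <- function(kOn, kIns, tau = NULL, tDouble = NULL) {
  if (is.null(tau) && is.null(tDouble))
    stop("one of 'tau' or 'tDouble' must be given")
  if (is.null(tau)) tau <- solveTau(kOn, kIns, tDouble)
  if (is.null(tDouble)) tDouble <- log(2) / growthRate(kOn, kIns, tau)
  new("KineticParams", kOn = as.numeric(kOn), kIns = as.numeric(kIns),
      tau = as.numeric(tau), tDouble = as.numeric(tDouble))
}

#' Create a labeling schedule
#'
#' @param light,dark convenience: durations (s) of a single light phase
#'   followed by a single dark phase. Defaults to the 15 min light / 75 min
#'   dark label-and-chase protocol.
#' @param phases alternatively, a data.frame with columns `duration` (s) and
#'   `label` (`"light"`/`"dark"`), overriding `light`/`dark`.
#' @return a [LabelSchedule-class].
#' @export
labelSchedule <- function(light = 15 * 60, dark = 75 * 60, phases = NULL) {
  if (!is.null(phases))
    return(new("LabelSchedule", durations = as.numeric(phases$duration),
               labels = as.character(phases$label)))
  new("LabelSchedule", durations = c(light, dark),
      labels = c("light", "dark"))
}

#' Label in force at a given time
#'
#' @param schedule a [LabelSchedule-class].
#' @param t time (s).
#' @return `"light"` or `"dark"`; after the last phase ends, the last
#'   phase's label persists.
#' @export
labelAt <- function(schedule, t) {
  ends <- cumsum(schedule@durations)
  i <- findInterval(t, c(0, ends), rightmost.closed = FALSE)
  schedule@labels[min(max(i, 1L), length(schedule@labels))]
}

#' Create a virtual microscope configuration
#'
#' @param na numerical aperture.
#' @param wavelength emission wavelength (nm).
#' @param magnification objective magnification.
#' @param cameraPixel physical camera pixel size (um).
#' @param psfModel `"gaussian"` or `"born_wolf"`.
#' @param zLayers number of axial slices over the cylinder surface.
#' @param photonScale photons per um^2 of labeled area.
#' @param readNoise read-noise sd (counts).
#' @param offset background offset (counts).
#' @param superSample sub-pixel rasterization factor.
#' @param margin image margin around the cell (um).
#' @return an [OpticsConfig-class].
#' @export
opticsConfig <- function(na = 1.4, wavelength = 575, magnification = 100,
                         cameraPixel = 6.8, psfModel = "gaussian",
                         zLayers = 9L, photonScale = 2e4, readNoise = 2,
                         offset = 100, superSample = 4L, margin = 0.4) {
  new("OpticsConfig", na = na, wavelength = wavelength,
      magnification = magnification, cameraPixel = cameraPixel,
      psfModel = psfModel, zLayers = as.integer(zLayers),
      photonScale = photonScale, readNoise = readNoise, offset = offset,
      superSample = as.integer(superSample), margin = margin)
}
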