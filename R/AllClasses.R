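#' @import methods
#' @importFrom stats rpois rexp runif rnorm median mad optim approx
#'   coef residuals lm sd var
#' @importFrom utils tail
#' @useDynLib omgrowth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Cylindrical cell geometry
#'
#' The growing (cylindrical) region of the outer membrane, unwrapped onto a
#' 2D strip: `x` is the axial coordinate, `y` the circumferential one,
#' periodic with period `P = 2*pi*R`. All lengths are in micrometres. The
#' hemispherical poles are not part of the model; the strip ends `xLeft`,
#' `xRight` are the (inert) pole boundaries towards which the growth flow
#' converges.
#'
#' @slot R cylinder radius (um).
#' @slot xLeft,xRight axial extent of the growing region (um).
#' @export
setClass("CylinderGeom",
  representation(R = "numeric", xLeft = "numeric", xRight = "numeric"))

setValidity("CylinderGeom", function(object) {
  msg <- character()
  if (length(object@R) != 1 || !is.finite(object@R) || object@R <= 0)
    msg <- c(msg, "R must be a single positive number")
  if (length(object@xLeft) != 1 || length(object@xRight) != 1 ||
      !is.finite(object@xLeft) || !is.finite(object@xRight))
    msg <- c(msg, "axial limits must be finite scalars")
  else if (object@xLeft >= object@xRight)
    msg <- c(msg, "xLeft must be smaller than xRight")
  if (length(msg)) msg else TRUE
})

#' Kinetic parameters of bursty membrane insertion
#'
#' The kinetic triple of the insertion model: events initiate as a Poisson
#' process with areal rate `kOn` (um^-2 s^-1), each adds membrane area at
#' rate `kIns` (um^2 s^-1) for an exponentially distributed duration with
#' mean `tau` (s). The mean-field system dA/dt = kIns * n,
#' dn/dt = kOn * A - n / tau grows with dominant exponent `lambda`, the
#' positive root of `lambda^2 + lambda/tau = kOn*kIns`, so the population
#' doubling time is `tDouble = log(2)/lambda`.
#'
#' @slot kOn event initiation rate per unit area (um^-2 s^-1).
#' @slot kIns area insertion rate per active event (um^2 s^-1).
#' @slot tau mean event duration (s).
#' @slot tDouble doubling time of the membrane area (s).
#' @export
setClass("KineticParams",
  representation(kOn = "numeric", kIns = "numeric",
                 tau = "numeric", tDouble = "numeric"))

setValidity("KineticParams", function(object) {
  v <- c(object@kOn, object@kIns, object@tau, object@tDouble)
  if (length(v) != 4 || any(is.na(v)))
    return("kOn, kIns, tau and tDouble must be numeric scalars")
  if (object@kOn < 0)
    return("kOn must be non-negative (0 is the growth-arrested limit)")
  if (object@kIns <= 0 || object@tau <= 0 || object@tDouble <= 0)
    return("kIns, tau and tDouble must be positive")
  if (object@kOn == 0) {
    if (is.finite(object@tDouble))
      return("with kOn = 0 the membrane never doubles: tDouble must be Inf")
    return(TRUE)
  }
  lam <- growthRate(object@kOn, object@kIns, object@tau)
  if (abs(log(2) / lam - object@tDouble) > 1e-6 * object@tDouble)
    return("inconsistent parameters: log(2)/lambda(kOn, kIns, tau) != tDouble")
  TRUE
})

#' Light/dark labeling schedule
#'
#' Ordered phases of the label-and-chase protocol: material inserted during a
#' "light" phase is fluorescent, material inserted during a "dark" phase is
#' not. After the last phase its label persists. The default mimics the
#' experimental protocol: 15 minutes of light insertion followed by 75
#' minutes of dark insertion.
#'
#' @slot durations phase durations (s).
#' @slot labels phase labels, each `"light"` or `"dark"`.
#' @export
setClass("LabelSchedule",
  representation(durations = "numeric", labels = "character"))

setValidity("LabelSchedule", function(object) {
  if (length(object@durations) != length(object@labels))
    return("durations and labels must have equal length")
  if (length(object@durations) == 0)
    return("schedule needs at least one phase")
  if (any(!is.finite(object@durations)) || any(object@durations <= 0))
    return("phase durations must be positive")
  if (!all(object@labels %in% c("light", "dark")))
    return("labels must be 'light' or 'dark'")
  TRUE
})

#' State of a membrane-growth simulation
#'
#' Snapshot of the simulator: the clock, the cylinder geometry (whose ends
#' move as the cell elongates), the inserted material patches (each a
#' polygon on the unwrapped strip), and the insertion-event sources.
#'
#' `patches` is a list; each element has `vertices` (an n x 2 matrix of
#' (x, y) strip coordinates in um), `label` (`"light"`, `"dark"` or
#' `"original"`), `sourceId` and `tBirth`. `sources` is a data.frame with
#' columns `id`, `x`, `y`, `strength` (area flux, um^2 s^-1), `active`,
#' `tStart`, `duration`, `label` and `areaInserted`.
#'
#' @slot t simulation clock (s).
#' @slot geom a [CylinderGeom-class].
#' @slot params a [KineticParams-class].
#' @slot schedule a [LabelSchedule-class].
#' @slot patches list of patch records (see Details).
#' @slot sources data.frame of insertion-event sources.
#' @slot rngState the R RNG state for exact replay of the next step.
#' @slot initialArea cylindrical area at t = 0 (um^2).
#' @export
setClass("SimulationState",
  representation(t = "numeric", geom = "CylinderGeom",
                 params = "KineticParams", schedule = "LabelSchedule",
                 patches = "list", sources = "data.frame",
                 rngState = "integer", initialArea = "numeric"))

#' Virtual microscope configuration
#'
#' Optics of the simulated widefield fluorescence microscope. The sample-
#' plane pixel is `cameraPixel / magnification`; the defaults (6.8 um camera
#' pixel, 100x, NA 1.4, 575 nm emission) give 68 nm pixels. The default PSF
#' is a defocused-Gaussian approximation with in-focus lateral sd
#' `0.21 * wavelength / NA`.
#'
#' @slot na numerical aperture.
#' @slot wavelength emission wavelength (nm).
#' @slot magnification objective magnification.
#' @slot cameraPixel physical camera pixel (um).
#' @slot psfModel `"gaussian"` (implemented) or `"born_wolf"` (stub).
#' @slot zLayers number of axial slices sampled over the cylinder.
#' @slot photonScale photons per um^2 of labeled area.
#' @slot readNoise additive Gaussian read noise sd (counts).
#' @slot offset constant background offset (counts).
#' @slot superSample sub-pixel rasterization factor.
#' @slot margin image margin beyond the cell outline (um).
#' @export
setClass("OpticsConfig",
  representation(na = "numeric", wavelength = "numeric",
                 magnification = "numeric", cameraPixel = "numeric",
                 psfModel = "character", zLayers = "integer",
                 photonScale = "numeric", readNoise = "numeric",
                 offset = "numeric", superSample = "integer",
                 margin = "numeric"))

setValidity("OpticsConfig", function(object) {
  pos <- c(object@na, object@wavelength, object@magnification,
           object@cameraPixel, object@photonScale, object@margin)
  if (any(!is.finite(pos)) || any(pos <= 0))
    return("na, wavelength, magnification, cameraPixel, photonScale and margin must be positive")
  if (object@readNoise < 0 || object@offset < 0)
    return("readNoise and offset must be non-negative")
  if (object@zLayers < 1L || object@superSample < 1L)
    return("zLayers and superSample must be >= 1")
  if (!object@psfModel %in% c("gaussian", "born_wolf"))
    return("psfModel must be 'gaussian' or 'born_wolf'")
  TRUE
})

#' Simulated micrograph
#'
#' A single simulated camera frame. `intensity` rows run along the lateral
#' (projected-circumference) axis, columns along the cell axis; units are
#' camera counts (arbitrary). `meta` records provenance: acquisition time,
#' cylinder radius and axial extent, the lateral coordinate of the first row
#' and noise settings.
#'
#' @slot intensity numeric matrix of pixel intensities.
#' @slot pixelSize sample-plane pixel size (nm).
#' @slot time acquisition time (s).
#' @slot meta provenance list.
#' @export
setClass("Micrograph",
  representation(intensity = "matrix", pixelSize = "numeric",
                 time = "numeric", meta = "list"))

setValidity("Micrograph", function(object) {
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    return("pixelSize must be a single positive number (nm)")
  if (any(!is.finite(object@intensity)))
    return("intensities must be finite")
  TRUE
})

#' Puncta-count curve
#'
#' Mean (with sd) number of detected puncta per cell as a function of time,
#' averaged over replicate simulations.
#'
#' @slot times frame times (s).
#' @slot mean mean count per frame.
#' @slot sd standard deviation of the count across replicates.
#' @slot nReplicates number of replicates.
#' @slot normalization `"raw"` or `"per-perimeter-length"`.
#' @export
setClass("PunctaCurve",
  representation(times = "numeric", mean = "numeric", sd = "numeric",
                 nReplicates = "integer", normalization = "character"))

setValidity("PunctaCurve", function(object) {
  if (length(object@times) != length(object@mean) ||
      length(object@times) != length(object@sd))
    return("times, mean and sd must have equal length")
  if (any(object@mean < 0)) return("counts must be non-negative")
  if (object@nReplicates < 1L) return("need at least one replicate")
  TRUE
})

#' Logistic fit of a puncta-count curve
#'
#' Parameters of the logistic fit
#' `N(t) = nMax / (1 + exp(-(t - midpoint)/scale))`; the initial punctum
#' appearance rate is the maximum slope `nMax / (4 * scale)`.
#'
#' @slot nMax plateau count.
#' @slot rate initial appearance rate (puncta s^-1).
#' @slot midpoint logistic midpoint (s).
#' @slot scale logistic time scale (s).
#' @slot residual residual norm of the fit.
#' @slot converged whether the fit converged and is well conditioned.
#' @slot message diagnostic message for degenerate fits.
#' @export
setClass("SigmoidFit",
  representation(nMax = "numeric", rate = "numeric", midpoint = "numeric",
                 scale = "numeric", residual = "numeric",
                 converged = "logical", message = "character"))

#' Result of a kinetic parameter-space screen
#'
#' One row per (kOn, kIns) pair with the constrained tau, the mean insertion
#' size tau*kIns, the per-perimeter-length initial punctum appearance rate
#' and maximum puncta count (replicate means and sds), and per-pair failure
#' messages. `meta` records seeds, protocol and normalization.
#'
#' @slot table per-pair metric data.frame.
#' @slot meta provenance list.
#' @export
setClass("ScanResult",
  representation(table = "data.frame", meta = "list"))
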