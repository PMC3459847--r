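#' Lateral PSF width and related optical scales
#'
#' For the Gaussian PSF approximation the in-focus lateral sd is
#' `sigma0 = 0.21 * wavelength / NA` (about 86 nm at 575 nm / NA 1.4), the
#' defocused sd is `sigma(z) = sigma0 * sqrt(1 + (z/zR)^2)` with
#' `zR = 2 * wavelength * n / NA^2` (n = 1.515 immersion), and the Rayleigh
#' resolution is `0.61 * wavelength / NA` (about 250 nm).
#'
#' @param optics an [OpticsConfig-class].
#' @return nm.
#' @export
psfSigma0 <- function(optics) 0.21 * optics@wavelength / optics@na

#' @rdname psfSigma0
#' @export
psfAxialScale <- function(optics) 2 * optics@wavelength * 1.515 / optics@na^2

#' @rdname psfSigma0
#' @export
rayleighRadius <- function(optics) 0.61 * optics@wavelength / optics@na

#' @rdname psfSigma0
#' @export
samplePixel <- function(optics) 1000 * optics@cameraPixel / optics@magnification

#' Point-spread-function kernel at a given defocus
#'
#' 2D kernel of the defocused-Gaussian PSF model at the requested defocus,
#' sampled on a square pixel grid. The in-focus kernel integrates to 1;
#' defocused kernels integrate to the Strehl-like factor
#' `1 / (1 + (z/zR)^2) <= 1` while their lateral sd grows as `sigma(z)`.
#'
#' @param optics an [OpticsConfig-class].
#' @param defocus axial distance from the focal plane (nm).
#' @param pixel kernel sampling pitch (nm); defaults to the supersampled
#'   rendering pitch `samplePixel(optics) / superSample`.
#' @return a square numeric matrix (odd side).
#' @export
psfKernel <- function(optics, defocus = 0,
                      pixel = samplePixel(optics) / optics@superSample) {
  if (optics@psfModel == "born_wolf")
    stop("the Born-Wolf PSF model is a planned extension; use psfModel = 'gaussian'")
  s0 <- psfSigma0(optics)
  zR <- psfAxialScale(optics)
  sigma <- s0 * sqrt(1 + (defocus / zR)^2)
  strehl <- 1 / (1 + (defocus / zR)^2)
  half <- max(2L, ceiling(4 * sigma / pixel))
  u <- (-half:half) * pixel
  g <- exp(-u^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k) * strehl
}

.gauss1d <- function(sigmaPx, halfMin = 2L) {
  half <- max(halfMin, ceiling(4 * sigmaPx))
  u <- -half:half
  g <- exp(-u^2 / (2 * sigmaPx^2))
  g / sum(g)
}

# 1D convolution of each column of m with kernel g (same size, zero-padded)
.convCols <- function(m, g) {
  nk <- length(g)
  half <- (nk - 1L) %/% 2L
  n <- nrow(m)
  padded <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
  out <- matrix(0, n, ncol(m))
  for (j in seq_len(nk))
    out <- out + g[j] * padded[(nk - j) + seq_len(n), , drop = FALSE]
  out
}

.sepConv <- function(m, g) t(.convCols(t(.convCols(m, g)), g))

#' Render a simulated fluorescence micrograph
#'
#' The virtual widefield microscope. Light-labeled patch polygons are
#' rasterized onto the unwrapped strip at sub-pixel resolution as
#' fluorophore density; the strip is wrapped onto the 3D cylinder, so each
#' surface element acquires a projected lateral position `R sin(theta)` and
#' a defocus `R cos(theta) - focus` (focal plane through the cylinder axis
#' by default, which is what makes the peripheral edges bright); each
#' z-layer is convolved with the PSF slice at its defocus; the layers are
#' summed, integrated onto camera pixels, and noise is applied (Poisson
#' photon noise at `photonScale` photons per um^2 of labeled area, constant
#' background offset, additive Gaussian read noise).
#'
#' With `noise = FALSE` the image is exactly linear in the labeled material.
#'
#' @param state a [SimulationState-class].
#' @param optics an [OpticsConfig-class].
#' @param noise apply photon and read noise.
#' @param focus focal-plane offset from the cylinder axis (um).
#' @return a [Micrograph-class]; rows run along the projected lateral axis
#'   (bottom edge `-R` first), columns along the cell axis.
#' @export
renderMicrograph <- function(state, optics, noise = TRUE, focus = 0) {
  validObject(optics)
  geom <- state@geom
  R <- geom@R
  P <- circumference(geom)
  ss <- optics@superSample
  h <- samplePixel(optics) / ss / 1000   # rendering pitch, um
  margin <- optics@margin

  x0 <- geom@xLeft - margin
  nxCam <- ceiling((geom@xRight + margin - x0) / (h * ss))
  nx <- nxCam * ss
  v0 <- -R - margin
  nvCam <- ceiling(2 * (R + margin) / (h * ss))
  nv <- nvCam * ss
  ny <- max(8L, round(P / h))
  hy <- P / ny

  # fluorophore density on the strip: material-label map painted in birth
  # order (later insertions occlude the material they displaced), then
  # light-labeled cells carry one cell-area of fluorophore each
  lg <- .labelGrid(state, x0, nx, h, ny, hy)
  D <- (lg == 1L) * (h * hy)

  # wrap strip rows onto the cylinder: projected lateral position and defocus
  yc <- (seq_len(ny) - 0.5) * hy
  theta <- 2 * pi * yc / P
  vpos <- R * sin(theta)
  z <- R * cos(theta) - focus
  ivRow <- pmin(pmax(1L, as.integer(ceiling((vpos - v0) / h))), nv)
  nz <- optics@zLayers
  zEdges <- seq(min(z) - 1e-9, max(z) + 1e-9, length.out = nz + 1L)
  zBin <- findInterval(z, zEdges, rightmost.closed = TRUE)
  zMid <- (zEdges[-1] + zEdges[-(nz + 1L)]) / 2

  img <- matrix(0, nv, nx)
  for (b in seq_len(nz)) {
    cols <- which(zBin == b)
    if (!length(cols)) next
    layer <- matrix(0, nv, nx)
    acc <- rowsum(t(D[, cols, drop = FALSE]), group = ivRow[cols])
    layer[as.integer(rownames(acc)), ] <- acc
    if (!any(layer > 0)) next
    s0 <- psfSigma0(optics)
    zR <- psfAxialScale(optics)
    sigmaPx <- s0 * sqrt(1 + (1000 * zMid[b] / zR)^2) / (1000 * h)
    strehl <- 1 / (1 + (1000 * zMid[b] / zR)^2)
    img <- img + strehl * .sepConv(layer, .gauss1d(sigmaPx))
  }

  # integrate supersampled grid onto camera pixels
  cam <- .binMatrix(img, ss)
  photons <- optics@photonScale * cam
  if (noise) {
    cam <- matrix(rpois(length(photons), lambda = photons),
                  nrow(photons), ncol(photons)) +
      optics@offset +
      matrix(rnorm(length(photons), sd = optics@readNoise),
             nrow(photons), ncol(photons))
  } else {
    cam <- photons + optics@offset
  }
  dimnames(cam) <- NULL
  new("Micrograph", intensity = cam, pixelSize = samplePixel(optics),
      time = state@t,
      meta = list(R = R, xLeft = geom@xLeft, xRight = geom@xRight,
                  x0 = x0, v0 = v0, focus = focus, noise = noise,
                  photonScale = optics@photonScale,
                  offset = optics@offset, readNoise = optics@readNoise))
}

# Paint the patches of a state onto a strip grid in birth order (painter's
# algorithm): each cell ends up with the label of the most recently created
# patch covering it, i.e. the material actually present there now. Codes:
# 0 original (background), 1 light, 2 dark, 3 explicit "original" patches.
.labelGrid <- function(state, x0, nx, h, ny, hy) {
  P <- circumference(state@geom)
  lg <- matrix(0L, nx, ny)
  ord <- order(vapply(state@patches, `[[`, numeric(1), "tBirth"))
  codes <- c(light = 1L, dark = 2L, original = 3L)
  yc <- (seq_len(ny) - 0.5) * hy
  xc <- x0 + (seq_len(nx) - 0.5) * h
  for (p in state@patches[ord]) {
    v <- p$vertices
    v[, 2] <- .unwrapY(v[, 2], P)
    ix <- which(xc >= min(v[, 1]) - h & xc <= max(v[, 1]) + h)
    if (!length(ix)) next
    ymin <- min(v[, 2]); ymax <- max(v[, 2])
    code <- codes[[p$label]]
    for (k in c(-1, 0, 1)) {
      yk <- yc + k * P
      iy <- which(yk >= ymin - hy & yk <= ymax + hy)
      if (!length(iy)) next
      gx <- rep(xc[ix], length(iy))
      gy <- yk[rep(iy, each = length(ix))]
      ins <- cpp_points_in_polygon(gx, gy, v)
      if (any(ins))
        lg[cbind(rep(ix, length(iy))[ins],
                 rep(iy, each = length(ix))[ins])] <- code
    }
  }
  lg
}

#' Material areas by label
#'
#' Rasterizes the patch configuration (painter's algorithm in birth order,
#' as in [renderMicrograph()]) and returns the area of the cylindrical
#' domain currently occupied by light, dark, explicit original-patch and
#' background (original) material. Unlike summing polygon areas, this
#' accounts for occlusion: material displaced outward by later insertions
#' at the same source is not double counted.
#'
#' @param state a [SimulationState-class].
#' @param resolution raster pitch (um).
#' @return named numeric vector (um^2): `original`, `light`, `dark`.
#' @export
labelAreas <- function(state, resolution = 0.01) {
  geom <- state@geom
  P <- circumference(geom)
  h <- resolution
  x0 <- geom@xLeft
  nx <- max(1L, ceiling((geom@xRight - geom@xLeft) / h))
  ny <- max(8L, round(P / h))
  hy <- P / ny
  lg <- .labelGrid(state, x0, nx, h, ny, hy)
  cell <- h * hy
  c(original = sum(lg == 0L | lg == 3L) * cell,
    light = sum(lg == 1L) * cell,
    dark = sum(lg == 2L) * cell)
}

.binMatrix <- function(m, f) {
  if (f == 1L) return(m)
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  m <- m[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  m <- rowsum(m, group = rep(seq_len(nr), each = f))
  t(rowsum(t(m), group = rep(seq_len(nc), each = f)))
}

#' Render a time series of snapshots
#'
#' @param sim an `omSimulation` (uses its snapshots) or a list of
#'   [SimulationState-class] objects.
#' @param optics an [OpticsConfig-class].
#' @param noise,focus as in [renderMicrograph()].
#' @return list of [Micrograph-class] frames.
#' @export
renderStack <- function(sim, optics, noise = TRUE, focus = 0) {
  states <- if (inherits(sim, "omSimulation")) sim$snapshots else sim
  lapply(states, renderMicrograph, optics = optics, noise = noise,
         focus = focus)
}
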