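#' Incompressible source flow on the unwrapped cylinder
#'
#' Velocity of the membrane flow at one or more points, from the truncated
#' method-of-images sum. Each active source of area flux Q is replicated at
#' `y + k * P` for `k = -(nImages-1)/2 .. (nImages-1)/2` (the periodic images
#' that wrap the plane onto the cylinder), and each image contributes the 2D
#' point-source velocity `(Q / 2 pi) (r - r_ik) / |r - r_ik|^2`. The field is
#' exactly linear in the sources.
#'
#' @param points numeric vector `c(x, y)` or an n x 2 matrix of strip
#'   coordinates (um).
#' @param sources a data.frame with columns `x`, `y`, `strength` (um^2 s^-1)
#'   and optionally `active` (inactive rows are dropped), or an m x 2 matrix
#'   with `strength` supplied via the `strength` argument.
#' @param geom a [CylinderGeom-class].
#' @param nImages odd total number of image terms (default 21, i.e. image
#'   copies k = -10..10).
#' @param eps singularity guard (um): evaluation closer than this to any
#'   source image is an error.
#' @param strength source fluxes when `sources` is a bare matrix.
#' @param excludeSelf optional integer vector, one per point: the 1-based
#'   source index whose direct (k = 0) term is omitted at that point (0 for
#'   none). Used to advect a source by the field of everything but its own
#'   monopole.
#' @return an n x 2 matrix of velocities (um s^-1).
#' @seealso [closedFormVelocity()] for the exact infinite-image solution.
#' @examples
#' g <- cylinderGeom()
#' src <- data.frame(x = 0, y = 0, strength = 0.00064)
#' velocityField(c(0.05, 0), src, g)   # ~ Q/(2*pi*d) away from the source
#' @export
velocityField <- function(points, sources, geom, nImages = 21L,
                          eps = 1e-4, strength = NULL, excludeSelf = NULL) {
  pts <- .asPointMatrix(points)
  if (is.data.frame(sources)) {
    if (!is.null(sources$active)) sources <- sources[sources$active, , drop = FALSE]
    src <- cbind(sources$x, sources$y)
    Q <- sources$strength
  } else {
    src <- .asPointMatrix(sources)
    Q <- if (is.null(strength)) rep(1, nrow(src)) else rep_len(strength, nrow(src))
  }
  nImages <- as.integer(nImages)
  if (length(nImages) != 1 || is.na(nImages) || nImages < 1L ||
      nImages %% 2L == 0L)
    stop("nImages must be a single odd positive integer")
  if (any(Q < 0)) stop("source strengths must be non-negative")
  if (nrow(src) == 0L)
    return(matrix(0, nrow(pts), 2))
  self <- if (is.null(excludeSelf)) integer(0) else as.integer(excludeSelf)
  cpp_velocity(pts, src, as.numeric(Q), circumference(geom), nImages,
               eps, self)
}

#' Exact periodic-source velocity (infinite image sum)
#'
#' Closed form of the infinite method-of-images sum for a single point
#' source on the periodic strip, from the complex potential of a periodic
#' row of sources:
#' `vx = (Q/2P) sinh(2 pi dx / P) / (cosh(2 pi dx / P) - cos(2 pi dy / P))`
#' and the analogous `vy` with `sin` in the numerator. Serves as the
#' independent oracle for [velocityField()].
#'
#' @param points point(s) as in [velocityField()].
#' @param source length-2 numeric, the source position (um).
#' @param strength source area flux Q (um^2 s^-1).
#' @param geom a [CylinderGeom-class].
#' @return an n x 2 matrix of velocities (um s^-1).
#' @export
closedFormVelocity <- function(points, source, strength, geom) {
  pts <- .asPointMatrix(points)
  P <- circumference(geom)
  dx <- 2 * pi * (pts[, 1] - source[1]) / P
  dy <- 2 * pi * (pts[, 2] - source[2]) / P
  den <- cosh(dx) - cos(dy)
  if (any(den < .Machine$double.eps))
    stop("closed-form velocity is singular at the source position")
  cbind(strength / (2 * P) * sinh(dx) / den,
        strength / (2 * P) * sin(dy) / den)
}

#' Wrap-aware polygon area
#'
#' Shoelace area of a patch polygon on the periodic strip. Vertices are
#' first unwrapped by continuity in y (consecutive vertices are assumed to
#' be less than half a circumference apart), so a polygon straddling the
#' periodic seam is measured correctly; translating a polygon by a whole
#' circumference leaves its area unchanged.
#'
#' @param patch a patch record (list with a `vertices` matrix) or a bare
#'   n x 2 vertex matrix.
#' @param geom a [CylinderGeom-class].
#' @param check if `TRUE`, reject self-intersecting polygons.
#' @return positive area (um^2).
#' @export
polygonArea <- function(patch, geom, check = TRUE) {
  v <- if (is.list(patch) && !is.null(patch$vertices)) patch$vertices else patch
  if (!is.matrix(v) || nrow(v) < 3L)
    stop("a patch needs at least three vertices")
  v[, 2] <- .unwrapY(v[, 2], circumference(geom))
  if (check && .selfIntersects(v))
    stop("invalid patch: polygon is self-intersecting")
  abs(.shoelace(v))
}

.shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  i2 <- c(seq_len(nrow(v))[-1], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

# unwrap a periodic coordinate sequence by continuity
.unwrapY <- function(y, P) {
  if (length(y) < 2L) return(y)
  d <- diff(y)
  d <- d - P * round(d / P)
  y[1] + c(0, cumsum(d))
}

.asPointMatrix <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 2) stop("a point must have two coordinates")
    matrix(as.numeric(p), 1, 2)
  } else {
    storage.mode(p) <- "double"
    if (ncol(p) != 2) stop("points must be an n x 2 matrix")
    p
  }
}

# O(n^2) proper-crossing test between non-adjacent edges
.selfIntersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  a <- v; b <- v[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (.segCross(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

.segCross <- function(p1, p2, p3, p4) {
  d1 <- .cross2(p4 - p3, p1 - p3)
  d2 <- .cross2(p4 - p3, p2 - p3)
  d3 <- .cross2(p2 - p1, p3 - p1)
  d4 <- .cross2(p2 - p1, p4 - p1)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

.cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Advect a simulation state through the source flow
#'
#' Moves every patch vertex and every source position through the flow of
#' the currently active sources for a time `dt`, and moves the axial domain
#' ends with the circumferentially averaged axial velocity (exactly
#' `+/- Q / (2P)` per enclosed source), so that the flow converges on the
#' inert poles and the area ledger `P * (xRight - xLeft)` stays exact.
#' Patch vertices feel the full field; each source is advected by all other
#' sources' fields plus its own periodic images, excluding only its own
#' direct monopole term (a monopole exerts no net force on itself).
#'
#' With no active sources the state is returned unchanged. The flow is
#' divergence-free away from the sources, so a passive polygon's area is
#' conserved to first order in `dt`; `areaTolerance` optionally enforces
#' this as a hard numerical-accuracy check.
#'
#' @param state a [SimulationState-class].
#' @param dt time step (s), positive.
#' @param nImages image-sum truncation, as in [velocityField()].
#' @param scheme `"euler"` (default) or `"rk2"` (midpoint).
#' @param areaTolerance if not `NULL`, maximum allowed relative area drift
#'   of any passive patch (one not attached to an active source) in this
#'   step; violation is an error.
#' @param eps singularity guard (um).
#' @return the advected [SimulationState-class] (clock unchanged;
#'   [step()] owns the clock and the event bookkeeping).
#' @export
advect <- function(state, dt, nImages = 21L, scheme = c("euler", "rk2"),
                   areaTolerance = NULL, eps = 1e-4) {
  scheme <- match.arg(scheme)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a single positive number")
  src <- state@sources
  act <- which(src$active)
  if (length(act) == 0L) return(state)

  passiveBefore <- NULL
  if (!is.null(areaTolerance)) {
    passive <- which(!vapply(state@patches, function(p)
      p$sourceId %in% src$id[act], logical(1)))
    passiveBefore <- vapply(state@patches[passive], polygonArea,
                            numeric(1), geom = state@geom, check = FALSE)
  }

  P <- circumference(state@geom)
  srcM <- cbind(src$x[act], src$y[act])
  Q <- src$strength[act]

  nvert <- vapply(state@patches, function(p) nrow(p$vertices), integer(1))
  verts <- do.call(rbind, c(lapply(state@patches, `[[`, "vertices"),
                            list(matrix(0, 0, 2))))
  pts <- rbind(verts, cbind(src$x, src$y))
  self <- c(rep(0L, nrow(verts)),
            match(seq_len(nrow(src)), act, nomatch = 0L))
  vel <- cpp_velocity(pts, srcM, Q, P, as.integer(nImages), eps, self)
  if (scheme == "rk2") {
    mid <- pts + 0.5 * dt * vel
    vel <- cpp_velocity(mid, srcM, Q, P, as.integer(nImages), eps, self)
  }
  pts <- pts + dt * vel

  if (length(nvert)) {
    ends <- cumsum(nvert)
    starts <- ends - nvert + 1L
    for (i in seq_along(state@patches))
      state@patches[[i]]$vertices <- pts[starts[i]:ends[i], , drop = FALSE]
  }
  nV <- sum(nvert)
  src$x <- pts[nV + seq_len(nrow(src)), 1]
  src$y <- pts[nV + seq_len(nrow(src)), 2]
  state@sources <- src

  dEnd <- sum(Q) * dt / (2 * P)
  state@geom@xLeft <- state@geom@xLeft - dEnd
  state@geom@xRight <- state@geom@xRight + dEnd

  if (!is.null(areaTolerance) && length(passiveBefore)) {
    after <- vapply(state@patches[passive], polygonArea, numeric(1),
                    geom = state@geom, check = FALSE)
    drift <- abs(after - passiveBefore) / passiveBefore
    if (any(drift > areaTolerance))
      stop(sprintf(
        "numerical accuracy: passive patch area drifted by %.3g (tolerance %.3g); reduce dt",
        max(drift), areaTolerance))
  }
  state
}
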