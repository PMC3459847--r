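#' Initialize a membrane-growth simulation
#'
#' Empty state: no patches, no sources, clock at zero, RNG seeded. The
#' default geometry is a typical E. coli cylinder, radius 0.5 um and
#' initial length 2 um (initial cylindrical area ~6.283 um^2).
#'
#' @param geom a [CylinderGeom-class].
#' @param params a [KineticParams-class].
#' @param seed integer RNG seed; the state carries the RNG stream so runs
#'   replay exactly.
#' @param schedule a [LabelSchedule-class].
#' @return a [SimulationState-class].
#' @export
initState <- function(geom = cylinderGeom(), params, seed = 1L,
                      schedule = labelSchedule()) {
  validObject(geom); validObject(params); validObject(schedule)
  set.seed(as.integer(seed))
  new("SimulationState", t = 0, geom = geom, params = params,
      schedule = schedule, patches = list(), sources = .emptySources(),
      rngState = get(".Random.seed", envir = globalenv()),
      initialArea = surfaceArea(geom))
}

.emptySources <- function()
  data.frame(id = integer(0), x = numeric(0), y = numeric(0),
             strength = numeric(0), active = logical(0),
             tStart = numeric(0), duration = numeric(0),
             label = character(0), areaInserted = numeric(0))

#' Add a material patch to a state
#'
#' Inserts a regular polygon of given area by hand, e.g. to construct
#' labeled-material configurations for rendering and detection tests or to
#' mimic pre-labeled material in a growth-arrested (rifampin-like) cell.
#' Manual patches carry no source and are passive under the flow.
#'
#' @param state a [SimulationState-class].
#' @param center length-2 numeric, patch center (um).
#' @param area patch area (um^2).
#' @param label `"light"`, `"dark"` or `"original"`.
#' @param nVertices number of polygon vertices.
#' @return the modified state.
#' @export
addPatch <- function(state, center, area, label = "light", nVertices = 12L) {
  stopifnot(area > 0, length(center) == 2)
  state@patches <- c(state@patches, list(list(
    vertices = .regularPolygon(center, area, as.integer(nVertices)),
    label = label, sourceId = NA_integer_, tBirth = state@t)))
  state
}

# regular nv-gon of given area, counter-clockwise
.regularPolygon <- function(center, area, nv) {
  r <- sqrt(2 * area / (nv * sin(2 * pi / nv)))
  th <- 2 * pi * (seq_len(nv) - 1) / nv
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# number of vertices for new patches: larger expected patches are smoother
.defaultVertexCount <- function(expectedArea)
  max(6L, min(24L, as.integer(round(6 + 4 * log10(expectedArea / 1e-3)))))

## ---- internal fast state (environment of flat arrays) -------------------

.newSimEnv <- function(geom, params, schedule, dtMax = 0.5, nImages = 21L,
                       scheme = "euler", trackPatches = TRUE,
                       nVertices = NULL, eps = 1e-4) {
  e <- new.env(parent = emptyenv())
  e$R <- geom@R; e$P <- 2 * pi * geom@R
  e$xL <- geom@xLeft; e$xR <- geom@xRight
  e$params <- params
  e$kOn <- params@kOn; e$kIns <- params@kIns; e$tau <- params@tau
  e$schedEnds <- cumsum(schedule@durations)
  e$schedLabs <- match(schedule@labels, c("light", "dark"))
  e$schedule <- schedule
  e$t <- 0; e$A0 <- e$P * (e$xR - e$xL)
  e$dtMax <- dtMax; e$nImages <- as.integer(nImages); e$scheme <- scheme
  e$trackPatches <- trackPatches; e$eps <- eps
  e$nv <- if (is.null(nVertices)) .defaultVertexCount(params@tau * params@kIns)
          else as.integer(nVertices)
  cap <- 64L
  e$sx <- numeric(cap); e$sy <- numeric(cap); e$sAct <- logical(cap)
  e$sT0 <- numeric(cap); e$sDur <- numeric(cap); e$sLab <- integer(cap)
  e$sArea <- numeric(cap); e$nSrc <- 0L
  e$V <- matrix(0, 512L, 2); e$nVert <- 0L
  e$pStart <- integer(0); e$pLen <- integer(0); e$pLab <- integer(0)
  e$pSrc <- integer(0); e$pBirth <- numeric(0)
  e$curLab <- .labelIntAt(e, 0)
  e
}

# append one patch polygon to the flat-array store
.appendPatch <- function(e, center, area, lab, srcIdx) {
  .growVerts(e, e$nv)
  vv <- .regularPolygon(center, area, e$nv)
  e$V[e$nVert + seq_len(e$nv), ] <- vv
  e$pStart <- c(e$pStart, e$nVert + 1L)
  e$pLen <- c(e$pLen, e$nv)
  e$pLab <- c(e$pLab, lab)
  e$pSrc <- c(e$pSrc, srcIdx)
  e$pBirth <- c(e$pBirth, e$t)
  e$nVert <- e$nVert + e$nv
}

.growSrc <- function(e, n) {
  need <- e$nSrc + n
  cap <- length(e$sx)
  if (need > cap) {
    newCap <- max(2L * cap, need)
    pad <- newCap - cap
    e$sx <- c(e$sx, numeric(pad)); e$sy <- c(e$sy, numeric(pad))
    e$sAct <- c(e$sAct, logical(pad)); e$sT0 <- c(e$sT0, numeric(pad))
    e$sDur <- c(e$sDur, numeric(pad)); e$sLab <- c(e$sLab, integer(pad))
    e$sArea <- c(e$sArea, numeric(pad))
  }
}

.growVerts <- function(e, n) {
  need <- e$nVert + n
  cap <- nrow(e$V)
  if (need > cap) {
    newV <- matrix(0, max(2L * cap, need), 2)
    newV[seq_len(e$nVert), ] <- e$V[seq_len(e$nVert), ]
    e$V <- newV
  }
}

.labelIntAt <- function(e, t) {
  i <- findInterval(t, c(0, e$schedEnds), rightmost.closed = FALSE)
  e$schedLabs[min(max(i, 1L), length(e$schedLabs))]
}

# One simulation step on the flat-array state. Order of operations:
# terminate expired events; sample initiations (Poisson) with durations
# (exponential) and uniform positions; advect all existing vertices and
# sources through the flow of the surviving active sources; move the domain
# ends by the total inserted area (surviving events' flux plus the area of
# the polygons created for the new events, keeping the area ledger exact);
# then create the new events' regular polygons of area kIns*dt. New events
# join the flow field from the next step on - their creation IS this step's
# insertion.
.stepOnce <- function(e, dtCap = Inf, dtOverride = NULL) {
  A <- e$P * (e$xR - e$xL)
  dt <- if (is.null(dtOverride))
    min(e$tau / 20, 1 / (20 * e$kOn * A), e$dtMax, dtCap)
  else dtOverride
  ns <- e$nSrc
  if (ns) {
    idx <- seq_len(ns)
    expired <- which(e$sAct[idx] & (e$sT0[idx] + e$sDur[idx] <= e$t))
    if (length(expired)) e$sAct[expired] <- FALSE
    act <- which(e$sAct[idx])
  } else act <- integer(0)

  # label phase boundary: events that keep inserting now deposit material of
  # the new label, so each surviving active source starts a fresh patch that
  # will overpaint the light core it displaces outward
  labNow <- .labelIntAt(e, e$t)
  if (labNow != e$curLab) {
    if (e$trackPatches)
      for (s in act)
        .appendPatch(e, c(e$sx[s], e$sy[s]), e$kIns * dt, labNow, s)
    e$curLab <- labNow
  }

  ev <- sampleEvents(A, dt, e$params)
  nNew <- ev$count
  if (nNew) {
    px <- runif(nNew, e$xL, e$xR)
    py <- runif(nNew, 0, e$P)
  }

  if (length(act) && (e$nVert + ns) > 0L) {
    srcM <- cbind(e$sx[act], e$sy[act])
    Q <- rep(e$kIns, length(act))
    pts <- rbind(e$V[seq_len(e$nVert), , drop = FALSE],
                 cbind(e$sx[seq_len(ns)], e$sy[seq_len(ns)]))
    self <- c(rep(0L, e$nVert), match(seq_len(ns), act, nomatch = 0L))
    vel <- cpp_velocity(pts, srcM, Q, e$P, e$nImages, e$eps, self)
    if (e$scheme == "rk2") {
      mid <- pts + 0.5 * dt * vel
      vel <- cpp_velocity(mid, srcM, Q, e$P, e$nImages, e$eps, self)
    }
    pts <- pts + dt * vel
    if (e$nVert) e$V[seq_len(e$nVert), ] <- pts[seq_len(e$nVert), ]
    e$sx[seq_len(ns)] <- pts[e$nVert + seq_len(ns), 1]
    e$sy[seq_len(ns)] <- pts[e$nVert + seq_len(ns), 2]
  }

  dA <- e$kIns * dt * (length(act) + nNew)
  shift <- dA / (2 * e$P)
  e$xL <- e$xL - shift
  e$xR <- e$xR + shift
  if (length(act)) e$sArea[act] <- e$sArea[act] + e$kIns * dt

  if (nNew) {
    .growSrc(e, nNew)
    j <- e$nSrc + seq_len(nNew)
    e$sx[j] <- px; e$sy[j] <- py
    e$sAct[j] <- TRUE; e$sT0[j] <- e$t; e$sDur[j] <- ev$durations
    e$sLab[j] <- labNow; e$sArea[j] <- e$kIns * dt
    e$nSrc <- e$nSrc + nNew
    if (e$trackPatches)
      for (m in seq_len(nNew))
        .appendPatch(e, c(px[m], py[m]), e$kIns * dt, labNow, j[m])
  }
  e$t <- e$t + dt
  dt
}

.envToState <- function(e, rngState, initialArea) {
  ns <- e$nSrc
  idx <- seq_len(ns)
  sources <- data.frame(
    id = idx, x = e$sx[idx], y = e$sy[idx] %% e$P,
    strength = rep(e$kIns, ns), active = e$sAct[idx],
    tStart = e$sT0[idx], duration = e$sDur[idx],
    label = c("light", "dark")[e$sLab[idx]], areaInserted = e$sArea[idx])
  patches <- vector("list", length(e$pStart))
  for (i in seq_along(patches)) {
    rows <- e$pStart[i] + seq_len(e$pLen[i]) - 1L
    patches[[i]] <- list(vertices = e$V[rows, , drop = FALSE],
                         label = c("light", "dark", "original")[e$pLab[i]],
                         sourceId = if (e$pSrc[i] > 0L) e$pSrc[i]
                                    else NA_integer_,
                         tBirth = e$pBirth[i])
  }
  new("SimulationState", t = e$t,
      geom = new("CylinderGeom", R = e$R, xLeft = e$xL, xRight = e$xR),
      params = e$params, schedule = e$schedule,
      patches = patches, sources = sources,
      rngState = rngState, initialArea = initialArea)
}

.stateToEnv <- function(state, dtMax = 0.5, nImages = 21L,
                        scheme = "euler", trackPatches = TRUE,
                        nVertices = NULL, eps = 1e-4) {
  e <- .newSimEnv(state@geom, state@params, state@schedule, dtMax, nImages,
                  scheme, trackPatches, nVertices, eps)
  e$t <- state@t
  e$A0 <- state@initialArea
  e$curLab <- .labelIntAt(e, state@t)
  src <- state@sources
  ns <- nrow(src)
  if (ns) {
    .growSrc(e, ns)
    idx <- seq_len(ns)
    e$sx[idx] <- src$x; e$sy[idx] <- src$y
    e$sAct[idx] <- src$active; e$sT0[idx] <- src$tStart
    e$sDur[idx] <- src$duration
    e$sLab[idx] <- match(src$label, c("light", "dark"))
    e$sArea[idx] <- src$areaInserted
    e$nSrc <- ns
  }
  for (p in state@patches) {
    nv <- nrow(p$vertices)
    .growVerts(e, nv)
    e$V[e$nVert + seq_len(nv), ] <- p$vertices
    e$pStart <- c(e$pStart, e$nVert + 1L)
    e$pLen <- c(e$pLen, nv)
    e$pLab <- c(e$pLab, match(p$label, c("light", "dark", "original"),
                              nomatch = 3L))
    e$pSrc <- c(e$pSrc, if (is.na(p$sourceId)) 0L else p$sourceId)
    e$pBirth <- c(e$pBirth, p$tBirth)
    e$nVert <- e$nVert + nv
  }
  e
}

#' Advance a simulation by one step
#'
#' One full simulator step: terminate expired insertion events, sample new
#' initiations (Poisson, uniform positions, label from the schedule), create
#' each new event's regular polygon of area `kIns * dt`, credit each
#' surviving active event's flux, and advect all vertices, sources and the
#' domain ends. The state's stored RNG stream is used and updated, so
#' repeated stepping replays exactly.
#'
#' @param state a [SimulationState-class].
#' @param dt step length (s); `NULL` (default) uses the kinetic step rule
#'   [timeStep()].
#' @param nImages,scheme,eps advection controls, see [advect()].
#' @param trackPatches if `FALSE`, patch polygons are not created (event and
#'   area bookkeeping is unchanged; the RNG stream and the area trajectory
#'   are identical, since the geometry never feeds back on the kinetics).
#' @return the advanced [SimulationState-class].
#' @export
step <- function(state, dt = NULL, nImages = 21L, scheme = "euler",
                 trackPatches = TRUE, eps = 1e-4) {
  e <- .stateToEnv(state, nImages = nImages, scheme = scheme,
                   trackPatches = trackPatches, eps = eps)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  assign(".Random.seed", state@rngState, envir = globalenv())
  .stepOnce(e, dtOverride = dt)
  .envToState(e, get(".Random.seed", envir = globalenv()),
              state@initialArea)
}

#' Build a simulation configuration
#'
#' Collects geometry, kinetics, labeling schedule, output and numerics
#' settings into the configuration consumed by [runSimulation()].
#' If `tau` is omitted it is constrained by the doubling time through
#' [solveTau()].
#'
#' @param R,length cylinder radius and initial length (um).
#' @param kOn,kIns,tau,tDouble kinetics (see [kineticParams()]).
#' @param light,dark label phase durations (s).
#' @param tMax total simulated time (s).
#' @param snapshotTimes times (s) at which full states are kept.
#' @param seed RNG seed.
#' @param dtMax cap on the kinetic step rule (s).
#' @param nImages image-sum truncation.
#' @param scheme `"euler"` or `"rk2"`.
#' @param trackPatches keep patch polygon geometry (see [step()]).
#' @param nVertices vertices per new patch polygon; `NULL` chooses from the
#'   mean event area.
#' @param stopAreaFactor if not `NULL`, stop once the cylindrical area
#'   reaches this multiple of the initial area and record the crossing time.
#' @param initialPatches optional list of pre-existing material patches,
#'   each a list with `center` (um), `area` (um^2), and optionally `label`
#'   (default `"light"`) and `nVertices`; useful as passive flow markers or
#'   to mimic pre-labeled material.
#' @return a list of class `omSimConfig`.
#' @export
simConfig <- function(R = 0.5, length = 2, kOn = 0.004, kIns = 0.00064,
                      tau = NULL, tDouble = 5400, light = 900, dark = 4500,
                      tMax = 5400, snapshotTimes = numeric(0), seed = 1L,
                      dtMax = 0.5, nImages = 21L, scheme = "euler",
                      trackPatches = TRUE, nVertices = NULL,
                      stopAreaFactor = NULL, initialPatches = NULL) {
  cfg <- list(geom = cylinderGeom(R = R, length = length),
              params = kineticParams(kOn, kIns, tau = tau,
                                     tDouble = if (is.null(tau)) tDouble else NULL),
              schedule = labelSchedule(light = light, dark = dark),
              tMax = tMax, snapshotTimes = snapshotTimes,
              seed = as.integer(seed), dtMax = dtMax,
              nImages = as.integer(nImages), scheme = scheme,
              trackPatches = trackPatches, nVertices = nVertices,
              stopAreaFactor = stopAreaFactor,
              initialPatches = initialPatches)
  class(cfg) <- "omSimConfig"
  cfg
}

#' Run a membrane-growth simulation
#'
#' Runs the stochastic simulator for `tMax` seconds (or until the area
#' crossing requested by `stopAreaFactor`), keeping full state snapshots at
#' the requested times and a per-step trace of the clock, cylindrical area
#' and number of active insertion events. Fully replayable from the seed.
#'
#' @param config an `omSimConfig` from [simConfig()] or [readSimConfig()].
#' @return an object of class `omSimulation`: a list with `snapshots` (list
#'   of [SimulationState-class]), `trace` (data.frame `t`, `area`,
#'   `nActive`), `doublingTime` (s; first crossing of twice the initial
#'   area, interpolated between steps, `NA` if never reached), `config` and
#'   `seed`.
#' @examples
#' cfg <- simConfig(tMax = 60, seed = 7)
#' sim <- runSimulation(cfg)
#' tail(sim$trace)
#' @export
runSimulation <- function(config) {
  stopifnot(inherits(config, "omSimConfig"))
  set.seed(config$seed)
  e <- .newSimEnv(config$geom, config$params, config$schedule,
                  dtMax = config$dtMax, nImages = config$nImages,
                  scheme = config$scheme, trackPatches = config$trackPatches,
                  nVertices = config$nVertices)
  for (p in config$initialPatches) {
    nvSave <- e$nv
    if (!is.null(p$nVertices)) e$nv <- as.integer(p$nVertices)
    .appendPatch(e, p$center, p$area,
                 match(p$label %||% "light", c("light", "dark", "original"),
                       nomatch = 3L), 0L)
    e$nv <- nvSave
  }
  tMax <- config$tMax
  snapT <- sort(config$snapshotTimes)
  snaps <- vector("list", length(snapT))
  snapIdx <- 1L
  A0 <- e$A0
  while (snapIdx <= length(snapT) && snapT[snapIdx] <= 0) {
    snaps[[snapIdx]] <- .envToState(e, get(".Random.seed", globalenv()), A0)
    snapIdx <- snapIdx + 1L
  }
  cap <- as.integer(min(2e6, ceiling(tMax / min(0.4, e$tau / 20)) + 64L))
  trT <- numeric(cap); trA <- numeric(cap); trN <- integer(cap)
  nTr <- 0L
  target <- if (is.null(config$stopAreaFactor)) Inf
            else config$stopAreaFactor * A0
  tCross <- NA_real_
  prevT <- 0; prevA <- A0
  while (e$t < tMax - 1e-9) {
    .stepOnce(e, dtCap = tMax - e$t)
    A <- e$P * (e$xR - e$xL)
    nTr <- nTr + 1L
    if (nTr > length(trT)) {
      trT <- c(trT, numeric(length(trT)))
      trA <- c(trA, numeric(length(trA)))
      trN <- c(trN, integer(length(trN)))
    }
    trT[nTr] <- e$t; trA[nTr] <- A
    trN[nTr] <- sum(e$sAct[seq_len(e$nSrc)])
    if (is.na(tCross) && A >= 2 * A0)
      tCross <- prevT + (2 * A0 - prevA) / (A - prevA) * (e$t - prevT)
    while (snapIdx <= length(snapT) && e$t >= snapT[snapIdx] - 1e-9) {
      snaps[[snapIdx]] <- .envToState(e, get(".Random.seed", globalenv()), A0)
      snapIdx <- snapIdx + 1L
    }
    if (A >= target) break
    prevT <- e$t; prevA <- A
  }
  out <- list(snapshots = snaps[!vapply(snaps, is.null, logical(1))],
              trace = data.frame(t = trT[seq_len(nTr)],
                                 area = trA[seq_len(nTr)],
                                 nActive = trN[seq_len(nTr)]),
              doublingTime = tCross, finalState = .envToState(
                e, get(".Random.seed", globalenv()), A0),
              config = config, seed = config$seed)
  class(out) <- "omSimulation"
  out
}

#' @export
print.omSimulation <- function(x, ...) {
  fs <- x$finalState
  cat(sprintf(paste0(
    "omSimulation: t = %.4g s, area %.4g um^2 (initial %.4g), ",
    "%d events, %d snapshots\n"),
    fs@t, surfaceArea(fs), fs@initialArea, nrow(fs@sources),
    length(x$snapshots)))
  if (!is.na(x$doublingTime))
    cat(sprintf("  area doubled at t = %.4g s (%.3g min)\n",
                x$doublingTime, x$doublingTime / 60))
  invisible(x)
}

#' Total patch area by label
#'
#' @param state a [SimulationState-class].
#' @param label patch label to sum over (`"light"`, `"dark"`,
#'   `"original"`), or `NULL` for all patches.
#' @return total area (um^2).
#' @export
totalPatchArea <- function(state, label = NULL) {
  ps <- state@patches
  if (!is.null(label))
    ps <- ps[vapply(ps, function(p) identical(p$label, label), logical(1))]
  if (!length(ps)) return(0)
  sum(vapply(ps, polygonArea, numeric(1), geom = state@geom, check = FALSE))
}

#' Patch centroids
#'
#' Vertex-average centroids of the patches of a state, wrap-aware in y.
#'
#' @param state a [SimulationState-class].
#' @param label optional label filter.
#' @return data.frame with `x`, `y` (um, y wrapped into `[0, P)`) and
#'   `label`.
#' @export
patchCentroids <- function(state, label = NULL) {
  ps <- state@patches
  if (!is.null(label))
    ps <- ps[vapply(ps, function(p) identical(p$label, label), logical(1))]
  P <- circumference(state@geom)
  if (!length(ps))
    return(data.frame(x = numeric(0), y = numeric(0), label = character(0)))
  data.frame(
    x = vapply(ps, function(p) mean(p$vertices[, 1]), numeric(1)),
    y = vapply(ps, function(p)
      mean(.unwrapY(p$vertices[, 2], P)), numeric(1)) %% P,
    label = vapply(ps, `[[`, character(1), "label"))
}
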