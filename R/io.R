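#' Read a simulation configuration file
#'
#' YAML configuration with sections `geometry` (`R`, `length`), `kinetics`
#' (`k_on`, `k_ins`, and `tau` or `t_double`), `schedule` (`light`, `dark`,
#' in seconds), `output` (`t_max`, `snapshot_times`, optional
#' `stop_area_factor`), `numerics` (optional `dt_max`, `n_images`,
#' `scheme`, `track_patches`) and `seed`.
#'
#' @param path file path.
#' @return an `omSimConfig`, see [simConfig()].
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  geo <- y$geometry %||% list()
  kin <- y$kinetics
  if (is.null(kin$k_on) || is.null(kin$k_ins))
    stop("config must set kinetics: k_on and k_ins")
  if (is.null(kin$tau) && is.null(kin$t_double))
    stop("config must set kinetics: tau or t_double")
  sch <- y$schedule %||% list()
  out <- y$output %||% list()
  num <- y$numerics %||% list()
  simConfig(R = geo$R %||% 0.5, length = geo$length %||% 2,
            kOn = kin$k_on, kIns = kin$k_ins, tau = kin$tau,
            tDouble = kin$t_double %||% 5400,
            light = sch$light %||% 900, dark = sch$dark %||% 4500,
            tMax = out$t_max %||% 5400,
            snapshotTimes = unlist(out$snapshot_times) %||% numeric(0),
            seed = y$seed %||% 1L,
            dtMax = num$dt_max %||% 0.5,
            nImages = num$n_images %||% 21L,
            scheme = num$scheme %||% "euler",
            trackPatches = num$track_patches %||% TRUE,
            stopAreaFactor = out$stop_area_factor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a virtual-microscope configuration file
#'
#' YAML with any subset of the [opticsConfig()] fields (`na`, `wavelength`,
#' `magnification`, `camera_pixel`, `psf_model`, `z_layers`,
#' `photon_scale`, `read_noise`, `offset`, `super_sample`, `margin`);
#' missing fields keep their defaults.
#'
#' @param path file path.
#' @return an [OpticsConfig-class].
#' @export
readOpticsConfig <- function(path) {
  y <- yaml::read_yaml(path) %||% list()
  opticsConfig(na = y$na %||% 1.4,
               wavelength = y$wavelength %||% 575,
               magnification = y$magnification %||% 100,
               cameraPixel = y$camera_pixel %||% 6.8,
               psfModel = y$psf_model %||% "gaussian",
               zLayers = y$z_layers %||% 9L,
               photonScale = y$photon_scale %||% 2e4,
               readNoise = y$read_noise %||% 2,
               offset = y$offset %||% 100,
               superSample = y$super_sample %||% 4L,
               margin = y$margin %||% 0.4)
}

.stateToList <- function(state) {
  list(t = state@t, units = list(length = "um", time = "s"),
       geom = list(R = state@geom@R, xLeft = state@geom@xLeft,
                   xRight = state@geom@xRight),
       params = list(kOn = state@params@kOn, kIns = state@params@kIns,
                     tau = state@params@tau, tDouble = state@params@tDouble),
       initialArea = state@initialArea,
       sources = state@sources,
       patches = lapply(state@patches, function(p)
         list(vertices = unname(p$vertices), label = p$label,
              sourceId = p$sourceId, tBirth = p$tBirth)))
}

#' Write simulation snapshots to JSON
#'
#' One JSON file per snapshot (`snapshot_<k>.json`, explicit units) plus an
#' `index.json` with times, the seed and the doubling-time estimate, so a
#' run can be re-examined or re-rendered without re-simulating.
#'
#' @param sim an `omSimulation` from [runSimulation()].
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
writeSnapshots <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(sim$snapshots)) {
    p <- file.path(dir, sprintf("snapshot_%03d.json", i))
    jsonlite::write_json(.stateToList(sim$snapshots[[i]]), p,
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  idx <- file.path(dir, "index.json")
  jsonlite::write_json(list(
    n = length(sim$snapshots),
    times = vapply(sim$snapshots, function(s) s@t, numeric(1)),
    seed = sim$seed, doublingTime = sim$doublingTime), idx,
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, idx))
}

#' Read one snapshot back from JSON
#'
#' @param path a `snapshot_*.json` written by [writeSnapshots()].
#' @param params,schedule optional [KineticParams-class] /
#'   [LabelSchedule-class] to attach (the JSON stores the kinetic scalars).
#' @return a [SimulationState-class] (with a fresh RNG state; replay
#'   continuity is only preserved through `runSimulation`).
#' @export
readSnapshot <- function(path, params = NULL, schedule = labelSchedule()) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(params))
    params <- kineticParams(j$params$kOn, j$params$kIns, tau = j$params$tau)
  geom <- cylinderGeom(R = j$geom$R, xLeft = j$geom$xLeft,
                       xRight = j$geom$xRight)
  patches <- lapply(seq_len(length(j$patches$label %||% character(0))),
                    function(i)
    list(vertices = matrix(unlist(j$patches$vertices[[i]]), ncol = 2),
         label = j$patches$label[i], sourceId = j$patches$sourceId[i],
         tBirth = j$patches$tBirth[i]))
  if (is.data.frame(j$patches))
    patches <- lapply(seq_len(nrow(j$patches)), function(i)
      list(vertices = matrix(unlist(j$patches$vertices[[i]]), ncol = 2),
           label = j$patches$label[i], sourceId = j$patches$sourceId[i],
           tBirth = j$patches$tBirth[i]))
  src <- if (length(j$sources)) as.data.frame(j$sources) else .emptySources()
  set.seed(0)
  new("SimulationState", t = j$t, geom = geom, params = params,
      schedule = schedule, patches = patches, sources = src,
      rngState = get(".Random.seed", envir = globalenv()),
      initialArea = j$initialArea)
}

#' Write a micrograph stack as (multi-page) TIFF
#'
#' 32-bit float TIFF, one page per frame; pixel size and frame times go to
#' a JSON sidecar (`<path>.json`), since baseline TIFF tags cannot carry
#' them portably. Intensities are stored unscaled.
#'
#' @param stack a [Micrograph-class] or list of them.
#' @param path output `.tif` path.
#' @return invisibly, `path`.
#' @export
writeStack <- function(stack, path) {
  if (is(stack, "Micrograph")) stack <- list(stack)
  # TIFF sample values must lie in [0, 1]; scale down and record the factor
  scale <- max(1, vapply(stack, function(f) max(f@intensity), numeric(1)))
  imgs <- lapply(stack, function(f) f@intensity / scale)
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(
    pixelSizeNm = stack[[1]]@pixelSize, scale = scale,
    times = vapply(stack, function(f) f@time, numeric(1)),
    meta = stack[[1]]@meta), paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TIFF stack written by [writeStack()] (or any plain TIFF)
#'
#' @param path `.tif` path; if a `<path>.json` sidecar exists, pixel size,
#'   times and geometry metadata are restored from it.
#' @param pixelSize pixel size (nm) when no sidecar is present.
#' @return list of [Micrograph-class] frames.
#' @export
readStack <- function(path, pixelSize = NULL) {
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(imgs)) imgs <- list(imgs)
  side <- paste0(path, ".json")
  meta <- list(); times <- seq_along(imgs) - 1; scale <- 1
  if (file.exists(side)) {
    j <- jsonlite::read_json(side, simplifyVector = TRUE)
    pixelSize <- j$pixelSizeNm
    times <- j$times
    scale <- j$scale %||% 1
    meta <- as.list(j$meta)
  }
  if (is.null(pixelSize))
    stop("uncalibrated stack: supply pixelSize (nm) or a JSON sidecar")
  lapply(seq_along(imgs), function(i)
    new("Micrograph", intensity = imgs[[i]] * scale, pixelSize = pixelSize,
        time = times[i], meta = meta))
}
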