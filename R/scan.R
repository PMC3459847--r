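#' Build a kinetic parameter-space scan grid
#'
#' Pairs of (kOn, kIns) with the mean event duration tau constrained by the
#' common doubling time through [solveTau()]. Every pair must be feasible
#' (`kOn * kIns > (log(2)/tDouble)^2`); infeasible pairs are rejected at
#' validation. The default grid is 10 x 10 log-spaced pairs plus the
#' headline pair (kOn = 0.004, kIns = 0.00064), 101 parameter sets.
#'
#' @param kOnValues,kInsValues grid axes (um^-2 s^-1 and um^2 s^-1).
#' @param tDouble common doubling time (s).
#' @param replicates simulations per pair.
#' @param seed base RNG seed; pair r of replicate k runs with a seed
#'   derived deterministically from it.
#' @param includeHeadline add the (0.004, 0.00064) pair if absent.
#' @return data.frame with columns `kOn`, `kIns`, `tau`, `meanEventArea`,
#'   plus attributes `tDouble`, `replicates`, `seed`.
#' @export
scanGrid <- function(kOnValues = 10^seq(log10(0.001), log10(0.03),
                                        length.out = 10),
                     kInsValues = 10^seq(log10(1e-4), log10(2e-2),
                                         length.out = 10),
                     tDouble = 5400, replicates = 21L, seed = 1L,
                     includeHeadline = TRUE) {
  g <- expand.grid(kOn = kOnValues, kIns = kInsValues)
  if (includeHeadline &&
      !any(abs(g$kOn - 0.004) < 1e-12 & abs(g$kIns - 0.00064) < 1e-12))
    g <- rbind(g, data.frame(kOn = 0.004, kIns = 0.00064))
  lambda <- log(2) / tDouble
  bad <- g$kOn * g$kIns <= lambda^2
  if (any(bad))
    stop(sprintf(
      "%d infeasible pair(s): kOn*kIns <= (log(2)/tDouble)^2; smallest product %.3g vs lambda^2 = %.3g",
      sum(bad), min(g$kOn * g$kIns), lambda^2))
  g$tau <- mapply(solveTau, g$kOn, g$kIns, tDouble)
  g$meanEventArea <- g$tau * g$kIns
  attr(g, "tDouble") <- tDouble
  attr(g, "replicates") <- as.integer(replicates)
  attr(g, "seed") <- as.integer(seed)
  g
}

#' Screen the kinetic parameter space
#'
#' For each (kOn, kIns) pair of the grid, runs replicate simulations under
#' continuous light insertion, renders the frames, counts puncta along the
#' top cell edge, fits the logistic appearance curve and extracts the
#' initial punctum appearance rate and maximum puncta count, normalized per
#' um of cell outline perimeter (`2 * L0 + 4 * R` of the initial cell, the
#' projected outline; recorded in the metadata). Per-pair failures are
#' recorded and the scan continues. Deterministic given the grid seed.
#'
#' @param grid a [scanGrid()] data.frame.
#' @param geom initial [CylinderGeom-class].
#' @param optics an [OpticsConfig-class].
#' @param tMax simulated induction time per replicate (s).
#' @param frameEvery rendering interval (s).
#' @param dtMax simulator step cap (s).
#' @param noise render with camera noise.
#' @param minSeparation,k detection settings, see [detectSpots()].
#' @param verbose print per-pair progress.
#' @return a [ScanResult-class].
#' @export
runScan <- function(grid, geom = cylinderGeom(), optics = opticsConfig(),
                    tMax = 2700, frameEvery = 180, dtMax = 0.5,
                    noise = TRUE, minSeparation = 0.61 * 575 / 1.4, k = 5,
                    verbose = FALSE) {
  reps <- attr(grid, "replicates")
  tDouble <- attr(grid, "tDouble")
  seed0 <- attr(grid, "seed")
  if (is.null(reps) || is.null(tDouble) || is.null(seed0))
    stop("grid must come from scanGrid()")
  L0 <- geom@xRight - geom@xLeft
  perimeter <- 2 * L0 + 4 * geom@R
  snapT <- seq(frameEvery, tMax, by = frameEvery)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    res <- try({
      rates <- nmaxs <- rep(NA_real_, reps)
      for (r in seq_len(reps)) {
        cfg <- simConfig(R = geom@R, length = L0, kOn = row$kOn,
                         kIns = row$kIns, tau = row$tau,
                         light = tMax + 1, dark = 1, tMax = tMax,
                         snapshotTimes = snapT,
                         seed = seed0 + 7919L * i + r, dtMax = dtMax)
        sim <- runSimulation(cfg)
        stack <- renderStack(sim, optics, noise = noise)
        counts <- vapply(stack, function(f)
          countProfileSpots(topEdgeProfile(f), f@pixelSize,
                            minSeparation, k,
                            threshold = backgroundThreshold(f, k)),
          numeric(1))
        fit <- fitSigmoid(data.frame(times = snapT, mean = counts))
        if (fit@converged) {
          rates[r] <- fit@rate
          nmaxs[r] <- fit@nMax
        }
      }
      data.frame(kOn = row$kOn, kIns = row$kIns, tau = row$tau,
                 meanEventArea = row$meanEventArea,
                 rate = mean(rates, na.rm = TRUE) / perimeter,
                 rateSd = sd(rates, na.rm = TRUE) / perimeter,
                 maxCount = mean(nmaxs, na.rm = TRUE) / perimeter,
                 maxCountSd = sd(nmaxs, na.rm = TRUE) / perimeter,
                 nConverged = sum(!is.na(rates)),
                 error = NA_character_)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      res <- data.frame(kOn = row$kOn, kIns = row$kIns, tau = row$tau,
                        meanEventArea = row$meanEventArea,
                        rate = NA_real_, rateSd = NA_real_,
                        maxCount = NA_real_, maxCountSd = NA_real_,
                        nConverged = 0L,
                        error = attr(res, "condition")$message)
    }
    if (verbose)
      message(sprintf("[%d/%d] kOn=%.3g kIns=%.3g tau=%.3g s: rate=%.3g max=%.3g",
                      i, nrow(grid), row$kOn, row$kIns, row$tau,
                      res$rate, res$maxCount))
    rows[[i]] <- res
  }
  new("ScanResult", table = do.call(rbind, rows),
      meta = list(tDouble = tDouble, replicates = reps, seed = seed0,
                  tMax = tMax, frameEvery = frameEvery,
                  perimeter = perimeter,
                  normalization = "per-perimeter-length (2*L0 + 4*R, um)"))
}

#' Classify parameter sets against experimental bounds
#'
#' Interval-membership classification of scan metrics against user-supplied
#' experimental bounds on the initial punctum appearance rate and the
#' maximum puncta count (both per perimeter length). The experimental
#' levels themselves are user inputs, not shipped constants.
#'
#' @param result a [ScanResult-class].
#' @param bounds list with `rate = c(lo, hi)` and `maxCount = c(lo, hi)`.
#' @return the scan table with a `label` column (`"rate-consistent"`,
#'   `"count-consistent"`, `"both"`, `"neither"`); the extents of the
#'   `"both"` region in kOn and tau*kIns are attached as attributes
#'   `kOnRange` and `meanEventAreaRange`.
#' @export
classifyConsistent <- function(result, bounds) {
  if (is.null(bounds$rate) || is.null(bounds$maxCount) ||
      length(bounds$rate) != 2L || length(bounds$maxCount) != 2L)
    stop("bounds must supply rate = c(lo, hi) and maxCount = c(lo, hi)")
  tb <- result@table
  rateOk <- !is.na(tb$rate) & tb$rate >= bounds$rate[1] &
    tb$rate <= bounds$rate[2]
  cntOk <- !is.na(tb$maxCount) & tb$maxCount >= bounds$maxCount[1] &
    tb$maxCount <= bounds$maxCount[2]
  tb$label <- ifelse(rateOk & cntOk, "both",
                     ifelse(rateOk, "rate-consistent",
                            ifelse(cntOk, "count-consistent", "neither")))
  both <- tb$label == "both"
  attr(tb, "kOnRange") <- if (any(both)) range(tb$kOn[both]) else c(NA, NA)
  attr(tb, "meanEventAreaRange") <-
    if (any(both)) range(tb$meanEventArea[both]) else c(NA, NA)
  tb
}
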