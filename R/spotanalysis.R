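#' Robust background level and threshold of a fluorescence frame
#'
#' The background level is the half-sample mode of the pixel intensities
#' (robust as long as background pixels are the largest coherent
#' population, even when the cell covers much of the frame), and the noise
#' scale is estimated from the lower tail -- pixels below the mode, whose
#' deviations are half-normal under symmetric noise, so fluorescent signal
#' (which only adds intensity) cannot inflate it. The detection threshold
#' is `background + k * sigma`.
#'
#' @param img a [Micrograph-class] or bare intensity matrix.
#' @param k threshold multiplier.
#' @return for `backgroundLevel`, named vector `c(bg, sigma)`; for
#'   `backgroundThreshold`, a single threshold value.
#' @export
backgroundLevel <- function(img) {
  m <- if (is(img, "Micrograph")) img@intensity else img
  bg <- .halfSampleMode(sort(as.vector(m)))
  below <- bg - m[m <= bg]
  sigma <- if (length(below) < 10) 0 else median(below) / 0.6745
  c(bg = bg, sigma = sigma)
}

#' @rdname backgroundLevel
#' @export
backgroundThreshold <- function(img, k = 5) {
  b <- backgroundLevel(img)
  unname(b["bg"] + k * b["sigma"])
}

# half-sample mode of a sorted vector
.halfSampleMode <- function(x) {
  n <- length(x)
  while (n > 3L) {
    h <- ceiling(n / 2)
    ranges <- x[h:n] - x[1:(n - h + 1L)]
    i <- which.min(ranges)
    x <- x[i:(i + h - 1L)]
    n <- h
  }
  mean(x)
}

#' Detect fluorescent puncta in a micrograph
#'
#' Local-maxima candidates above a robust background threshold
#' ([backgroundThreshold()]: half-sample-mode background plus k lower-tail
#' noise sigmas), merged when closer than `minSeparation` (brightest kept),
#' then refined to sub-pixel position and lateral width by a 2D Gaussian
#' least-squares fit on a small window (moment estimates as fallback).
#' Detection is invariant to rescaling the image intensity, since both the
#' background level and the noise scale rescale with it.
#'
#' @param img a [Micrograph-class].
#' @param minSeparation merge radius (nm); default is the Rayleigh radius
#'   `0.61 * 575 / 1.4` (about 250 nm).
#' @param k robust threshold multiplier.
#' @param refine run the Gaussian fit (otherwise moment estimates).
#' @param window half-width (px) of the refinement window.
#' @return data.frame with one row per spot: `x` (axial, nm, in the frame's
#'   physical coordinates), `v` (lateral, nm), `row`, `col` (px),
#'   `intensity` (peak counts above background), `sd` (fitted lateral sd,
#'   nm) and `frame` (`NA`; filled by callers that process stacks).
#' @export
detectSpots <- function(img, minSeparation = NULL, k = 5, refine = TRUE,
                        window = 4L) {
  m <- img@intensity
  px <- img@pixelSize
  if (!length(px) || px <= 0) stop("uncalibrated image: pixel size missing")
  if (is.null(minSeparation)) minSeparation <- 0.61 * 575 / 1.4
  b <- backgroundLevel(m)
  bg <- unname(b["bg"])
  thr <- bg + k * unname(b["sigma"])
  peaks <- .localMaxima(m, thr)
  if (nrow(peaks) == 0L) return(.emptySpots())
  ord <- order(m[peaks], decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  keep <- logical(nrow(peaks))
  sepPx <- minSeparation / px
  for (i in seq_len(nrow(peaks))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    prev <- peaks[which(keep[seq_len(i - 1L)]), , drop = FALSE]
    d2 <- (prev[, 1] - peaks[i, 1])^2 + (prev[, 2] - peaks[i, 2])^2
    keep[i] <- all(d2 > sepPx^2)
  }
  peaks <- peaks[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(peaks)), function(i)
    .refineSpot(m, peaks[i, 1], peaks[i, 2], bg, window, refine))
  out <- do.call(rbind, out)
  x0 <- if (!is.null(img@meta$x0)) img@meta$x0 * 1000 else 0
  v0 <- if (!is.null(img@meta$v0)) img@meta$v0 * 1000 else 0
  data.frame(x = x0 + (out[, "col"] - 0.5) * px,
             v = v0 + (out[, "row"] - 0.5) * px,
             row = out[, "row"], col = out[, "col"],
             intensity = out[, "peak"], sd = out[, "sd"] * px,
             frame = NA_integer_)
}

.emptySpots <- function()
  data.frame(x = numeric(0), v = numeric(0), row = numeric(0),
             col = numeric(0), intensity = numeric(0), sd = numeric(0),
             frame = integer(0))

.localMaxima <- function(m, thr) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(cbind(row = integer(0), col = integer(0)))
  core <- m[2:(nr - 1), 2:(nc - 1)]
  isMax <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    isMax <- isMax & core >= m[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  w <- which(isMax, arr.ind = TRUE)
  cbind(row = w[, 1] + 1L, col = w[, 2] + 1L)
}

.refineSpot <- function(m, r, cc, bg, w, refine) {
  r1 <- max(1L, r - w); r2 <- min(nrow(m), r + w)
  c1 <- max(1L, cc - w); c2 <- min(ncol(m), cc + w)
  win <- m[r1:r2, c1:c2, drop = FALSE] - bg
  win[win < 0] <- 0
  rows <- r1:r2; cols <- c1:c2
  tot <- sum(win)
  if (tot <= 0)
    return(c(row = r, col = cc, peak = m[r, cc] - bg, sd = 1))
  mr <- sum(rows * rowSums(win)) / tot
  mc <- sum(cols * colSums(win)) / tot
  vr <- sum((rows - mr)^2 * rowSums(win)) / tot
  vc <- sum((cols - mc)^2 * colSums(win)) / tot
  s <- sqrt(max(0.25, (vr + vc) / 2))
  peak <- m[r, cc] - bg
  if (refine) {
    grid <- expand.grid(r = rows, c = cols)
    obj <- function(p) {
      mu <- p[1] * exp(-((grid$r - p[2])^2 + (grid$c - p[3])^2) /
                         (2 * p[4]^2)) + p[5]
      sum((mu - as.vector(win))^2)
    }
    fit <- try(optim(c(peak, mr, mc, s, 0), obj), silent = TRUE)
    if (!inherits(fit, "try-error") && fit$par[4] > 0.2 &&
        fit$par[4] < 4 * s + 2 &&
        fit$par[2] > r1 - 1 && fit$par[2] < r2 + 1 &&
        fit$par[3] > c1 - 1 && fit$par[3] < c2 + 1) {
      mr <- fit$par[2]; mc <- fit$par[3]
      s <- abs(fit$par[4]); peak <- fit$par[1]
    }
  }
  c(row = mr, col = mc, peak = peak, sd = s)
}

#' Intensity profile along the top cell edge
#'
#' The image row at the maximum projected radius (`v = +R`): the top edge of
#' the cell outline, where the wrapped-cylinder projection is brightest.
#'
#' @param img a [Micrograph-class] rendered by [renderMicrograph()].
#' @return numeric vector, one value per axial pixel; the axial coordinate
#'   of entry j is `meta$x0 * 1000 + (j - 0.5) * pixelSize` nm.
#' @export
topEdgeProfile <- function(img) {
  if (is.null(img@meta$R) || is.null(img@meta$v0))
    stop("micrograph lacks cylinder geometry metadata")
  pxUm <- img@pixelSize / 1000
  iv <- round((img@meta$R - img@meta$v0) / pxUm + 0.5)
  iv <- min(max(1L, iv), nrow(img@intensity))
  img@intensity[iv, ]
}

#' Count puncta along a 1D edge profile
#'
#' 1D analogue of [detectSpots()]: local maxima of the profile above
#' median + k * MAD, merged within `minSeparation`.
#'
#' @param profile numeric vector from [topEdgeProfile()].
#' @param px pixel size (nm).
#' @param minSeparation merge radius (nm).
#' @param k robust threshold multiplier.
#' @param threshold explicit intensity threshold; the default, median +
#'   k * MAD of the profile itself, is only appropriate for profiles that
#'   are mostly background -- callers holding the full frame (e.g.
#'   [punctaCurve()]) pass the whole-frame background threshold instead, so
#'   that a uniformly bright edge is not thresholded against itself.
#' @return integer count.
#' @export
countProfileSpots <- function(profile, px, minSeparation = 0.61 * 575 / 1.4,
                              k = 5, threshold = NULL) {
  n <- length(profile)
  if (n < 3L) return(0L)
  thr <- if (is.null(threshold)) median(profile) + k * mad(profile)
         else threshold
  core <- profile[2:(n - 1)]
  isMax <- core > thr & core >= profile[1:(n - 2)] & core >= profile[3:n]
  pos <- which(isMax) + 1L
  if (!length(pos)) return(0L)
  ord <- pos[order(profile[pos], decreasing = TRUE)]
  kept <- numeric(0)
  sepPx <- minSeparation / px
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) > sepPx)) kept <- c(kept, p)
  length(kept)
}

#' Kymograph along the top cell edge
#'
#' Stacks the top-edge intensity profiles of a rendered time series into a
#' position x time array. `policy = "absolute"` keeps the fixed camera
#' axial coordinate; `policy = "normalized"` resamples each frame onto a
#' fixed number of samples spanning that frame's cell extent, so traces are
#' shown in relative cell coordinates as the cell elongates.
#'
#' @param stack list of [Micrograph-class] frames with consistent geometry.
#' @param policy `"absolute"` or `"normalized"`.
#' @param nSamples resampling length for the normalized policy.
#' @return numeric matrix (position x frame) with attributes `times` (s)
#'   and `positions` (axial nm for `"absolute"`, relative 0..1 otherwise).
#' @export
kymographTopEdge <- function(stack, policy = c("absolute", "normalized"),
                             nSamples = 200L) {
  policy <- match.arg(policy)
  if (!length(stack)) stop("empty stack")
  R0 <- stack[[1]]@meta$R
  for (f in stack) if (!isTRUE(all.equal(f@meta$R, R0)))
    stop("geometry mismatch across frames")
  profs <- lapply(stack, topEdgeProfile)
  times <- vapply(stack, function(f) f@time, numeric(1))
  if (policy == "absolute") {
    n <- max(lengths(profs))
    k <- vapply(profs, function(p) c(p, rep(0, n - length(p)))[seq_len(n)],
                numeric(n))
    px <- stack[[1]]@pixelSize
    x0 <- stack[[1]]@meta$x0 * 1000
    attr(k, "positions") <- x0 + (seq_len(n) - 0.5) * px
  } else {
    k <- vapply(seq_along(profs), function(i) {
      f <- stack[[i]]
      px <- f@pixelSize / 1000
      xc <- f@meta$x0 + (seq_along(profs[[i]]) - 0.5) * px
      rel <- (xc - f@meta$xLeft) / (f@meta$xRight - f@meta$xLeft)
      approx(rel, profs[[i]], xout = seq(0, 1, length.out = nSamples),
             rule = 2)$y
    }, numeric(nSamples))
    attr(k, "positions") <- seq(0, 1, length.out = nSamples)
  }
  attr(k, "times") <- times
  k
}

#' Link detected spots into tracks
#'
#' Greedy nearest-neighbour frame-to-frame linking: candidate links sorted
#' by distance, accepted while below `maxStep` per frame interval; spots
#' left unmatched start new tracks. A new track whose first position lies
#' within `splitRadius` of an existing track's position in the previous
#' frame is annotated as a split child of that track.
#'
#' @param frames list of per-frame spot data.frames from [detectSpots()]
#'   (columns `x`, `v` in nm).
#' @param maxStep maximum link distance per frame interval (nm).
#' @param splitRadius distance (nm) within which a newborn track is called
#'   a split of its neighbour.
#' @param times optional frame times (s), stored in the tracks.
#' @return list with `tracks` (each a list with `id`, `frames`, `t`, `x`,
#'   `v`, `parent`) and `splits` (data.frame `frame`, `parent`, `child`).
#' @export
linkTracks <- function(frames, maxStep = 300, splitRadius = maxStep,
                       times = NULL) {
  if (length(frames) < 2L) stop("need at least two frames to link")
  if (is.null(times)) times <- seq_along(frames)
  tracks <- list()
  active <- integer(0)           # indices into tracks
  splits <- data.frame(frame = integer(0), parent = integer(0),
                       child = integer(0))
  newTrack <- function(f, x, v, parent = NA_integer_) {
    tracks[[length(tracks) + 1L]] <<- list(
      id = length(tracks) + 1L, frames = f, t = times[f], x = x, v = v,
      parent = parent)
    length(tracks)
  }
  sp <- frames[[1]]
  active <- vapply(seq_len(nrow(sp)), function(i)
    newTrack(1L, sp$x[i], sp$v[i]), integer(1))
  for (f in seq_along(frames)[-1]) {
    sp <- frames[[f]]
    prevPos <- do.call(rbind, lapply(tracks[active], function(tr)
      c(tail(tr$x, 1), tail(tr$v, 1))))
    matchedTrack <- logical(length(active))
    matchedSpot <- logical(nrow(sp))
    if (length(active) && nrow(sp)) {
      d <- sqrt(outer(prevPos[, 1], sp$x, "-")^2 +
                outer(prevPos[, 2], sp$v, "-")^2)
      ord <- order(d)
      for (o in ord) {
        if (d[o] > maxStep) break
        i <- (o - 1L) %% length(active) + 1L
        j <- (o - 1L) %/% length(active) + 1L
        if (matchedTrack[i] || matchedSpot[j]) next
        matchedTrack[i] <- TRUE; matchedSpot[j] <- TRUE
        ti <- active[i]
        tracks[[ti]]$frames <- c(tracks[[ti]]$frames, f)
        tracks[[ti]]$t <- c(tracks[[ti]]$t, times[f])
        tracks[[ti]]$x <- c(tracks[[ti]]$x, sp$x[j])
        tracks[[ti]]$v <- c(tracks[[ti]]$v, sp$v[j])
      }
    }
    newIds <- integer(0)
    for (j in which(!matchedSpot)) {
      parent <- NA_integer_
      if (length(active)) {
        d2 <- (prevPos[, 1] - sp$x[j])^2 + (prevPos[, 2] - sp$v[j])^2
        i <- which.min(d2)
        if (sqrt(d2[i]) <= splitRadius) {
          parent <- tracks[[active[i]]]$id
          splits <- rbind(splits, data.frame(frame = f, parent = parent,
                                             child = length(tracks) + 1L))
        }
      }
      newIds <- c(newIds, newTrack(f, sp$x[j], sp$v[j], parent))
    }
    active <- c(active[matchedTrack], newIds)
  }
  list(tracks = tracks, splits = splits)
}

#' Puncta-count curve over replicate rendered time series
#'
#' Counts detected puncta per frame (top edge by default, the simulated
#' kymograph convention; or whole cell) and averages across replicates.
#'
#' @param stacks list of replicates, each a list of [Micrograph-class]
#'   frames at identical times.
#' @param mode `"top"` (1D top-edge counting) or `"whole"` (2D detection).
#' @param minSeparation,k detection settings, see [detectSpots()].
#' @return a [PunctaCurve-class].
#' @export
punctaCurve <- function(stacks, mode = c("top", "whole"),
                        minSeparation = 0.61 * 575 / 1.4, k = 5) {
  mode <- match.arg(mode)
  if (!length(stacks)) stop("need at least one replicate")
  times <- vapply(stacks[[1]], function(f) f@time, numeric(1))
  for (s in stacks) {
    tt <- vapply(s, function(f) f@time, numeric(1))
    if (length(tt) != length(times) || any(abs(tt - times) > 1e-6))
      stop("ragged frame times across replicates")
  }
  counts <- vapply(stacks, function(s) {
    vapply(seq_along(s), function(i) {
      if (mode == "top")
        countProfileSpots(topEdgeProfile(s[[i]]), s[[i]]@pixelSize,
                          minSeparation, k,
                          threshold = backgroundThreshold(s[[i]], k))
      else nrow(detectSpots(s[[i]], minSeparation, k))
    }, numeric(1))
  }, numeric(length(times)))
  counts <- matrix(counts, nrow = length(times))
  new("PunctaCurve", times = times, mean = rowMeans(counts),
      sd = apply(counts, 1, sd), nReplicates = length(stacks),
      normalization = "raw")
}

#' Fit a logistic sigmoid to a puncta-count curve
#'
#' Least-squares fit of `N(t) = nMax / (1 + exp(-(t - t0)/s))` via
#' Levenberg-Marquardt. The initial punctum appearance rate is the maximum
#' slope `nMax / (4 s)`. If `perimeter` is given, `nMaxPerLength` and
#' `ratePerLength` (per um of cell outline) are attached as attributes.
#' Degenerate inputs (no rise within the sampled window, or non-convergent
#' fits) are flagged, never silently returned.
#'
#' @param curve a [PunctaCurve-class] (or data.frame with `times`, `mean`).
#' @param perimeter optional cell outline length (um) for normalization.
#' @return a [SigmoidFit-class].
#' @export
fitSigmoid <- function(curve, perimeter = NULL) {
  if (is(curve, "PunctaCurve")) {
    tt <- curve@times; y <- curve@mean
  } else {
    tt <- curve$times; y <- curve$mean
  }
  if (length(tt) < 5L)
    stop("need at least 5 time points spanning rise and plateau")
  bad <- function(msg) new("SigmoidFit", nMax = NA_real_, rate = NA_real_,
                           midpoint = NA_real_, scale = NA_real_,
                           residual = NA_real_, converged = FALSE,
                           message = msg)
  if (max(y) <= 0) return(bad("all counts are zero"))
  rise <- max(y) - min(y)
  nMax0 <- max(y)
  t00 <- tt[which.min(abs(y - nMax0 / 2))]
  s0 <- diff(range(tt)) / 10
  fit <- try(minpack.lm::nlsLM(
    y ~ nMax / (1 + exp(-(tt - t0) / s)),
    start = list(nMax = nMax0, t0 = t00, s = s0),
    lower = c(1e-9, -Inf, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(bad(paste("sigmoid fit did not converge:",
                     attr(fit, "condition")$message)))
  p <- coef(fit)
  res <- sqrt(sum(residuals(fit)^2))
  if (rise < 0.05 * nMax0 || p[["t0"]] < min(tt) - p[["s"]])
    return(bad(paste("initial rise not sampled (plateau-only input);",
                     "appearance rate is ill-conditioned")))
  if (p[["nMax"]] > 2 * max(y))
    return(bad(paste("plateau not sampled within the time window;",
                     "nMax extrapolates beyond twice the observed maximum")))
  out <- new("SigmoidFit", nMax = unname(p[["nMax"]]),
             rate = unname(p[["nMax"]] / (4 * p[["s"]])),
             midpoint = unname(p[["t0"]]), scale = unname(p[["s"]]),
             residual = res, converged = TRUE, message = "")
  if (!is.null(perimeter)) {
    attr(out, "nMaxPerLength") <- out@nMax / perimeter
    attr(out, "ratePerLength") <- out@rate / perimeter
  }
  out
}

#' Pairwise divergence of neighbouring puncta
#'
#' For tracks ordered along the top edge, measures the separation of each
#' adjacent pair over their common frames and fits an exponential rate
#' (slope of log separation vs time), the signature of material points
#' carried apart by exponential surface growth. Pairs are classified
#' `"polar"` when their mean position lies within `poleFraction` of the
#' cell half-length from a domain end (where convergent flow retains
#' material), else `"cylindrical"`.
#'
#' @param tracks track list from [linkTracks()].
#' @param xLimits optional axial extent `c(xLeft, xRight)` in um, for the
#'   polar classification.
#' @param poleFraction fraction of the cell length counted as polar zone.
#' @param minFrames minimum number of common frames per pair.
#' @return data.frame with `i`, `j` (track ids), `rate` (s^-1), `meanSep`
#'   (nm), `n` (common frames) and `class`; the per-pair separation series
#'   is attached as attribute `series`.
#' @export
pairwiseDivergence <- function(tracks, xLimits = NULL, poleFraction = 0.15,
                               minFrames = 3L) {
  if (length(tracks) < 2L) stop("need at least two tracks")
  mx <- vapply(tracks, function(tr) mean(tr$x), numeric(1))
  ord <- order(mx)
  out <- NULL
  series <- list()
  for (a in seq_len(length(ord) - 1L)) {
    i <- ord[a]; j <- ord[a + 1L]
    common <- intersect(tracks[[i]]$frames, tracks[[j]]$frames)
    if (length(common) < minFrames) next
    xi <- tracks[[i]]$x[match(common, tracks[[i]]$frames)]
    xj <- tracks[[j]]$x[match(common, tracks[[j]]$frames)]
    ti <- tracks[[i]]$t[match(common, tracks[[i]]$frames)]
    sep <- abs(xj - xi)
    ok <- sep > 0
    rate <- if (sum(ok) >= 2L && var(log(sep[ok])) > 0)
      unname(coef(lm(log(sep[ok]) ~ ti[ok]))[2]) else 0
    cls <- "cylindrical"
    if (!is.null(xLimits)) {
      mid <- mean(c(xi, xj)) / 1000
      zone <- poleFraction * (xLimits[2] - xLimits[1])
      if (mid < xLimits[1] + zone || mid > xLimits[2] - zone)
        cls <- "polar"
    }
    out <- rbind(out, data.frame(i = tracks[[i]]$id, j = tracks[[j]]$id,
                                 rate = rate, meanSep = mean(sep),
                                 n = length(common), class = cls))
    series[[length(series) + 1L]] <- data.frame(t = ti, sep = sep)
  }
  if (is.null(out)) stop("no track pairs with overlapping frames")
  attr(out, "series") <- series
  out
}
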