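test_that("spot detection resolves well-separated puncta and merges close ones", {
  opt <- opticsConfig()
  # seeded blank: no spots
  st0 <- initState(defaultGeom(), headlineParams(), seed = 2)
  set.seed(6)
  expect_identical(nrow(detectSpots(renderMicrograph(st0, opt))), 0L)
  # two sub-diffraction patches 800 nm apart: two spots at the true positions
  y <- topEdgeY()
  st2 <- staticState(list(c(-0.4, y), c(0.4, y)), c(1e-3, 1e-3))
  sp2 <- detectSpots(renderMicrograph(st2, opt, noise = FALSE))
  expect_identical(nrow(sp2), 2L)
  expect_lt(max(abs(sort(sp2$x) - c(-400, 400))), 68)
  # 150 nm apart: below the Rayleigh separation, a single spot
  st1 <- staticState(list(c(-0.075, y), c(0.075, y)), c(1e-3, 1e-3))
  expect_identical(nrow(detectSpots(renderMicrograph(st1, opt,
                                                     noise = FALSE))), 1L)
})

test_that("detection is invariant to rescaling the image intensity", {
  opt <- opticsConfig()
  st <- staticState(list(c(-0.6, topEdgeY()), c(0.5, topEdgeY())),
                    c(0.02, 0.01))
  img <- renderMicrograph(st, opt, noise = FALSE)
  sp1 <- detectSpots(img)
  img@intensity <- img@intensity * 7.3
  sp2 <- detectSpots(img)
  expect_identical(nrow(sp1), nrow(sp2))
  # same spots at the same positions (sub-pixel refinement may move by
  # far less than a nanometre)
  expect_lt(max(abs(sp1$x - sp2$x)), 0.01)
  expect_lt(max(abs(sp1$v - sp2$v)), 0.01)
  expect_error(detectSpots(new("Micrograph",
                               intensity = img@intensity,
                               pixelSize = 68, time = 0, meta = list())),
               NA)
})

test_that("edge counting saturates at the resolution limit", {
  set.seed(8)
  px <- 68
  profile <- 100 + 50 * runif(120)
  n <- countProfileSpots(profile, px, minSeparation = 250, threshold = 110)
  expect_lte(n, length(profile) * px / 250 + 1)
})

test_that("track linking follows static, moving and splitting puncta", {
  # static: zero net displacement
  f <- data.frame(x = c(0, 1000), v = c(0, 0))
  lt <- linkTracks(list(f, f, f, f), maxStep = 300)
  expect_length(lt$tracks, 2)
  for (tr in lt$tracks) {
    expect_identical(tr$frames, 1:4)
    expect_equal(diff(range(tr$x)), 0)
  }
  # two spots diverging 50 nm per frame: monotone separation
  frames <- lapply(0:5, function(i)
    data.frame(x = c(-25, 25) * i, v = c(0, 0)))
  lt2 <- linkTracks(frames, maxStep = 300)
  expect_length(lt2$tracks, 2)
  sep <- abs(lt2$tracks[[2]]$x - lt2$tracks[[1]]$x)
  expect_true(all(diff(sep) > 0))
  # a punctum splitting in two: child track annotated with its parent
  fr <- list(data.frame(x = 0, v = 0),
             data.frame(x = c(-40, 40), v = c(0, 0)),
             data.frame(x = c(-90, 90), v = c(0, 0)))
  lt3 <- linkTracks(fr, maxStep = 300, splitRadius = 300)
  expect_identical(nrow(lt3$splits), 1L)
  child <- lt3$tracks[[lt3$splits$child]]
  expect_identical(child$parent, lt3$splits$parent)
  expect_error(linkTracks(list(f), maxStep = 300), "two frames")
})

test_that("kymographs trace static and moving puncta along the top edge", {
  opt <- opticsConfig()
  y <- topEdgeY()
  # static punctum: one bright horizontal line
  st <- staticState(list(c(0, y)), 0.02)
  frames <- lapply(0:4, function(i) {
    st@t <- i * 60
    renderMicrograph(st, opt, noise = FALSE)
  })
  ky <- kymographTopEdge(frames)
  expect_identical(dim(ky)[2], 5L)
  expect_identical(attr(ky, "times"), (0:4) * 60)
  peaks <- apply(ky, 2, which.max)
  expect_true(all(peaks == peaks[1]))
  # constant-velocity punctum: straight sloped trace
  mov <- lapply(0:4, function(i) {
    s <- staticState(list(c(-0.4 + 0.2 * i, y)), 0.02)
    s@t <- i * 60
    renderMicrograph(s, opt, noise = FALSE)
  })
  km <- kymographTopEdge(mov)
  pk <- apply(km, 2, which.max)
  steps <- diff(pk)
  expect_true(all(steps > 0))
  expect_lte(diff(range(steps)), 1)   # straight line up to pixelation
  # normalized policy rescales to relative cell coordinates
  kn <- kymographTopEdge(mov, policy = "normalized", nSamples = 120)
  expect_identical(dim(kn)[1], 120L)
  bad <- mov
  bad[[2]]@meta$R <- 0.7
  expect_error(kymographTopEdge(bad), "geometry mismatch")
})

test_that("puncta curves aggregate replicates and validate frame times", {
  opt <- opticsConfig()
  p0 <- kineticParams(0, 0.00064, tau = 50)
  blank <- lapply(0:2, function(i) {
    s <- initState(defaultGeom(), p0, seed = i + 1)
    s@t <- i * 60
    renderMicrograph(s, opt, noise = FALSE)
  })
  cv <- punctaCurve(list(blank, blank))
  expect_true(all(cv@mean == 0))
  expect_identical(cv@nReplicates, 2L)
  ragged <- blank
  ragged[[2]]@time <- 999
  expect_error(punctaCurve(list(blank, ragged)), "ragged")
})

test_that("sigmoid fits recover exact and noisy logistic curves and flag degenerate ones", {
  tt <- seq(0, 3000, by = 100)
  y <- 12 / (1 + exp(-(tt - 900) / 300))
  fit <- fitSigmoid(data.frame(times = tt, mean = y), perimeter = 6)
  expect_true(fit@converged)
  expect_equal(fit@nMax, 12, tolerance = 0.01)
  expect_equal(fit@midpoint, 900, tolerance = 0.01 * 900)
  expect_equal(fit@rate, 12 / (4 * 300), tolerance = 0.01)
  expect_equal(attr(fit, "nMaxPerLength"), 2, tolerance = 0.01)
  # noisy logistic: nMax within 10%
  set.seed(12)
  fitN <- fitSigmoid(data.frame(times = tt, mean = y + rnorm(length(tt), 0, 0.5)))
  expect_true(fitN@converged)
  expect_lt(abs(fitN@nMax - 12) / 12, 0.10)
  # plateau-only input: flagged, never a silent answer
  flat <- fitSigmoid(data.frame(times = tt, mean = rep(12, length(tt)) +
                                  c(1e-9, numeric(length(tt) - 1))))
  expect_false(flat@converged)
  expect_match(flat@message, "ill-conditioned|zero|converge")
  expect_error(fitSigmoid(data.frame(times = 1:3, mean = 1:3)), "5 time")
})

test_that("neighbour divergence is zero without growth and ~log(2)/tDouble with it", {
  # static tracks: rates exactly zero
  mk <- function(x) list(id = x, frames = 1:5, t = (0:4) * 60,
                         x = rep(x * 1000, 5), v = numeric(5))
  dv0 <- pairwiseDivergence(list(mk(1), mk(2), mk(3)))
  expect_true(all(dv0$rate == 0))
  # uniform exponential growth: marker pair separation grows at the area rate
  snapT <- seq(900, 3600, by = 900)
  markers <- list(list(center = c(-0.85, 1), area = 0.005, label = "original"),
                  list(center = c(0.85, 1), area = 0.005, label = "original"))
  slopes <- vapply(1:12, function(i) {
    sim <- runSimulation(simConfig(tMax = 3600, snapshotTimes = snapT,
                                   seed = 900 + i,
                                   initialPatches = markers))
    sep <- vapply(sim$snapshots, function(s) {
      cc <- patchCentroids(s)
      cc$x[2] - cc$x[1]
    }, numeric(1))
    unname(coef(lm(log(sep) ~ snapT))[2])
  }, numeric(1))
  lam <- log(2) / 5400
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - lam), 3 * se + 0.05 * lam)
})

test_that("pairs are classified polar or cylindrical by axial position", {
  mk <- function(id, x) list(id = id, frames = 1:4, t = (0:3) * 60,
                             x = rep(x, 4), v = numeric(4))
  tracks <- list(mk(1, -1350), mk(2, -1250), mk(3, -100), mk(4, 100))
  dv <- pairwiseDivergence(tracks, xLimits = c(-1.5, 1.5),
                           poleFraction = 0.15)
  cls <- dv$class[order(dv$i)]
  expect_identical(dv$class[dv$i == 1], "polar")
  expect_identical(dv$class[dv$i == 3], "cylindrical")
  expect_error(pairwiseDivergence(list(mk(1, 0))), "two tracks")
})
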