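test_that("initial states are validated, sized and replayable", {
  p <- headlineParams()
  st <- initState(defaultGeom(), p, seed = 7)
  expect_equal(surfaceArea(st), 2 * pi * 0.5 * 2, tolerance = 1e-12)
  expect_length(patches(st), 0)
  expect_identical(nrow(sources(st)), 0L)
  st2 <- initState(defaultGeom(), p, seed = 7)
  expect_identical(st, st2)
  expect_error(initState(cylinderGeom(xLeft = 1, xRight = 1), p), "xLeft")
  expect_error(cylinderGeom(R = -1), "positive")
})

test_that("with no initiation the state only advances its clock (growth arrest)", {
  p0 <- kineticParams(0, 0.00064, tau = 50)
  st <- addPatch(initState(defaultGeom(), p0, 3), c(0.3, 1), 0.03)
  out <- st
  for (i in 1:20) out <- step(out)
  expect_identical(out@patches, st@patches)
  expect_identical(out@geom, st@geom)
  expect_gt(out@t, 0)
})

test_that("a single event's patch grows to kIns * duration (area ledger)", {
  p0 <- kineticParams(0, 0.00064, tau = 50)
  kIns <- 0.00064
  d <- 20
  dt <- 0.05
  # enough vertices that the polygon-chord area deficit is below the
  # tolerance (a regular n-gon holds sin(2*pi/n)*n/(2*pi) of its
  # circumcircle's area)
  st <- initState(defaultGeom(), p0, 4)
  st <- addPatch(st, c(0, 1), kIns * dt, "light", nVertices = 48L)
  st@sources <- data.frame(id = 1L, x = 0, y = 1, strength = kIns,
                           active = TRUE, tStart = 0, duration = d,
                           label = "light", areaInserted = kIns * dt)
  for (i in seq_len(d / dt)) st <- advect(st, dt)
  target <- kIns * dt + kIns * d
  expect_equal(totalPatchArea(st), target, tolerance = 0.01)
})

test_that("runSimulation keeps an exact area ledger and replays from its seed", {
  cfg <- simConfig(tMax = 900, seed = 31, snapshotTimes = c(0, 450, 900))
  sim <- runSimulation(cfg)
  for (s in sim$snapshots) {
    expect_equal(surfaceArea(s),
                 s@initialArea + sum(sources(s)$areaInserted),
                 tolerance = 1e-9)
    act <- sources(s)[sources(s)$active, ]
    expect_true(all(act$tStart <= s@t & s@t < act$tStart + act$duration))
  }
  sim2 <- runSimulation(cfg)
  expect_identical(sim$trace, sim2$trace)
  expect_identical(patches(sim$finalState), patches(sim2$finalState))
  # zero-duration run: single snapshot equal to the initial state
  z <- runSimulation(simConfig(tMax = 0, seed = 31, snapshotTimes = 0))
  expect_length(z$snapshots, 1)
  expect_identical(z$snapshots[[1]]@t, 0)
  expect_length(patches(z$snapshots[[1]]), 0)
})

test_that("patch polygons never feed back on the area process", {
  a <- runSimulation(simConfig(tMax = 600, seed = 43, trackPatches = TRUE))
  b <- runSimulation(simConfig(tMax = 600, seed = 43, trackPatches = FALSE))
  expect_identical(a$trace, b$trace)
  expect_length(patches(b$finalState), 0)
  expect_gt(length(patches(a$finalState)), 0)
})

test_that("public step() reproduces the internal run loop exactly", {
  st <- initState(defaultGeom(), headlineParams(), seed = 123)
  for (i in 1:40) st <- step(st)
  sim <- runSimulation(simConfig(tMax = 20, seed = 123))  # 40 steps of 0.5 s
  expect_equal(surfaceArea(st), surfaceArea(sim$finalState),
               tolerance = 1e-12)
  expect_identical(length(patches(st)), length(patches(sim$finalState)))
})

test_that("no light material is created after the light phase ends", {
  snapT <- seq(300, 2400, by = 300)
  sim <- runSimulation(simConfig(tMax = 2400, light = 900, dark = 4500,
                                 seed = 21, snapshotTimes = snapT))
  la <- t(vapply(sim$snapshots, labelAreas, numeric(3)))
  darkIdx <- which(snapT > 900)
  lightAtEnd <- la[max(which(snapT <= 900)), "light"]
  # conserved to raster/advection tolerance, never growing beyond it
  expect_true(all(la[darkIdx, "light"] <= lightAtEnd * 1.02))
  expect_true(all(diff(la[darkIdx, "dark"]) > 0))
})

test_that("domain ends move monotonically outward (convergence to the poles)", {
  sim <- runSimulation(simConfig(tMax = 1800, seed = 9,
                                 snapshotTimes = seq(0, 1800, by = 300)))
  xl <- vapply(sim$snapshots, function(s) axialLimits(s@geom)[1], numeric(1))
  xr <- vapply(sim$snapshots, function(s) axialLimits(s@geom)[2], numeric(1))
  expect_true(all(diff(xl) <= 0))
  expect_true(all(diff(xr) >= 0))
})

test_that("label spatial correlation scale grows with the mean insertion size", {
  # equal doubling time, tau*kIns ~ 0.008 / 0.032 / 0.13 um^2
  nn <- vapply(c(0.016, 0.004, 0.001), function(ko) {
    sim <- runSimulation(simConfig(kOn = ko, kIns = 0.00064, tMax = 2700,
                                   seed = 55, snapshotTimes = 2700))
    meanNNDistance(sim$snapshots[[1]])
  }, numeric(1))
  expect_true(all(diff(nn) > 0))
})

test_that("events straddling the phase boundary continue as dark material", {
  set.seed(99)
  sim <- runSimulation(simConfig(tMax = 1200, light = 900, dark = 4500,
                                 seed = 99, snapshotTimes = 1200))
  s <- sim$snapshots[[1]]
  src <- sources(s)
  straddlers <- src$label == "light" & src$tStart + src$duration > 900
  if (any(straddlers)) {
    ids <- src$id[straddlers]
    labs <- vapply(patches(s), function(p)
      if (!is.na(p$sourceId) && p$sourceId %in% ids) p$label else NA_character_,
      character(1))
    expect_true("dark" %in% labs[!is.na(labs)])
  }
  # events initiated after the boundary are dark
  lateIds <- src$tStart > 900
  expect_true(all(src$label[lateIds] == "dark"))
})
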