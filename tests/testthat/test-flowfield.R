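test_that("closed-form periodic velocity matches the corrected brute-force image sum", {
  g <- defaultGeom()
  P <- circumference(g)
  Q <- 0.00064
  set.seed(11)
  for (i in 1:25) {
    p <- c(runif(1, -3, 3), runif(1, 0, P))
    s <- c(runif(1, -1, 1), runif(1, 0, P))
    if (sqrt(sum((p - s)^2)) < 0.05) p <- p + 0.5
    cf <- closedFormVelocity(p, s, Q, g)
    bf <- bruteForceVelocity(p, s, Q, P)
    expect_lt(max(abs(cf - bf)) / max(abs(bf)), 1e-10)
  }
})

test_that("closed form has the right limits and symmetry points", {
  g <- defaultGeom()
  P <- circumference(g)
  Q <- 0.002
  # far along the axis: uniform axial outflow Q/(2P)
  v <- closedFormVelocity(c(40, 1), c(0, 1), Q, g)
  expect_equal(v[1], Q / (2 * P), tolerance = 1e-12)
  expect_equal(v[2], 0, tolerance = 1e-15)
  # diametrically opposite point: zero by symmetry
  v0 <- closedFormVelocity(c(0, 1 + P / 2), c(0, 1), Q, g)
  expect_equal(as.numeric(v0), c(0, 0), tolerance = 1e-15)
  expect_error(closedFormVelocity(c(0, 1), c(0, 1), Q, g), "singular")
})

test_that("truncated image sum reproduces the free-space field near a source", {
  g <- defaultGeom()
  Q <- 0.00064
  src <- data.frame(x = 0, y = 0, strength = Q)
  v <- velocityField(c(0.05, 0), src, g, nImages = 21)
  speed <- sqrt(sum(v^2))
  expect_lt(abs(speed - Q / (2 * pi * 0.05)) / (Q / (2 * pi * 0.05)), 0.003)
  # diametrically opposite the source the axial component vanishes
  P <- circumference(g)
  vop <- velocityField(c(0, P / 2), src, g)
  expect_equal(vop[1], 0, tolerance = 1e-18)
  # far along the axis the infinite image array gives uniform outflow;
  # the truncated sum approaches it as the truncation is widened
  vfar <- velocityField(c(10, 1), src, g, nImages = 1001)
  expect_equal(vfar[1], Q / (2 * P), tolerance = 0.01)
  err <- function(n) abs(velocityField(c(10, 1), src, g, n)[1] - Q / (2 * P))
  expect_gt(err(21), err(201))
  expect_gt(err(201), err(1001))
})

test_that("image sum is exactly linear in the sources", {
  g <- defaultGeom()
  src <- data.frame(x = c(0, 0.7, -0.4), y = c(0.3, 2.0, 1.1),
                    strength = c(0.01, 0.02, 0.005))
  pts <- rbind(c(0.5, 1), c(-0.3, 2.5), c(1.2, 0.1))
  whole <- velocityField(pts, src, g)
  parts <- Reduce(`+`, lapply(1:3, function(i)
    velocityField(pts, src[i, ], g)))
  expect_identical(dim(whole), c(3L, 2L))
  expect_lt(max(abs(whole - parts)), 1e-15)
})

test_that("velocity evaluation validates its inputs", {
  g <- defaultGeom()
  src <- data.frame(x = 0, y = 0, strength = 1)
  expect_error(velocityField(c(1, 0), src, g, nImages = 20), "odd")
  expect_error(velocityField(c(1, 0), src, g, nImages = 0), "odd")
  expect_error(velocityField(c(1e-6, 0), src, g, eps = 1e-4), "epsilon")
  # inactive sources are dropped
  src2 <- data.frame(x = 0, y = 0, strength = 1, active = FALSE)
  expect_equal(velocityField(c(1, 0), src2, g), matrix(0, 1, 2))
})

test_that("wrap-aware polygon area handles translation, wrap and invalid rings", {
  g <- defaultGeom()
  P <- circumference(g)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygonArea(sq, g), 1)
  expect_equal(polygonArea(sweep(sq, 2, c(0, P), "+"), g), 1)
  # polygon straddling the periodic seam
  seam <- sweep(sq, 2, c(0, P - 0.5), "+")
  expect_equal(polygonArea(seam, g), 1)
  r <- 0.3
  th <- 2 * pi * (0:5) / 6
  hexagon <- cbind(r * cos(th), r * sin(th))
  expect_equal(polygonArea(hexagon, g), 3 * sqrt(3) / 2 * r^2)
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygonArea(bowtie, g), "self-intersecting")
  expect_error(polygonArea(rbind(c(0, 0), c(1, 1)), g), "three vertices")
})

test_that("advection without active sources leaves the state bitwise unchanged", {
  st <- staticState(list(c(0.3, 1)), 0.02)
  out <- advect(st, 0.5)
  expect_identical(out@patches, st@patches)
  expect_identical(out@geom, st@geom)
})

test_that("a passive polygon's area is conserved under advection, converging with dt", {
  st <- staticState(list(c(1, 0.5)), 0.02, nVertices = 3L)
  st@sources <- data.frame(id = 1L, x = 0, y = 0, strength = 0.1,
                           active = TRUE, tStart = 0, duration = 1e6,
                           label = "light", areaInserted = 0)
  a0 <- totalPatchArea(st)
  drift <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    s <- st
    for (i in 1:100) s <- advect(s, dt)
    abs(totalPatchArea(s) - a0) / a0
  }, numeric(1))
  # first-order convergence and < 0.1% at the finest step
  expect_lt(drift[3], 0.001)
  expect_true(all(diff(drift) < 0))
  expect_gt(drift[1] / drift[3], 2.5)
  # the tolerance check raises a numerical-accuracy error when violated
  expect_error(advect(st, 50, areaTolerance = 1e-6), "numerical accuracy")
})

test_that("domain length grows by inserted area over circumference (flux ledger)", {
  st <- staticState(list(c(1.5, 0.5)), 0.001)
  Q <- 0.05
  st@sources <- data.frame(id = 1L, x = 0, y = 1, strength = Q,
                           active = TRUE, tStart = 0, duration = 1e6,
                           label = "light", areaInserted = 0)
  P <- circumference(st@geom)
  L0 <- diff(axialLimits(st@geom))
  s <- st
  for (i in 1:50) s <- advect(s, 0.2)
  inserted <- Q * 50 * 0.2
  expect_equal(diff(axialLimits(s@geom)) - L0, inserted / P,
               tolerance = 1e-12)
})
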