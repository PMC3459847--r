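# Shared fixtures and independent oracles for the test suite.

headlineParams <- function() kineticParams(0.004, 0.00064, tDouble = 5400)

defaultGeom <- function() cylinderGeom(R = 0.5, length = 2)

# Independent oracle for the periodic-source velocity: direct image sum over
# |k| <= K plus the analytic integral of the truncated tails (the vx tail is
# one-sided and decays only as 1/K, so the correction is required for high
# accuracy).
bruteForceVelocity <- function(point, source, Q, P, K = 1e4) {
  k <- -K:K
  dx <- point[1] - source[1]
  dy <- point[2] - source[2]
  dyk <- dy - k * P
  r2 <- dx^2 + dyk^2
  vx <- sum(dx / r2)
  vy <- sum(dyk / r2)
  u <- (K + 0.5) * P
  if (dx != 0)
    vx <- vx + (1 / P) * (pi * sign(dx) - atan((u - dy) / dx) -
                            atan((u + dy) / dx))
  vy <- vy + (1 / (2 * P)) * log((dx^2 + (u - dy)^2) / (dx^2 + (u + dy)^2))
  c(vx, vy) * Q / (2 * pi)
}

# state with manually placed patches and no kinetics (kOn = 0)
staticState <- function(centers, areas, labels = "light", seed = 1,
                        nVertices = 16L, geom = defaultGeom()) {
  p <- kineticParams(0, 0.00064, tau = 50)
  st <- initState(geom, p, seed = seed)
  labels <- rep_len(labels, length(areas))
  for (i in seq_along(areas))
    st <- addPatch(st, centers[[i]], areas[i], labels[i],
                   nVertices = nVertices)
  st
}

topEdgeY <- function(geom = defaultGeom()) circumference(geom) / 4

# mean nearest-neighbour distance between patch centroids (torus metric in y)
meanNNDistance <- function(state) {
  cc <- patchCentroids(state)
  P <- circumference(state@geom)
  d <- vapply(seq_len(nrow(cc)), function(i) {
    dx <- cc$x[-i] - cc$x[i]
    dy <- abs(cc$y[-i] - cc$y[i])
    dy <- pmin(dy, P - dy)
    min(sqrt(dx^2 + dy^2))
  }, numeric(1))
  mean(d)
}

# frame background threshold used for edge counting
frameThreshold <- function(img, k = 5) backgroundThreshold(img, k)
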