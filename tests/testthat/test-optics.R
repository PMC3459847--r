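test_that("the PSF kernel is normalized, isotropic and widens with defocus", {
  opt <- opticsConfig()
  k0 <- psfKernel(opt, 0)
  expect_equal(sum(k0), 1, tolerance = 1e-9)
  expect_equal(k0, k0[rev(seq_len(nrow(k0))), rev(seq_len(ncol(k0)))])
  expect_equal(psfSigma0(opt), 0.21 * 575 / 1.4)
  # lateral sd of the sampled kernel matches sigma0 (86 nm)
  px <- samplePixel(opt) / opt@superSample
  u <- (seq_len(nrow(k0)) - (nrow(k0) + 1) / 2) * px
  sdk <- sqrt(sum(u^2 * rowSums(k0)) / sum(k0))
  expect_equal(sdk, psfSigma0(opt), tolerance = 0.02)
  # defocus: Strehl-like integral <= 1, width grows
  zR <- psfAxialScale(opt)
  kz <- psfKernel(opt, zR)
  expect_equal(sum(kz), 0.5, tolerance = 1e-6)
  uz <- (seq_len(nrow(kz)) - (nrow(kz) + 1) / 2) * px
  sdz <- sqrt(sum(uz^2 * rowSums(kz)) / sum(kz))
  expect_equal(sdz, psfSigma0(opt) * sqrt(2), tolerance = 0.03)
  expect_error(psfKernel(opticsConfig(psfModel = "born_wolf"), 0),
               "extension")
})

test_that("an unlabeled cell renders as background plus noise", {
  st <- initState(defaultGeom(), headlineParams(), seed = 2)
  opt <- opticsConfig()
  set.seed(5)
  img <- renderMicrograph(st, opt, noise = TRUE)
  m <- intensity(img)
  expect_lt(abs(mean(m) - opt@offset),
            3 * opt@readNoise / sqrt(length(m)) + 0.05)
  clean <- renderMicrograph(st, opt, noise = FALSE)
  expect_true(all(intensity(clean) == opt@offset))
})

test_that("a sub-diffraction patch renders at the PSF width", {
  opt <- opticsConfig()
  st <- staticState(list(c(0, topEdgeY())), 1e-3)
  img <- renderMicrograph(st, opt, noise = FALSE)
  sp <- detectSpots(img)
  expect_identical(nrow(sp), 1L)
  expect_lt(abs(sp$sd - psfSigma0(opt)) / psfSigma0(opt), 0.10)
  expect_lt(abs(sp$x - 0), img@pixelSize)     # at the true position
})

test_that("rendering is linear in the labeled material (noise off)", {
  opt <- opticsConfig()
  a <- staticState(list(c(-0.5, topEdgeY())), 0.02)
  b <- staticState(list(c(0.5, topEdgeY())), 0.02)
  ab <- staticState(list(c(-0.5, topEdgeY()), c(0.5, topEdgeY())),
                    c(0.02, 0.02))
  ia <- intensity(renderMicrograph(a, opt, noise = FALSE))
  ib <- intensity(renderMicrograph(b, opt, noise = FALSE))
  iab <- intensity(renderMicrograph(ab, opt, noise = FALSE))
  expect_equal(iab, ia + ib - opt@offset, tolerance = 1e-9)
})

test_that("translating all patches by one circumference leaves the image unchanged", {
  opt <- opticsConfig()
  st <- staticState(list(c(0.2, 1.1), c(-0.4, 2.6)), c(0.03, 0.02))
  sh <- st
  P <- circumference(st@geom)
  sh@patches <- lapply(sh@patches, function(p) {
    p$vertices[, 2] <- p$vertices[, 2] + P
    p
  })
  expect_equal(intensity(renderMicrograph(st, opt, noise = FALSE)),
               intensity(renderMicrograph(sh, opt, noise = FALSE)),
               tolerance = 1e-12)
})

test_that("pixel noise follows photon statistics on a flat bright field", {
  opt <- opticsConfig(photonScale = 5e4, readNoise = 2, offset = 100)
  # label the whole strip: rows away from the cell edges are flat in x
  st <- staticState(list(c(0, pi / 2)), 1e-9, geom = cylinderGeom(length = 4))
  st@patches[[1]]$vertices <- rbind(c(-2.2, -0.1), c(2.2, -0.1),
                                    c(2.2, pi + 0.1), c(-2.2, pi + 0.1))
  set.seed(7)
  img <- renderMicrograph(st, opt, noise = TRUE)
  clean <- renderMicrograph(st, opt, noise = FALSE)
  m <- intensity(img); mc <- intensity(clean)
  # standardized residuals against the noise-free expectation: for Poisson
  # photons plus Gaussian read noise, var = (mean photons) + read^2
  mu <- mc - opt@offset
  sel <- mu > 50
  z <- (m[sel] - mc[sel]) / sqrt(mu[sel] + opt@readNoise^2)
  expect_gt(sum(sel), 300)
  expect_lt(abs(var(z) - 1), 0.15)
  expect_lt(abs(mean(z)), 3 / sqrt(sum(sel)))
})

test_that("label areas account for occlusion by later insertions", {
  st <- staticState(list(c(0, 1.5)), 0.1)
  la1 <- labelAreas(st, resolution = 0.005)
  # a dark patch born later covers half of the light one
  dark <- list(vertices = rbind(c(-0.25, 1.5), c(0.25, 1.5),
                                c(0.25, 1.9), c(-0.25, 1.9)),
               label = "dark", sourceId = NA_integer_, tBirth = 1)
  st2 <- st
  st2@patches <- c(st2@patches, list(dark))
  la2 <- labelAreas(st2, resolution = 0.005)
  expect_lt(la2[["light"]], la1[["light"]])
  expect_gt(la2[["dark"]], 0.15)
  expect_equal(sum(la2), surfaceArea(st2), tolerance = 0.01 * sum(la2))
})
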