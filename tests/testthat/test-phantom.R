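test_that("phantom generation is deterministic and honours labeling", {
  a <- makeCellPhantom(nFilaments = 12, gridSize = 64, pixelSize = 400,
                       seed = 42)
  b <- makeCellPhantom(nFilaments = 12, gridSize = 64, pixelSize = 400,
                       seed = 42)
  expect_identical(densityMap(a), densityMap(b))
  expect_identical(labelMap(a), labelMap(b))
  expect_identical(trueFilaments(a), trueFilaments(b))

  expect_equal(nrow(trueFilaments(a)), 12)
  expect_equal(sum(trueFilaments(a)$labeled), round(0.7 * 12))

  # same seed, finer raster: identical physical specimen
  c <- makeCellPhantom(nFilaments = 12, gridSize = 128, pixelSize = 200,
                       seed = 42)
  expect_equal(trueFilaments(c), trueFilaments(a), tolerance = 1e-12)
})

test_that("empty filament network leaves nucleus plus envelope only", {
  ph <- makeCellPhantom(nFilaments = 0, labelFraction = 0, gridSize = 64,
                        pixelSize = 400, seed = 1)
  expect_true(all(labelMap(ph) == 0))
  expect_equal(nrow(trueFilaments(ph)), 0)
  # nucleus dominates the density
  expect_gt(max(densityMap(ph)), 1.5)
  expect_true(all(densityMap(ph) >= 0))
  expect_equal(phase(ph), -ph@phaseScale * densityMap(ph))
})

test_that("phantom rejects invalid arguments", {
  expect_error(makeCellPhantom(pixelSize = 0), "pixelSize")
  expect_error(makeCellPhantom(labelFraction = 1.2), "labelFraction")
  expect_error(makeCellPhantom(gridSize = 32), "gridSize")
})

test_that("filament orientation scatter matches the sampling distribution", {
  sds <- vapply(1:100, function(s) {
    ph <- makeCellPhantom(nFilaments = 20, orientationSpread = 15,
                          gridSize = 64, pixelSize = 400, seed = s)
    corrmicro:::axialSD(trueFilaments(ph)$orientation)
  }, numeric(1))
  expect_lt(abs(mean(sds) - 15), 3)
})

test_that("fluorescence rendering is Poisson with the right PSF", {
  ph <- makeCellPhantom(nFilaments = 0, gridSize = 64, pixelSize = 100,
                        seed = 1)
  f0 <- renderFluorescence(ph, photonBudget = 100, seed = 1)
  expect_true(all(counts(f0) == 0))          # nothing labeled, no signal

  # mean linearity: doubling the budget doubles total expected counts
  ph2 <- makeCellPhantom(nFilaments = 10, gridSize = 128, pixelSize = 100,
                         seed = 7)
  e1 <- renderFluorescence(ph2, photonBudget = 2000, noise = FALSE)
  e2 <- renderFluorescence(ph2, photonBudget = 4000, noise = FALSE)
  expect_equal(sum(counts(e2)) / sum(counts(e1)), 2, tolerance = 1e-10)
  n1 <- renderFluorescence(ph2, photonBudget = 2000, seed = 3)
  n2 <- renderFluorescence(ph2, photonBudget = 4000, seed = 4)
  expect_lt(abs(sum(counts(n2)) / sum(counts(n1)) - 2), 0.02)

  # impulse response: single-pixel label, noiseless image FWHM = psf FWHM
  lbl <- matrix(0, 65, 65); lbl[33, 33] <- 1
  imp <- labelOnlyPhantom(lbl, pixelSize = 50)
  fwhmNm <- 343
  e <- counts(renderFluorescence(imp, psfFwhm = fwhmNm, photonBudget = 1,
                                 noise = FALSE))
  prof <- e[33, ]
  half <- max(prof) / 2
  above <- which(prof >= half)
  measured <- (max(above) - min(above) + 1) * 50
  expect_lt(abs(measured - fwhmNm), 50 + 1e-9)   # within one pixel
  expect_error(renderFluorescence(imp, photonBudget = 0), "photonBudget")
})

test_that("hologram of the empty phantom is flat with Poisson statistics", {
  g <- geomForGrid(64)
  zero <- matrix(0, 64, 64)
  h0 <- simulateHologram(zero, g, noise = FALSE)
  expect_equal(max(abs(intensity(h0) - 1)), 0, tolerance = 1e-12)

  budget <- 2000
  pass <- vapply(1:40, function(s) {
    h <- simulateHologram(zero, g, photonBudget = budget, seed = s)
    cnt <- intensity(h) * budget
    x <- sum((cnt - budget)^2) / budget      # chi-square vs Poisson(budget)
    p <- stats::pchisq(x, df = length(cnt) - 1)
    p > 0.005 && p < 0.995                   # two-sided at alpha = 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)

  h1 <- simulateHologram(zero, g, seed = 11)
  h2 <- simulateHologram(zero, g, seed = 11)
  expect_identical(intensity(h1), intensity(h2))
})

test_that("weak sinusoidal phase produces the CTF contrast amplitude", {
  g <- geomForGrid(256)
  n <- 256; dx <- effPixelSize(g)
  nu0 <- 8 / (n * dx)
  y <- matrix((seq_len(n) - (n + 1) / 2) * dx, n, n, byrow = TRUE)
  phi <- 0.01 * cos(2 * pi * nu0 * y)
  h <- simulateHologram(phi, g, noise = FALSE)
  contrast <- (max(intensity(h)) - min(intensity(h))) / 2
  pred <- 2 * 0.01 * abs(sin(pi * wavelength(g) * effDistance(g) * 1e6 * nu0^2))
  expect_lt(abs(contrast / pred - 1), 0.01)
})

test_that("scan simulation conserves energy and scales with exposure", {
  ph <- makeCellPhantom(nFilaments = 3, gridSize = 128, pixelSize = 100,
                        seed = 5)
  beam <- beamProfile(exposure = 1e-4)
  st <- simulateScanSAXS(ph, beam, nY = 2, nZ = 2, stepY = 1000, stepZ = 1000,
                         window = 64, backgroundRate = 0, noise = FALSE)
  photons <- beam@flux * beam@exposure
  for (k in 1:4)
    expect_lt(abs(sum(frames(st)[, , k]) - photons) / photons, 1e-10)

  beam2 <- beamProfile(exposure = 2e-4)
  st2 <- simulateScanSAXS(ph, beam2, nY = 2, nZ = 2, stepY = 1000,
                          stepZ = 1000, window = 64, backgroundRate = 0,
                          noise = FALSE)
  expect_equal(sum(frames(st2)), 2 * sum(frames(st)), tolerance = 1e-12)

  # determinism and empty flags
  stA <- simulateScanSAXS(ph, beam, nY = 3, nZ = 3, stepY = 8000,
                          stepZ = 8000, window = 32, seed = 4)
  stB <- simulateScanSAXS(ph, beam, nY = 3, nZ = 3, stepY = 8000,
                          stepZ = 8000, window = 32, seed = 4)
  expect_identical(frames(stA), frames(stB))
  expect_true(any(scanPositions(stA)$empty))   # 8 um steps leave the FOV
})

test_that("an oriented fibre elongates the diffraction pattern across it", {
  # horizontal Gaussian ridge (orientation 0 deg) as a pure phase object
  n <- 128; dx <- 50
  co <- (seq_len(n) - (n + 1) / 2) * dx
  zz <- matrix(co, n, n)
  dens <- exp(-zz^2 / (2 * corrmicro:::fwhmToSigma(250)^2))
  phan <- methods::new("CellPhantom", density = dens, phase = -0.3 * dens,
                       labelMap = dens * 0, pixelSize = dx, phaseScale = 0.3,
                       filaments = data.frame(), nucleus = list(), seed = 0L)
  beam <- beamProfile(exposure = 1e-4)
  st <- simulateScanSAXS(phan, beam, nY = 1, nZ = 1, stepY = 1000,
                         stepZ = 1000, window = 64, backgroundRate = 0,
                         noise = FALSE, beamstopRadius = 10)
  qm <- qMap(st@qcal, c(64, 64))
  r <- pcaAnisotropy(frames(st)[, , 1], detectorMask(st), qm,
                     qRange = c(0, Inf))
  expect_lt(corrmicro:::axialDistance(r$thetaRecip, 90), 5)
  expect_lt(corrmicro:::axialDistance(r$thetaReal, 0), 5)
  expect_gt(r$omega, 0.3)
})
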