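test_that("q map matches the scattering-vector formula", {
  cal <- qCalibration(c(101, 101), distance = 5000, pixelSize = 172,
                      wavelength = 0.08984362)
  qm <- qMap(cal, c(201, 201))
  expect_equal(qm$q[101, 101], 0)
  expect_equal(qm$qy[101, 101], 0)
  # r = 100 px * 172 um = 17.2 mm at D = 5 m
  expect_equal(qm$q[101, 201], 0.2406, tolerance = 2e-4)

  # small-angle limit: |q| ~ 2 pi r / (lambda D) within 1e-4 relative
  r <- 30 * 172e3                      # nm, r/D = 1e-3
  qSmall <- 2 * pi * r / (0.08984362 * 5e9)
  expect_lt(abs(qm$q[101, 131] / qSmall - 1), 1e-4)

  expect_error(qMap(qCalibration(c(1, 1), 0, 172, 0.09), c(5, 5)))
})

test_that("detector masks compose as set intersections", {
  m0 <- composeMask(c(100, 100))
  expect_true(all(m0))

  mB <- composeMask(c(100, 100), beamstop = list(center = c(50, 50),
                                                 radius = 20))
  excluded <- sum(!mB)
  expect_lt(abs(excluded - pi * 400), 2 * pi * 20 + 10)   # within the rim

  gaps <- list(c(30, 46), c(70, 86))
  mG <- composeMask(c(100, 100), gaps = gaps)
  expect_equal(sum(!mG), 2 * 17 * 100)

  mBoth <- composeMask(c(100, 100),
                       beamstop = list(center = c(50, 50), radius = 20),
                       gaps = gaps)
  stripAttr <- function(m) { attr(m, "validCount") <- NULL; m }
  expect_identical(stripAttr(mBoth), stripAttr(mB) & stripAttr(mG))

  expect_error(composeMask(c(10, 10), gaps = list(c(5, 20))), "gap")
  expect_error(composeMask(c(10, 10),
                           beamstop = list(center = c(50, 5), radius = 2)),
               "beamstop")
})

test_that("background subtraction is unbiased and clipped at zero", {
  f <- matrix(5, 8, 8)
  expect_true(all(subtractBackground(f, f) == 0))
  expect_identical(subtractBackground(f, matrix(0, 8, 8)), f)
  expect_error(subtractBackground(f, list()), "background")

  set.seed(7)
  sig <- matrix(20, 16, 16)
  b <- 6
  bgs <- lapply(1:100, function(k) matrix(rpois(256, b), 16, 16))
  noisy <- matrix(rpois(256, sig + b), 16, 16)
  corr <- subtractBackground(noisy, bgs)
  se <- sqrt((sig[1] + b) + b / 100) / 16   # SE of the mean pixel value
  expect_lt(abs(mean(corr) - 20), 3 * se)
})

test_that("dark field equals the brute-force masked sum exactly", {
  ph <- makeCellPhantom(nFilaments = 2, gridSize = 64, pixelSize = 100,
                        seed = 2)
  beam <- beamProfile(exposure = 1e-5)
  st <- simulateScanSAXS(ph, beam, nY = 2, nZ = 2, stepY = 1000,
                         stepZ = 1000, window = 16, seed = 3,
                         beamstopRadius = 3, gapRows = list(c(6L, 7L)))
  msk <- detectorMask(st)
  df <- darkField(st)
  pos <- scanPositions(st)
  for (k in seq_len(nrow(pos))) {
    acc <- 0
    fr <- frames(st)[, , k]
    for (i in 1:16) for (j in 1:16) if (msk[i, j]) acc <- acc + fr[i, j]
    expect_identical(values(df)[pos$iz[k], pos$iy[k]], acc)
  }

  # additivity over disjoint mask partitions, and the all-false mask
  mA <- msk; mA[, 1:8] <- FALSE
  mB <- msk; mB[, 9:16] <- FALSE
  expect_equal(values(darkField(st, mA)) + values(darkField(st, mB)),
               values(df))
  expect_true(all(values(darkField(st, matrix(FALSE, 16, 16))) == 0))

  # ones frame with a known number of valid pixels
  stOnes <- st
  stOnes@frames[] <- 1
  expect_true(all(values(darkField(stOnes)) == sum(msk)))
})

test_that("PCA anisotropy matches the brute-force oracle to 1e-12", {
  set.seed(42)
  q9 <- list(cal = qCalibration(c(4.3, 5.1), 1000, 100, 0.1))
  q9$qm <- qMap(q9$cal, c(9, 9))
  for (rep in 1:5) {
    f9 <- matrix(rpois(81, 5), 9)
    m9 <- matrix(TRUE, 9, 9); m9[sample(81, 10)] <- FALSE
    got <- pcaAnisotropy(f9, m9, q9$qm, qRange = c(0, Inf))
    want <- pcaOracle(f9, m9, q9$qm)
    expect_equal(got$lambda1, want$lambda1, tolerance = 1e-12)
    expect_equal(got$lambda2, want$lambda2, tolerance = 1e-12)
    expect_equal(got$omega, want$omega, tolerance = 1e-12)
    expect_lt(corrmicro:::axialDistance(got$thetaRecip, want$thetaRecip),
              1e-9)
  }
})

test_that("anisotropy symmetries: isotropy, degenerate line, rotation, scaling", {
  n <- 65
  cq <- centredQMap(n)
  mask <- matrix(TRUE, n, n)
  ctr <- (n + 1) / 2
  rr <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, `+`))

  iso <- exp(-rr^2 / 60)
  r0 <- pcaAnisotropy(iso, mask, cq$qm, qRange = c(0, Inf))
  expect_equal(r0$omega, 0, tolerance = 1e-10)
  expect_false(r0$thetaDefined)
  expect_true(is.na(r0$thetaRecip))

  lin <- matrix(0, n, n); lin[ctr, ] <- 1; lin[ctr, ctr] <- 0
  r1 <- pcaAnisotropy(lin, mask, cq$qm, qRange = c(0, Inf))
  expect_equal(r1$omega, 1, tolerance = 1e-12)
  expect_equal(r1$thetaRecip, 0)
  expect_equal(r1$thetaReal, 90)

  # zero weight -> flagged invalid
  r2 <- pcaAnisotropy(matrix(0, n, n), mask, cq$qm)
  expect_false(r2$valid)

  # 90-degree rotation rotates theta by 90 (mod 180), omega unchanged
  set.seed(5)
  fr <- matrix(rpois(n * n, 3) * exp(-rr^2 / 200), n, n) +
    outer(exp(-(1:n - 20)^2 / 40), exp(-(1:n - 44)^2 / 40))
  rA <- pcaAnisotropy(fr, mask, cq$qm, qRange = c(0, Inf))
  frRot <- t(fr)[n:1, ]                  # 90-degree rotation on a square grid
  rB <- pcaAnisotropy(frRot, mask, cq$qm, qRange = c(0, Inf))
  expect_equal(rB$omega, rA$omega, tolerance = 1e-10)
  expect_lt(corrmicro:::axialDistance(rB$thetaRecip,
                                      (rA$thetaRecip + 90) %% 180), 1e-6)

  # omega in [0,1], invariant under global intensity scaling
  r7 <- pcaAnisotropy(fr * 7, mask, cq$qm, qRange = c(0, Inf))
  expect_equal(r7$omega, rA$omega, tolerance = 1e-12)
  expect_gte(rA$omega, 0); expect_lte(rA$omega, 1)
  expect_equal((rA$thetaRecip + 90) %% 180, rA$thetaReal)
})

test_that("dark-field thresholding limits the analysis to bright points", {
  df <- methods::new("DarkFieldMap",
                     values = matrix(c(1e5, 8e5, 0, 7.5e5), 2, 2),
                     exposure = 1, stepY = 1000, stepZ = 1000)
  v <- thresholdMap(df, 7.5e5)
  expect_identical(as.vector(v), c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(as.vector(thresholdMap(df, 0)),
                   as.vector(values(df) > 0))
  # monotone: raising the threshold never adds valid points
  v2 <- thresholdMap(df, 9e5)
  expect_true(all(v | !v2))
})

test_that("azimuthal averaging reproduces radial profiles", {
  n <- 65
  cq <- centredQMap(n)
  mask <- matrix(TRUE, n, n)

  const <- matrix(3, n, n)
  pr <- azimuthalAverage(const, mask, cq$qm, nBins = 10)
  expect_true(all(abs(pr$intensity[pr$n > 0] - 3) < 1e-12))

  # isotropic Gaussian: profile matches the radial law within binning error
  sigQ <- 0.3 * max(cq$qm$q)
  gauss <- exp(-cq$qm$q^2 / (2 * sigQ^2))
  pg <- azimuthalAverage(gauss, mask, cq$qm, nBins = 16)
  ok <- pg$n > 0
  expect_lt(max(abs(pg$intensity[ok] - exp(-pg$q[ok]^2 / (2 * sigQ^2)))),
            0.05)

  # masking a wedge leaves an isotropic profile essentially unchanged
  wedge <- mask
  ang <- atan2(matrix(1:n - 33, n, n), matrix(1:n - 33, n, n, byrow = TRUE))
  wedge[ang > 0 & ang < pi / 4] <- FALSE
  pw <- azimuthalAverage(gauss, wedge, cq$qm, nBins = 16)
  both <- pg$n > 0 & pw$n > 0
  expect_lt(max(abs(pw$intensity[both] - pg$intensity[both])), 0.02)

  expect_error(azimuthalAverage(const, mask, cq$qm, nBins = 1), "nBins")
})
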