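test_that("rebinning preserves constants and integrated intensity", {
  img <- matrix(3, 64, 64)
  expect_identical(rebinImage(img, 50, 50), img)
  rb <- rebinImage(img, 50, 100)
  expect_equal(dim(rb), c(32L, 32L))
  expect_true(all(abs(rb - 3) < 1e-12))

  set.seed(2)
  r <- matrix(runif(120 * 80), 120, 80)
  out <- rebinImage(r, 50, 130)
  expect_lt(abs(sum(out) * 130^2 - sum(r) * 50^2) / (sum(r) * 50^2), 1e-6)
})

test_that("translation registration recovers shifts to sub-pixel accuracy", {
  set.seed(9)
  img <- corrmicro:::blur2(matrix(rnorm(128^2), 128), 2)

  same <- registerTranslation(img, img)
  expect_equal(c(same$dy, same$dz), c(0, 0))
  expect_equal(same$score, 1, tolerance = 1e-10)

  # integer circular shift recovered exactly
  shifted <- img[c(125:128, 1:124), c(8:128, 1:7)]  # dz = +4, dy = -7
  ri <- registerTranslation(img, shifted)
  expect_equal(c(ri$dz, ri$dy), c(4, -7))

  # sub-pixel shift via the Fourier shift theorem, upsampling 100
  fz <- corrmicro:::fftFreq(128); fy <- corrmicro:::fftFreq(128)
  shift <- function(m, dz, dy) {
    Fm <- stats::fft(m)
    Re(stats::fft(Fm * exp(-1i * 2 * pi * (outer(fz * dz, rep(1, 128)) +
                                             outer(rep(1, 128), fy * dy))),
                  inverse = TRUE) / length(m))
  }
  mov <- shift(img, 2.30, -3.70)
  rs <- registerTranslation(img, mov, upsample = 100)
  expect_lt(abs(rs$dz - 2.30), 0.1)
  expect_lt(abs(rs$dy + 3.70), 0.1)
  expect_gt(rs$score, 0.9)

  expect_error(registerTranslation(matrix(1, 8, 8), matrix(1, 8, 8)), "flat")
})

test_that("axial distances live in [0, 90] and ignore 180-degree offsets", {
  set.seed(4)
  a <- runif(1000, 0, 360); b <- runif(1000, 0, 360)
  d <- corrmicro:::axialDistance(a, b)
  expect_true(all(d >= 0 & d <= 90))
  expect_equal(corrmicro:::axialDistance(a + 180, b), d, tolerance = 1e-9)
  # expectation of the distance between independent uniform orientations
  expect_lt(abs(mean(corrmicro:::axialDistance(runif(1e4, 0, 180),
                                               runif(1e4, 0, 180))) - 45), 1)
})

makeAniso <- function(nyc, nzr, thetaReal, stepY = 1000, stepZ = 1000) {
  mk <- function(v) matrix(v, nzr, nyc)
  methods::new("AnisotropyMap", omega = mk(0.8), thetaRecip = mk((thetaReal + 90) %% 180),
               thetaReal = mk(thetaReal), lambda1 = mk(2), lambda2 = mk(1),
               valid = matrix(TRUE, nzr, nyc), stepY = stepY, stepZ = stepZ)
}

gridPositions <- function(nyc, nzr, step = 1000) {
  g <- expand.grid(iy = seq_len(nyc), iz = seq_len(nzr))
  g$y <- (g$iy - (nyc + 1) / 2) * step
  g$z <- (g$iz - (nzr + 1) / 2) * step
  g
}

test_that("orientation agreement matches aligned and orthogonal cases", {
  pos <- gridPositions(8, 8)
  fs <- data.frame(y1 = -3000, z1 = 0, y2 = 3000, z2 = 3000 * tan(30 * pi / 180),
                   orientation = 30, length = 3000 / cos(30 * pi / 180) * 2)

  agree <- orientationAgreement(fs, makeAniso(8, 8, 30), pos)
  expect_gt(agree$n, 0)
  expect_equal(agree$medianDTheta, 0, tolerance = 1e-9)
  expect_equal(agree$fracBelow20, 1)

  ortho <- orientationAgreement(fs, makeAniso(8, 8, 120), pos)
  expect_equal(ortho$medianDTheta, 90, tolerance = 1e-9)
  expect_equal(ortho$fracBelow20, 0)

  # empty filament set
  none <- orientationAgreement(fs[0, ], makeAniso(8, 8, 30), pos)
  expect_equal(none$n, 0L)

  # a transform translates the segment into / out of the grid
  far <- fs; far$y1 <- far$y1 + 1e6; far$y2 <- far$y2 + 1e6
  off <- orientationAgreement(far, makeAniso(8, 8, 30), pos)
  expect_equal(off$n, 0L)
  back <- orientationAgreement(far, makeAniso(8, 8, 30), pos,
                               transform = list(dy = -1e6, dz = 0, scale = 1))
  expect_gt(back$n, 0)
})

test_that("segment coordinates convert to the centred physical frame", {
  fs <- data.frame(y1 = 1, z1 = 1, y2 = 65, z2 = 65,
                   orientation = 45, length = 64 * sqrt(2))
  phys <- segmentsToPhysical(fs, pixelSize = 50, dims = c(65, 65))
  expect_equal(phys$y1, -32 * 50)
  expect_equal(phys$z2, 32 * 50)
  expect_equal(phys$length, 64 * sqrt(2) * 50)
})
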