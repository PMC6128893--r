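test_that("effective geometry derives magnification, pixel and distance", {
  g <- opticalGeometry(z1 = 10, z2 = 5000, pixelSize = 6.5,
                       photonEnergy = 13.8)
  expect_equal(magnification(g), 501)
  expect_equal(effPixelSize(g), 6.5e3 / 501, tolerance = 1e-12)
  expect_equal(effDistance(g), 10 * 5000 / 5010, tolerance = 1e-12)
  expect_equal(wavelength(g), 1.239842 / 13.8, tolerance = 1e-12)

  # contact plane
  g0 <- opticalGeometry(z1 = 10, z2 = 0)
  expect_equal(magnification(g0), 1)
  expect_equal(effPixelSize(g0), 6500)
  expect_equal(effDistance(g0), 0)

  expect_error(opticalGeometry(z1 = 0, z2 = 10), "z1")
  expect_error(opticalGeometry(z1 = 10, z2 = 10, photonEnergy = -1))

  # algebraic identities over random geometries
  set.seed(1)
  for (k in 1:20) {
    z1 <- runif(1, 1, 1000); z2 <- runif(1, 1, 10000)
    g <- opticalGeometry(z1, z2)
    expect_equal(magnification(g), (z1 + z2) / z1)
    expect_equal(effPixelSize(g), 6.5e3 / magnification(g))
    expect_equal(effDistance(g), z1 * z2 / (z1 + z2))
    expect_lte(effDistance(g), min(z1, z2))
  }
})

test_that("Fresnel propagation is unitary, invertible, and alias-guarded", {
  set.seed(3)
  f <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64)
  p <- fresnelPropagate(f, pixelSize = 1, lambda = 1e-3, distance = 2e4)
  expect_lt(abs(sum(Mod(p)^2) - sum(Mod(f)^2)) / sum(Mod(f)^2), 1e-10)
  back <- fresnelPropagate(p, 1, 1e-3, -2e4)
  expect_lt(max(Mod(back - f)), 1e-10)

  # plane wave is an eigenfunction (unchanged up to a global phase)
  cst <- matrix(1 + 0i, 64, 64)
  pc <- fresnelPropagate(cst, 1, 1e-3, 1e4)
  expect_lt(max(Mod(pc / pc[1, 1] - 1)), 1e-12)

  expect_error(fresnelPropagate(f, 1, 1e-3, 1e6), "aliased")

  # Gaussian beam: waist after propagation matches the analytic formula
  n <- 256; w0 <- 20
  co <- (seq_len(n) - (n + 1) / 2)
  rr2 <- outer(co^2, co^2, `+`)
  g <- exp(-rr2 / w0^2) + 0i
  lam <- 1e-3; d <- 2e5
  zR <- pi * w0^2 / lam
  wTheory <- w0 * sqrt(1 + (d / zR)^2)
  I <- Mod(fresnelPropagate(g, 1, lam, d))^2
  # for intensity exp(-2 r^2 / w^2), the per-axis second moment is w^2/4
  wMeas <- 2 * sqrt(sum(I * outer(co^2, rep(1, n))) / sum(I))
  expect_lt(abs(wMeas / wTheory - 1), 0.005)
})

test_that("CTF inversion recovers weak phases", {
  g <- geomForGrid(256)
  n <- 256; dx <- effPixelSize(g)

  # flat hologram -> zero phase
  flat <- methods::new("Hologram", intensity = matrix(1, n, n), geometry = g)
  expect_equal(max(abs(phase(ctfPhaseRetrieval(flat)))), 0, tolerance = 1e-12)

  # sinusoid away from CTF zeros, alpha -> 1e-6: amplitude within 2%
  nu0 <- 8 / (n * dx)
  y <- matrix((seq_len(n) - (n + 1) / 2) * dx, n, n, byrow = TRUE)
  h <- simulateHologram(0.01 * cos(2 * pi * nu0 * y), g, noise = FALSE)
  rec <- ctfPhaseRetrieval(h, alphaLow = 1e-6, alphaHigh = 1e-6,
                           zeroBackground = FALSE)
  expect_lt(abs(max(abs(phase(rec))) / 0.01 - 1), 0.02)

  # full weak-phase phantom (|phi| <= 0.1), noiseless: NRMSE < 5% on support
  ph <- makeCellPhantom(nFilaments = 8, gridSize = n, pixelSize = dx,
                        seed = 3, phaseScale = 0.03)
  expect_lte(max(abs(phase(ph))), 0.1)
  hw <- simulateHologram(ph, g, noise = FALSE)
  pw <- ctfPhaseRetrieval(hw, alphaLow = 1e-6, alphaHigh = 1e-3)
  sup <- phase(ph) < -0.001
  nrmse <- sqrt(mean((phase(pw)[sup] - phase(ph)[sup])^2)) /
    sqrt(mean(phase(ph)[sup]^2))
  expect_lt(nrmse, 0.05)

  # contact plane carries no contrast
  flat0 <- methods::new("Hologram", intensity = matrix(1, 16, 16),
                        geometry = opticalGeometry(z1 = 10, z2 = 0))
  expect_error(ctfPhaseRetrieval(flat0), "z_eff")
})

test_that("support estimation recovers a disc and grows with dilation", {
  g <- geomForGrid(256)
  dx <- effPixelSize(g)
  disc <- discPhase(256, dx, radiusPx = 60)
  h <- simulateHologram(disc, g, noise = FALSE)
  ctf <- ctfPhaseRetrieval(h)
  sup <- estimateSupport(ctf)
  expect_lt(abs(sum(sup) / (pi * 60^2) - 1), 0.15)
  expect_gte(sum(sup & disc < 0) / sum(disc < 0), 0.999)  # circumscribes

  areas <- vapply(c(0, 2, 4, 6), function(d)
    sum(estimateSupport(ctf, dilation = d)), numeric(1))
  expect_true(all(diff(areas) > 0))

  expect_error(estimateSupport(phaseMap(matrix(0, 64, 64), dx)), "support")
})

test_that("RAAR has the fixed-point property and reconstructs a disc", {
  g <- geomForGrid(256)
  dx <- effPixelSize(g)
  disc <- discPhase(256, dx, radiusPx = 60)
  h <- simulateHologram(disc, g, noise = FALSE)

  # exact solution is a fixed point with vanishing residual
  co <- (seq_len(256) - 257 / 2) * dx
  supTrue <- sqrt(outer(co^2, co^2, `+`)) < 64 * dx
  fp <- raarReconstruct(h, supTrue, nIter = 2, init = phaseMap(disc, dx))
  expect_lt(fp$residuals[1], 1e-8)
  expect_lt(max(abs(phase(fp$phase) - disc)), 1e-8)

  # CTF init + estimated support: Pearson correlation > 0.99
  ctf <- ctfPhaseRetrieval(h)
  sup <- estimateSupport(ctf)
  rec <- raarReconstruct(h, sup, nIter = 400)
  expect_gt(cor(as.vector(phase(rec$phase)), as.vector(disc)), 0.99)
  # final magnitude residual does not exceed that of the CTF initialization
  expect_lte(rec$residuals[length(rec$residuals)], rec$residuals[1])

  # unconstrained support on a flat hologram converges to zero phase
  flat <- methods::new("Hologram", intensity = matrix(1, 64, 64),
                       geometry = geomForGrid(64))
  z <- raarReconstruct(flat, matrix(TRUE, 64, 64), nIter = 30,
                       init = phaseMap(matrix(0, 64, 64),
                                       effPixelSize(geomForGrid(64))))
  expect_lt(max(abs(phase(z$phase))), 1e-10)

  expect_error(raarReconstruct(h, matrix(FALSE, 256, 256)), "support")
})
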