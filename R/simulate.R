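## Forward simulation of the two X-ray modalities.

#' Simulate an in-line near-field hologram
#'
#' Propagates the pure-phase exit wave \eqn{e^{i\phi}} by the effective
#' distance of the (cone-beam) geometry, takes the intensity, adds Poisson
#' noise at \code{photonBudget} photons per pixel, and flat-field normalizes
#' so that the empty-beam expectation is 1. The phantom (or phase matrix)
#' must be sampled at the effective pixel size of the geometry.
#'
#' @param object a \linkS4class{CellPhantom} or a phase matrix (radians)
#' @param geom an \linkS4class{OpticalGeometry}
#' @param photonBudget expected photons per detector pixel for the empty beam
#' @param noise simulate Poisson counting noise (default TRUE)
#' @param seed RNG seed for the noise realization
#' @return a \linkS4class{Hologram}
#' @export
setGeneric("simulateHologram",
  function(object, geom, photonBudget = 5000, noise = TRUE, seed = NULL)
    standardGeneric("simulateHologram"))

.simulateHologramPhase <- function(phi, geom, photonBudget, noise, seed) {
  stopifnot(methods::is(geom, "OpticalGeometry"))
  checkPositive(photonBudget = photonBudget)
  fn <- fresnelNumber(geom)
  if (is.finite(fn) && (fn < 1e-4 || fn > 10))
    stop(sprintf(paste0("per-pixel Fresnel number %.3g outside the sampling-",
                        "valid range [1e-4, 10]"), fn))
  u <- propagateEffective(exp(1i * phi), geom, sign = 1)
  I <- Mod(u)^2
  if (noise) {
    I <- withSeed(seed, matrix(stats::rpois(length(I), I * photonBudget),
                               nrow(I), ncol(I)) / photonBudget)
  }
  methods::new("Hologram", intensity = I, geometry = geom)
}

#' @rdname simulateHologram
#' @export
setMethod("simulateHologram", "matrix",
  function(object, geom, photonBudget = 5000, noise = TRUE, seed = NULL)
    .simulateHologramPhase(object, geom, photonBudget, noise, seed))

#' @rdname simulateHologram
#' @export
setMethod("simulateHologram", "CellPhantom",
  function(object, geom, photonBudget = 5000, noise = TRUE, seed = NULL) {
    if (abs(object@pixelSize - geom@effPixelSize) >
        1e-3 * geom@effPixelSize)
      stop(sprintf(paste0("phantom pixel size (%.3f nm) does not match the ",
                          "effective pixel size of the geometry (%.3f nm); ",
                          "rasterize the phantom at effPixelSize(geom)"),
                   object@pixelSize, geom@effPixelSize))
    .simulateHologramPhase(object@phase, geom, photonBudget, noise, seed)
  })

# Gaussian illumination amplitude for a window, centred at (offY, offZ) nm
# from the window centre; intensity FWHM fwhmY/fwhmZ; total intensity = flux
.beamAmplitude <- function(nWin, pixelSize, fwhmY, fwhmZ, offY, offZ, photons) {
  co <- axisCoords(nWin, pixelSize)
  sy <- fwhmToSigma(fwhmY)
  sz <- fwhmToSigma(fwhmZ)
  gy <- exp(-(co - offY)^2 / (2 * sy^2))
  gz <- exp(-(co - offZ)^2 / (2 * sz^2))
  I <- outer(gz, gy)                    # rows = z, cols = y
  I <- I * (photons / sum(I))
  sqrt(I)
}

#' Simulate a scanning-SAXS raster scan
#'
#' The sample is translated through the nano-focus on a regular grid; at each
#' position the far-field intensity is the squared modulus of the 2D Fourier
#' transform of the locally illuminated exit wave (Gaussian beam amplitude
#' times \eqn{e^{i\phi}}), Parseval-normalized so the noiseless total equals
#' the incident photons, shifted so that q = 0 sits at the beam centre of the
#' frame. A uniform background rate is added, Poisson noise applied, and the
#' detector mask (beamstop disc plus inter-module gap stripes) zeroes the
#' blocked pixels. Scan positions whose window centre falls outside the
#' phantom are flagged empty (beam through vacuum).
#'
#' The q calibration is derived from the simulation grid: detector pixel size
#' \eqn{p = \lambda D / (N_{win} \Delta x)} at detector distance \code{D}, so
#' the small-angle q of detector pixels matches the Fourier grid of the
#' window.
#'
#' @param phantom a \linkS4class{CellPhantom}
#' @param beam a \linkS4class{BeamProfile}
#' @param nY,nZ scan grid size (positions along y and z)
#' @param stepY,stepZ scan step, nm (default 1000 nm; must be >= the phantom
#'   pixel size)
#' @param window simulation/detector window size in pixels (power of two
#'   recommended)
#' @param backgroundRate uniform background, counts per pixel per frame
#' @param detectorDistance sample-detector distance, mm
#' @param beamstopRadius beamstop disc radius, detector pixels
#' @param gapRows list of integer vectors c(first, last): masked detector row
#'   stripes (inter-module gaps)
#' @param noise Poisson-sample the frames (default TRUE)
#' @param photonEnergy keV, for the derived wavelength of the q calibration
#' @param seed RNG seed
#' @return a \linkS4class{ScanStack}
#' @export
simulateScanSAXS <- function(phantom, beam, nY = 20, nZ = 20,
                             stepY = 1000, stepZ = 1000, window = 64,
                             backgroundRate = 0.05, detectorDistance = 5000,
                             beamstopRadius = 10,
                             gapRows = NULL,
                             noise = TRUE, photonEnergy = 13.8, seed = NULL) {
  stopifnot(methods::is(phantom, "CellPhantom"),
            methods::is(beam, "BeamProfile"))
  dx <- phantom@pixelSize
  if (stepY < dx || stepZ < dx)
    stop("scan step must be at least the phantom pixel size")
  n <- nrow(phantom@phase)
  nw <- as.integer(window)
  if (is.null(gapRows)) {
    g1 <- round(nw / 3); g2 <- round(2 * nw / 3)
    gapRows <- list(c(g1, g1 + 1L), c(g2, g2 + 1L))
  }
  lambda <- .hc_keV_nm / photonEnergy    # only used for the derived q-cal
  center <- floor(nw / 2) + 1L
  pDetUm <- lambda * detectorDistance * 1e6 / (nw * dx) * 1e-3  # nm -> um
  qcal <- qCalibration(beamCenter = c(center, center),
                       distance = detectorDistance, pixelSize = pDetUm,
                       wavelength = lambda)
  mask <- composeMask(c(nw, nw),
                      beamstop = list(center = c(center, center),
                                      radius = beamstopRadius),
                      gaps = gapRows)
  attr(mask, "validCount") <- NULL

  photons <- beam@flux * beam@exposure
  ys <- (seq_len(nY) - (nY + 1) / 2) * stepY
  zs <- (seq_len(nZ) - (nZ + 1) / 2) * stepZ
  coords <- axisCoords(n, dx)
  half <- nw %/% 2

  positions <- expand.grid(iy = seq_len(nY), iz = seq_len(nZ))
  positions$y <- ys[positions$iy]
  positions$z <- zs[positions$iz]
  positions$empty <- abs(positions$y) > max(abs(coords)) |
                     abs(positions$z) > max(abs(coords))
  framesArr <- array(0, dim = c(nw, nw, nrow(positions)))

  doFrame <- function(k) {
    yk <- positions$y[k]; zk <- positions$z[k]
    # window centred on the nearest phantom pixel; off-grid regions are vacuum
    ic <- which.min(abs(coords - yk))
    ir <- which.min(abs(coords - zk))
    rIdx <- (ir - half):(ir + half - 1L)
    cIdx <- (ic - half):(ic + half - 1L)
    phiLoc <- matrix(0, nw, nw)
    rOk <- rIdx >= 1L & rIdx <= n
    cOk <- cIdx >= 1L & cIdx <= n
    if (any(rOk) && any(cOk) && !positions$empty[k])
      phiLoc[which(rOk), which(cOk)] <- phantom@phase[rIdx[rOk], cIdx[cOk]]
    A <- .beamAmplitude(nw, dx, beam@fwhmY, beam@fwhmZ,
                        yk - coords[ic], zk - coords[ir], photons)
    far <- fftShift(Mod(stats::fft(A * exp(1i * phiLoc)))^2) / (nw * nw)
    far + backgroundRate
  }

  expectationOnly <- !noise
  framesList <- lapply(seq_len(nrow(positions)), doFrame)
  if (expectationOnly) {
    for (k in seq_along(framesList)) framesArr[, , k] <- framesList[[k]]
  } else {
    withSeed(seed, {
      for (k in seq_along(framesList)) {
        f <- matrix(stats::rpois(nw * nw, framesList[[k]]), nw, nw)
        f[!mask] <- 0
        framesArr[, , k] <- f
      }
    })
  }

  methods::new("ScanStack", frames = framesArr, mask = mask,
               positions = positions, stepY = stepY, stepZ = stepZ,
               exposure = beam@exposure, qcal = qcal)
}
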