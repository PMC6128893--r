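## Synthetic adherent-cell phantom: oriented filament bundles, an elliptical
## nucleus (the strong unlabeled scatterer), and a faint cytoplasm envelope.
##
## The cell geometry is drawn in physical coordinates (nm, centred on the
## field of view) BEFORE rasterization, so the same seed produces the same
## physical specimen at any grid size / pixel size. All random draws happen
## in a fixed order that does not depend on the raster grid.

# elliptical metric: ((y,z) relative to centre, rotated by -angle) scaled by
# semi-axes; m <= 1 inside the ellipse
.ellipseMetric <- function(yy, zz, cy, cz, semiY, semiZ, angleDeg) {
  a <- angleDeg * pi / 180
  u <- (yy - cy) * cos(a) + (zz - cz) * sin(a)
  v <- -(yy - cy) * sin(a) + (zz - cz) * cos(a)
  (u / semiY)^2 + (v / semiZ)^2
}

#' Generate a synthetic cell phantom
#'
#' Builds a 2D projected-electron-density model of an adherent cell:
#' \code{nFilaments} straight filament bundles with Gaussian cross-section,
#' drawn around a randomly oriented main cell axis with normally distributed
#' orientation scatter; a denser elliptical nucleus (projected-ellipsoid
#' profile); and a low-density cytoplasm envelope. A fraction
#' \code{labelFraction} of the filaments carries fluorophore label; only those
#' contribute to \code{labelMap}. The phase map is \eqn{\phi = -c \cdot
#' density} (pure phase object, non-positive by convention).
#'
#' Filament centres are drawn inside the envelope and segments are clipped to
#' it; widths (FWHM) are uniform in \code{widthRange} and footprints truncated
#' at 3 sigma, so the label map is strictly zero off the filaments.
#'
#' @param nFilaments number of filament bundles (>= 0)
#' @param orientationSpread SD (degrees) of filament orientations about the
#'   main cell axis
#' @param labelFraction fraction in [0,1] of filaments that are labeled;
#'   exactly \code{round(labelFraction * nFilaments)} contribute to the label
#'   map
#' @param gridSize raster size in pixels (square, >= 64)
#' @param pixelSize raster pixel size in nm (> 0)
#' @param seed integer seed; regeneration with the same seed is bit-identical
#' @param phaseScale positive constant c in \eqn{\phi = -c \cdot density}
#' @param cellSemiY,cellSemiZ envelope semi-axes, nm
#' @param nucleusSemiY,nucleusSemiZ nucleus semi-axes, nm
#' @param nucleusScale nucleus density scale
#' @param envelopeDensity cytoplasm envelope peak density
#' @param widthRange filament FWHM range, nm
#' @param lengthRange filament length range, nm (clipped to the envelope)
#' @return a \linkS4class{CellPhantom}
#' @examples
#' ph <- makeCellPhantom(nFilaments = 10, gridSize = 128, pixelSize = 100,
#'                       seed = 7)
#' range(phase(ph))
#' @export
makeCellPhantom <- function(nFilaments = 30, orientationSpread = 15,
                            labelFraction = 0.7, gridSize = 512,
                            pixelSize = 50, seed = 1, phaseScale = 0.25,
                            cellSemiY = 10000, cellSemiZ = 6500,
                            nucleusSemiY = 3500, nucleusSemiZ = 2500,
                            nucleusScale = 1, envelopeDensity = 0.1,
                            widthRange = c(150, 400),
                            lengthRange = c(6000, 16000)) {
  if (pixelSize <= 0) stop("'pixelSize' must be strictly positive")
  if (labelFraction < 0 || labelFraction > 1)
    stop("'labelFraction' must lie in [0, 1]")
  if (gridSize < 64) stop("'gridSize' must be at least 64")
  if (nFilaments < 0) stop("'nFilaments' must be >= 0")
  checkPositive(phaseScale = phaseScale)
  seed <- as.integer(seed)

  geomDraw <- withSeed(seed, {
    theta0 <- stats::runif(1, 0, 180)
    nucCenter <- stats::rnorm(2, 0, 400)
    fil <- NULL
    if (nFilaments > 0) {
      ori <- (theta0 + stats::rnorm(nFilaments, 0, orientationSpread)) %% 180
      # centre points: uniform over a shrunken envelope
      ang <- stats::runif(nFilaments, 0, 2 * pi)
      rad <- sqrt(stats::runif(nFilaments))
      a0 <- theta0 * pi / 180
      u <- 0.8 * cellSemiY * rad * cos(ang)
      v <- 0.8 * cellSemiZ * rad * sin(ang)
      cy <- u * cos(a0) - v * sin(a0)
      cz <- u * sin(a0) + v * cos(a0)
      len <- stats::runif(nFilaments, lengthRange[1], lengthRange[2])
      wid <- stats::runif(nFilaments, widthRange[1], widthRange[2])
      amp <- stats::runif(nFilaments, 0.6, 1)
      nLab <- round(labelFraction * nFilaments)
      labeled <- rep(FALSE, nFilaments)
      if (nLab > 0) labeled[sample.int(nFilaments, nLab)] <- TRUE
      fil <- data.frame(orientation = ori, cy = cy, cz = cz, length = len,
                        widthFwhm = wid, amplitude = amp, labeled = labeled)
    }
    list(theta0 = theta0, nucCenter = nucCenter, fil = fil)
  })

  # clip each filament to the 0.95 envelope along its own direction
  filaments <- data.frame(y1 = numeric(0), z1 = numeric(0), y2 = numeric(0),
                          z2 = numeric(0), orientation = numeric(0),
                          length = numeric(0), widthFwhm = numeric(0),
                          amplitude = numeric(0), labeled = logical(0))
  if (!is.null(geomDraw$fil)) {
    f <- geomDraw$fil
    a0 <- geomDraw$theta0 * pi / 180
    for (i in seq_len(nrow(f))) {
      th <- f$orientation[i] * pi / 180
      dirY <- cos(th); dirZ <- sin(th)
      # envelope metric along c + t*dir is a quadratic q2 t^2 + q1 t + q0
      rotC <- c((f$cy[i]) * cos(a0) + (f$cz[i]) * sin(a0),
                -(f$cy[i]) * sin(a0) + (f$cz[i]) * cos(a0))
      rotD <- c(dirY * cos(a0) + dirZ * sin(a0),
                -dirY * sin(a0) + dirZ * cos(a0))
      q2 <- (rotD[1] / cellSemiY)^2 + (rotD[2] / cellSemiZ)^2
      q1 <- 2 * (rotC[1] * rotD[1] / cellSemiY^2 + rotC[2] * rotD[2] / cellSemiZ^2)
      q0 <- (rotC[1] / cellSemiY)^2 + (rotC[2] / cellSemiZ)^2 - 0.95^2
      disc <- q1^2 - 4 * q2 * q0
      if (disc <= 0) next               # centre outside the clip ellipse
      tA <- (-q1 - sqrt(disc)) / (2 * q2)
      tB <- (-q1 + sqrt(disc)) / (2 * q2)
      t1 <- max(tA, -f$length[i] / 2)
      t2 <- min(tB, f$length[i] / 2)
      if (t2 - t1 < 500) next           # degenerate sliver
      filaments <- rbind(filaments, data.frame(
        y1 = f$cy[i] + t1 * dirY, z1 = f$cz[i] + t1 * dirZ,
        y2 = f$cy[i] + t2 * dirY, z2 = f$cz[i] + t2 * dirZ,
        orientation = f$orientation[i], length = t2 - t1,
        widthFwhm = f$widthFwhm[i], amplitude = f$amplitude[i],
        labeled = f$labeled[i]))
    }
  }

  n <- as.integer(gridSize)
  coords <- axisCoords(n, pixelSize)
  yy <- matrix(coords, n, n, byrow = TRUE)   # columns = y
  zz <- matrix(coords, n, n, byrow = FALSE)  # rows    = z

  mEnv <- .ellipseMetric(yy, zz, 0, 0, cellSemiY, cellSemiZ, geomDraw$theta0)
  dens <- matrix(0, n, n)
  inEnv <- mEnv < 1
  dens[inEnv] <- envelopeDensity * sqrt(1 - mEnv[inEnv])

  nuc <- list(centerY = geomDraw$nucCenter[1], centerZ = geomDraw$nucCenter[2],
              semiY = nucleusSemiY, semiZ = nucleusSemiZ,
              angle = geomDraw$theta0, scale = nucleusScale)
  mNuc <- .ellipseMetric(yy, zz, nuc$centerY, nuc$centerZ, nuc$semiY,
                         nuc$semiZ, nuc$angle)
  inNuc <- mNuc < 1
  dens[inNuc] <- dens[inNuc] + 2 * nucleusScale * sqrt(1 - mNuc[inNuc])

  label <- matrix(0, n, n)
  if (nrow(filaments) > 0) {
    for (i in seq_len(nrow(filaments))) {
      s <- filaments[i, ]
      sg <- fwhmToSigma(s$widthFwhm)
      pad <- 3 * sg
      cl <- range(s$y1, s$y2); rl <- range(s$z1, s$z2)
      ci <- which(coords >= cl[1] - pad & coords <= cl[2] + pad)
      ri <- which(coords >= rl[1] - pad & coords <= rl[2] + pad)
      if (!length(ci) || !length(ri)) next
      d <- segmentDistance(yy[ri, ci, drop = FALSE], zz[ri, ci, drop = FALSE],
                           s$y1, s$z1, s$y2, s$z2)
      contrib <- s$amplitude * exp(-d^2 / (2 * sg^2))
      contrib[d > 3 * sg] <- 0           # hard footprint truncation
      dens[ri, ci] <- dens[ri, ci] + contrib
      if (s$labeled) label[ri, ci] <- label[ri, ci] + contrib
    }
  }

  methods::new("CellPhantom", density = dens, phase = -phaseScale * dens,
               labelMap = label, pixelSize = pixelSize,
               phaseScale = phaseScale, filaments = filaments, nucleus = nuc,
               seed = seed)
}

#' Simulate a confocal or STED fluorescence recording of a phantom
#'
#' The expected image is the fluorophore map convolved with an isotropic
#' Gaussian point-spread function, scaled so the brightest pixel has
#' expectation \code{photonBudget}; photon counts are Poisson-distributed.
#'
#' @param phantom a \linkS4class{CellPhantom}
#' @param psfFwhm PSF full width at half maximum, nm; defaults to 343 nm for
#'   confocal (the diffraction limit at 651 nm emission and NA 0.95) and a
#'   three-fold sharper 114.3 nm for STED
#' @param photonBudget expected counts at the brightest pixel (> 0)
#' @param mode "confocal" or "sted"
#' @param seed RNG seed for the Poisson noise
#' @param noise if FALSE, return the noiseless expectation (non-integer)
#' @return a \linkS4class{FluorescenceImage}
#' @export
renderFluorescence <- function(phantom, psfFwhm = NULL, photonBudget = 500,
                               mode = c("confocal", "sted"), seed = NULL,
                               noise = TRUE) {
  stopifnot(methods::is(phantom, "CellPhantom"))
  mode <- match.arg(mode)
  if (is.null(psfFwhm)) psfFwhm <- if (mode == "sted") 114.3 else 343
  checkPositive(psfFwhm = psfFwhm)
  if (photonBudget <= 0) stop("'photonBudget' must be strictly positive")
  sigmaPx <- fwhmToSigma(psfFwhm) / phantom@pixelSize
  expected <- blur2(phantom@labelMap, sigmaPx)
  expected[expected < 0] <- 0            # filter ringing guard
  mx <- max(expected)
  if (mx > 0) expected <- expected * (photonBudget / mx)
  cnt <- if (noise) {
    withSeed(seed, matrix(stats::rpois(length(expected), expected),
                          nrow(expected), ncol(expected)))
  } else expected
  methods::new("FluorescenceImage", counts = cnt,
               pixelSize = phantom@pixelSize, psfFwhm = psfFwhm, mode = mode)
}
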