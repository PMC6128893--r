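## Cross-modality registration and orientation-agreement statistics.

# 1D overlap matrix mapping ns source pixels (size ps) onto target pixels
# (size pt), mean-preserving rows; colSums = ps/pt exactly for covered pixels
.rebinMatrix <- function(ns, ps, pt) {
  nt <- ceiling(ns * ps / pt - 1e-9)
  W <- matrix(0, nt, ns)
  for (i in seq_len(nt)) {
    aa <- (i - 1) * pt / ps             # target bin in source-pixel units
    bb <- i * pt / ps
    j1 <- max(1L, floor(aa) + 1L)
    j2 <- min(ns, ceiling(bb))
    for (j in j1:j2)
      W[i, j] <- max(0, min(bb, j) - max(aa, j - 1)) * ps / pt
  }
  W
}

#' Area-weighted rebinning of an image onto a new pixel size
#'
#' Resamples by exact pixel-overlap weighting: each target pixel is the
#' area-weighted mean of the source pixels it covers. Total integrated
#' intensity (value times pixel area) is conserved exactly up to round-off.
#'
#' @param image matrix
#' @param srcPixel source pixel size, nm
#' @param dstPixel target pixel size, nm
#' @return matrix on the target grid (same physical extent)
#' @export
rebinImage <- function(image, srcPixel, dstPixel) {
  checkPositive(srcPixel = srcPixel, dstPixel = dstPixel)
  if (!is.matrix(image)) stop("'image' must be a matrix")
  if (abs(srcPixel - dstPixel) < 1e-12 * srcPixel) return(image)
  Wr <- .rebinMatrix(nrow(image), srcPixel, dstPixel)
  Wc <- .rebinMatrix(ncol(image), srcPixel, dstPixel)
  Wr %*% image %*% t(Wc)
}

#' Sub-pixel translation registration by phase cross-correlation
#'
#' Finds the translation of \code{moving} relative to \code{reference} as
#' the peak of their cross-correlation, refined on an upsampled grid around
#' the integer peak by direct evaluation of the inverse Fourier sum (matrix
#' multiply DFT). Images must share shape and pixel size (rebin first).
#'
#' @param reference,moving matrices of equal dimensions
#' @param upsample sub-pixel refinement factor (1 = integer shifts)
#' @return list of class \code{RegistrationTransform}: \code{dy}, \code{dz}
#'   (shift of \code{moving} relative to \code{reference}, px: moving is the
#'   reference translated by (+dy, +dz)), \code{scale} (1), \code{score}
#'   (normalized cross-correlation at the peak, in [-1, 1])
#' @export
registerTranslation <- function(reference, moving, upsample = 1) {
  if (!all(dim(reference) == dim(moving)))
    stop("images must have identical dimensions")
  r <- reference - mean(reference)
  m <- moving - mean(moving)
  er <- sqrt(sum(r^2)); em <- sqrt(sum(m^2))
  if (er == 0 || em == 0) stop("flat (zero-variance) input")
  Fr <- stats::fft(r); Fm <- stats::fft(m)
  CC <- Fm * Conj(Fr)   # peak at +s when moving = reference shifted by s
  np <- length(r)
  cc <- Re(stats::fft(CC, inverse = TRUE)) / np
  pk <- which.max(cc)
  pr <- (pk - 1) %% nrow(r) + 1
  pc <- (pk - 1) %/% nrow(r) + 1
  sz <- pr - 1; if (sz > nrow(r) / 2) sz <- sz - nrow(r)
  sy <- pc - 1; if (sy > ncol(r) / 2) sy <- sy - ncol(r)
  score <- cc[pk] / (er * em)
  if (upsample > 1) {
    fz <- fftFreq(nrow(r))
    fy <- fftFreq(ncol(r))
    halfSpan <- ceiling(0.75 * upsample) / upsample
    gz <- sz + seq(-halfSpan, halfSpan, by = 1 / upsample)
    gy <- sy + seq(-halfSpan, halfSpan, by = 1 / upsample)
    Ez <- exp(1i * 2 * pi * outer(gz, fz))       # rows: candidate sz
    Ey <- exp(1i * 2 * pi * outer(gy, fy))
    up <- Re(Ez %*% CC %*% t(Ey)) / np
    pk2 <- which(up == max(up), arr.ind = TRUE)[1, ]
    sz <- gz[pk2[1]]; sy <- gy[pk2[2]]
    score <- max(up) / (er * em)
  }
  structure(list(dy = sy, dz = sz, scale = 1, score = score,
                 upsample = upsample),
            class = "RegistrationTransform")
}

#' @export
print.RegistrationTransform <- function(x, ...) {
  cat(sprintf("RegistrationTransform: dy = %.3f, dz = %.3f px, scale = %g, score = %.4f\n",
              x$dy, x$dz, x$scale, x$score))
  invisible(x)
}

#' Convert filament segment endpoints from image pixels to physical nm
#'
#' Image pixel (column y, row z) coordinates are mapped to the centred
#' physical frame shared by phantoms and scan grids:
#' \eqn{y_{nm} = (col - (n_c + 1)/2) \cdot dx}.
#'
#' @param fs FilamentSet with pixel coordinates
#' @param pixelSize nm
#' @param dims image dimensions c(rows, cols)
#' @return the FilamentSet with y1..z2 in nm
#' @export
segmentsToPhysical <- function(fs, pixelSize, dims) {
  out <- fs
  out$y1 <- (fs$y1 - (dims[2] + 1) / 2) * pixelSize
  out$y2 <- (fs$y2 - (dims[2] + 1) / 2) * pixelSize
  out$z1 <- (fs$z1 - (dims[1] + 1) / 2) * pixelSize
  out$z2 <- (fs$z2 - (dims[1] + 1) / 2) * pixelSize
  out$length <- fs$length * pixelSize
  out
}

#' Orientation agreement between filaments and SAXS anisotropy
#'
#' For every valid scan point whose step-size square contains at least one
#' filament segment footprint, computes the circular (axial) distance
#' between the length-weighted mean filament orientation and the real-space
#' principal axis \code{thetaReal} of the diffraction anisotropy. Distances
#' lie in [0, 90] degrees and are invariant under adding 180 degrees to any
#' orientation.
#'
#' Segments are sampled at quarter-step spacing; a sample belongs to the
#' scan cell whose square it falls in, so the weight of a segment in a cell
#' approximates its intersection length with that cell.
#'
#' @param fs FilamentSet with coordinates in nm (see
#'   \code{\link{segmentsToPhysical}})
#' @param aniso an \linkS4class{AnisotropyMap}
#' @param positions scan positions data.frame (iy, iz, y, z in nm), as from
#'   \code{scanPositions}
#' @param transform optional \code{RegistrationTransform}-like list with
#'   \code{dy}, \code{dz} in nm and \code{scale}, applied to the filament
#'   coordinates before matching
#' @return list: \code{points} (data.frame iy, iz, dTheta, meanOrientation,
#'   thetaReal, nSegments, mass), \code{medianDTheta}, \code{fracBelow20},
#'   \code{n}
#' @export
orientationAgreement <- function(fs, aniso, positions, transform = NULL) {
  stopifnot(methods::is(aniso, "AnisotropyMap"))
  empty <- list(points = data.frame(), medianDTheta = NA_real_,
                fracBelow20 = NA_real_, n = 0L)
  if (nrow(fs) == 0) return(empty)
  sc <- if (is.null(transform)) 1 else transform$scale
  dy <- if (is.null(transform)) 0 else transform$dy
  dz <- if (is.null(transform)) 0 else transform$dz
  stepY <- aniso@stepY; stepZ <- aniso@stepZ
  ds <- min(stepY, stepZ) / 4

  cellKey <- integer(0); segId <- integer(0); w <- numeric(0); th <- numeric(0)
  nyc <- max(positions$iy); nzr <- max(positions$iz)
  y0 <- min(positions$y); z0 <- min(positions$z)
  for (i in seq_len(nrow(fs))) {
    y1 <- sc * fs$y1[i] + dy; y2 <- sc * fs$y2[i] + dy
    z1 <- sc * fs$z1[i] + dz; z2 <- sc * fs$z2[i] + dz
    L <- sqrt((y2 - y1)^2 + (z2 - z1)^2)
    nS <- max(2L, ceiling(L / ds) + 1L)
    t <- seq(0, 1, length.out = nS)
    ys <- y1 + t * (y2 - y1); zs <- z1 + t * (z2 - z1)
    iy <- round((ys - y0) / stepY) + 1L
    iz <- round((zs - z0) / stepZ) + 1L
    ok <- iy >= 1L & iy <= nyc & iz >= 1L & iz <= nzr
    if (!any(ok)) next
    key <- (iy[ok] - 1L) * nzr + iz[ok]
    cellKey <- c(cellKey, key)
    segId <- c(segId, rep(i, sum(ok)))
    w <- c(w, rep(L / (nS - 1), sum(ok)))
    th <- c(th, rep(fs$orientation[i], sum(ok)))
  }
  if (!length(cellKey)) return(empty)

  a2 <- 2 * th * pi / 180
  keyF <- factor(cellKey)
  mass <- tapply(w, keyF, sum)
  c2 <- tapply(w * cos(a2), keyF, sum)
  s2 <- tapply(w * sin(a2), keyF, sum)
  nSeg <- tapply(paste(cellKey, segId), keyF,
                 function(v) length(unique(v)))
  keys <- as.integer(levels(keyF))
  iz <- (keys - 1L) %% nzr + 1L
  iy <- (keys - 1L) %/% nzr + 1L
  meanOri <- (atan2(as.numeric(s2), as.numeric(c2)) / 2 * 180 / pi) %% 180

  validHere <- aniso@valid[cbind(iz, iy)]
  thReal <- aniso@thetaReal[cbind(iz, iy)]
  keep <- validHere & is.finite(thReal)
  pts <- data.frame(iy = iy[keep], iz = iz[keep],
                    dTheta = axialDistance(meanOri[keep], thReal[keep]),
                    meanOrientation = meanOri[keep],
                    thetaReal = thReal[keep],
                    nSegments = as.integer(nSeg)[keep],
                    mass = as.numeric(mass)[keep])
  list(points = pts,
       medianDTheta = if (nrow(pts)) stats::median(pts$dTheta) else NA_real_,
       fracBelow20 = if (nrow(pts)) mean(pts$dTheta < 20) else NA_real_,
       n = nrow(pts))
}
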