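## Scanning-SAXS processing: q calibration, masking, background subtraction,
## dark field, PCA anisotropy, thresholding, azimuthal profiles.

#' Per-pixel momentum transfer map of a detector frame
#'
#' \eqn{|q| = (4\pi/\lambda) \sin(\arctan(r/D)/2)} at radial detector
#' distance r, with components along the detector (y = column, z = row) axes.
#'
#' @param cal a \linkS4class{QCalibration}
#' @param dim frame dimensions c(rows, cols)
#' @return list with matrices \code{qy}, \code{qz}, \code{q} in nm^-1
#' @export
qMap <- function(cal, dim) {
  stopifnot(methods::is(cal, "QCalibration"))
  if (cal@distance <= 0) stop("zero detector distance")
  nr <- dim[1]; nc <- dim[2]
  pxNm <- cal@pixelSize * 1e3          # um -> nm
  dNm <- cal@distance * 1e6            # mm -> nm
  ry <- matrix((seq_len(nc) - cal@beamCenter[2]) * pxNm, nr, nc, byrow = TRUE)
  rz <- matrix((seq_len(nr) - cal@beamCenter[1]) * pxNm, nr, nc)
  r <- sqrt(ry^2 + rz^2)
  q <- 4 * pi / cal@wavelength * sin(atan(r / dNm) / 2)
  frac <- ifelse(r > 0, q / r, 0)
  list(qy = ry * frac, qz = rz * frac, q = q)
}

#' Compose a detector validity mask
#'
#' Conjunction of exclusions: a centred beamstop disc, horizontal
#' inter-module gap stripes, and individual bad pixels. TRUE marks valid
#' pixels.
#'
#' @param dim frame dimensions c(rows, cols)
#' @param beamstop NULL or list(center = c(row, col), radius = pixels)
#' @param gaps NULL or list of integer vectors c(firstRow, lastRow)
#' @param badPixels NULL or two-column matrix of (row, col) indices
#' @return logical matrix with attribute \code{validCount}
#' @export
composeMask <- function(dim, beamstop = NULL, gaps = NULL, badPixels = NULL) {
  nr <- dim[1]; nc <- dim[2]
  mask <- matrix(TRUE, nr, nc)
  if (!is.null(beamstop)) {
    ctr <- beamstop$center
    if (is.null(ctr)) ctr <- c((nr + 1) / 2, (nc + 1) / 2)
    rad <- beamstop$radius
    if (is.null(rad)) rad <- 20
    if (ctr[1] < 1 || ctr[1] > nr || ctr[2] < 1 || ctr[2] > nc)
      stop("beamstop centre outside the frame")
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    mask[(rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2] <- FALSE
  }
  if (!is.null(gaps)) {
    for (g in gaps) {
      if (g[1] < 1 || g[2] > nr || g[1] > g[2])
        stop("gap stripe outside the frame")
      mask[g[1]:g[2], ] <- FALSE
    }
  }
  if (!is.null(badPixels)) {
    bp <- as.matrix(badPixels)
    if (any(bp[, 1] < 1 | bp[, 1] > nr | bp[, 2] < 1 | bp[, 2] > nc))
      stop("bad pixel outside the frame")
    mask[bp] <- FALSE
  }
  attr(mask, "validCount") <- sum(mask)
  mask
}

#' Subtract the mean background frame, clipped at zero
#'
#' @param frame counts matrix
#' @param backgrounds a matrix, a list of matrices, or a 3D array of
#'   background frames (same shape and exposure normalization as
#'   \code{frame})
#' @return corrected non-negative frame
#' @export
subtractBackground <- function(frame, backgrounds) {
  if (is.matrix(backgrounds)) backgrounds <- list(backgrounds)
  if (is.array(backgrounds) && length(dim(backgrounds)) == 3L)
    backgrounds <- lapply(seq_len(dim(backgrounds)[3]),
                          function(k) backgrounds[, , k])
  if (!length(backgrounds)) stop("at least one background frame is required")
  for (b in backgrounds)
    if (!all(dim(b) == dim(frame)))
      stop("background frame shape must match the frame")
  meanBg <- Reduce(`+`, backgrounds) / length(backgrounds)
  pmax(frame - meanBg, 0)
}

#' X-ray dark-field map: masked sum of each diffraction frame
#'
#' The dark-field value of a scan point is the exact sum of photon counts
#' over valid detector pixels of its frame (in photons; divide by the
#' exposure for photons/s).
#'
#' @param stack a \linkS4class{ScanStack}
#' @param mask optional logical matrix; defaults to the stack's own mask
#' @return a \linkS4class{DarkFieldMap} with values[z index, y index]
#' @export
darkField <- function(stack, mask = NULL) {
  stopifnot(methods::is(stack, "ScanStack"))
  if (is.null(mask)) mask <- stack@mask
  if (!all(dim(mask) == dim(stack@frames)[1:2]))
    stop("mask shape must match the frames")
  pos <- stack@positions
  vals <- matrix(NA_real_, max(pos$iz), max(pos$iy))
  for (k in seq_len(nrow(pos))) {
    f <- stack@frames[, , k]
    vals[pos$iz[k], pos$iy[k]] <- sum(f[mask])
  }
  methods::new("DarkFieldMap", values = vals, exposure = stack@exposure,
               stepY = stack@stepY, stepZ = stack@stepZ)
}

#' PCA anisotropy of a single diffraction frame
#'
#' Intensity-weighted second moments of the momentum transfer about q = 0
#' (diffraction patterns are Friedel-symmetric, so the centroid vanishes):
#' \deqn{C = \sum w \, (q_y, q_z)^T (q_y, q_z) / \sum w}
#' with weights w equal to the masked (optionally background-subtracted,
#' non-negative) counts. Eigen-decomposition gives the principal variances
#' \eqn{\lambda_1 \ge \lambda_2}, the degree of anisotropy
#' \eqn{\omega = (\lambda_1 - \lambda_2)/(\lambda_1 + \lambda_2)}, the
#' reciprocal-space orientation of the major axis, and the real-space long
#' axis \code{thetaReal = (thetaRecip + 90) mod 180}.
#'
#' @param frame counts matrix
#' @param mask logical matrix, TRUE = valid
#' @param qmap output of \code{\link{qMap}} for this frame shape
#' @param qRange optional c(qmin, qmax) annulus restriction in nm^-1
#'   (default c(0, 0.8), the data extent of the emulated detector)
#' @return list: \code{omega}, \code{thetaRecip}, \code{thetaReal} (degrees
#'   in [0,180), NA when the pattern is isotropic), \code{lambda1},
#'   \code{lambda2}, \code{valid} (FALSE when no weight survives the mask),
#'   \code{thetaDefined}
#' @export
pcaAnisotropy <- function(frame, mask, qmap, qRange = c(0, 0.8)) {
  w <- frame
  sel <- mask & qmap$q > 0 & qmap$q >= qRange[1] & qmap$q <= qRange[2]
  w[!sel] <- 0
  w[w < 0] <- 0
  W <- sum(w)
  if (W <= 0)
    return(list(omega = NA_real_, thetaRecip = NA_real_,
                thetaReal = NA_real_, lambda1 = NA_real_,
                lambda2 = NA_real_, valid = FALSE, thetaDefined = FALSE))
  syy <- sum(w * qmap$qy^2) / W
  szz <- sum(w * qmap$qz^2) / W
  syz <- sum(w * qmap$qy * qmap$qz) / W
  e <- eigen(matrix(c(syy, syz, syz, szz), 2, 2), symmetric = TRUE)
  l1 <- e$values[1]; l2 <- max(e$values[2], 0)
  omega <- if (l1 + l2 > 0) (l1 - l2) / (l1 + l2) else 0
  thetaDefined <- (l1 - l2) > 1e-12 * max(l1 + l2, .Machine$double.xmin)
  if (thetaDefined) {
    v <- e$vectors[, 1]
    thR <- (atan2(v[2], v[1]) * 180 / pi) %% 180
    thReal <- (thR + 90) %% 180
  } else {
    thR <- NA_real_; thReal <- NA_real_
  }
  list(omega = omega, thetaRecip = thR, thetaReal = thReal,
       lambda1 = l1, lambda2 = l2, valid = TRUE, thetaDefined = thetaDefined)
}

#' PCA anisotropy over a whole scan
#'
#' Applies \code{\link{pcaAnisotropy}} to every frame of a scan, with
#' optional background subtraction and dark-field thresholding: scan points
#' whose dark-field signal (photons/s) does not exceed
#' \code{darkfieldThreshold} are flagged invalid, limiting the analysis to
#' the cell.
#'
#' @param stack a \linkS4class{ScanStack}
#' @param mask optional detector mask (defaults to the stack's)
#' @param qRange annulus restriction in nm^-1
#' @param darkfieldThreshold photons/s; default 7.5e5
#' @param backgrounds optional background frames for
#'   \code{\link{subtractBackground}}
#' @return an \linkS4class{AnisotropyMap}
#' @export
anisotropyMap <- function(stack, mask = NULL, qRange = c(0, 0.8),
                          darkfieldThreshold = 7.5e5, backgrounds = NULL) {
  stopifnot(methods::is(stack, "ScanStack"))
  if (is.null(mask)) mask <- stack@mask
  qm <- qMap(stack@qcal, dim(stack@frames)[1:2])
  pos <- stack@positions
  nzr <- max(pos$iz); nyc <- max(pos$iy)
  mk <- function() matrix(NA_real_, nzr, nyc)
  omega <- mk(); thR <- mk(); thRe <- mk(); l1 <- mk(); l2 <- mk()
  valid <- matrix(FALSE, nzr, nyc)
  df <- darkField(stack, mask)
  thr <- if (is.null(darkfieldThreshold)) -Inf else darkfieldThreshold
  for (k in seq_len(nrow(pos))) {
    f <- stack@frames[, , k]
    if (!is.null(backgrounds)) f <- subtractBackground(f, backgrounds)
    r <- pcaAnisotropy(f, mask, qm, qRange)
    i <- pos$iz[k]; j <- pos$iy[k]
    omega[i, j] <- r$omega; thR[i, j] <- r$thetaRecip
    thRe[i, j] <- r$thetaReal; l1[i, j] <- r$lambda1; l2[i, j] <- r$lambda2
    valid[i, j] <- isTRUE(r$valid) && isTRUE(r$thetaDefined) &&
      (df@values[i, j] / stack@exposure > thr)
  }
  methods::new("AnisotropyMap", omega = omega, thetaRecip = thR,
               thetaReal = thRe, lambda1 = l1, lambda2 = l2, valid = valid,
               stepY = stack@stepY, stepZ = stack@stepZ)
}

#' Dark-field threshold mask over the scan grid
#'
#' A scan point is valid iff its dark-field rate exceeds the threshold; the
#' default threshold is 7.5e5 photons/s, which restricts the analysis to the
#' cell and excludes empty background positions.
#'
#' @param df a \linkS4class{DarkFieldMap}
#' @param threshold photons per second
#' @return logical matrix over the scan grid
#' @export
thresholdMap <- function(df, threshold = 7.5e5) {
  stopifnot(methods::is(df, "DarkFieldMap"))
  df@values / df@exposure > threshold
}

#' Azimuthally averaged 1D intensity profile I(|q|)
#'
#' Mean counts per |q| annulus over valid pixels; empty bins are NA.
#'
#' @param frame counts matrix
#' @param mask logical matrix
#' @param qmap output of \code{\link{qMap}}
#' @param nBins number of radial bins (>= 2)
#' @param qRange optional c(qmin, qmax); defaults to the frame's q extent
#' @return data.frame with columns q (bin centre), intensity, n (pixels)
#' @export
azimuthalAverage <- function(frame, mask, qmap, nBins = 50, qRange = NULL) {
  if (nBins < 2) stop("'nBins' must be at least 2")
  q <- qmap$q[mask]
  v <- frame[mask]
  if (is.null(qRange)) qRange <- c(0, max(q))
  edges <- seq(qRange[1], qRange[2], length.out = nBins + 1)
  idx <- findInterval(q, edges, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= nBins
  sums <- tapply(v[keep], factor(idx[keep], levels = seq_len(nBins)), sum)
  cnts <- tapply(rep(1, sum(keep)), factor(idx[keep], levels = seq_len(nBins)),
                 sum)
  cnts[is.na(cnts)] <- 0
  out <- data.frame(q = (edges[-1] + edges[-(nBins + 1)]) / 2,
                    intensity = as.numeric(sums) / ifelse(cnts > 0, cnts, NA),
                    n = as.numeric(cnts))
  out
}
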