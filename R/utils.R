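## Internal numerical helpers shared across modules.
##
## Coordinate convention used throughout the package: images are matrices in
## row-major display order with origin at the top-left; columns are the
## horizontal y axis, rows the vertical z axis. Orientations are in degrees in
## [0, 180), measured from the +y (column) axis.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded simulation calls do
#' not perturb the caller's RNG stream. With \code{seed = NULL} the expression
#' runs on the ambient stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  expr
}

#' FFT sample frequencies (cycles per unit), matching stats::fft ordering
#' @noRd
fftFreq <- function(n, d = 1) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

#' Shift zero frequency to the centre of a matrix (and its inverse)
#' @noRd
fftShift <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(seq.int(floor(nr / 2) + 1L, nr), seq_len(floor(nr / 2))),
    c(seq.int(floor(nc / 2) + 1L, nc), seq_len(floor(nc / 2))), drop = FALSE]
}

#' @noRd
ifftShift <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(seq.int(ceiling(nr / 2) + 1L, nr), seq_len(ceiling(nr / 2))),
    c(seq.int(ceiling(nc / 2) + 1L, nc), seq_len(ceiling(nc / 2))), drop = FALSE]
}

#' Squared-frequency grid |nu|^2 for an nr x nc image with pixel size d
#' @noRd
freqSqGrid <- function(nr, nc, d) {
  fy <- fftFreq(nc, d)  # columns = y
  fz <- fftFreq(nr, d)  # rows    = z
  outer(fz^2, fy^2, `+`)
}

#' Gaussian FWHM to standard deviation
#' @noRd
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Axial (180-degree periodic) circular mean of orientations in degrees
#'
#' Orientations are doubled, averaged as unit vectors, and halved back.
#' Weights default to 1. Returns a value in [0, 180).
#' @noRd
axialMean <- function(theta, w = NULL) {
  if (length(theta) == 0L) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(theta))
  a <- 2 * theta * pi / 180
  m <- atan2(sum(w * sin(a)), sum(w * cos(a))) / 2 * 180 / pi
  m %% 180
}

#' Axial circular standard deviation in degrees
#' @noRd
axialSD <- function(theta) {
  a <- 2 * theta * pi / 180
  R <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  R <- min(max(R, .Machine$double.eps), 1)
  sqrt(-2 * log(R)) / 2 * 180 / pi
}

#' Axial circular distance between two orientations, result in [0, 90]
#' @noRd
axialDistance <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Physical pixel-centre coordinates (nm) of an n-pixel axis centred on zero
#' @noRd
axisCoords <- function(n, pixelSize) (seq_len(n) - (n + 1) / 2) * pixelSize

#' Normalized 2D Gaussian blur that tolerates sigma = 0
#' @noRd
blur2 <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::gblur(m, sigma = sigma)
}

#' Matrix of per-pixel distances to a line segment (vectorized)
#'
#' yy, zz are coordinate matrices; the segment runs (y1,z1)-(y2,z2).
#' @noRd
segmentDistance <- function(yy, zz, y1, z1, y2, z2) {
  dy <- y2 - y1; dz <- z2 - z1
  L2 <- dy * dy + dz * dz
  if (L2 == 0) return(sqrt((yy - y1)^2 + (zz - z1)^2))
  t <- ((yy - y1) * dy + (zz - z1) * dz) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((yy - (y1 + t * dy))^2 + (zz - (z1 + t * dz))^2)
}

#' Stop unless all values are strictly positive
#' @noRd
checkPositive <- function(...) {
  vals <- list(...)
  nm <- names(vals)
  for (i in seq_along(vals)) {
    if (!is.numeric(vals[[i]]) || any(!is.finite(vals[[i]])) || any(vals[[i]] <= 0))
      stop(sprintf("'%s' must be strictly positive and finite", nm[i]), call. = FALSE)
  }
  invisible(TRUE)
}

#' 8-connected component labeling of a logical matrix
#'
#' Breadth-first labeling over the 8-neighbourhood; returns an integer
#' matrix (0 = background). Suited to sparse masks such as skeletons.
#' @noRd
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  inMask <- logical(nr * nc)
  inMask[idx] <- TRUE
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  cur <- 0L
  for (p in idx) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p
    lab[p] <- cur
    while (length(queue)) {
      q <- queue[[1]]
      queue <- queue[-1]
      r <- (q - 1L) %% nr + 1L
      nbr <- q + offs
      keep <- rep(TRUE, 8L)
      if (r == 1L) keep[c(1L, 5L, 7L)] <- FALSE
      if (r == nr) keep[c(2L, 6L, 8L)] <- FALSE
      nbr <- nbr[keep]
      nbr <- nbr[nbr >= 1L & nbr <= nr * nc]
      nbr <- nbr[inMask[nbr] & lab[nbr] == 0L]
      lab[nbr] <- cur
      queue <- c(queue, nbr)
    }
  }
  lab
}
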