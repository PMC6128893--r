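## Filament tracing: oriented line-filter bank, quantile threshold,
## skeletonization, junction cutting, straight-segment fitting. A simplified,
## phantom-validated tracer for line-like structures in STED / phase images.

# shift a matrix by (dr, dc) with zero padding
.shiftPad <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Zhang-Suen binary thinning (skeletonization)
#'
#' Iteratively peels boundary pixels while preserving connectivity, until no
#' pixel changes. Used to reduce thresholded ridge responses to 1-px-wide
#' skeletons.
#'
#' @param mask logical matrix
#' @return logical matrix of the skeleton
#' @export
thinSkeleton <- function(mask) {
  m <- mask * 1
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours P2..P9: N, NE, E, SE, S, SW, W, NW (row -1 is up)
      p2 <- .shiftPad(m, 1, 0);  p3 <- .shiftPad(m, 1, -1)
      p4 <- .shiftPad(m, 0, -1); p5 <- .shiftPad(m, -1, -1)
      p6 <- .shiftPad(m, -1, 0); p7 <- .shiftPad(m, -1, 1)
      p8 <- .shiftPad(m, 0, 1);  p9 <- .shiftPad(m, 1, 1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m > 0
}

# oriented zero-mean line kernel: length L along thetaDeg, Gaussian profile
# (sigma 1 px) across the line
.lineKernel <- function(L, thetaDeg) {
  k <- 2L * ceiling(L / 2) + 1L
  off <- seq_len(k) - (k + 1) / 2
  dc <- matrix(off, k, k, byrow = TRUE)   # y (columns)
  dr <- matrix(off, k, k)                 # z (rows)
  th <- thetaDeg * pi / 180
  uPar <- dc * cos(th) + dr * sin(th)
  uPerp <- -dc * sin(th) + dr * cos(th)
  kern <- exp(-uPerp^2 / 2) * (abs(uPar) <= L / 2)
  kern - mean(kern)
}

#' Trace line-like structures in an image
#'
#' A bank of \code{nOrientations} oriented line filters (evenly spaced over
#' [0, 180) degrees) is applied to the smoothed image; the pixelwise maximum
#' response is thresholded at a quantile, skeletonized, cut at junction
#' pixels (more than two skeleton neighbours), and each remaining connected
#' component of at least \code{minSegment} px extent is fitted with a
#' straight segment via the principal axis of its pixel coordinates.
#'
#' Because the threshold is a quantile of the response, detection is
#' invariant under global intensity scaling. An empty detection returns an
#' empty set, not an error.
#'
#' @param image matrix, \linkS4class{FluorescenceImage} (counts), or
#'   \linkS4class{PhaseMap} (sign-flipped so filaments are bright)
#' @param smoothing Gaussian pre-smoothing sigma, px
#' @param nOrientations number of filter orientations
#' @param lineLength filter line length, px
#' @param threshold response quantile in (0, 1) above which pixels are kept
#' @param minSegment minimum segment length, px
#' @return a data.frame of class \code{FilamentSet}: columns y1, z1, y2, z2
#'   (endpoints, image pixel coordinates: y = column, z = row), orientation
#'   (degrees in [0, 180), consistent with the endpoints), length (px),
#'   strength (mean ridge response)
#' @export
traceFilaments <- function(image, smoothing = 1.5, nOrientations = 12,
                           lineLength = 15, threshold = 0.95,
                           minSegment = 10) {
  if (methods::is(image, "FluorescenceImage")) image <- image@counts
  else if (methods::is(image, "PhaseMap")) image <- -image@phase
  if (!is.matrix(image)) stop("'image' must be a matrix or a known class")
  if (nrow(image) < 64 || ncol(image) < 64)
    stop("image must be at least 64 x 64")
  emptySet <- function() {
    out <- data.frame(y1 = numeric(0), z1 = numeric(0), y2 = numeric(0),
                      z2 = numeric(0), orientation = numeric(0),
                      length = numeric(0), strength = numeric(0))
    class(out) <- c("FilamentSet", "data.frame")
    out
  }
  mx <- max(image)
  if (mx <= min(image)) return(emptySet())
  img <- blur2(image / mx, smoothing)
  thetas <- seq(0, 180, length.out = nOrientations + 1)[seq_len(nOrientations)]
  resp <- matrix(-Inf, nrow(img), ncol(img))
  for (th in thetas) {
    r <- EBImage::filter2(img, .lineKernel(lineLength, th))
    resp <- pmax(resp, r)
  }
  thr <- stats::quantile(resp, threshold)
  bin <- resp > max(thr, 0)
  if (!any(bin)) return(emptySet())
  skel <- thinSkeleton(bin)
  # branch points by crossing number: >= 3 transitions 0->1 around the
  # 8-neighbourhood (robust against diagonal staircase pixels)
  sk <- skel * 1
  p2 <- .shiftPad(sk, 1, 0);  p3 <- .shiftPad(sk, 1, -1)
  p4 <- .shiftPad(sk, 0, -1); p5 <- .shiftPad(sk, -1, -1)
  p6 <- .shiftPad(sk, -1, 0); p7 <- .shiftPad(sk, -1, 1)
  p8 <- .shiftPad(sk, 0, 1);  p9 <- .shiftPad(sk, 1, 1)
  crossings <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
    (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) +
    (p7 == 0 & p8 == 1) + (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  junction <- skel & crossings >= 3
  if (any(junction)) {
    # remove the junction neighbourhood: under 8-connectivity the arms stay
    # bridged diagonally if only the centre pixel is dropped
    junction <- EBImage::dilate(junction * 1,
                                EBImage::makeBrush(3, "box")) > 0.5
    skel[junction] <- FALSE
  }
  if (!any(skel)) return(emptySet())
  lab <- label8(skel)
  segs <- emptySet()
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < 3) next
    z <- idx[, 1]; y <- idx[, 2]
    cy <- mean(y); cz <- mean(z)
    covM <- stats::cov(cbind(y, z))
    e <- eigen(covM, symmetric = TRUE)
    v <- e$vectors[, 1]
    t <- (y - cy) * v[1] + (z - cz) * v[2]
    len <- diff(range(t))
    if (len < minSegment) next
    p1 <- c(cy, cz) + min(t) * v
    p2 <- c(cy, cz) + max(t) * v
    ori <- (atan2(p2[2] - p1[2], p2[1] - p1[1]) * 180 / pi) %% 180
    segs <- rbind(segs, data.frame(y1 = p1[1], z1 = p1[2], y2 = p2[1],
                                   z2 = p2[2], orientation = ori,
                                   length = len,
                                   strength = mean(resp[lab == l])))
  }
  class(segs) <- c("FilamentSet", "data.frame")
  attr(segs, "params") <- list(smoothing = smoothing,
                               nOrientations = nOrientations,
                               lineLength = lineLength, threshold = threshold,
                               minSegment = minSegment)
  segs
}

#' Circular orientation histogram of a filament set
#'
#' Bins segment orientations over [0, 180) with mass equal to segment length
#' (default) or count; total mass is conserved exactly.
#'
#' @param fs a FilamentSet data.frame (or any data.frame with columns
#'   \code{orientation} and \code{length})
#' @param binWidth degrees; must divide 180
#' @param weight "length" or "count"
#' @return data.frame: binStart, binMid, mass
#' @export
orientationHistogram <- function(fs, binWidth = 10,
                                 weight = c("length", "count")) {
  weight <- match.arg(weight)
  if (180 %% binWidth != 0) stop("'binWidth' must divide 180")
  nb <- 180 %/% binWidth
  starts <- (seq_len(nb) - 1) * binWidth
  idx <- floor((fs$orientation %% 180) / binWidth) + 1
  w <- if (weight == "length") fs$length else rep(1, nrow(fs))
  mass <- vapply(seq_len(nb), function(b) sum(w[idx == b]), numeric(1))
  data.frame(binStart = starts, binMid = starts + binWidth / 2, mass = mass)
}
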