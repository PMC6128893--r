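## Power-spectral-density curves and noise-floor cross-over resolution
## estimation, plus the fluorescence diffraction-limit calculator.

#' Azimuthally averaged power spectral density of an image
#'
#' The image is mean-subtracted, optionally apodized with a periodic Hann
#' window, Fourier transformed, and the squared modulus (normalized by the
#' pixel count, so that the unwindowed 2D total equals variance times pixel
#' count by Parseval) is averaged over annuli of radial spatial frequency.
#' Frequencies are reported as a scattering-vector equivalent
#' \eqn{q = 2\pi\nu} so that curves from different modalities are directly
#' comparable.
#'
#' @param image matrix, \linkS4class{FluorescenceImage}, or
#'   \linkS4class{PhaseMap}
#' @param pixelSize nm; taken from the object when available
#' @param window "hann" (default; reduces spectral leakage) or "none"
#' @param nBins number of radial bins (default: half the smaller dimension)
#' @return data.frame (q in nm^-1, psd, n) with attributes
#'   \code{totalPower} (unbinned 2D sum), \code{pixelSize}, \code{window}
#' @export
powerSpectralDensity <- function(image, pixelSize = NULL,
                                 window = c("hann", "none"), nBins = NULL) {
  window <- match.arg(window)
  if (methods::is(image, "FluorescenceImage")) {
    if (is.null(pixelSize)) pixelSize <- image@pixelSize
    image <- image@counts
  } else if (methods::is(image, "PhaseMap")) {
    if (is.null(pixelSize)) pixelSize <- image@pixelSize
    image <- image@phase
  }
  if (is.null(pixelSize)) stop("'pixelSize' is required for a plain matrix")
  checkPositive(pixelSize = pixelSize)
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 16 || nc < 16) stop("image must be at least 16 x 16")
  x <- image - mean(image)
  if (window == "hann") {
    hr <- 0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / nr))
    hc <- 0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / nc))
    x <- x * outer(hr, hc)
  }
  psd2 <- Mod(stats::fft(x))^2 / (nr * nc)
  fy <- fftFreq(nc, pixelSize)
  fz <- fftFreq(nr, pixelSize)
  nu <- sqrt(outer(fz^2, fy^2, `+`))
  if (is.null(nBins)) nBins <- floor(min(nr, nc) / 2)
  nuMax <- 1 / (2 * pixelSize)
  edges <- seq(0, nuMax, length.out = nBins + 1)
  idx <- findInterval(nu, edges, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= nBins & nu > 0
  fct <- factor(idx[keep], levels = seq_len(nBins))
  sums <- tapply(psd2[keep], fct, sum)
  cnts <- tapply(rep(1, sum(keep)), fct, sum)
  cnts[is.na(cnts)] <- 0
  out <- data.frame(q = 2 * pi * (edges[-1] + edges[-(nBins + 1)]) / 2,
                    psd = as.numeric(sums) / ifelse(cnts > 0, cnts, NA),
                    n = as.numeric(cnts))
  attr(out, "totalPower") <- sum(psd2)
  attr(out, "pixelSize") <- pixelSize
  attr(out, "window") <- window
  out
}

#' Fit a power-law signal plus constant noise floor to a PSD curve
#'
#' Models the curve as \eqn{I(q_r) = a q_r^b + bgr}: the constant noise
#' floor \code{bgr} is the mean PSD over \code{noiseRange} (high q), the
#' decaying signal \eqn{a q^b} is fitted by least squares on
#' \eqn{\log(I - bgr)} vs \eqn{\log q} over \code{signalRange}. The
#' cross-over to the noise floor solves \eqn{a q_i^b = bgr}, i.e.
#' \eqn{q_i = (bgr/a)^{1/b}}, and the critical (smallest trustworthy)
#' structure size is \eqn{d_{cr} = \pi/q_i}.
#'
#' @param psd data.frame from \code{\link{powerSpectralDensity}} (columns q,
#'   psd) or any data.frame with those columns
#' @param signalRange c(qlo, qhi) of the decaying signal, nm^-1
#' @param noiseRange c(qlo, qhi) of the flat noise floor, nm^-1;
#'   non-overlapping with \code{signalRange}, each covering >= 5 points
#' @return an object of class \code{PowerLawFit}: list(a, b, bgr, qi, dcr,
#'   signalRange, noiseRange, ok). \code{ok} is FALSE (and qi, dcr are NA)
#'   when no decaying signal is found (b >= 0).
#' @export
fitPowerLaw <- function(psd, signalRange, noiseRange) {
  stopifnot(all(c("q", "psd") %in% names(psd)))
  if (signalRange[1] <= noiseRange[2] && noiseRange[1] <= signalRange[2])
    stop("signalRange and noiseRange must not overlap")
  inSig <- psd$q >= signalRange[1] & psd$q <= signalRange[2] &
    is.finite(psd$psd)
  inNoi <- psd$q >= noiseRange[1] & psd$q <= noiseRange[2] &
    is.finite(psd$psd)
  if (sum(inSig) < 5) stop("signalRange must cover at least 5 points")
  if (sum(inNoi) < 5) stop("noiseRange must cover at least 5 points")
  bgr <- mean(psd$psd[inNoi])
  qs <- psd$q[inSig]
  ys <- psd$psd[inSig] - bgr
  pos <- ys > 0 & qs > 0
  ok <- sum(pos) >= 5
  a <- b <- qi <- dcr <- NA_real_
  if (ok) {
    fit <- stats::lm(log(ys[pos]) ~ log(qs[pos]))
    b <- unname(stats::coef(fit)[2])
    a <- exp(unname(stats::coef(fit)[1]))
    ok <- is.finite(b) && b < 0
    if (ok) {
      qi <- (bgr / a)^(1 / b)
      dcr <- pi / qi
    }
  }
  structure(list(a = a, b = b, bgr = bgr, qi = qi, dcr = dcr,
                 signalRange = signalRange, noiseRange = noiseRange, ok = ok),
            class = "PowerLawFit")
}

#' @export
print.PowerLawFit <- function(x, ...) {
  if (x$ok)
    cat(sprintf(
      "PowerLawFit: I(q) = %.4g * q^%.3f + %.4g ; q_i = %.4g, d_cr = %.4g\n",
      x$a, x$b, x$bgr, x$qi, x$dcr))
  else cat("PowerLawFit: no decaying signal found (flagged)\n")
  invisible(x)
}

#' Abbe diffraction limit of a fluorescence microscope
#'
#' \eqn{d_{min} = \lambda_{fl} / (2\,\mathrm{NA})}.
#'
#' @param lambdaFl emission wavelength, nm
#' @param na numerical aperture, in (0, 1.7]
#' @return smallest resolvable structure size, nm
#' @examples
#' diffractionLimit(651, 0.95)   # ~343 nm
#' @export
diffractionLimit <- function(lambdaFl, na) {
  checkPositive(lambdaFl = lambdaFl, na = na)
  if (na > 1.7) stop("'na' must be at most 1.7")
  lambdaFl / (2 * na)
}
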