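## Phase retrieval: CTF inversion, support estimation, RAAR iteration.

#' CTF (contrast transfer function) phase retrieval
#'
#' Linearized single-step inversion for a weak pure-phase object: with
#' \eqn{\chi(\nu) = \pi \lambda z_{eff} |\nu|^2}, the hologram contrast obeys
#' \eqn{F[I - 1] = 2 \sin\chi \cdot F[\phi]} and the phase estimate is
#' \deqn{\hat\phi(\nu) = F[I-1](\nu) \frac{\sin\chi}{2\sin^2\chi + \alpha(\nu)}}
#' with a two-level Tikhonov term: \code{alphaLow} below the first CTF
#' maximum (\eqn{\chi < \pi/2}) and \code{alphaHigh} above.
#'
#' The DC component of the contrast carries no phase information (energy
#' conservation), so the retrieved phase has an undetermined offset; with
#' \code{zeroBackground = TRUE} the median of the map (the empty background
#' for a compact object) is subtracted.
#'
#' @param holo a \linkS4class{Hologram} (flat-field normalized)
#' @param alphaLow,alphaHigh regularization below/above the first CTF maximum
#' @param zeroBackground subtract the median so empty regions sit at phase 0
#' @return a \linkS4class{PhaseMap} at the effective pixel size
#' @export
ctfPhaseRetrieval <- function(holo, alphaLow = 1e-3, alphaHigh = 1e-1,
                              zeroBackground = TRUE) {
  stopifnot(methods::is(holo, "Hologram"))
  geom <- holo@geometry
  if (geom@effDistance <= 0)
    stop("z_eff = 0: the contact plane carries no phase contrast")
  I <- holo@intensity
  nu2 <- freqSqGrid(nrow(I), ncol(I), geom@effPixelSize)
  chi <- pi * geom@wavelength * geom@effDistance * 1e6 * nu2
  s <- sin(chi)
  alpha <- ifelse(chi < pi / 2, alphaLow, alphaHigh)
  filt <- s / (2 * s^2 + alpha)
  phi <- Re(stats::fft(stats::fft(I - 1) * filt, inverse = TRUE) / length(I))
  if (zeroBackground) phi <- phi - stats::median(phi)
  phaseMap(phi, geom@effPixelSize)
}

#' Estimate the object support from a CTF phase map
#'
#' Smooths the phase map, thresholds at a fraction of its most negative
#' value, keeps the largest connected component, and applies morphological
#' closing plus dilation. Errors if the thresholded support is empty.
#'
#' @param phaseCtf a \linkS4class{PhaseMap} (typically the CTF estimate)
#' @param smoothingFwhm Gaussian smoothing FWHM in pixels
#' @param thresholdFraction fraction of the most negative smoothed phase;
#'   pixels at or below \code{thresholdFraction * min} enter the support
#' @param dilation dilation radius in pixels applied after closing
#' @return a logical support mask matrix
#' @export
estimateSupport <- function(phaseCtf, smoothingFwhm = 6,
                            thresholdFraction = 0.05, dilation = 2) {
  stopifnot(methods::is(phaseCtf, "PhaseMap"))
  phi <- blur2(phaseCtf@phase, fwhmToSigma(smoothingFwhm))
  mn <- min(phi)
  if (mn >= 0) stop("empty support: the phase map has no negative values")
  mask <- phi <= thresholdFraction * mn
  if (!any(mask)) stop("empty support after thresholding")
  lab <- label8(mask)
  tab <- tabulate(lab[lab > 0])
  mask <- lab == which.max(tab)
  brush <- EBImage::makeBrush(5, shape = "disc")
  mask <- EBImage::closing(mask * 1, brush) > 0.5
  # strong objects thin out in the middle of the CTF estimate while keeping a
  # deep rim; filling enclosed holes turns the rim ring into the full support
  mask <- EBImage::fillHull(mask * 1) > 0.5
  if (dilation > 0) {
    b2 <- EBImage::makeBrush(2L * as.integer(dilation) + 1L, shape = "disc")
    mask <- EBImage::dilate(mask * 1, b2) > 0.5
  }
  mask
}

#' Iterative phase retrieval by relaxed averaged alternating reflections
#'
#' Runs the RAAR update
#' \deqn{u \leftarrow \tfrac{\beta}{2}(R_S R_M + I)\,u + (1-\beta) P_M u}
#' on the object-plane field. \eqn{P_M} propagates to the detector, replaces
#' the modulus by the measured \eqn{\sqrt{I}} (magnitude constraint) and
#' propagates back; \eqn{P_S} enforces the sample constraints of a pure phase
#' object: unit modulus everywhere, phase zero outside the support, and
#' (optionally) non-positive phase inside. \eqn{R = 2P - I} are the
#' corresponding reflectors. The iteration is initialized from the CTF
#' estimate unless \code{init} is given.
#'
#' @param holo a \linkS4class{Hologram}
#' @param support logical support mask (nonempty), as from
#'   \code{\link{estimateSupport}}
#' @param beta relaxation parameter (fixed schedule; default 0.99)
#' @param nIter number of iterations (default 500)
#' @param init optional \linkS4class{PhaseMap} initialization
#' @param clipNonpositive enforce phase <= 0 inside the support (default TRUE)
#'
#' @details The residual trace is the relative magnitude residual
#' \eqn{\||D x_k| - \sqrt I\| / \|\sqrt I\|} of the constrained object
#' estimate \eqn{x_k = P_S P_M u_k} (not of the internal relaxed iterate,
#' whose distance from the measurement set grows without bound on noisy,
#' i.e. inconsistent, data even while the estimate converges). On noiseless
#' data it decreases to numerical zero; on noisy data it settles at the
#' noise floor. A residual that stays above ten times its initial value for
#' over 100 consecutive iterations aborts with a diagnostic.
#'
#' @return a list with elements \code{phase} (a \linkS4class{PhaseMap}: the
#'   phase of the final constrained object estimate, zero outside the
#'   support), \code{residuals} (per-iteration relative magnitude residual,
#'   see Details), \code{beta}, \code{nIter}
#' @export
raarReconstruct <- function(holo, support, beta = 0.99, nIter = 500,
                            init = NULL, clipNonpositive = TRUE) {
  stopifnot(methods::is(holo, "Hologram"))
  if (!is.matrix(support) || !any(support)) stop("support must be nonempty")
  if (!all(dim(support) == dim(holo@intensity)))
    stop("support shape must match the hologram")
  geom <- holo@geometry
  sqrtI <- sqrt(holo@intensity)
  normI <- sqrt(sum(sqrtI^2))
  if (is.null(init)) init <- ctfPhaseRetrieval(holo)
  stopifnot(methods::is(init, "PhaseMap"))

  nu2 <- freqSqGrid(nrow(sqrtI), ncol(sqrtI), geom@effPixelSize)
  dNm <- geom@effDistance * 1e6
  if (geom@wavelength * dNm > min(dim(sqrtI)) * geom@effPixelSize^2 * (1 + 1e-12))
    stop("propagator aliased for this grid; see fresnelPropagate")
  H <- exp(-1i * pi * geom@wavelength * dNm * nu2)
  Hb <- Conj(H)
  np <- length(sqrtI)
  prop <- function(u, k) stats::fft(stats::fft(u) * k, inverse = TRUE) / np

  u <- exp(1i * init@phase)
  outside <- !support
  projectSample <- function(v) {
    ph <- Arg(v)
    ph[outside] <- 0
    if (clipNonpositive) ph[ph > 0] <- 0
    ph
  }
  residuals <- numeric(nIter)
  phEst <- NULL
  highStreak <- 0L
  for (it in seq_len(nIter)) {
    Du <- prop(u, H)
    mDu <- Mod(Du)
    ratio <- sqrtI / pmax(mDu, 1e-300)
    PMu <- prop(Du * ratio, Hb)
    # constrained estimate x = P_S(P_M u) and its magnitude residual
    phEst <- projectSample(PMu)
    Dx <- prop(exp(1i * phEst), H)
    residuals[it] <- sqrt(sum((Mod(Dx) - sqrtI)^2)) / normI
    if (!is.finite(residuals[it]))
      stop(sprintf("RAAR diverged at iteration %d (non-finite residual)", it))
    highStreak <- if (it > 1 && residuals[it] > 10 * residuals[1])
      highStreak + 1L else 0L
    if (highStreak > 100L)
      stop(sprintf(paste0("RAAR diverged: residual %.3g stayed above 10x the ",
                          "initial %.3g for over 100 iterations (iteration %d)"),
                   residuals[it], residuals[1], it))
    RMu <- 2 * PMu - u
    RSu <- 2 * exp(1i * projectSample(RMu)) - RMu
    u <- beta * 0.5 * (RSu + u) + (1 - beta) * PMu
  }
  list(phase = phaseMap(phEst, geom@effPixelSize), residuals = residuals,
       beta = beta, nIter = nIter)
}
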