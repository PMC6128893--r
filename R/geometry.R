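## Cone-beam geometry and Fresnel propagation.

# hc in keV*nm: lambda[nm] = 1.239842 / E[keV]
.hc_keV_nm <- 1.239842

#' Effective parallel-beam geometry of a divergent-beam holography setup
#'
#' Computes the derived quantities of the cone-beam recording geometry: the
#' geometrical magnification \eqn{M = (z_1 + z_2)/z_1}, the effective pixel
#' size \eqn{p_{eff} = p/M}, and the effective propagation distance
#' \eqn{z_{eff} = z_1 z_2/(z_1+z_2)} of the equivalent parallel-beam problem
#' (Fresnel scaling theorem). The wavelength follows from
#' \eqn{\lambda = hc/E}.
#'
#' @param z1 focus-to-sample distance, mm
#' @param z2 sample-to-detector distance, mm (0 = contact plane)
#' @param pixelSize detector pixel size, micrometres (default 6.5)
#' @param photonEnergy photon energy, keV (default 13.8)
#' @return an \linkS4class{OpticalGeometry}
#' @examples
#' g <- opticalGeometry(z1 = 10, z2 = 5000)
#' magnification(g)   # 501
#' effPixelSize(g)    # ~12.97 nm
#' @export
opticalGeometry <- function(z1, z2, pixelSize = 6.5, photonEnergy = 13.8) {
  checkPositive(z1 = z1, pixelSize = pixelSize, photonEnergy = photonEnergy)
  if (!is.numeric(z2) || !is.finite(z2) || z2 < 0)
    stop("'z2' must be finite and >= 0")
  lambda <- .hc_keV_nm / photonEnergy
  M <- (z1 + z2) / z1
  methods::new("OpticalGeometry",
    photonEnergy = photonEnergy, wavelength = lambda, z1 = z1, z2 = z2,
    pixelSize = pixelSize, magnification = M,
    effPixelSize = pixelSize * 1e3 / M,           # um -> nm
    effDistance = z1 * z2 / (z1 + z2))
}

#' Per-pixel Fresnel number of a geometry
#'
#' \eqn{F = p_{eff}^2 / (\lambda z_{eff})}: the Fresnel number of one
#' effective pixel over the effective propagation distance. It controls the
#' sampling of the free-space propagator on the reconstruction grid.
#'
#' @param geom an \linkS4class{OpticalGeometry}
#' @return dimensionless Fresnel number
#' @export
fresnelNumber <- function(geom) {
  stopifnot(methods::is(geom, "OpticalGeometry"))
  if (geom@effDistance == 0) return(Inf)
  geom@effPixelSize^2 / (geom@wavelength * geom@effDistance * 1e6)  # mm -> nm
}

#' Free-space Fresnel propagation of a complex field
#'
#' Transfer-function (Fourier multiplier) propagation
#' \eqn{u_d = F^{-1}[ F[u] \cdot e^{-i\pi\lambda d |\nu|^2} ]} with the
#' forward-transform kernel \eqn{e^{-i 2\pi \nu r}}. The multiplier has unit
#' modulus, so total intensity is conserved exactly and propagation by
#' \code{-distance} inverts propagation by \code{distance}.
#'
#' The chirp is sampled without aliasing only when
#' \eqn{\lambda |d| \le N_{min} \Delta x^2} (equivalently, per-pixel Fresnel
#' number \eqn{\ge 1/N_{min}}); violating grids raise an error rather than
#' returning an aliased field.
#'
#' @param field complex (or numeric) matrix, the field in the source plane
#' @param pixelSize sampling interval, nm (square pixels)
#' @param lambda wavelength, nm
#' @param distance propagation distance, nm; may be negative
#' @return complex matrix of the propagated field
#' @export
fresnelPropagate <- function(field, pixelSize, lambda, distance) {
  if (!is.matrix(field)) stop("'field' must be a matrix")
  checkPositive(pixelSize = pixelSize, lambda = lambda)
  if (distance == 0) return(field + 0i)
  nmin <- min(dim(field))
  if (lambda * abs(distance) > nmin * pixelSize^2 * (1 + 1e-12))
    stop(sprintf(paste0(
      "propagator aliased: lambda*|d| = %.4g nm^2 exceeds N*dx^2 = %.4g nm^2; ",
      "reduce the distance or enlarge the pixels/grid"),
      lambda * abs(distance), nmin * pixelSize^2))
  nu2 <- freqSqGrid(nrow(field), ncol(field), pixelSize)
  H <- exp(-1i * pi * lambda * distance * nu2)
  stats::fft(stats::fft(field) * H, inverse = TRUE) / length(field)
}

#' Propagate by the effective distance of a geometry
#'
#' Convenience wrapper used by the simulation and retrieval code: propagates a
#' field sampled at the effective pixel size by \code{sign * z_eff}.
#' @noRd
propagateEffective <- function(field, geom, sign = 1) {
  fresnelPropagate(field, pixelSize = geom@effPixelSize,
                   lambda = geom@wavelength,
                   distance = sign * geom@effDistance * 1e6)
}
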