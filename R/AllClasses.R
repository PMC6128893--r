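## S4 containers for the three imaging modalities.

#' OpticalGeometry: divergent-beam holography geometry
#'
#' Holds the cone-beam recording geometry of an in-line holography setup
#' (focus-to-sample distance \code{z1}, sample-to-detector distance \code{z2},
#' detector pixel \code{p}) together with the derived parallel-beam
#' equivalents: geometrical magnification \eqn{M = (z1 + z2)/z1}, effective
#' pixel size \eqn{p_{eff} = p/M} and effective propagation distance
#' \eqn{z_{eff} = z1 z2/(z1 + z2)} (Fresnel scaling).
#'
#' @slot photonEnergy photon energy in keV
#' @slot wavelength X-ray wavelength in nm (derived, \eqn{\lambda = hc/E})
#' @slot z1 focus-to-sample distance, mm
#' @slot z2 sample-to-detector distance, mm
#' @slot pixelSize detector pixel size, micrometres
#' @slot magnification geometrical magnification (dimensionless)
#' @slot effPixelSize effective (demagnified) pixel size, nm
#' @slot effDistance effective propagation distance, mm
#' @export
setClass("OpticalGeometry",
  representation(photonEnergy = "numeric", wavelength = "numeric",
                 z1 = "numeric", z2 = "numeric", pixelSize = "numeric",
                 magnification = "numeric", effPixelSize = "numeric",
                 effDistance = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@z1 <= 0) msg <- c(msg, "z1 must be > 0")
    if (object@z2 < 0) msg <- c(msg, "z2 must be >= 0")
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
    if (object@photonEnergy <= 0) msg <- c(msg, "photonEnergy must be > 0")
    M <- (object@z1 + object@z2) / object@z1
    if (abs(object@magnification - M) > 1e-9 * M)
      msg <- c(msg, "magnification inconsistent with z1, z2")
    if (length(msg)) msg else TRUE
  })

#' BeamProfile: nano-focused illumination
#'
#' @slot fwhmY,fwhmZ full width at half maximum of the focal intensity
#'   profile in the horizontal/vertical direction, nm
#' @slot flux total photon flux I0, photons per second
#' @slot exposure dwell time per exposure, seconds
#' @export
setClass("BeamProfile",
  representation(fwhmY = "numeric", fwhmZ = "numeric",
                 flux = "numeric", exposure = "numeric"),
  validity = function(object) {
    if (any(c(object@fwhmY, object@fwhmZ, object@flux, object@exposure) <= 0))
      "all beam parameters must be strictly positive" else TRUE
  })

#' CellPhantom: synthetic adherent-cell ground truth
#'
#' Projected electron density (arbitrary units), the corresponding phase map
#' (\eqn{\phi = -c \cdot density}, radians, non-positive), a fluorophore
#' density map that is non-zero only on labeled filaments, and the true
#' filament segments in physical coordinates. Physical coordinates are nm,
#' centred on the grid centre.
#'
#' @slot density projected electron density, matrix, >= 0
#' @slot phase phase map in radians, \code{-phaseScale * density}
#' @slot labelMap fluorophore density, >= 0
#' @slot pixelSize raster pixel size, nm
#' @slot phaseScale positive constant c relating density to phase
#' @slot filaments data.frame of true segments: y1, z1, y2, z2 (nm),
#'   orientation (deg in [0,180)), widthFwhm (nm), amplitude, labeled (logical)
#' @slot nucleus list: centerY, centerZ (nm), semiY, semiZ (nm), angle (deg),
#'   scale
#' @slot seed integer seed that generated the phantom
#' @export
setClass("CellPhantom",
  representation(density = "matrix", phase = "matrix", labelMap = "matrix",
                 pixelSize = "numeric", phaseScale = "numeric",
                 filaments = "data.frame", nucleus = "list", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
    if (any(object@labelMap < 0)) msg <- c(msg, "labelMap must be >= 0")
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
    if (object@phaseScale <= 0) msg <- c(msg, "phaseScale must be > 0")
    if (max(abs(object@phase + object@phaseScale * object@density)) >
        1e-9 * max(1, max(object@density)))
      msg <- c(msg, "phase must equal -phaseScale * density")
    if (length(msg)) msg else TRUE
  })

#' FluorescenceImage: simulated confocal or STED recording
#'
#' @slot counts integer photon counts
#' @slot pixelSize nm
#' @slot psfFwhm point-spread-function FWHM, nm
#' @slot mode "confocal" or "sted"
#' @export
setClass("FluorescenceImage",
  representation(counts = "matrix", pixelSize = "numeric",
                 psfFwhm = "numeric", mode = "character"),
  validity = function(object) {
    msg <- character()
    if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
    if (!object@mode %in% c("confocal", "sted", "expectation"))
      msg <- c(msg, "mode must be 'confocal' or 'sted'")
    if (object@psfFwhm <= 0) msg <- c(msg, "psfFwhm must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Hologram: flat-field normalized near-field intensity
#'
#' @slot intensity dimensionless normalized intensity (empty beam = 1)
#' @slot geometry the \linkS4class{OpticalGeometry} it was recorded in
#' @export
setClass("Hologram",
  representation(intensity = "matrix", geometry = "OpticalGeometry"),
  validity = function(object) {
    if (any(object@intensity < 0)) "intensity must be >= 0" else TRUE
  })

#' PhaseMap: reconstructed (or true) object phase
#'
#' The reconstructed phase is proportional to the projected electron density;
#' under the sign convention used here object pixels have phase <= 0.
#'
#' @slot phase radians
#' @slot pixelSize nm (the effective pixel size of the geometry)
#' @export
setClass("PhaseMap",
  representation(phase = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@phase))) "phase must be finite everywhere" else TRUE
  })

#' QCalibration: detector-to-momentum-transfer calibration
#'
#' @slot beamCenter length-2 numeric (row, column) of the direct beam in
#'   detector pixels; fractional values allowed
#' @slot distance sample-detector distance, mm
#' @slot pixelSize detector pixel size, micrometres
#' @slot wavelength nm
#' @export
setClass("QCalibration",
  representation(beamCenter = "numeric", distance = "numeric",
                 pixelSize = "numeric", wavelength = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@beamCenter) != 2L) msg <- c(msg, "beamCenter must have length 2")
    if (any(c(object@distance, object@pixelSize, object@wavelength) <= 0))
      msg <- c(msg, "distance, pixelSize, wavelength must be > 0")
    if (length(msg)) msg else TRUE
  })

#' ScanStack: raster scan of far-field diffraction frames
#'
#' @slot frames array [frame rows, frame cols, position] of photon counts
#'   (or noiseless expectations)
#' @slot mask logical matrix, TRUE = valid detector pixel
#' @slot positions data.frame: iy, iz (grid indices), y, z (nm), empty (logical)
#' @slot stepY,stepZ scan step sizes, nm
#' @slot exposure seconds per frame
#' @slot qcal \linkS4class{QCalibration}
#' @export
setClass("ScanStack",
  representation(frames = "array", mask = "matrix", positions = "data.frame",
                 stepY = "numeric", stepZ = "numeric", exposure = "numeric",
                 qcal = "QCalibration"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@frames)) != 3L) msg <- c(msg, "frames must be a 3D array")
    else if (!all(dim(object@frames)[1:2] == dim(object@mask)))
      msg <- c(msg, "mask shape must match frames")
    if (nrow(object@positions) != dim(object@frames)[3])
      msg <- c(msg, "one frame per scan position required")
    if (length(msg)) msg else TRUE
  })

#' DarkFieldMap: integrated diffraction intensity per scan point
#'
#' @slot values matrix over the scan grid (rows = z index, cols = y index),
#'   integrated photons (divide by exposure for ph/s)
#' @slot exposure seconds
#' @slot stepY,stepZ nm
#' @export
setClass("DarkFieldMap",
  representation(values = "matrix", exposure = "numeric",
                 stepY = "numeric", stepZ = "numeric"),
  validity = function(object) {
    if (any(object@values < 0, na.rm = TRUE)) "values must be >= 0" else TRUE
  })

#' AnisotropyMap: PCA anisotropy of diffraction patterns over a scan grid
#'
#' Per scan point, the intensity-weighted second-moment matrix of the momentum
#' transfer is eigen-decomposed into principal variances lambda1 >= lambda2.
#' The degree of anisotropy is \eqn{\omega = |\lambda_1 - \lambda_2| /
#' (\lambda_1 + \lambda_2)}; \code{thetaRecip} is the orientation of the major
#' principal axis in reciprocal space and \code{thetaReal = (thetaRecip + 90)
#' mod 180} the corresponding real-space long axis.
#'
#' @slot omega,thetaRecip,thetaReal,lambda1,lambda2 matrices over the scan grid
#' @slot valid logical matrix (dark-field threshold and well-definedness)
#' @slot stepY,stepZ nm
#' @export
setClass("AnisotropyMap",
  representation(omega = "matrix", thetaRecip = "matrix", thetaReal = "matrix",
                 lambda1 = "matrix", lambda2 = "matrix", valid = "matrix",
                 stepY = "numeric", stepZ = "numeric"),
  validity = function(object) {
    msg <- character()
    ok <- is.finite(object@omega)
    if (any(object@omega[ok] < -1e-12 | object@omega[ok] > 1 + 1e-12))
      msg <- c(msg, "omega must lie in [0, 1]")
    l1 <- object@lambda1; l2 <- object@lambda2
    fin <- is.finite(l1) & is.finite(l2)
    if (any(l1[fin] + 1e-12 < l2[fin])) msg <- c(msg, "lambda1 must be >= lambda2")
    if (length(msg)) msg else TRUE
  })
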