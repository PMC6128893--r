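## Accessors, show methods, and small constructors.

#' @rdname accessors
#' @param object,x an object of one of the package's S4 classes
#' @details Accessor functions are provided instead of direct slot access.
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("phase", function(object) standardGeneric("phase"))
#' @rdname accessors
#' @export
setGeneric("densityMap", function(object) standardGeneric("densityMap"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("trueFilaments", function(object) standardGeneric("trueFilaments"))
#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("scanPositions", function(object) standardGeneric("scanPositions"))
#' @rdname accessors
#' @export
setGeneric("detectorMask", function(object) standardGeneric("detectorMask"))
#' @rdname accessors
#' @export
setGeneric("values", function(object) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("magnification", function(object) standardGeneric("magnification"))
#' @rdname accessors
#' @export
setGeneric("effPixelSize", function(object) standardGeneric("effPixelSize"))
#' @rdname accessors
#' @export
setGeneric("effDistance", function(object) standardGeneric("effDistance"))
#' @rdname accessors
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' Accessors for corrmicro classes
#' @name accessors
#' @return the corresponding slot value
NULL

#' @rdname accessors
#' @export
setMethod("intensity", "Hologram", function(object) object@intensity)
#' @rdname accessors
#' @export
setMethod("phase", "PhaseMap", function(object) object@phase)
#' @rdname accessors
#' @export
setMethod("phase", "CellPhantom", function(object) object@phase)
#' @rdname accessors
#' @export
setMethod("densityMap", "CellPhantom", function(object) object@density)
#' @rdname accessors
#' @export
setMethod("labelMap", "CellPhantom", function(object) object@labelMap)
#' @rdname accessors
#' @export
setMethod("pixelSize", "CellPhantom", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "PhaseMap", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "FluorescenceImage", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("trueFilaments", "CellPhantom", function(object) object@filaments)
#' @rdname accessors
#' @export
setMethod("counts", "FluorescenceImage", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("frames", "ScanStack", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("scanPositions", "ScanStack", function(object) object@positions)
#' @rdname accessors
#' @export
setMethod("detectorMask", "ScanStack", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("values", "DarkFieldMap", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("geometry", "Hologram", function(object) object@geometry)
#' @rdname accessors
#' @export
setMethod("magnification", "OpticalGeometry", function(object) object@magnification)
#' @rdname accessors
#' @export
setMethod("effPixelSize", "OpticalGeometry", function(object) object@effPixelSize)
#' @rdname accessors
#' @export
setMethod("effDistance", "OpticalGeometry", function(object) object@effDistance)
#' @rdname accessors
#' @export
setMethod("wavelength", "OpticalGeometry", function(object) object@wavelength)
#' @rdname accessors
#' @export
setMethod("wavelength", "QCalibration", function(object) object@wavelength)

setMethod("show", "OpticalGeometry", function(object) {
  cat("OpticalGeometry\n")
  cat(sprintf("  E = %.3f keV (lambda = %.5f nm)\n",
              object@photonEnergy, object@wavelength))
  cat(sprintf("  z1 = %g mm, z2 = %g mm, detector pixel = %g um\n",
              object@z1, object@z2, object@pixelSize))
  cat(sprintf("  M = %.3f, p_eff = %.3f nm, z_eff = %.3f mm\n",
              object@magnification, object@effPixelSize, object@effDistance))
})

setMethod("show", "CellPhantom", function(object) {
  d <- dim(object@density)
  cat(sprintf("CellPhantom %d x %d @ %g nm/px (FOV %.2f x %.2f um)\n",
              d[1], d[2], object@pixelSize,
              d[2] * object@pixelSize / 1e3, d[1] * object@pixelSize / 1e3))
  cat(sprintf("  %d filaments (%d labeled), phase in [%.3f, %.3f] rad, seed %d\n",
              nrow(object@filaments), sum(object@filaments$labeled),
              min(object@phase), max(object@phase), object@seed))
})

setMethod("show", "Hologram", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("Hologram %d x %d, intensity mean %.4f (flat-field normalized)\n",
              d[1], d[2], mean(object@intensity)))
})

setMethod("show", "PhaseMap", function(object) {
  d <- dim(object@phase)
  cat(sprintf("PhaseMap %d x %d @ %g nm/px, phase in [%.4f, %.4f] rad\n",
              d[1], d[2], object@pixelSize, min(object@phase), max(object@phase)))
})

setMethod("show", "ScanStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ScanStack: %d frames of %d x %d, step %g x %g nm, exposure %g s\n",
              d[3], d[1], d[2], object@stepY, object@stepZ, object@exposure))
  cat(sprintf("  valid detector pixels: %d / %d\n",
              sum(object@mask), length(object@mask)))
})

setMethod("show", "DarkFieldMap", function(object) {
  cat(sprintf("DarkFieldMap %d x %d scan points, %.3g .. %.3g photons\n",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "AnisotropyMap", function(object) {
  v <- object@valid
  cat(sprintf("AnisotropyMap %d x %d scan points, %d valid\n",
              nrow(v), ncol(v), sum(v)))
  if (any(v))
    cat(sprintf("  omega (valid): median %.3f, range [%.3f, %.3f]\n",
                stats::median(object@omega[v]), min(object@omega[v]),
                max(object@omega[v])))
})

setMethod("show", "FluorescenceImage", function(object) {
  d <- dim(object@counts)
  cat(sprintf("FluorescenceImage (%s) %d x %d @ %g nm/px, PSF FWHM %g nm\n",
              object@mode, d[1], d[2], object@pixelSize, object@psfFwhm))
})

#' Construct a nano-focused beam profile
#'
#' Defaults follow the instrument configuration emulated by the package: a
#' Kirkpatrick-Baez focus of 300 x 300 nm^2 FWHM and a flux of
#' 1.1e11 photons/s.
#'
#' @param fwhmY,fwhmZ focal spot FWHM (intensity) in nm
#' @param flux photon flux in photons/s
#' @param exposure dwell time in s
#' @return a \linkS4class{BeamProfile}
#' @export
beamProfile <- function(fwhmY = 300, fwhmZ = 300, flux = 1.1e11,
                        exposure = 0.002) {
  checkPositive(fwhmY = fwhmY, fwhmZ = fwhmZ, flux = flux, exposure = exposure)
  methods::new("BeamProfile", fwhmY = fwhmY, fwhmZ = fwhmZ, flux = flux,
               exposure = exposure)
}

#' Construct a detector q calibration
#'
#' @param beamCenter numeric(2): (row, column) of the direct beam, detector px
#' @param distance sample-detector distance in mm
#' @param pixelSize detector pixel size in micrometres
#' @param wavelength X-ray wavelength in nm
#' @return a \linkS4class{QCalibration}
#' @export
qCalibration <- function(beamCenter, distance, pixelSize, wavelength) {
  methods::new("QCalibration", beamCenter = as.numeric(beamCenter),
               distance = distance, pixelSize = pixelSize,
               wavelength = wavelength)
}

#' Construct a PhaseMap
#' @param phase matrix of phase values, radians
#' @param pixelSize nm
#' @return a \linkS4class{PhaseMap}
#' @export
phaseMap <- function(phase, pixelSize) {
  methods::new("PhaseMap", phase = phase, pixelSize = pixelSize)
}
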