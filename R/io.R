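## Plain-file serialization: float TIFF images with JSON sidecars, CSV
## tables. Images are stored normalized to [0, 1] at 32-bit with the value
## range recorded in the sidecar (float TIFF writers are only well-defined on
## [0, 1]); round-trips are exact to single precision.

.writeFloatTiff <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  ranges <- lapply(images, function(m) {
    rg <- range(m)
    if (rg[2] <= rg[1]) rg[2] <- rg[1] + 1
    rg
  })
  norm <- Map(function(m, rg) (m - rg[1]) / (rg[2] - rg[1]), images, ranges)
  suppressWarnings(tiff::writeTIFF(norm, path, bits.per.sample = 32,
                                   compression = "none", reduce = FALSE))
  ranges
}

.readFloatTiff <- function(path, ranges) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  Map(function(m, rg) m * (rg[2] - rg[1]) + rg[1], pages, ranges)
}

#' Write / read a cell phantom as TIFF + JSON
#'
#' Density, phase and label map go into a multi-page 32-bit TIFF; the true
#' filament segments, nucleus parameters, seed and pixel size into a JSON
#' sidecar. \code{readPhantom} rebuilds the \linkS4class{CellPhantom}
#' (the phase is recomputed as \code{-phaseScale * density} so the stored
#' object satisfies the class invariant exactly).
#'
#' @param phantom a \linkS4class{CellPhantom}
#' @param prefix file path prefix; writes \code{<prefix>.tif} and
#'   \code{<prefix>.json}
#' @return (invisibly) the two file paths
#' @export
writePhantom <- function(phantom, prefix) {
  tif <- paste0(prefix, ".tif")
  js <- paste0(prefix, ".json")
  ranges <- .writeFloatTiff(list(phantom@density, phantom@labelMap), tif)
  meta <- list(pixelSize = phantom@pixelSize, phaseScale = phantom@phaseScale,
               seed = phantom@seed, nucleus = phantom@nucleus,
               filaments = phantom@filaments,
               pages = c("density", "labelMap"), ranges = ranges)
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, js))
}

#' @rdname writePhantom
#' @export
readPhantom <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  ranges <- lapply(seq_len(nrow(meta$ranges)), function(i) meta$ranges[i, ])
  pages <- .readFloatTiff(paste0(prefix, ".tif"), ranges)
  fil <- as.data.frame(meta$filaments)
  methods::new("CellPhantom", density = pages[[1]],
               phase = -meta$phaseScale * pages[[1]], labelMap = pages[[2]],
               pixelSize = meta$pixelSize, phaseScale = meta$phaseScale,
               filaments = fil, nucleus = meta$nucleus,
               seed = as.integer(meta$seed))
}

#' Write / read a phase map as TIFF + JSON
#' @param pm a \linkS4class{PhaseMap}
#' @param prefix path prefix
#' @export
writePhaseMap <- function(pm, prefix) {
  ranges <- .writeFloatTiff(pm@phase, paste0(prefix, ".tif"))
  jsonlite::write_json(list(pixelSize = pm@pixelSize, ranges = ranges),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writePhaseMap
#' @export
readPhaseMap <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rg <- meta$ranges
  if (is.matrix(rg)) rg <- lapply(seq_len(nrow(rg)), function(i) rg[i, ])
  else if (is.numeric(rg)) rg <- list(rg)
  pages <- .readFloatTiff(paste0(prefix, ".tif"), rg)
  phaseMap(pages[[1]], meta$pixelSize)
}

#' Write a scan stack as multi-page TIFF + CSV + JSON
#'
#' Frames become TIFF pages (single-precision; large counts lose integer
#' exactness), positions a CSV table, and mask/calibration/exposure a JSON
#' sidecar.
#'
#' @param stack a \linkS4class{ScanStack}
#' @param prefix path prefix
#' @export
writeScanStack <- function(stack, prefix) {
  fr <- lapply(seq_len(dim(stack@frames)[3]), function(k) stack@frames[, , k])
  ranges <- .writeFloatTiff(fr, paste0(prefix, "_frames.tif"))
  utils::write.csv(stack@positions, paste0(prefix, "_positions.csv"),
                   row.names = FALSE)
  cal <- stack@qcal
  meta <- list(stepY = stack@stepY, stepZ = stack@stepZ,
               exposure = stack@exposure,
               qcal = list(beamCenter = cal@beamCenter,
                           distance = cal@distance,
                           pixelSize = cal@pixelSize,
                           wavelength = cal@wavelength),
               mask = which(!stack@mask) - 1L,
               frameDim = dim(stack@frames)[1:2], ranges = ranges)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname writeScanStack
#' @export
readScanStack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rg <- meta$ranges
  rg <- lapply(seq_len(nrow(rg)), function(i) rg[i, ])
  pages <- .readFloatTiff(paste0(prefix, "_frames.tif"), rg)
  dimF <- as.integer(meta$frameDim)
  arr <- array(0, c(dimF, length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  mask <- matrix(TRUE, dimF[1], dimF[2])
  if (length(meta$mask)) mask[as.integer(meta$mask) + 1L] <- FALSE
  pos <- utils::read.csv(paste0(prefix, "_positions.csv"))
  methods::new("ScanStack", frames = arr, mask = mask, positions = pos,
               stepY = meta$stepY, stepZ = meta$stepZ,
               exposure = meta$exposure,
               qcal = qCalibration(meta$qcal$beamCenter, meta$qcal$distance,
                                   meta$qcal$pixelSize, meta$qcal$wavelength))
}

#' Write a filament set as CSV (+ JSON parameters)
#' @param fs FilamentSet data.frame
#' @param prefix path prefix
#' @export
writeFilamentSet <- function(fs, prefix) {
  utils::write.csv(as.data.frame(fs), paste0(prefix, ".csv"),
                   row.names = FALSE)
  p <- attr(fs, "params")
  if (!is.null(p))
    jsonlite::write_json(p, paste0(prefix, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(prefix)
}

#' Write an anisotropy map as a long-format CSV
#' @param aniso an \linkS4class{AnisotropyMap}
#' @param path CSV path
#' @export
writeAnisotropyMap <- function(aniso, path) {
  nzr <- nrow(aniso@omega); nyc <- ncol(aniso@omega)
  grid <- expand.grid(iz = seq_len(nzr), iy = seq_len(nyc))
  out <- data.frame(iy = grid$iy, iz = grid$iz,
                    omega = as.vector(aniso@omega),
                    thetaRecip = as.vector(aniso@thetaRecip),
                    thetaReal = as.vector(aniso@thetaReal),
                    lambda1 = as.vector(aniso@lambda1),
                    lambda2 = as.vector(aniso@lambda2),
                    valid = as.vector(aniso@valid))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
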