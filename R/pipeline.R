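## Orchestration: run configuration (JSON round-trip) and the end-to-end
## demo pipeline on the synthetic phantom.

#' Build a run configuration
#'
#' Collects every pipeline parameter with defaults matching the instrument
#' configuration the package emulates: 13.8 keV photons, 6.5 um detector
#' pixels ~5 m behind the sample, a 300 nm FWHM focus at 1.1e11 ph/s, 1 um
#' scan steps, and a dark-field threshold of 7.5e5 ph/s. Remaining values
#' (photon budgets, grid sizes, retrieval and tracer parameters) are the
#' package's own documented choices.
#'
#' @param seed master seed; per-stage seeds are derived from it
#'   deterministically
#' @param ... named overrides of the form \code{section.parameter}, e.g.
#'   \code{phantom.nFilaments = 10}
#' @return a nested list of class \code{RunConfig}
#' @export
runConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.numeric(seed),
    geometry = list(photonEnergy = 13.8, pixelSize = 6.5, z1 = 125,
                    z2 = 5000),
    beam = list(fwhmY = 300, fwhmZ = 300, flux = 1.1e11, exposure = 0.002),
    phantom = list(nFilaments = 30, orientationSpread = 15,
                   labelFraction = 0.7, gridSize = 512, pixelSize = 50,
                   phaseScale = 0.25),
    fluorescence = list(confocalFwhm = 343, stedFwhm = 114.3,
                        photonBudget = 500),
    holography = list(gridSize = 512, photonBudget = 5000, alphaLow = 1e-3,
                      alphaHigh = 1e-1, beta = 0.99, nIter = 500,
                      supportSmoothing = 6, supportFraction = 0.05,
                      supportDilation = 2),
    scan = list(nY = 20, nZ = 20, stepY = 1000, stepZ = 1000, window = 64,
                backgroundRate = 0.05, detectorDistance = 5000,
                beamstopRadius = 10),
    saxs = list(qRange = c(0, 0.8), darkfieldThreshold = 7.5e5),
    psd = list(signalRange = c(0.004, 0.02), noiseRange = c(0.04, 0.06),
               signalRangeHolo = c(0.002, 0.008),
               noiseRangeHolo = c(0.012, 0.018)),
    tracer = list(smoothing = 1.5, nOrientations = 12, lineLength = 15,
                  threshold = 0.95, minSegment = 10),
    registration = list(upsample = 20))
  ov <- list(...)
  for (nm in names(ov)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) cfg[[parts]] <- ov[[nm]]
    else cfg[[parts[1]]][[parts[2]]] <- ov[[nm]]
  }
  structure(.normalizeConfig(cfg), class = "RunConfig")
}

# coerce all numerics to double so save/load round-trips are identical
.normalizeConfig <- function(x) {
  if (is.list(x)) return(lapply(x, .normalizeConfig))
  if (is.numeric(x)) return(as.numeric(x))
  x
}

#' Save / load a run configuration as JSON
#'
#' \code{loadRunConfig(saveRunConfig(cfg, path))} is identical to \code{cfg}.
#'
#' @param cfg a \code{RunConfig}
#' @param path JSON file path
#' @return \code{saveRunConfig}: the path, invisibly; \code{loadRunConfig}:
#'   the \code{RunConfig}
#' @export
saveRunConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveRunConfig
#' @export
loadRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(.normalizeConfig(cfg), class = "RunConfig")
}

# deterministic per-stage seeds below 2^31, derived from the master seed
.stageSeeds <- function(seed) {
  withSeed(as.integer(seed) %% .Machine$integer.max, {
    s <- sample.int(.Machine$integer.max - 1L, 6)
    names(s) <- c("phantom", "fluorescence", "hologram", "scan", "noise",
                  "extra")
    s
  })
}

#' Run the end-to-end demo pipeline on a synthetic phantom
#'
#' Executes the full analysis chain: phantom generation; confocal and STED
#' rendering; hologram simulation, CTF + support + RAAR phase retrieval;
#' scanning-SAXS simulation, dark field, thresholded PCA anisotropy;
#' per-modality PSD curves with power-law/noise-floor fits; filament tracing
#' on the STED image; registration of the STED image onto the phase map; and
#' the filament-vs-anisotropy orientation agreement. Artifacts are written
#' under \code{outDir} together with a provenance manifest (config, seeds,
#' MD5 of every file).
#'
#' The phantom is rasterized twice from the same seed: at the configured
#' phantom pixel size for fluorescence/SAXS and at the effective pixel size
#' of the holography geometry, so each modality is simulated on its natural
#' grid and the physical specimen is identical.
#'
#' @param cfg a \code{RunConfig}
#' @param outDir output directory (created if missing); NULL skips writing
#' @return (invisibly) a list with all intermediate objects and summary
#'   statistics
#' @export
runDemo <- function(cfg = runConfig(), outDir = NULL) {
  stopifnot(inherits(cfg, "RunConfig"))
  seeds <- .stageSeeds(cfg$seed)
  g <- cfg$geometry
  geom <- opticalGeometry(z1 = g$z1, z2 = g$z2, pixelSize = g$pixelSize,
                          photonEnergy = g$photonEnergy)
  beam <- beamProfile(cfg$beam$fwhmY, cfg$beam$fwhmZ, cfg$beam$flux,
                      cfg$beam$exposure)

  p <- cfg$phantom
  phantom <- makeCellPhantom(nFilaments = p$nFilaments,
                             orientationSpread = p$orientationSpread,
                             labelFraction = p$labelFraction,
                             gridSize = p$gridSize, pixelSize = p$pixelSize,
                             seed = seeds[["phantom"]],
                             phaseScale = p$phaseScale)
  phantomHolo <- makeCellPhantom(nFilaments = p$nFilaments,
                                 orientationSpread = p$orientationSpread,
                                 labelFraction = p$labelFraction,
                                 gridSize = cfg$holography$gridSize,
                                 pixelSize = effPixelSize(geom),
                                 seed = seeds[["phantom"]],
                                 phaseScale = p$phaseScale)

  fl <- cfg$fluorescence
  confocal <- renderFluorescence(phantom, psfFwhm = fl$confocalFwhm,
                                 photonBudget = fl$photonBudget,
                                 mode = "confocal",
                                 seed = seeds[["fluorescence"]])
  sted <- renderFluorescence(phantom, psfFwhm = fl$stedFwhm,
                             photonBudget = fl$photonBudget, mode = "sted",
                             seed = seeds[["fluorescence"]] + 1)

  h <- cfg$holography
  holo <- simulateHologram(phantomHolo, geom, photonBudget = h$photonBudget,
                           seed = seeds[["hologram"]])
  ctf <- ctfPhaseRetrieval(holo, alphaLow = h$alphaLow,
                           alphaHigh = h$alphaHigh)
  support <- estimateSupport(ctf, smoothingFwhm = h$supportSmoothing,
                             thresholdFraction = h$supportFraction,
                             dilation = h$supportDilation)
  raar <- raarReconstruct(holo, support, beta = h$beta, nIter = h$nIter,
                          init = ctf)

  s <- cfg$scan
  stack <- simulateScanSAXS(phantom, beam, nY = s$nY, nZ = s$nZ,
                            stepY = s$stepY, stepZ = s$stepZ,
                            window = s$window,
                            backgroundRate = s$backgroundRate,
                            detectorDistance = s$detectorDistance,
                            beamstopRadius = s$beamstopRadius,
                            photonEnergy = g$photonEnergy,
                            seed = seeds[["scan"]])
  df <- darkField(stack)
  dfValid <- thresholdMap(df, cfg$saxs$darkfieldThreshold)
  aniso <- anisotropyMap(stack, qRange = cfg$saxs$qRange,
                         darkfieldThreshold = cfg$saxs$darkfieldThreshold)

  psdConfocal <- powerSpectralDensity(confocal)
  psdSted <- powerSpectralDensity(sted)
  psdPhase <- powerSpectralDensity(raar$phase)
  fits <- list(
    confocal = fitPowerLaw(psdConfocal, cfg$psd$signalRange,
                           cfg$psd$noiseRange),
    sted = fitPowerLaw(psdSted, cfg$psd$signalRange, cfg$psd$noiseRange),
    holography = fitPowerLaw(psdPhase, cfg$psd$signalRangeHolo,
                             cfg$psd$noiseRangeHolo))

  tr <- cfg$tracer
  fsSted <- traceFilaments(sted, smoothing = tr$smoothing,
                           nOrientations = tr$nOrientations,
                           lineLength = tr$lineLength,
                           threshold = tr$threshold,
                           minSegment = tr$minSegment)
  hist <- orientationHistogram(fsSted)

  # register the (rebinned) STED image onto the reconstructed phase map
  stedOnHolo <- rebinImage(counts(sted), pixelSize(sted), effPixelSize(geom))
  nH <- nrow(phase(raar$phase))
  reg <- NULL
  if (all(dim(stedOnHolo) <= nH)) {
    padded <- matrix(0, nH, nH)
    o <- floor((nH - dim(stedOnHolo)) / 2)
    padded[o[1] + seq_len(nrow(stedOnHolo)), o[2] + seq_len(ncol(stedOnHolo))] <-
      stedOnHolo
    reg <- registerTranslation(-phase(raar$phase), padded,
                               upsample = cfg$registration$upsample)
  }

  fsPhys <- segmentsToPhysical(fsSted, pixelSize(sted), dim(counts(sted)))
  agreement <- orientationAgreement(fsPhys, aniso, scanPositions(stack))

  result <- list(config = cfg, seeds = seeds, geometry = geom,
                 phantom = phantom, phantomHolo = phantomHolo,
                 confocal = confocal, sted = sted, hologram = holo,
                 ctf = ctf, support = support, raar = raar, stack = stack,
                 darkfield = df, darkfieldValid = dfValid, aniso = aniso,
                 psd = list(confocal = psdConfocal, sted = psdSted,
                            holography = psdPhase),
                 fits = fits, filaments = fsSted,
                 orientationHist = hist, registration = reg,
                 agreement = agreement)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(...) file.path(outDir, ...)
    saveRunConfig(cfg, fp("config.json"))
    writePhantom(phantom, fp("phantom"))
    writePhaseMap(ctf, fp("phase_ctf"))
    writePhaseMap(raar$phase, fp("phase_raar"))
    utils::write.csv(data.frame(iteration = seq_along(raar$residuals),
                                residual = raar$residuals),
                     fp("raar_residuals.csv"), row.names = FALSE)
    writeScanStack(stack, fp("scan"))
    utils::write.csv(as.data.frame(as.table(values(df))),
                     fp("darkfield.csv"), row.names = FALSE)
    writeAnisotropyMap(aniso, fp("anisotropy.csv"))
    for (nm in names(result$psd))
      utils::write.csv(result$psd[[nm]], fp(paste0("psd_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(lapply(fits, unclass), fp("psd_fits.json"),
                         auto_unbox = TRUE, digits = NA)
    writeFilamentSet(fsSted, fp("filaments_sted"))
    utils::write.csv(agreement$points, fp("agreement.csv"),
                     row.names = FALSE)
    files <- list.files(outDir, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest <- list(seed = cfg$seed,
                     stageSeeds = as.list(seeds),
                     configMd5 = unname(tools::md5sum(fp("config.json"))),
                     files = lapply(stats::setNames(files, basename(files)),
                                    function(f) unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    result$manifest <- fp("manifest.json")
  }
  invisible(result)
}
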