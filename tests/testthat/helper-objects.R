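# Shared fixture builders. Geometries are chosen so the Fresnel propagator is
# well sampled on the grid used (per-pixel Fresnel number >= 1/N).

geomForGrid <- function(n) {
  z1 <- switch(as.character(n), "512" = 125, "256" = 250, "128" = 500,
               "64" = 1000, stop("no geometry preset for n = ", n))
  opticalGeometry(z1 = z1, z2 = 5000, pixelSize = 6.5, photonEnergy = 13.8)
}

discPhase <- function(n, dx, radiusPx, value = -0.5) {
  co <- (seq_len(n) - (n + 1) / 2) * dx
  rr <- sqrt(outer(co^2, co^2, `+`))
  m <- matrix(0, n, n)
  m[rr < radiusPx * dx] <- value
  m
}

# minimal phantom with prescribed label map (for impulse-response tests)
labelOnlyPhantom <- function(label, pixelSize) {
  z <- matrix(0, nrow(label), ncol(label))
  methods::new("CellPhantom", density = z, phase = z, labelMap = label,
               pixelSize = pixelSize, phaseScale = 1,
               filaments = data.frame(), nucleus = list(), seed = 0L)
}

# centred q-map for an odd frame (exactly symmetric under 90-degree rotation)
centredQMap <- function(n, distance = 5000, pixelSize = 172,
                        wavelength = 0.08984362) {
  cal <- qCalibration(c((n + 1) / 2, (n + 1) / 2), distance, pixelSize,
                      wavelength)
  list(cal = cal, qm = qMap(cal, c(n, n)))
}

# brute-force PCA anisotropy oracle: explicit double loop plus closed-form
# 2x2 eigendecomposition
pcaOracle <- function(frame, mask, qm, qRange = c(0, Inf)) {
  W <- Syy <- Szz <- Syz <- 0
  for (i in seq_len(nrow(frame))) for (j in seq_len(ncol(frame))) {
    if (!mask[i, j]) next
    q <- qm$q[i, j]
    if (q <= 0 || q < qRange[1] || q > qRange[2]) next
    w <- max(frame[i, j], 0)
    W <- W + w
    Syy <- Syy + w * qm$qy[i, j]^2
    Szz <- Szz + w * qm$qz[i, j]^2
    Syz <- Syz + w * qm$qy[i, j] * qm$qz[i, j]
  }
  Syy <- Syy / W; Szz <- Szz / W; Syz <- Syz / W
  tr <- Syy + Szz; dt <- Syy * Szz - Syz^2
  l1 <- tr / 2 + sqrt(tr^2 / 4 - dt)
  l2 <- tr / 2 - sqrt(tr^2 / 4 - dt)
  theta <- if (abs(Syz) < 1e-300 && Syy >= Szz) 0
           else (atan2(l1 - Syy, Syz) * 180 / pi) %% 180
  list(lambda1 = l1, lambda2 = l2, omega = (l1 - l2) / (l1 + l2),
       thetaRecip = theta)
}
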