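# corrmicro

Correlative X-ray holography, scanning SAXS and STED image analysis in R.

Single adherent cells can be imaged on one instrument with three
complementary contrasts: **in-line X-ray holography** (full-field phase
contrast — every molecular constituent, labeled or not, contributes to the
projected electron density), **scanning SAXS** with a nano-focused beam
(a far-field diffraction pattern per scan position, condensed into
dark-field and orientation maps), and **confocal/STED fluorescence**
(only the labeled cytoskeleton, down to super-resolution). `corrmicro`
implements the full analysis chain for such an experiment, together with a
seeded synthetic cardiac-cell phantom that supplies ground truth for every
stage, so the pipeline is testable end to end without external data.

The core methods:

* **Phase retrieval.** The cone-beam geometry is reduced to parallel beam
  via the Fresnel scaling theorem (M = (z₁+z₂)/z₁, p_eff = p/M,
  z_eff = z₁z₂/(z₁+z₂)). A contrast-transfer-function (CTF) step inverts
  the weak-object relation F[I−1] = 2 sin(πλz_eff|ν|²)·F[φ] with two-level
  regularization and yields the support estimate; relaxed averaged
  alternating reflections (RAAR),
  u ← β/2(R_S R_M + I)u + (1−β)P_M u, then reconstructs the phase under the
  magnitude, support and pure-phase (φ ≤ 0) constraints.
* **Scanning SAXS.** Per-pixel momentum transfer
  |q| = (4π/λ)sin(atan(r/D)/2); beamstop/gap masking; dark field as the
  exact masked photon sum; PCA anisotropy from the intensity-weighted
  second moments of q about the origin, ω = (λ₁−λ₂)/(λ₁+λ₂) with the
  real-space axis θ_real = θ_recip + 90°; dark-field thresholding
  (I_df = 7.5·10⁵ ph/s) restricts the analysis to the cell.
* **Resolution.** Azimuthally averaged power spectral densities (q = 2πν)
  per modality; fits I(q) = a·q^b + bgr locate the noise-floor cross-over
  q_i (a·q_i^b = bgr) and the critical structure size d_cr = π/q_i; the
  fluorescence diffraction limit is d_min = λ_fl/(2NA).
* **Filaments & correlation.** An oriented-filter/skeleton tracer extracts
  straight filament segments with orientations; area-weighted rebinning and
  sub-pixel phase cross-correlation register the modalities; per scan point
  the axial distance Δθ ∈ [0°, 90°] between filament orientation and SAXS
  anisotropy axis quantifies their agreement.

## Worked example

```r
library(corrmicro)

geom <- opticalGeometry(z1 = 125, z2 = 5000)   # 13.8 keV, 6.5 um pixels
geom
#> OpticalGeometry
#>   E = 13.800 keV (lambda = 0.08984 nm)
#>   z1 = 125 mm, z2 = 5000 mm, detector pixel = 6.5 um
#>   M = 41.000, p_eff = 158.537 nm, z_eff = 121.951 mm

res <- runDemo(runConfig(seed = 1), outDir = "demo_out")

# holographic phase retrieval vs ground truth
cor(as.vector(phase(res$raar$phase)), as.vector(phase(res$phantomHolo)))
#> [1] 0.9948515

# SAXS anisotropy vs traced STED filaments, per scan point
res$agreement$medianDTheta   # median angular disagreement, degrees
#> [1] 3.350248
res$agreement$fracBelow20    # fraction of scan points agreeing within 20 deg
#> [1] 0.8828829

# resolution cross-overs per modality (nm^-1): confocal < STED < holography
sapply(res$fits, function(f) f$qi)
#>   confocal       sted holography
#> 0.01632427 0.03939706 0.04085991

diffractionLimit(651, 0.95)  # Abbe limit of the emulated STED microscope, nm
#> [1] 342.6316
```

The demo writes every artifact (phantom, holograms, phase maps, scan stack,
dark-field/anisotropy maps, PSD curves and fits, filament tables, agreement
tables) plus a provenance manifest with per-file MD5 sums under
`demo_out/`; rerunning with the same seed reproduces the files
bit-identically.

The interpretation: the reconstructed phase tracks the projected electron
density (correlation ≈ 0.99 against truth), the principal axis of the local
diffraction anisotropy aligns with the filament orientations where a single
filament dominates a scan point (median within a few degrees), and the PSD
cross-overs rank confocal below STED, as the point-spread functions dictate
(STED and holography are deliberately close in resolution at this scale).

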