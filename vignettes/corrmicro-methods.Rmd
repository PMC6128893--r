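---
title: "Methods: correlative holography, scanning SAXS and STED on a synthetic cell"
author: "corrmicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlative holography, scanning SAXS and STED on a synthetic cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`corrmicro` implements the analysis chain of a correlative single-cell
imaging experiment that combines three contrasts recorded on one instrument:

* **in-line X-ray holography** — a full-field phase-contrast image of the
  projected electron density, reconstructed from a near-field hologram;
* **scanning SAXS** — a raster scan of far-field diffraction patterns from a
  nano-focused beam, condensed into dark-field and orientation-anisotropy
  maps;
* **confocal / STED fluorescence** — diffraction-limited and super-resolved
  images of the labeled actin cytoskeleton.

Because each modality sees a different subset of the specimen (all electron
density vs. only the labeled filaments), the package also ships a seeded
synthetic cardiac-cell phantom that provides ground truth for every stage,
so the full pipeline can be exercised and validated end to end without any
external data.

# The phantom: what it emulates and what it does not

`makeCellPhantom()` draws a cell in *physical coordinates* (nm) first and
rasterizes afterwards, so one seed defines one specimen at any grid/pixel
size. The model is:

* `nFilaments` straight filament bundles (Gaussian cross-section, FWHM
  150–400 nm, amplitudes 0.6–1) whose orientations are normal around a
  random main cell axis with SD `orientationSpread` (default 15°); segments
  are clipped to the cell envelope; footprints are truncated at 3 sigma so
  the fluorophore map is exactly zero off the filaments;
* an elliptical nucleus (default semi-axes 3.5 × 2.5 µm, projected-ellipsoid
  profile) — the strong *unlabeled* scatterer;
* a faint smooth cytoplasm envelope (default semi-axes 10 × 6.5 µm).

The phase map is `phi = -phaseScale * density` (pure phase object, phase
non-positive by convention); `phaseScale = 0.25` puts the nucleus near
−0.6 rad and filaments near −0.2 rad, i.e. a strong but unwrapped phase.

A `labelFraction` (default 0.7) of the filaments carries fluorophore;
exactly `round(labelFraction * nFilaments)` contribute to the label map.

What the phantom deliberately does **not** model: 3D structure (everything
is a 2D projection), partial coherence and polychromaticity, detector
point-spread functions, radiation damage, curved or branching filaments,
and any organelle besides the nucleus. Tests passing on this phantom
therefore validate the *algorithms* under known ground truth; they do not
certify performance on real cellular data, where model mismatch (curved
fibres, 3D overlap, structured background) is the dominant difficulty.

# Holography

## Geometry

`opticalGeometry()` reduces the divergent-beam (cone) recording geometry to
its parallel-beam equivalent by the Fresnel scaling theorem: magnification
$M = (z_1+z_2)/z_1$, effective pixel $p_{\mathrm{eff}} = p/M$, effective
distance $z_{\mathrm{eff}} = z_1 z_2/(z_1+z_2)$, and
$\lambda = hc/E$. Defaults: $E = 13.8$ keV, $p = 6.5$ µm, $z_2 = 5$ m.

The default $z_1 = 125$ mm is chosen so that on the default 512² grid the
transfer-function Fresnel propagator is sampled without aliasing: the
chirp $e^{-i\pi\lambda d|\nu|^2}$ is alias-free when
$\lambda|d| \le N \Delta x^2$, i.e. per-pixel Fresnel number
$F = p_{\mathrm{eff}}^2/(\lambda z_{\mathrm{eff}}) \ge 1/N$; at these
defaults $F = 2.3\times 10^{-3} > 1/512$. `fresnelPropagate()` enforces
this bound as an error rather than silently returning an aliased field, and
`simulateHologram()` additionally requires $F \in [10^{-4}, 10]$.

## CTF step

For a weak pure-phase object the hologram contrast is linear in the phase,
$\mathcal{F}[I-1] = 2\sin\chi \cdot \mathcal{F}[\phi]$ with
$\chi = \pi\lambda z_{\mathrm{eff}}|\nu|^2$. `ctfPhaseRetrieval()` inverts
this with a two-level Tikhonov term (`alphaLow = 1e-3` below the first CTF
maximum, `alphaHigh = 1e-1` above — the low band is well transferred, the
high band oscillates through zeros and needs stronger damping). The DC term
carries no information (flux is conserved), so the retrieved map has a free
offset; by default the median of the map (the empty background around a
compact cell) is shifted to zero.

## Support estimation

The support is estimated from the CTF map: Gaussian smoothing (FWHM 6 px),
threshold at 5 % of the most negative value, largest 8-connected component,
morphological closing, **hole filling**, and 2 px dilation. Two of these
choices deserve a note:

* the threshold errs *outwards* (5 % of the minimum): RAAR tolerates a
  support that is somewhat too large, but pixels of the true object wrongly
  excluded make the constraint set inconsistent and visibly stall the
  reconstruction (verified on disc phantoms, where a circumscribing support
  recovers the object to correlation 1.0 while a 90 %-coverage support
  saturates near 0.87);
* hole filling matters for strong objects, whose CTF estimate keeps a deep
  rim but a shallow interior; the filled rim ring yields the full support.

## RAAR iteration

`raarReconstruct()` runs
$u \leftarrow \tfrac{\beta}{2}(R_S R_M + I)u + (1-\beta)P_M u$ with
$\beta = 0.99$ fixed, 500 iterations by default, initialized from the CTF
estimate. $P_M$ replaces the propagated modulus by $\sqrt I$; $P_S$ enforces
the sample constraints (unit modulus, zero phase outside the support,
non-positive phase inside — the last switchable via `clipNonpositive`).

The reported residual is the relative magnitude misfit of the *constrained
estimate* $x_k = P_S P_M u_k$, not of the internal relaxed iterate: for
noisy (inconsistent) data the RAAR iterate drifts away from the measurement
set without bound even while $x_k$ converges, so the iterate's own residual
is not a usable convergence or divergence signal. On noiseless data the
estimate residual decreases to numerical zero; on noisy data it settles at
the Poisson noise floor. A residual that stays above ten times its initial
value for more than 100 consecutive iterations aborts with a diagnostic
(transient excursions above that level are normal early in the iteration).

# Scanning SAXS

`simulateScanSAXS()` translates the phantom through a Gaussian focus
(default 300 × 300 nm² FWHM intensity, flux $1.1\times10^{11}$ ph/s) on a
raster grid (default 1 µm steps) and records
$|\mathcal{F}[A\,e^{i\phi}]|^2$, Parseval-normalized so the noiseless frame
total equals the incident photons, with a uniform background rate, Poisson
noise, and a detector mask (centred beamstop disc + two horizontal
inter-module gap stripes, a scaled-down two-module layout). The derived q
calibration sets the detector pixel to $\lambda D/(N_w \Delta x)$ so the
small-angle q of detector pixels coincides with the Fourier grid of the
simulation window.

The q range is a scaled-down study condition: with 50 nm phantom pixels the
pattern extends to $q_{\max} = \pi/\Delta x \approx 0.063$ nm⁻¹, an order of
magnitude below a real nanodiffraction detector. Nothing in the analysis
depends on the absolute extent; the default PCA annulus cap of 0.8 nm⁻¹ is
simply inactive at this scale.

Processing follows the standard chain: `composeMask()` (exclusion
conjunction), `subtractBackground()` (mean background, clipped at zero),
`darkField()` (exact masked photon sum per scan point; photons, divided by
exposure only for comparison against the dark-field threshold),
`pcaAnisotropy()` and `thresholdMap()` (default $I_{df} = 7.5\times10^5$
ph/s, which cleanly separates off-cell scan points — beam-tail plus
background, about $4\times10^5$ ph/s at the defaults — from on-cell points
at $10^6$–$10^8$ ph/s).

PCA second moments are taken about $q = 0$ without mean subtraction:
diffraction patterns are Friedel-symmetric, so the intensity centroid
vanishes and the origin-centred moments are the physically meaningful
ones. Weights are the masked, non-negative counts. The orientation is
reported both in reciprocal space (`thetaRecip`) and as the real-space long
axis (`thetaReal = thetaRecip + 90° mod 180°`), which is the convention
used for overlay with filaments; $\omega = (\lambda_1-\lambda_2)/
(\lambda_1+\lambda_2) \in [0,1]$.

# Resolution estimation

`powerSpectralDensity()` computes the azimuthally averaged PSD
(mean-subtracted, periodic Hann window by default to curb leakage from the
non-periodic cell image, normalization such that the unwindowed 2D total
equals variance × pixel count). Frequencies are reported as $q = 2\pi\nu$
so curves from all modalities share an axis.

`fitPowerLaw()` models a curve as $I(q) = a q^b + bgr$: the floor $bgr$ is
the mean over the user-chosen noise range, and $(a, b)$ come from least
squares on $\log(I - bgr)$ vs $\log q$ over the signal range (subtracting
the floor first makes the fit exact on synthetic $aq^b + bgr$ curves with
well-separated ranges). The cross-over solves $a q_i^b = bgr$ and the
critical structure size is $d_{cr} = \pi/q_i$. Fit ranges are mandatory
configuration, per modality (the holography map lives on a coarser grid
with a smaller Nyquist q). A non-decaying signal range is flagged, not
fitted. `diffractionLimit()` is the Abbe bound $\lambda_{fl}/(2\,\mathrm{NA})$.

# Filament tracing

`traceFilaments()` is a deliberately simple, phantom-validated tracer (the
published filament-sensor algorithms are substantially more elaborate): an
oriented zero-mean line-filter bank (12 orientations, 15 px lines, 1 px
Gaussian profile) on the smoothed image, maximum response thresholded at a
quantile (default 0.95 — high enough to reject background, low enough to
keep ridges contiguous), Zhang–Suen skeletonization, junction cutting by
crossing number (≥ 3 transitions around the 8-neighbourhood; the junction's
3 × 3 neighbourhood is removed because under 8-connectivity dropping the
centre pixel alone leaves arms bridged diagonally), and a principal-axis
straight-segment fit per remaining component of at least `minSegment` px.
The quantile threshold makes detection exactly invariant under intensity
scaling. Known limitations: curved fibres are chopped into straight pieces,
dense crossings lose a few pixels around each junction, and closely
parallel fibres within the PSF merge.

# Registration and agreement

`rebinImage()` resamples by exact 1D overlap matrices (area-weighted means),
conserving integrated intensity to round-off. `registerTranslation()` is
phase cross-correlation with sub-pixel refinement by direct evaluation of
the inverse Fourier sum on an upsampled neighbourhood of the integer peak.

`orientationAgreement()` maps filament segments (nm, centred frame,
optionally through a translation+scale transform) onto the scan grid by
sampling each segment at quarter-step spacing; per valid scan point it
compares the length-weighted axial mean filament orientation with
`thetaReal`, giving $\Delta\theta \in [0°, 90°]$, plus summary statistics
(median, fraction below 20°). The per-point segment count allows selecting
scan points dominated by a single filament, which is the cleanest
ground-truth comparison.

# Orchestration, sizes and budgets

`runConfig()` collects all parameters (instrument values as defaults:
13.8 keV, 6.5 µm pixels, 300 nm beam, 1 µm steps, $I_{df} = 7.5\times10^5$
ph/s) and round-trips identically through JSON. `runDemo()` derives
per-stage seeds from the master seed, rasterizes the same physical phantom
at 50 nm (fluorescence/SAXS, 512²) and at $p_{\mathrm{eff}}$ (holography,
512²), runs every stage, and writes all artifacts with a manifest (config
MD5 + per-file MD5), so a repeated run is bit-identical.

Problem sizes were chosen so the full demo completes in about two minutes
on one CPU (RAAR at 512² dominates) and the whole test suite in a few
minutes; the photon budgets (5000 ph/px hologram, 2 ms SAXS dwell) are
package choices — the corresponding real-experiment values are not part of
the emulated configuration.

Serialization uses 32-bit float TIFF (images normalized to [0, 1] with the
range in a JSON sidecar — exact to single precision), CSV tables and JSON
metadata; a `ScanStack` becomes a multi-page TIFF + positions CSV + JSON
attributes.

# Known limitations

* Single-distance holography only; no multi-distance or ptychographic
  retrieval, no absorption retrieval, no astigmatic waveguide optics.
* The SAXS simulation is a thin-sample 2D Fourier model; multiple
  scattering, absolute intensity calibration and detector distortions are
  out of scope.
* The PSD floor/cross-over analysis needs user-chosen fit ranges; automatic
  range selection is deliberately not attempted.
* The tracer is a functional stand-in validated on phantoms, not a
  re-implementation of any published filament-sensor parameterization.
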