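---
title: "Simulating and reconstructing spatio-temporal optical coherence tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and reconstructing spatio-temporal optical coherence tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoct)
```

## The imaging problem

Full-field swept-source optical coherence tomography records, for every
camera pixel, a spectral interferogram: the intensity of the sample field
interfering with a reference field while the source sweeps across a
wavelength band. A Fourier transform along the wavenumber axis turns each
pixel's fringe into a depth profile. In weakly scattering samples this works
beautifully; in turbid media it degrades, because light scattered at one
object point spills into many detector pixels. This *optical crosstalk*
adds a spatially coherent, speckle-like background that can bury real
structure and famously produces depth profiles that look "anomalously
uniform" — flat where Beer–Lambert attenuation says they should decay.

Spatio-temporal optical coherence (STOC) manipulation suppresses crosstalk
by imposing a different random spatial phase pattern on the illumination for
each of many acquisitions and averaging the recorded interferograms. The
ballistic (mirror-image) component of the sample field and the reference
field traverse the same modulator, so the imposed phase cancels in their
interference term: the fringe that encodes true structure is identical in
every acquisition. Multiply scattered light arrives with an effectively
random phase relative to the reference in each realization, so its
interference terms average toward zero at a rate of $1/\sqrt{M}$ in the
number $M$ of uncorrelated masks. The volumetric variant (STOC-T) combines
this with the swept-source depth reconstruction.

This package provides the three pieces needed to study that mechanism
quantitatively on synthetic data: a forward model of the acquisition with
separable mirror and crosstalk components, the averaging/filtering and
coherence-matrix diagnostics, and the full volumetric post-processing chain
including computational aberration correction.

## Forward model

**Ballistic channel.** A phantom is a stack of planar layers, each with a
lateral reflectivity map, an attenuation coefficient $\mu$ (1/µm) and a
crosstalk strength. The mirror field at wavenumber $k$ is the sum over
layers of reflectivity × cumulative round-trip attenuation
$\exp(-2\sum\mu d)$ of the material above × the round-trip phase
$e^{-i2kz}$, times the mask phase $e^{i\Delta\varphi(x,y)}$. Thick slabs are
discretized into thin sub-layers (default 25 µm) so reconstructed profiles
sample the exponential decay densely.

**Crosstalk channel.** The multiply scattered field is not propagated
through a wave equation — the whole point of the statistical treatment is
that only its ensemble behavior matters. Each scattering layer sheds a
circular complex Gaussian speckle field whose per-pixel variance equals
`crosstalk_strength` × the ballistic energy the layer removes,
$1-\exp(-2\mu d)$, low-pass filtered to the detection NA (a hard circular
aperture in the spatial-frequency plane — the simplest testable contract).
Each realization carries the round-trip phase of a depth drawn uniformly
within the layer, reflecting the variable path lengths of diffuse light.
Realizations are seeded by the mask seed, so different masks see independent
crosstalk while reruns are bit-identical. Two spectral-correlation limits
are exposed: `"frozen"` (one realization per mask, fully correlated across
the sweep) and `"per_k"` (independent per spectral frame). Real tissue lies
somewhere between; neither limit is asserted as ground truth, and analyses
that depend on the choice state it.

**Detection.** The camera records
$I = |E_s|^2 + |E_r|^2 + 2\,\mathrm{Re}(E_s E_r^*)$. With the modulator
ahead of the interferometer both arms share $e^{i\Delta\varphi}$ and the
mirror fringe is exactly mask-invariant; the package also exposes the
object-arm geometry (`mask_arm = "object"`) in which only
coherence-matrix analysis can recover the correlation structure. Optional
Poisson shot noise and bit-depth quantization are off by default so that
statistical properties can be tested at machine precision.

**Masks.** Four generators mirror the hardware families: piecewise-constant
random tiles (`slm`), a smooth random surface rescaled to at least $2\pi$
peak-to-valley (`membrane`), a random superposition of speckle-like modes
with uniform modal phases (`fiber_modes`), and `flat` (the coherent
control). Any two seeds give ensemble correlation well below 0.1, which is
the property the averaging argument actually needs.

## Crosstalk suppression and its diagnostics

`average_stacks()` is a plain arithmetic mean of intensity interferograms —
matching both hardware integration on the camera chip and post-hoc
averaging; DC removal (per-pixel spectral mean subtraction, or a zero-phase
Gaussian high-pass with cutoff at 2% of the Nyquist fringe frequency)
isolates the interferometric term. Residual crosstalk is quantified in the
*fringe band* (spectral frequencies above the DC cutoff), where the
mirror fringe and crosstalk fringes live and the autocorrelation terms do
not. The expected behaviors, verified in the test suite, are: exact
preservation of the mirror fringe, residual crosstalk RMS
$\propto M^{-1/2}$ (fitted log–log slope $-0.5 \pm 0.05$), and a
suppression factor of about $\sqrt{846} \approx 29$ when averaging over as
many masks as the reference multimode fiber has guided modes.

The coherence matrix $G$ holds the normalized complex degree of coherence
between every pair of linearized pixels ($\chi = n + mN$), with the mask
ensemble standing in for the time ensemble of a stationary ergodic field.
Under coherent illumination the common ballistic field correlates all
pixels (strong off-diagonal structure); under STOC modulation only each
pixel's own waveform survives, and $G$ collapses toward the diagonal. The
`diagonality()` metric is simply mean on-diagonal over mean off-diagonal
magnitude; zero-energy pixels are flagged as masked rather than reported as
incoherent. $G$ is computed per wavelength on ROIs of at most 64×64 pixels
(K ≤ 4096) to bound memory; a pooling flag would be a trivial extension but
no pooled analysis is implemented.

Intensity statistics at a reflecting plane follow a modified Rician
(non-central exponential) law
$p(I) = \sigma^{-2} e^{-(I+I_d)/\sigma^2} I_0(2\sqrt{I I_d}/\sigma^2)$:
the coherent superposition of a deterministic signal of strength $I_d$ and
circular crosstalk noise of variance $\sigma_n^2$. The exact density used in
earlier experimental work is not uniquely pinned down in print, so this
intensity-domain parameterization was adopted and documented; it reduces to
the exponential (fully developed speckle) law as $I_d \to 0$. The
maximum-likelihood fit uses a moment start
($\sigma^2 = \bar I - \sqrt{\bar I^2 - s^2}$) and a Nelder–Mead refinement
with the Bessel term evaluated through its exponentially scaled form. As
the mask count grows, $\sigma_n^2$ falls and $I_d$ rises — the signature of
crosstalk giving way to signal.

## Reconstruction chain

The processing order is: fixed-pattern notch filtering → DC removal →
(optional) spectral phase correction → zero-padded FFT along $k$ with
Hermitian half retention → split-aperture defocus estimation →
entropy-driven Zernike correction. Numerical choices that matter:

* **Uniform-k resampling.** Swept sources tune essentially uniformly in
  wavelength, so the wavenumber grid is chirped by several percent across
  an 800–875 nm sweep. Because the data are uniformly sampled in sweep
  index, the package first oversamples each pixel's spectrum 8× by
  zero-padded FFT in the index domain (exact for fringes below the local
  Nyquist depth) and then interpolates to the uniform-k grid with a local
  cubic Lagrange stencil. A plain cubic directly on the chirped grid loses
  several percent of amplitude per high-frequency fringe — enough to bias a
  fitted attenuation coefficient by tens of percent — whereas the
  oversampled scheme keeps the depth response flat across the usable range.
* **Apodization.** A Hann window (amplitude-normalized) is applied before
  the depth FFT by default. With densely stacked reflecting sub-layers the
  rectangular sweep window's coherent sidelobe leakage produces ±30% peak
  scalloping; the Hann window removes it at the cost of ~1.6× axial PSF
  broadening. `window = "none"` restores the rectangular transform (used
  when comparing against the direct Fourier-sum oracle).
* **Depth axis.** $\Delta z = \pi/(N_{pad}\,\delta k)$, positive-depth half
  retained; the unambiguous depth range is $\pi/(2\delta k)$, and study
  phantoms are sized to stay inside it.
* **Reference strength.** The default study configurations use a reference
  amplitude 10–100× the sample amplitudes. Self-interference
  (autocorrelation) terms between layers scale with sample/reference ratio
  and land at inter-layer distances that can coincide with true depths;
  a strong reference keeps them below a few percent of the fringe, as in
  practical Fourier-domain systems.

**Fixed-pattern filter.** Per-plane 2D FFT magnitudes are summed along the
third axis; a 9×9 median filter estimates the smooth background; bins
exceeding 4× background outside a 3-bin DC guard are flagged and
point-symmetrized so real planes stay real. On featureless noise the false
positive rate is below 0.1% of frequency bins.

**Kurtosis dispersion correction.** The five-parameter spectral phase
$\varphi(\kappa) = \sum_{j=1}^5 a_j\kappa^j$ (with $\kappa$ the wavenumber
normalized to $[-1,1]$) is optimized to maximize the kurtosis of B-scan
intensity. The monomial-order convention is a documented choice: orders
2–3 are physical group-velocity dispersion, order 1 absorbs bulk axial
motion, orders 4–5 residual chirp. A coarse pre-scan of $a_2$ seeds a
Nelder–Mead simplex (restarted once for convergence); the corrector is
accepted only if it improves kurtosis by at least 1%, so already-sharp data
keep a zero corrector instead of chasing sub-bin alignment jitter. The
converged phase is applied to the whole volume.

**Split-aperture defocus.** Defocus bends the pupil phase quadratically, so
images formed from the left and right half-apertures shift in opposite
directions, linearly in depth. The relative shift is measured by
cross-correlation with parabolic sub-pixel refinement and converted to a
Noll-$Z_4$ coefficient through the geometric shear relation evaluated at
the *energy-weighted* spectral centroids of the two half-apertures (the
uniform-pupil centroid $4f_{max}/(3\pi)$ is only correct for flat object
spectra). The conversion constant is verified by inject–recover tests, not
against a printed number, since no such number is available.

**Entropy-driven Zernike correction.** Zernike polynomials (Noll indexing,
RMS-normalized, on the disk inscribed in the Nyquist square) form a
variable pupil phase; piston, tip and tilt are excluded. Coordinate descent
tunes one coefficient at a time by a 9-point bracketing grid plus local
refinement. Two details proved essential for reliability: the coefficients
are visited in order of their *achievable improvement* probed from the
current state (otherwise a correlated lower-impact term, e.g. defocus under
an astigmatic aberration, absorbs part of the error and strands the descent
in a local minimum), and the full search span is kept for the first two
cycles before the bracket shrinks. Sharpness is measured by Shannon entropy
of normalized intensity, *minimized* by default: sharp images concentrate
energy into few pixels, which lowers entropy. The opposite direction is
exposed by a flag for comparison, since the literature's wording is
ambiguous on this point.

## What the synthetic generator does and does not emulate

The generator reproduces the features the method's claims rest on: a
mask-invariant ballistic fringe, mask-decorrelated crosstalk with
layer-resolved variance, detection-NA spatial correlation, Beer–Lambert
depth decay, swept-source chirp, and camera quantization/shot noise when
enabled. It does not solve a wave equation: there is no diffraction between
layers, no multiple-scattering geometry, no polarization, no dispersion in
the sample itself, no motion. Consequently, passing tests demonstrate the
*statistical mechanics* of crosstalk suppression and the correctness of the
reconstruction/correction algorithms — they do not validate radiometric
accuracy for any real tissue. The spectral decorrelation of real-tissue
crosstalk across a sweep is unknown to us; both implemented limits bracket
it.

## Study conditions and problem sizes

The validation suite runs the statistical studies at sizes chosen once, as
a balance between estimator stability and desk-scale runtime, and holds
them fixed:

* $M^{-1/2}$ scaling: 32×32×48 stacks, $M \in \{4,16,64,256\}$, 20 seed
  replicates; slope tolerance ±0.05.
* Suppression at the fiber mode count: 846 masks, 32×32×16 stacks,
  replicate-averaged "before" reference.
* $G$-matrix: 16×16 ROI (K = 256), 256 masks, weak diffuser
  ($\mu = 0.001$/µm over 150 µm) over a strong reflector, SLM tiles of
  2 px — an operating point where coherent illumination is visibly
  corrupted and the STOC/coherent diagonality ratio is stably ≈ 10.
* Rician trend: 32×32×64, per-k crosstalk, $M \in \{1,4,16,64\}$.
* Attenuation recovery: a two-slab phantom (µ = 0.0015 and 0.003 1/µm,
  200 µm each, 25 µm sub-layers), 64 membrane masks versus a single
  coherent acquisition, fitted on the deeper slab.
* Aberration recovery: 256-sample spectra for dispersion; 64×64 point
  grids for defocus and astigmatism.

## Known limitations

* The crosstalk model is statistical; effects that depend on deterministic
  scattering structure (e.g. wavefront-shaping gains) are out of reach.
* `camera_integrated` mode averages noiseless intensities; saturation and
  finite-full-well effects during on-chip integration are not modeled.
* The Rician fit assumes a single deterministic component per pixel; mixed
  multi-layer statistics within one en-face plane are not separated.
* Sub-aperture defocus assumes a laterally well-correlated object across
  the two half-aperture images; pure speckle fields decorrelate the halves
  and the displacement estimate degrades.
* The kurtosis stage optimizes one B-scan and applies the corrector
  globally, as the processing chain it models does; laterally varying
  dispersion is not representable.
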