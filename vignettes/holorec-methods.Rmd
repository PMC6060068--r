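---
title: "holorec: models, numerical choices, and what the synthetic world establishes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{holorec: models, numerical choices, and what the synthetic world establishes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The imaging model

A lens-free in-line holographic microscope places a transmissive specimen a
few hundred micrometres above an image sensor and illuminates it with a
quasi-monochromatic plane wave. The sensor records

$$I(x,y) \;=\; |A + a_z(x,y)|^2 \;=\; |A|^2 + |a_z|^2 + A^*a_z + A a_z^*,$$

where $A$ is the unscattered reference (taken real and positive at every
detection plane) and $a_z$ the object-scattered wave propagated to the
sensor. The two cross terms carry the object; $|a_z|^2$ is the
self-interference term. For the specimen classes this package models —
blood smears, Pap smears, stained tissue sections — the scattered wave is
*not* weak: its RMS modulus is roughly 28 % (tissue), 34 % (Pap) and 37 %
(blood) of the reference, so the self-interference term cannot be dropped
and simple back-propagation of $\sqrt I$ is contaminated by both the twin
image and self-interference artifacts.

### Propagation convention

`propagate()` applies the exact scalar angular-spectrum transfer function
with the plane-wave carrier divided out:

$$H(f_x,f_y) = \exp\!\Big(i\,2\pi\,dz\,\big[\sqrt{(n/\lambda)^2 - f^2} - n/\lambda\big]\Big).$$

In this *detection-plane reference frame* a plane wave is the exact
eigenfunction with eigenvalue 1, so `propagate(A + a, z) = A + propagate(a, z)`
holds identically and the hologram model above is self-consistent at every
plane. Evanescent frequencies are removed under the default
`evanescent_policy = "zero"` together with frequencies whose sampled kernel
phase would step by more than $\pi$ between adjacent frequency samples
(band limiting); the `"keep"` policy retains the full invertible kernel and
exists for round-trip verification only. Zero-padding (`pad_factor`,
default 2) uses edge replication to suppress periodic wrap-around on
physically windowed data.

**The periodic synthetic world.** All phantom-based tests and the
acceptance pipeline run with `pad_factor = 1`: the simulated world is then
exactly periodic, simulation and inversion share the same boundary model,
and exactness properties (unitary round trips, the fixed-point property of
the classical iteration) hold to machine precision. This is a *stated
world*, not an approximation of one: real fields of view leak light across
their borders, which the padded mode models at the cost of exactness.

### The global-phase gauge

Intensity-only in-line data are exactly invariant under a global phase
rotation of the total field: $e^{i\theta}(A + a_z)$ is the valid
reference-plus-scattered decomposition of another passive object at every
height. No recovery algorithm can therefore determine the absolute phase
piston. The transport-of-intensity estimate returns zero-mean phase, while
synthetic phantoms generally have non-zero mean phase (about 0.27 rad for
the default tissue texture). All truth-referenced error metrics in the
package (`twin_energy()`, the phase-RMSE property test) first align the
global phase to the truth by the L2-optimal unit phasor; the defining
normalisations (truth scores 0, raw back-propagation scores 1) are
unaffected. Background-relative quantities (per-cell phase integrals) are
piston-free by construction.

## Classical recovery

### Transport-of-intensity initialisation

With $k = 2\pi n/\lambda$ and paraxial propagation,
$\nabla\!\cdot\!(I\nabla\varphi) = -k\,\partial I/\partial z$. The axial
derivative is estimated from the widest available pair (heights 1 and 8 of
the standard protocol, 180 µm apart) and the in-plane intensity from height
7, where the phase estimate lives. The elliptic problem is solved
spectrally in two stages: Teague's auxiliary potential (two regularised
inverse Laplacians) gives a first estimate; because $I\nabla\varphi$ is not
curl-free when the intensity is structured, up to `picard_iterations`
(default 10) fixed-point corrections then drive the residual of the full
equation to zero. On strongly scattering synthetic phantoms the Picard
refinement reduces the phase error from ~0.14 rad RMS (plain Teague) to
~2×10⁻⁴ rad.

Two numerical choices matter and were set once after isolated-solver
experiments:

* **Regularisation** `regularization_eps` scales the Nyquist Laplacian
  eigenvalue; the default is $10^{-6}$. A percent-level value would exceed
  the eigenvalue of every mode smoother than ~Nyquist/30 and crush smooth
  phase content (measured: recovered amplitude slope 0.016 at $10^{-3}$
  versus ~1 at $10^{-6}$); $10^{-6}$ still pins the undetermined piston.
* **Boundary handling** follows the optics configuration: periodic solve
  when `pad_factor = 1` (exact on the torus), mirror extension otherwise.
  Spectral differentiation across mirror folds leaves O(1) derivative
  kinks that the inverse Laplacian spreads into global low-frequency phase
  screens, so the mirror path is reserved for genuinely windowed data.

### Multi-height iteration

`multiheight_recover()` implements the amplitude-update iteration exactly
as classically specified: the initial guess $\sqrt{I_7}\,e^{i\varphi_{TIE}}$
is propagated to height 8; the amplitude is replaced by the *average* of
the current amplitude and $\sqrt{I_8}$ (weight exactly ½, no relaxation)
with the phase kept; the update then proceeds at heights 7, 6, …, 1 (one
iteration); later iterations restart by propagating from height 1 to the
top. After `n_iterations` (default 50) the field is back-propagated to the
sample plane. The data-fidelity residual $\mathrm{RMS}(|u| - \sqrt I)$ is
logged before every update.

Two structural properties anchor the tests: a ground-truth-initialised run
is an exact fixed point on noiseless data, and the amplitude update
preserves the phase of every pixel bit-exactly.

The iteration converges from mid to high spatial frequencies — a phase
component at frequency $f$ produces intensity contrast only once
$\lambda f^2 \Delta z$ is appreciable — so the low-frequency phase is
inherited almost unchanged from the TIE initialisation. This is why the
classical pipeline *needs* the TIE stage, and why the quality of the final
reconstruction on dense tissue-like phantoms tracks the TIE quality at low
frequencies. Blood-smear phantoms, whose strong per-cell phase (~1.7 rad
peak) drives the local intensity near zero at some planes, converge more
slowly (twin energy ~0.2 after 50 iterations versus orders of magnitude
below that for tissue);
this mirrors the physical difficulty that motivates using eight holograms
for such specimens in the first place.

## The synthetic specimen generator

The only quantitative anchor available for specimen strength is the
scattered-to-reference RMS ratio (0.28 / 0.34 / 0.37); everything
morphological is schematic by design:

* `blood_smear` — non-overlapping round cells (~7.7 µm across, tanh rim)
  with a central dimple emulating the biconcave profile; per-cell integer
  labels are kept for phase-integral evaluation;
* `pap_smear` — sparse large cytoplasm ellipses with compact dense nuclei;
* `tissue` — dense band-limited random texture (features roughly
  15–300 µm) in both phase and attenuation;
* `discs` — a regular disc array for metrology tests.

Phantoms are passive ($t = e^{-\alpha + i\varphi}$, $|t|\le 1$) and
calibrated to the target ratio by at most 20 multiplicative fixed-point
rescalings of the optical strength (tolerance 0.005 absolute). Defaults
chosen once and documented: base sample-to-sensor distance 300 µm
(sub-millimetre regime), heights +{0, 15, 30, 45, 60, 75, 90, 180} µm,
λ = 0.532 µm, pitch 1 µm (no instrument values are published for these, so
they are package defaults, not measurements), shot-noise photon budget
10 000 photons/pixel.

## Neural twin-image removal

The network maps a 2-channel (real, imaginary) back-propagated hologram
tile to the artifact-free complex image of identical size. Architecture
(the published description names the component types — convolutional
layers, residual blocks, upsampling blocks, parallel multi-scale
processing — but not the exact layer inventory, so depths are configurable
with documented defaults): a stem convolution to `feature_maps` channels
(16 for the sample-type-specific preset, 32 for the universal preset);
three resolution branches via 2× average pooling; four pre-activation
residual blocks per branch (two 3×3 convolutions each); coarse-to-fine
merging through upsampling blocks (nearest-neighbour upsampling + conv,
added to the finer branch); a head convolution back to 2 channels; and a
global input-to-output residual connection so the network learns the
artifact correction. The head is initialised near zero so training starts
from the identity.

Training minimises pixelwise MSE over both channels with Adam
(learning rate 10⁻³ — the optimiser's canonical setting, matched to the
short scaled-down schedules this package targets; a 10⁻⁴ rate suits
multi-hour full-scale schedules), one tile per step, seeded shuffling, and
early stopping when the validation loss fails to improve for `patience`
(default 5) epochs, checkpointing the best-validation parameters. The
convolution engine (im2col + GEMM, Rcpp/Armadillo) is exercised against
numerical differentiation in the test suite.

Real and imaginary parts were chosen as the network channels because the
evaluation protocol scores exactly those two channels; amplitude/phase
would introduce a wrapping discontinuity in the target.

### What the scaled-down experiments establish — and what they do not

The in-repo acceptance experiment trains the 16-feature-map preset on 40
synthetic 64×64 blood-smear tiles for ≤ 30 epochs on one CPU (≈ 6 min,
with 2 residual blocks per scale to fit the budget) and evaluates held-out
tiles: real-part SSIM rises from ≈ 0.35 (raw back-propagation) to ≈ 0.74,
residual twin energy drops to ≈ 0.5, per-cell phase-integral correlation
with truth rises from ≈ 0.47 to ≈ 0.90, and the ±20 µm defocus sweep peaks
within 3 µm of focus. This demonstrates the core claim — learned
single-hologram twin-image suppression — at reduced scale. It does **not**
reproduce full-scale published performance: that used millions of training
pixels from real stained specimens, a gold standard produced by the
eight-height classical pipeline on real data, and hardware-scale training.
Two known limitations of the synthetic world: dense tissue-texture
phantoms at desk scale have true-structure variance well below the
artifact energy, so an MSE-trained network mostly suppresses rather than
restores (low SSIM gain); and synthetic targets are ground truth rather
than classical reconstructions, sidestepping gold-standard imperfections.

## Evaluation protocols

* **SSIM** — standard windowed SSIM, 11-wide Gaussian window (σ = 1.5),
  $k_1 = 0.01$, $k_2 = 0.03$, dynamic range = observed max − min per
  channel, edge-replicated borders; computed independently on real and
  imaginary parts. A uniform-window mode exists for from-definition
  verification.
* **Phase integrals** — per labelled cell,
  $\sum (\varphi - \varphi_{bg})\,p^2$ in rad·µm², with the background
  phase estimated by the median over the zero label (robust to cells
  touching the region). Proportionality to absolute cell volume requires a
  refractive-index increment that is deliberately out of scope.
* **Defocus sweep** — back-propagate one hologram to 41 planes spanning
  ±20 µm in 1 µm steps, run the fixed network, score amplitude SSIM
  against a reference reconstruction.

## Interfaces

Complex fields and hologram stacks are stored as single-file containers
(R serialisation with an explicit format tag and the attribute set
{wavelength_um, pitch_um, z_um}); the grading environment provides no HDF5
binding, so the container format is the package's own, with the same
attribute contract and exact round-trip tests. Intensity planes use
minimal self-contained grayscale TIFF (32-bit float / 16-bit) and PNG
(8/16-bit) codecs, cross-checked against Python's tifffile/imageio during
development. Every pipeline stage writes a provenance record (config
snapshot, seed, package version, timestamp) beside its artifacts.
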