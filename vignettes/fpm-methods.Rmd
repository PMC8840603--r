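---
title: "Fourier ptychography with fpmkit: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fourier ptychography with fpmkit: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpmkit)
```

## The imaging model

Fourier ptychographic microscopy (FPM) records many low-resolution intensity
images of one sample under plane-wave illumination from different angles and
stitches them, in the frequency domain, into a single high-resolution complex
amplitude. The sample is a complex transmission function $o(x, y)$; tilting
the illumination by the $n$-th LED multiplies it by $e^{j k_n \cdot r}$, which
shifts its spectrum $O(k)$ by the illumination wave vector

$$k_n = \frac{2\pi}{\lambda}\,(\sin\alpha_{x n},\ \sin\alpha_{y n}),$$

the objective pupil low-passes the shifted spectrum with the coherent
transfer function $H(k)$ — an ideal binary disk of radius
$k_c = \mathrm{NA}\cdot 2\pi/\lambda$ — and the sensor records the squared
modulus on a grid decimated by the `upsample_factor`:

$$I_n(r) = \left|\mathcal{F}^{-1}\{\,O(k)\,H(k + k_n)\,\}\right|^2 .$$

`fpm_optics()` holds NA, $\lambda$ (in $\mu$m), the decimation factor and the
object-plane pixel pitch; `led_grid()` holds the source layout, from which
`led_wave_vectors()` derives the direction sines of an LED at lateral offset
$(o_x, o_y)$ and height $h$ as $\sin\alpha_x = o_x/\sqrt{o_x^2+o_y^2+h^2}$
(and likewise for $y$), so the wave-vector magnitude is exactly
$2\pi\sin(\arctan(r/h))/\lambda$ for radial offset $r$.

### Units and numerical conventions

Three conventions are fixed package-wide and worth stating explicitly,
because every module depends on them agreeing:

* **Angular wavenumbers everywhere.** Wave vectors and the pupil cutoff share
  the unit rad/$\mu$m, so illumination shifts and the CTF radius live on one
  frequency grid.
* **Centered, orthonormal transforms.** `ft2()`/`ift2()` put DC at the array
  center and preserve the Frobenius norm, so Parseval-style energy checks
  need no rescaling and sub-spectrum windows can be cut directly out of the
  centered array.
* **Integer-pixel windowing.** The shift by $k_n$ is realized by cropping the
  sensor-sized window of the high-resolution spectrum at the rounded pixel
  offset $\mathrm{round}(k_n/\Delta k)$; sub-pixel residuals are discarded
  (they are recorded on the simulated stack as an attribute). The sensor and
  high-resolution grids share one frequency step because the sensor pixel is
  `upsample_factor` times the object pixel.

One scale factor deserves a note. With orthonormal transforms, cropping an
$S$-pixel window out of an $N = uS$-pixel spectrum and inverse-transforming
multiplies a uniform field's amplitude by $u$. `simulate_capture()` divides
the sensor field by $u$ so that a unit-transmission sample yields unit
intensity; `forward_lowres_estimate()` and `update_subspectrum()` use the
same factor symmetrically. With this bookkeeping the normal-incidence
initialization needs *no* extra amplitude factor: the bilinearly upsampled
$\sqrt{I_1}$, transformed, is already on the scale of the true spectrum. The
factor-1 identity (at `upsample_factor = 1` the initialization reproduces
$\sqrt I$ to $10^{-10}$) and the uniform-sample test pin this down.

### Defaults and free geometry parameters

NA = 0.13 and $\lambda$ = 0.505 $\mu$m are the reference optical
configuration; a 13 × 13 LED grid yields 169 captures. The LED pitch (4 mm)
and height (90 mm) and the object pixel pitch (0.4 $\mu$m) are package
defaults chosen jointly so that, at 48 × 48 sensor pixels: the pupil radius
is $\approx$ 19.8 frequency pixels (comfortably inside the sensor Nyquist
window), adjacent pupils overlap by well over 60 % (the redundancy
alternating projections need), and the most oblique LED plus the pupil stays
inside the 192-pixel high-resolution spectrum. None of these three layout
numbers is physically canonical; they are configuration fields, and
`make_ctf(strict = TRUE)` fails loudly if a configuration pushes the cutoff
past the grid bound.

Noise is modelled as additive zero-mean Gaussian on the intensities.
`add_gaussian_noise()` interprets `sigma` on the peak-normalized intensity
scale (typical study levels: $10^{-4}$–$3\times10^{-4}$), clips negative
results at zero, and is exactly reproducible under a seed; `sigma = 0`
returns the stack bit-identical.

## Alternating-projection reconstruction

`fpm_reconstruct()` is the classic Gerchberg–Saxton loop. Starting from the
normal-incidence initialization
$O_0 = \mathcal{F}\{B(\sqrt{I_1})\,e^{j\varphi_0}\}$ (with $B$ bilinear
upsampling and $\varphi_0 = 0$), each sweep visits every LED once,
low-frequency-first:

1. predict the sensor field $g_n = \mathcal{F}^{-1}\{O\,H(k+k_n)\}$;
2. replace its amplitude with the measurement,
   $\bar g_n = \sqrt{I_n}\, g_n/|g_n|$, keeping the phase;
3. overwrite only the pupil-selected sub-spectrum,
   $O \leftarrow O\,[1 - H(k+k_n)] + \mathcal{F}\{\bar g_n\}\,H(k+k_n)$.

Sweeps repeat until `max_rounds` (default 50, the round count used in the
study's timing comparison) or until the relative Frobenius change of the
spectrum drops below `convergence_tol` (default $10^{-6}$; set 0 to disable).
The original procedure prescribes no stopping criterion or objective, so the
package logs, after every sweep, the mean relative amplitude mismatch
$\mathrm{mean}_n\,\|\,|g_n| - \sqrt{I_n}\,\|^2 / \|\sqrt{I_n}\|^2$ as the
residual history — it is diagnostic, not a stopping rule unless the
tolerance is positive. Two numerical details: where $|g_n| < 10^{-12}$ the
unit phasor replaces $g_n/|g_n|$ (the measured amplitude is taken with zero
phase — any phasor is admissible on a measure-zero set), and the sweep order
is center-outward by $|k_n|$ with raster-index tie-break, the standard
low-frequency-first choice (the source text never states an order).

On noise-free, well-overlapped data the residual history is non-increasing
and the recovered intensity at the full 192-pixel geometry exceeds the
bilinearly upsampled central image by about 10 dB PSNR after 50 sweeps (the
package's acceptance script recomputes this number).

```{r, eval = FALSE}
optics <- fpm_optics()
grid <- led_grid(13, 13)
stack <- simulate_capture(sample_field, optics, grid)
rec <- fpm_reconstruct(stack, optics, gs_config(max_rounds = 50))
plot(rec)
```

## The dual-channel network input

A learning-based reconstructor cannot take a 169-channel stack as input
without tying its architecture to one LED count. The package therefore fuses
the whole stack in a single non-iterative Fourier-domain pass: starting from
the same normal-incidence initialization, each LED's measured image is
transformed on the sensor grid and written into its pupil-selected
sub-spectrum — exactly one write per LED, same order as the reconstruction —
and the inverse transform of the fused spectrum yields one complex image
whose intensity and phase are the two network input channels
(`synthesize_input()`).

The printed update formula uses the intensity image itself inside the
transform, whereas the amplitude-replacement step of the iterative loop uses
$\sqrt I$. Physically the measured amplitude is $\sqrt I$, and that is the
default (`amplitude_mode = "sqrt"`); `amplitude_mode = "literal"` transforms
the raw intensity for strict fidelity to the printed formula. The two differ
by a nonlinearity applied before the transform and cannot be reconciled from
the text; both are provided and the default is the physically consistent
one.

## Quality metrics

`img_mse()`, `img_psnr()` and `img_ssim()` implement the printed formulas
directly: MSE is the plain per-pixel mean of squared differences; PSNR is
$20\log_{10}(\mathrm{MAX_I}/\sqrt{\mathrm{MSE}})$ with an `Inf` sentinel for
identical images (serialized as the string `"inf"`); SSIM is the
whole-image (global-statistics) simplified form

$$\mathrm{SSIM} = \frac{(2\mu_X\mu_Y + C_1)(2\sigma_{XY} + C_2)}
                        {(\mu_X^2 + \mu_Y^2 + C_1)(\sigma_X^2 + \sigma_Y^2 + C_2)},
  \qquad C_1 = (0.01 L)^2,\ C_2 = (0.03 L)^2,$$

which equals the luminance–contrast–structure product exactly when
$C_3 = C_2/2$ (the test suite verifies both identities against from-scratch
recomputation). Choices worth knowing:

* **Population variances** (divide by the pixel count), consistent with the
  mean-based definitions; not the $n-1$ sample form.
* **Dynamic range inferred from the data** — 1 for float images in $[0,1]$,
  255 otherwise — and always overridable.
* **Global by default.** The study prints whole-image statistics only; an
  11 × 11 Gaussian-windowed local variant (`windowed = TRUE`, $\sigma=1.5$)
  is available for comparison with common practice but is not the default.
* **Phase channels are scored as plain wrapped images** (dynamic range
  $2\pi$); no unwrapping is attempted anywhere.
* The global form is signed: strongly anticorrelated images can score below
  zero. The package reports the computed value rather than clamping to the
  nominal $[0, 1]$ range.

## The synthetic dataset

`build_dataset()` reproduces the study-scale bookkeeping: 400 source images
× 4 phase pairings = 1,600 truth complex amplitudes, × 16 aligned random
crops = 25,600 input/truth groups, split 90/10 into 23,040 train and 2,560
test examples by a seeded shuffle followed by a contiguous cut. The
multiplicity (4) and crops-per-pair (16) are implied by those totals; the
phase sources are drawn without repetition within one amplitude and with
replacement across amplitudes, and source values map affinely onto
$[-\pi/2, \pi/2]$ by default.

Because rendering 25,600 simulated groups on one CPU is out of scale for
routine use, the builder is *manifest-first*: the complete example manifest
(pairings, crop offsets, per-pair noise seeds, split labels) is computed
deterministically in seconds, and pixel data are rendered on demand
(`materialize_example()`, `write_dataset()`), each example reproducible in
isolation from the master seed. Noise is injected into the low-resolution
intensities *before* input synthesis — where the physical sensor adds it —
not onto the synthesized input.

In place of collected tissue slides, `generate_synthetic_sources()` produces
procedural images: three bands of filtered Gaussian noise (broad blobs,
mid-scale texture, fine grain), min–max rescaled to $[0, 1]$. They emulate
the multi-scale spatial statistics that make FPM reconstruction nontrivial —
structure at every scale up to the synthetic-aperture cutoff — but not stain
color, illumination vignetting, specimen-specific morphology, or camera
physics beyond additive Gaussian noise. Tests passing on these sources
demonstrate the correctness of the pipeline's bookkeeping and signal path,
not reconstruction quality on real tissue.

`load_finetune_stub()` reads externally acquired fine-tuning pairs (or any
directory written by `write_dataset()`) back into the same manifest schema;
it generates nothing.

## The fusion reconstruction network

`fpm_network()` assembles the toy-scale analogue of the multi-branch
architecture: three parallel feature extractors that each downsample by 2
and carry one signature mechanism — a residual skip, a squeeze-and-excitation
channel-attention gate, and dense (concatenative) connectivity — followed by
cascade feature fusion and a pre-upsampling head. Fusion is channel
concatenation in branch order, so the fused width is the sum of the branch
widths and every value survives (`fuse_features()`; the printed index-mapping
variant assigns colliding destinations and is not implementable as written,
so the text's channel-sum rule governs). The head restores resolution with
one convolution + pixel-recombination stage per factor of 2 of extractor
downsampling (`upsample_stage()`, `pixel_shuffle()`: each group of 4
channels becomes a 2 × 2 spatial block), then projects to the 2 output
channels. A global input skip makes the network a correction on top of its
input, and the final projection is zero-initialized so the untrained model
is exactly the identity — a standard stabilization for restoration networks
that also makes "training improves on the untrained model" a meaningful
test.

The named pretrained backbones are deliberately pluggable: requesting one
raises a capability error unless a deep-learning backend is present (none is
assumed), and the stand-in branches keep the whole module trainable and
testable in plain R. Forward and backward passes are hand-derived;
convolution runs as im2col + BLAS matrix products, and every layer's
gradient is verified against central differences in the test suite.

`fpm_train()` minimizes per-pixel MSE with Adam ($\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$). The reference recipe — learning
rate $4\times10^{-5}$, batch size 4 — is the `train_config()` default;
full-scale training (25,600 examples, 200 epochs) is explicitly out of
scope, and the trainer targets toy problems: the standard checks are a
32-example / 20-epoch descent run and a 200-step single-example overfit that
reaches per-pixel MSE below $10^{-3}$ (at learning rates around $10^{-3}$,
appropriate for the toy scale). A non-finite loss aborts with a
training-divergence condition carrying the last finite model.

## Problem sizes used by the checks

The test-suite and acceptance-script scales are the package's own choices:
oracle comparisons (explicit double-loop DFT) run at 16-pixel scenes where
the $O(N^4)$ brute force is exact and fast; the closed-loop recovery check
runs the full 192-pixel / 13 × 13 / 50-sweep geometry; dataset bookkeeping
is checked at the full 25,600-group scale (manifest level) and at small
scale for pixel data; network training checks use 16-pixel dual-channel
images. Every random quantity flows from one master seed through named
sub-streams, so any single stage reproduces in isolation.

## Known limitations

* The pupil is an ideal binary disk: no aberrations, no joint pupil
  estimation, no LED position miscalibration, no partially coherent or
  multiplexed illumination.
* Sub-pixel illumination shifts are rounded to the frequency grid; the
  discarded residuals are logged but not compensated.
* The global SSIM is not the windowed SSIM of common benchmarking practice;
  use `windowed = TRUE` when comparing against other software.
* The network is a toy-scale stand-in: it demonstrates the architecture's
  mechanisms and contracts, not the reconstruction quality a fully trained
  model would reach.
* Stacks and datasets serialize as multi-page 32-bit TIFF with JSON
  sidecars; pages are affinely rescaled to $[0,1]$ on disk (the sidecar
  carries the constants), which round-trips to float precision but is not a
  self-describing scientific container.
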