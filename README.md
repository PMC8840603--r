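# fpmkit

Fourier ptychographic microscopy (FPM) recovers wide-field, high-resolution,
quantitative-phase images from many low-resolution intensity captures taken
under angled LED illumination. Each LED at angle $(\alpha_x, \alpha_y)$
shifts the sample spectrum $O(k)$ by
$k_n = 2\pi(\sin\alpha_x, \sin\alpha_y)/\lambda$; the objective pupil
$H(k)$ — an ideal disk of radius $\mathrm{NA}\cdot 2\pi/\lambda$ — low-passes
it, and the sensor records

$$I_n(r) = \left|\mathcal{F}^{-1}\{O(k)\,H(k + k_n)\}\right|^2 .$$

Because many shifted pupil windows overlap, alternating projections between
the measured amplitudes (spatial domain) and the pupil support (frequency
domain) recover the complex field far beyond the objective's native
resolution.

`fpmkit` is an R toolkit for the full computational loop, aimed at people
developing or teaching FPM reconstruction methods:

* **Forward model** — `fpm_optics()`, `led_grid()`, `simulate_capture()`,
  `add_gaussian_noise()`: simulate the multi-angle acquisition with an ideal
  coherent transfer function.
* **Reconstruction** — `fpm_reconstruct()`: the alternating-projection
  (Gerchberg–Saxton) loop, returning a classed object with
  `print`/`summary`/`plot`/`residuals` methods.
* **Network input synthesis** — `synthesize_input()`: one non-iterative
  Fourier-domain pass that fuses any number of LED captures into a
  dual-channel (intensity, phase) image, the input representation of a
  learning-based reconstructor.
* **Metrics** — `img_mse()`, `img_psnr()`, `img_ssim()`,
  `quality_report()`: the printed-formula scores, with global SSIM by
  default and a Gaussian-windowed variant behind a flag.
* **Dataset builder** — `generate_synthetic_sources()`,
  `build_truth_pairs()`, `build_dataset()`: seeded procedural sources,
  random intensity/phase pairing (400 × 4 → 1,600 truth fields), aligned
  random crops (× 16 → 25,600 groups) and a 90/10 split (23,040 / 2,560),
  manifest-first with on-demand rendering.
* **Reconstruction network** — `fpm_network()`, `fpm_train()`, `predict()`:
  a toy-scale three-branch extractor (residual / channel-attention / dense
  mechanisms) with cascade feature fusion, a pixel-recombination upsampling
  head, and a hand-derived Adam/MSE trainer in plain R.
* **Pipeline & CLI** — `fpm_load_config()`, `fpm_run()` and a thin
  `inst/exec/fpmkit` script: validated YAML/JSON configs, seeded dispatch,
  artifacts stamped with config hash and seed.

## Worked example

Simulate a 192 × 192 complex scene at the reference geometry (NA 0.13,
λ = 0.505 µm, 13 × 13 LEDs, 48 × 48 captures), reconstruct it, and score the
result:

```r
library(fpmkit)

optics <- fpm_optics()          # NA 0.13, 0.505 um, 4x decimation, 0.4 um px
grid <- led_grid(13, 13)

src <- generate_synthetic_sources(2, 192, seed = 11)
truth <- field_from_images(0.2 + 0.8 * src[[1]],        # amplitude in [0.2, 1]
                           (src[[2]] - 0.5) * pi / 2,   # phase in [-pi/4, pi/4]
                           0.4)
stack <- simulate_capture(truth, optics, grid)
stack
#> Low-resolution stack: 169 images of 48 x 48  noise sigma 0

rec <- fpm_reconstruct(stack, optics, gs_config(max_rounds = 50))
rec
#> FPM alternating-projection reconstruction
#>   field: 192 x 192 px  ( 0.4 um/px )
#>   rounds: 20   final residual: 7.29e-12

pred <- dual_channel(field_intensity(rec$field), field_phase(rec$field))
ref  <- dual_channel(field_intensity(truth), field_phase(truth))
quality_report(pred, ref, max_i = max(ref$intensity), l = max(ref$intensity))
#> Quality report (MAX_I = 1 , L = 1 )
#>   intensity MSE 0.0008056  PSNR 30.94 dB  SSIM 0.9651
#>   phase     MSE 0.002322  PSNR 42.30 dB  SSIM 0.9454
```

The reconstruction stopped after 20 sweeps (relative spectrum change below
the default tolerance of 1e-6) with the measured amplitudes matched to
~1e-12 relative. For scale: bilinearly upsampling the central capture scores
only 20.36 dB intensity PSNR against the same truth, so the
alternating-projection loop contributes about 10.6 dB. `plot(rec)` shows
the recovered amplitude, phase, and the residual history.

The same loop runs from the shell:

```sh
Rscript inst/exec/fpmkit demo --seed 11 --out report.json
```

## Documentation

`vignette("fpm-methods")` describes the imaging model and its conventions
(wavenumber units, centered orthonormal transforms, integer-pixel spectrum
windowing, scale bookkeeping), the reconstruction and input-synthesis
procedures, the metric definitions, what the synthetic sources do and do not
emulate, the network design, and the package's known limitations.
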