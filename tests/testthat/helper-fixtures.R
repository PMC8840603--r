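# Shared fixtures: small optical scenes and brute-force Fourier oracles.
# The naive transforms evaluate the centered DFT by explicit double loops and
# are deliberately independent of the package's fft-based path.

naive_ft2 <- function(x) {
  n <- nrow(x)
  c0 <- n %/% 2 + 1
  out <- matrix(0 + 0i, n, n)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    acc <- 0 + 0i
    for (m in seq_len(n)) for (l in seq_len(n)) {
      acc <- acc + x[m, l] *
        exp(-2i * pi * ((p - c0) * (m - c0) + (q - c0) * (l - c0)) / n)
    }
    out[p, q] <- acc / n
  }
  out
}

naive_ift2 <- function(x) Conj(naive_ft2(Conj(x)))

# Brute-force forward model: same discretization conventions as the package
# (integer-pixel window shifts, ideal disk pupil, sensor field divided by the
# upsample factor) but every transform is an explicit double-loop DFT.
naive_capture <- function(sample, optics, grid) {
  n <- sample$side
  u <- optics$upsample_factor
  s <- n %/% u
  dk <- 2 * pi / (n * sample$pixel_um)
  kc <- ctf_cutoff(optics)
  ax <- ((seq_len(s)) - (s %/% 2 + 1)) * dk
  mask <- (outer(ax^2, ax^2, "+") <= kc^2) * 1
  spectrum <- naive_ft2(sample$values)
  k <- led_wave_vectors(grid, optics$wavelength)
  c_hi <- n %/% 2 + 1
  c_lo <- s %/% 2 + 1
  lapply(seq_len(nrow(k)), function(i) {
    sh <- round(k[i, ] / dk)
    rows <- (c_hi - sh[2]) - c_lo + seq_len(s)
    cols <- (c_hi - sh[1]) - c_lo + seq_len(s)
    g <- naive_ift2(spectrum[rows, cols] * mask) / u
    Mod(g)^2
  })
}

# A tissue-like complex scene on an n x n grid.
make_scene <- function(side, pixel_um, seed = 1,
                       amp_range = c(0.2, 1), phase_scale = pi / 4) {
  src <- generate_synthetic_sources(2, side, seed)
  field_from_images(amp_range[1] + diff(amp_range) * src[[1]],
                    (src[[2]] - 0.5) * 2 * phase_scale, pixel_um)
}

# A real nonnegative sample strictly band-limited inside the pupil of the
# given optics at the given sensor side.
make_bandlimited_sample <- function(optics, sensor_side, seed = 1) {
  u <- optics$upsample_factor
  side <- sensor_side * u
  ctf <- make_ctf(optics, sensor_side)
  set.seed(seed)
  base <- matrix(rnorm(sensor_side^2), sensor_side, sensor_side)
  # shrink the passband slightly so interpolation effects stay in-band
  ax <- freq_axis(sensor_side, optics$object_pixel_um * u)
  tight <- (outer(ax^2, ax^2, "+") <= (0.8 * ctf$cutoff)^2) * 1
  lo <- Re(ift2(ft2(base) * tight))
  lo <- lo - min(lo) + 0.1
  # place on the high-res grid through the frequency domain (exact embed)
  if (u == 1) return(field_from_images(lo, pixel_um = optics$object_pixel_um))
  spec_lo <- ft2(lo)
  spec_hi <- matrix(0 + 0i, side, side)
  c_hi <- side %/% 2 + 1
  c_lo <- sensor_side %/% 2 + 1
  idx <- c_hi - c_lo + seq_len(sensor_side)
  spec_hi[idx, idx] <- spec_lo
  complex_field(ift2(spec_hi) * u, optics$object_pixel_um)
}

# Tiny restoration task for the network: recover a sharp dual-channel image
# from its 3x3 box-blurred version.
toy_dataset <- function(n, side = 16L, seed = 1) {
  blur <- function(m) fpmkit:::filter2_same(m, matrix(1 / 9, 3, 3))
  srcs <- generate_synthetic_sources(2 * n, side, seed)
  lapply(seq_len(n), function(i) {
    truth <- array(c(srcs[[2 * i - 1]], (srcs[[2 * i]] - 0.5)),
                   c(side, side, 2))
    input <- array(c(blur(truth[, , 1]), blur(truth[, , 2])),
                   c(side, side, 2))
    list(input = input, truth = truth)
  })
}

# Small optics used across tests: 16 -> 8 px decimation with a mid-sized pupil.
tiny_optics <- function(upsample = 2L)
  fpm_optics(na = 0.25, wavelength = 0.5, upsample_factor = upsample,
             object_pixel_um = 0.5)
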