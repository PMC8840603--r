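test_that("initialization: constant image gives a DC delta; factor 1 is exact", {
  optics1 <- fpm_optics(na = 0.25, wavelength = 0.5, upsample_factor = 1,
                        object_pixel_um = 1)
  ctf <- make_ctf(optics1, 16)
  img <- matrix(1, 16, 16)
  stack <- lowres_stack(list(img), matrix(0, 1, 2))
  est <- initialize_spectrum(stack, ctf, gs_config(), optics1)
  c0 <- 16 %/% 2 + 1
  off_dc <- est$spectrum
  off_dc[c0, c0] <- 0
  expect_lt(max(Mod(off_dc)), 1e-10)
  expect_equal(Mod(est$spectrum[c0, c0])^2, sum(Mod(est$spectrum)^2),
               tolerance = 1e-10)
  # factor 1: inverse transform reproduces sqrt(I) exactly
  set.seed(8)
  img2 <- matrix(runif(256, 0.1, 1), 16, 16)
  est2 <- initialize_spectrum(lowres_stack(list(img2), matrix(0, 1, 2)),
                              ctf, gs_config(), optics1)
  expect_equal(Re(ift2(est2$spectrum)), sqrt(img2), tolerance = 1e-10)
  expect_lt(max(abs(Im(ift2(est2$spectrum)))), 1e-10)
})

test_that("a 48 px capture at factor 4 initializes a 192 px spectrum", {
  optics <- fpm_optics()
  stack <- simulate_capture(make_scene(192, 0.4, seed = 1), optics,
                            led_grid(1, 1))
  est <- initialize_spectrum(stack, make_ctf(optics, 48), gs_config(), optics)
  expect_equal(dim(est$spectrum), c(192L, 192L))
})

test_that("initialization requires a normal-incidence capture", {
  optics <- tiny_optics()
  stack <- simulate_capture(make_scene(16, 0.5, seed = 2), optics,
                            led_grid(2, 2))  # even grid: no axial LED
  expect_error(initialize_spectrum(stack, make_ctf(optics, 8), gs_config(),
                                   optics),
               "central")
})

test_that("forward estimate is identity for in-band fields and matches the DFT oracle", {
  optics1 <- fpm_optics(na = 0.25, wavelength = 0.5, upsample_factor = 1,
                        object_pixel_um = 1)
  sample <- make_bandlimited_sample(optics1, 16, seed = 3)
  ctf <- make_ctf(optics1, 16)
  est <- structure(list(spectrum = ft2(sample$values), round = 0L,
                        last_led = 0L, residual_history = numeric(0)),
                   class = "spectrum_estimate")
  g <- forward_lowres_estimate(est, ctf, c(0, 0), optics1)
  expect_equal(g, sample$values, tolerance = 1e-10)
  # oblique case against the naive double-loop DFT
  optics <- tiny_optics()
  scene <- make_scene(16, 0.5, seed = 4)
  est2 <- structure(list(spectrum = ft2(scene$values), round = 0L,
                         last_led = 0L, residual_history = numeric(0)),
                    class = "spectrum_estimate")
  ctf2 <- make_ctf(optics, 8)
  grid <- led_grid(2, 2, pitch_mm = 6, height_mm = 90)
  k <- led_wave_vectors(grid, optics$wavelength)
  slow <- naive_capture(scene, optics, grid)
  for (i in seq_len(nrow(k))) {
    g2 <- forward_lowres_estimate(est2, ctf2, k[i, ], optics)
    expect_equal(Mod(g2)^2, slow[[i]], tolerance = 1e-8)
  }
})

test_that("amplitude replacement keeps phase and enforces measured modulus", {
  set.seed(5)
  g <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  measured <- matrix(runif(64, 0, 2), 8, 8)
  g_bar <- replace_amplitude(g, measured)
  expect_equal(Mod(g_bar)^2, measured, tolerance = 1e-12)
  expect_equal(Arg(g_bar), Arg(g), tolerance = 1e-12)
  # idempotent on consistent data
  expect_equal(replace_amplitude(g, Mod(g)^2), g, tolerance = 1e-12)
  # zero measurement zeroes the field
  expect_equal(replace_amplitude(g, matrix(0, 8, 8)), matrix(0 + 0i, 8, 8))
  # zero-amplitude pixels take the measured amplitude with zero phase
  g0 <- g; g0[1, 1] <- 0
  expect_equal(replace_amplitude(g0, measured)[1, 1],
               sqrt(measured[1, 1]) + 0i)
})

test_that("sub-spectrum update is a local idempotent projector", {
  optics <- tiny_optics()
  scene <- make_scene(16, 0.5, seed = 6)
  ctf <- make_ctf(optics, 8)
  est <- structure(list(spectrum = ft2(scene$values), round = 0L,
                        last_led = 0L, residual_history = numeric(0)),
                   class = "spectrum_estimate")
  k <- c(0.4, -0.4)
  g <- forward_lowres_estimate(est, ctf, k, optics)
  # writing back the unmodified forward estimate changes nothing
  est2 <- update_subspectrum(est, g, ctf, k, optics)
  expect_equal(est2$spectrum, est$spectrum, tolerance = 1e-10)
  # an empty pupil changes nothing, exactly
  ctf0 <- ctf; ctf0$mask[] <- 0
  est3 <- update_subspectrum(est, matrix(1 + 0i, 8, 8), ctf0, k, optics)
  expect_identical(est3$spectrum, est$spectrum)
  # pixels outside the shifted pupil are bit-identical after any update
  g_bar <- replace_amplitude(g, matrix(runif(64, 0.1, 1), 8, 8))
  est4 <- update_subspectrum(est, g_bar, ctf, k, optics)
  win <- fpmkit:::subspectrum_window(16, 8, k, ctf$dk)
  outside <- matrix(TRUE, 16, 16)
  outside[win$rows, win$cols][ctf$mask == 1] <- FALSE
  expect_identical(est4$spectrum[outside], est$spectrum[outside])
  # a single-pixel pupil changes exactly one spectrum pixel
  ctf1 <- ctf; ctf1$mask[] <- 0; ctf1$mask[5, 5] <- 1
  est5 <- update_subspectrum(est, g_bar, ctf1, k, optics)
  expect_equal(sum(est5$spectrum != est$spectrum), 1)
})

test_that("one consistent constraint set is recovered in a single round", {
  optics1 <- fpm_optics(na = 0.25, wavelength = 0.5, upsample_factor = 1,
                        object_pixel_um = 1)
  sample <- make_bandlimited_sample(optics1, 16, seed = 7)
  stack <- simulate_capture(sample, optics1, led_grid(1, 1))
  rec <- fpm_reconstruct(stack, optics1, gs_config(max_rounds = 1))
  low <- Re(ift2(ft2(sample$values) * make_ctf(optics1, 16)$mask))
  expect_equal(Mod(rec$field$values), abs(low), tolerance = 1e-8)
})

test_that("residual history is non-increasing on noise-free stacks", {
  optics <- tiny_optics()
  grid <- led_grid(3, 3)
  for (seed in 1:20) {
    stack <- simulate_capture(make_scene(16, 0.5, seed = seed), optics, grid)
    rec <- fpm_reconstruct(stack, optics,
                           gs_config(max_rounds = 8, convergence_tol = 0))
    expect_true(all(diff(rec$residuals) <= 1e-12),
                info = paste("seed", seed))
  }
})

test_that("reconstruction is deterministic and respects max_rounds", {
  optics <- tiny_optics()
  stack <- simulate_capture(make_scene(16, 0.5, seed = 9), optics,
                            led_grid(3, 3))
  cfg <- gs_config(max_rounds = 5, convergence_tol = 0)
  r1 <- fpm_reconstruct(stack, optics, cfg)
  r2 <- fpm_reconstruct(stack, optics, cfg)
  expect_identical(r1$field$values, r2$field$values)
  expect_identical(r1$residuals, r2$residuals)
  expect_equal(r1$rounds, 5L)
  expect_length(residuals(r1), 5L)
})

test_that("empty stacks are rejected", {
  optics <- tiny_optics()
  expect_error(lowres_stack(list(), matrix(0, 0, 2)))
})
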