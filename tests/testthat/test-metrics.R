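test_that("MSE: identity, unit offset, and the explicit loop oracle", {
  z <- matrix(0, 2, 2)
  expect_equal(img_mse(z, z), 0)
  expect_equal(img_mse(z, z + 1), 1)
  set.seed(1)
  a <- matrix(runif(25), 5, 5)
  b <- matrix(runif(25), 5, 5)
  acc <- 0
  for (i in 1:5) for (j in 1:5) acc <- acc + (a[i, j] - b[i, j])^2
  expect_equal(img_mse(a, b), acc / 25, tolerance = 1e-12)
  expect_error(img_mse(a, matrix(0, 4, 4)), "shape")
})

test_that("PSNR: zero-dB case, 8-bit unit-MSE case, infinity sentinel", {
  z <- matrix(0, 4, 4)
  expect_equal(img_psnr(z, z + 7, max_i = 7), 0)
  # 8-bit images with MSE exactly 1
  a <- matrix(128, 4, 4)
  b <- a; b[] <- a + 1
  expect_equal(img_psnr(a, b, max_i = 255), 20 * log10(255), tolerance = 1e-12)
  expect_identical(img_psnr(a, a, max_i = 255), Inf)
})

test_that("PSNR decreases with noise level on a fixed image", {
  set.seed(2)
  img <- matrix(runif(64^2), 64, 64)
  mean_psnr <- vapply(c(0.01, 0.03, 0.1), function(s) {
    mean(vapply(1:10, function(i) {
      img_psnr(img + matrix(rnorm(64^2, 0, s), 64, 64), img, max_i = 1)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_psnr) < 0))
})

test_that("SSIM equals the from-scratch luminance/contrast/structure product", {
  set.seed(3)
  for (rep in 1:5) {
    a <- matrix(runif(64), 8, 8)
    b <- matrix(runif(64), 8, 8)
    l <- 1
    c1 <- (0.01 * l)^2; c2 <- (0.03 * l)^2; c3 <- c2 / 2
    mx <- mean(a); my <- mean(b)
    sx <- sqrt(mean((a - mx)^2)); sy <- sqrt(mean((b - my)^2))
    sxy <- mean((a - mx) * (b - my))
    lum <- (2 * mx * my + c1) / (mx^2 + my^2 + c1)
    con <- (2 * sx * sy + c2) / (sx^2 + sy^2 + c2)
    str <- (sxy + c3) / (sx * sy + c3)
    expect_equal(img_ssim(a, b, l = 1), lum * con * str, tolerance = 1e-10)
    # the simplified covariance form and the factored form agree exactly
    simplified <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
      ((mx^2 + my^2 + c1) * (sx^2 + sy^2 + c2))
    expect_equal(lum * con * str, simplified, tolerance = 1e-12)
  }
})

test_that("SSIM: perfect similarity, bounds, and symmetry", {
  set.seed(4)
  a <- matrix(runif(64), 8, 8)
  expect_equal(img_ssim(a, a, l = 1), 1, tolerance = 1e-12)
  for (rep in 1:20) {
    x <- matrix(rnorm(64), 8, 8)
    y <- matrix(rnorm(64), 8, 8)
    v <- img_ssim(x, y, l = 1)
    expect_gte(v, -1 - 1e-12)
    expect_lte(v, 1 + 1e-12)
    expect_equal(v, img_ssim(y, x, l = 1), tolerance = 1e-12)
    # nonnegatively correlated images with positive means score in [0, 1]
    xp <- x - min(x) + 0.1
    yp <- xp + matrix(rnorm(64, 0, 0.2), 8, 8)
    vp <- img_ssim(xp, yp - min(yp) + 0.1, l = 1)
    expect_gte(vp, 0)
    expect_lte(vp, 1 + 1e-12)
  }
  set.seed(5)
  m1 <- matrix(runif(64), 8, 8); m2 <- matrix(runif(64), 8, 8)
  expect_equal(img_mse(m1, m2), img_mse(m2, m1), tolerance = 1e-15)
})

test_that("windowed SSIM tracks the global form for identical images", {
  set.seed(6)
  a <- matrix(runif(32^2), 32, 32)
  expect_equal(img_ssim(a, a, l = 1, windowed = TRUE), 1, tolerance = 1e-10)
  b <- a + matrix(rnorm(32^2, 0, 0.1), 32, 32)
  expect_lt(img_ssim(a, b, l = 1, windowed = TRUE), 1)
})

test_that("quality reports score both channels and serialize infinities", {
  optics <- tiny_optics()
  stack <- simulate_capture(make_scene(16, 0.5, seed = 7), optics,
                            led_grid(3, 3))
  inp <- synthesize_input(stack, optics)
  rep_ <- quality_report(inp, inp)
  expect_s3_class(rep_, "quality_report")
  expect_identical(rep_$intensity$psnr, Inf)
  expect_equal(rep_$intensity$ssim, 1, tolerance = 1e-12)
  expect_equal(rep_$constants$c3, rep_$constants$c2 / 2)
  js <- jsonlite::fromJSON(write_quality_report(rep_))
  expect_identical(js$intensity$psnr, "inf")
  expect_equal(js$phase$mse, 0)
})
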