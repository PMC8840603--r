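# Forward imaging model: oblique plane-wave illumination shifts the sample
# spectrum, the objective pupil low-passes it, and the sensor records the
# squared modulus on a decimated grid.

#' Complex sample field
#'
#' The sample transmission function o(x, y): a square complex matrix with a
#' physical pixel pitch. Amplitude is `Mod(values)`, phase `Arg(values)`.
#'
#' @param values square complex (or numeric) matrix, all finite
#' @param pixel_um pixel pitch in micrometers
#' @return an object of class `complex_field`
#' @export
complex_field <- function(values, pixel_um) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("`values` must be a square matrix", call. = FALSE)
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("`values` must be finite", call. = FALSE)
  stopifnot(pixel_um > 0)
  structure(list(values = as.matrix(values) + 0i, side = nrow(values),
                 pixel_um = pixel_um),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat("Complex field:", x$side, "x", x$side, " pixel", x$pixel_um, "um\n")
  cat("  amplitude range [", format(min(Mod(x$values)), digits = 4), ",",
      format(max(Mod(x$values)), digits = 4), "]\n")
  invisible(x)
}

#' Build a complex field from amplitude and phase images
#'
#' @param amplitude,phase square numeric matrices of equal size; `phase` may
#'   be `NULL` for a purely real field
#' @param pixel_um pixel pitch in micrometers
#' @export
field_from_images <- function(amplitude, phase = NULL, pixel_um) {
  if (is.null(phase)) phase <- matrix(0, nrow(amplitude), ncol(amplitude))
  stopifnot(all(dim(amplitude) == dim(phase)))
  complex_field(amplitude * exp(1i * phase), pixel_um)
}

#' Stack of low-resolution intensity captures
#'
#' @param images list of nonnegative numeric matrices, one per LED, all of
#'   one size
#' @param wave_vectors matching `n x 2` matrix of illumination wave vectors
#'   (rad/um), raster order
#' @param noise_sigma standard deviation of Gaussian noise already applied
#'   (0 for a clean stack)
#' @return an object of class `lowres_stack`
#' @export
lowres_stack <- function(images, wave_vectors, noise_sigma = 0) {
  stopifnot(is.list(images), length(images) >= 1,
            is.matrix(wave_vectors), nrow(wave_vectors) == length(images),
            ncol(wave_vectors) == 2)
  side <- nrow(images[[1]])
  for (im in images) {
    if (!is.matrix(im) || !all(dim(im) == c(side, ncol(images[[1]]))))
      stop("all images in a stack must share one shape", call. = FALSE)
  }
  structure(list(images = images, wave_vectors = wave_vectors,
                 noise_sigma = noise_sigma, side = side),
            class = "lowres_stack")
}

#' @export
print.lowres_stack <- function(x, ...) {
  cat("Low-resolution stack:", length(x$images), "images of",
      x$side, "x", x$side, " noise sigma", x$noise_sigma, "\n")
  invisible(x)
}

#' @export
length.lowres_stack <- function(x) length(x$images)

#' Index of the normal-incidence (k = 0) capture in a stack
#' @param stack a `lowres_stack`
#' @export
central_led_index <- function(stack) {
  mag <- sqrt(stack$wave_vectors[, 1]^2 + stack$wave_vectors[, 2]^2)
  i <- which.min(mag)
  if (mag[i] > 1e-9)
    stop("stack contains no normal-incidence (central LED) capture",
         call. = FALSE)
  i
}

# Shared primitive: crop the sensor-sized window of a centered high-res
# spectrum for wave vector k, filter by the pupil, and return the sensor
# field. Division by the upsample factor puts the sensor field on the sample's
# own amplitude scale (a unit sample yields unit intensity), which makes the
# simulate -> initialize -> update loop self-consistent with orthonormal
# transforms.
lowres_field_from_spectrum <- function(spectrum, ctf, k_xy, upsample_factor) {
  win <- subspectrum_window(nrow(spectrum), ctf$side, k_xy, ctf$dk)
  ift2(spectrum[win$rows, win$cols] * ctf$mask) / upsample_factor
}

#' Simulate the FPM acquisition of a sample
#'
#' For each LED the centered sample spectrum is shifted by the illumination
#' wave vector (realized as cropping the sensor-sized sub-window at the
#' rounded pixel offset), filtered by the ideal pupil, inverse-transformed,
#' and recorded as intensity (squared modulus). Deterministic given its
#' inputs.
#'
#' @param sample a `complex_field` whose side is
#'   `upsample_factor * sensor_side`
#' @param optics an `fpm_optics`
#' @param grid a `led_grid`
#' @return a clean `lowres_stack` with one image per LED in raster order
#' @export
simulate_capture <- function(sample, optics, grid) {
  stopifnot(inherits(sample, "complex_field"), inherits(optics, "fpm_optics"),
            inherits(grid, "led_grid"))
  u <- optics$upsample_factor
  if (sample$side %% u != 0)
    stop("sample side must be a multiple of the upsample factor", call. = FALSE)
  sensor_side <- sample$side %/% u
  if (abs(sample$pixel_um - optics$object_pixel_um) > 1e-9)
    stop("sample pixel pitch disagrees with the optical configuration",
         call. = FALSE)
  ctf <- make_ctf(optics, sensor_side)
  k <- led_wave_vectors(grid, optics$wavelength)
  spectrum <- ft2(sample$values)
  images <- vector("list", nrow(k))
  resid <- numeric(nrow(k))
  for (n in seq_len(nrow(k))) {
    g <- lowres_field_from_spectrum(spectrum, ctf, k[n, ], u)
    images[[n]] <- Mod(g)^2
    win <- subspectrum_window(sample$side, sensor_side, k[n, ], ctf$dk)
    resid[n] <- max(abs(win$residual))
  }
  out <- lowres_stack(images, k, noise_sigma = 0)
  attr(out, "subpixel_residual") <- resid  # discarded fractions of k_n / dk
  out
}

#' Add zero-mean Gaussian noise to a stack of intensities
#'
#' `sigma` is interpreted on the peak-normalized intensity scale: the noise
#' standard deviation applied to the raw images is `sigma * max(stack)`.
#' Negative results are clipped at zero. `sigma = 0` returns the stack
#' unchanged, bit for bit.
#'
#' @param stack a `lowres_stack`
#' @param sigma noise standard deviation (normalized intensity units), >= 0
#' @param seed integer seed; the same seed reproduces the same noise
#' @return a `lowres_stack` with `noise_sigma = sigma`
#' @export
add_gaussian_noise <- function(stack, sigma, seed) {
  stopifnot(inherits(stack, "lowres_stack"))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop("`sigma` must be a single nonnegative number", call. = FALSE)
  if (sigma == 0) return(stack)
  scale <- max(vapply(stack$images, max, numeric(1)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  images <- lapply(stack$images, function(im) {
    pmax(im + stats::rnorm(length(im), 0, sigma * scale), 0)
  })
  lowres_stack(images, stack$wave_vectors, noise_sigma = sigma)
}
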