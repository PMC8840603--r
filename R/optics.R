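# Optical system description: objective + illumination geometry. Angular
# wavenumbers k = 2*pi*sin(alpha)/lambda are used throughout so the pupil
# cutoff NA*2*pi/lambda and the illumination shifts live in one unit system
# (rad/um).

#' Optical configuration of the simulated microscope
#'
#' @param na numerical aperture of the objective, in (0, 1)
#' @param wavelength illumination wavelength in micrometers
#' @param upsample_factor integer ratio of the object-grid side to the
#'   sensor-grid side (the synthetic-aperture resolution gain)
#' @param object_pixel_um object-plane pixel pitch in micrometers; the sensor
#'   pixel pitch is `upsample_factor * object_pixel_um`
#' @return an object of class `fpm_optics`
#' @examples
#' fpm_optics()
#' @export
fpm_optics <- function(na = 0.13, wavelength = 0.505, upsample_factor = 4L,
                       object_pixel_um = 0.4) {
  if (!is.numeric(na) || length(na) != 1 || na <= 0 || na >= 1)
    stop("`na` must be a single number in (0, 1)", call. = FALSE)
  if (!is.numeric(wavelength) || length(wavelength) != 1 || wavelength <= 0)
    stop("`wavelength` must be a positive number (micrometers)", call. = FALSE)
  if (!is.numeric(upsample_factor) || length(upsample_factor) != 1 ||
      upsample_factor < 1 || upsample_factor != round(upsample_factor))
    stop("`upsample_factor` must be a positive integer", call. = FALSE)
  if (!is.numeric(object_pixel_um) || length(object_pixel_um) != 1 ||
      object_pixel_um <= 0)
    stop("`object_pixel_um` must be positive (micrometers)", call. = FALSE)
  structure(
    list(na = na, wavelength = wavelength,
         upsample_factor = as.integer(upsample_factor),
         object_pixel_um = object_pixel_um),
    class = "fpm_optics")
}

#' @export
print.fpm_optics <- function(x, ...) {
  cat("FPM optics: NA =", x$na, " lambda =", x$wavelength, "um",
      " upsample x", x$upsample_factor,
      " object pixel", x$object_pixel_um, "um\n")
  cat("  pupil cutoff k_c =", format(ctf_cutoff(x), digits = 4), "rad/um\n")
  invisible(x)
}

#' Pupil cutoff frequency NA * 2 pi / lambda in rad/um
#' @param optics an `fpm_optics` object
#' @export
ctf_cutoff <- function(optics) optics$na * 2 * pi / optics$wavelength

#' Planar LED illumination array
#'
#' LEDs sit on a regular grid centered on the optical axis at distance
#' `height_mm` below the sample. The reference layout is a 13 x 13 array;
#' pitch and height are package defaults (the physical layout of the source
#' is a free design parameter of the simulated instrument).
#'
#' @param rows,cols grid dimensions
#' @param pitch_mm center-to-center LED spacing in millimeters
#' @param height_mm LED-plane-to-sample distance in millimeters
#' @return an object of class `led_grid`
#' @export
led_grid <- function(rows = 13L, cols = 13L, pitch_mm = 4, height_mm = 90) {
  stopifnot(rows >= 1, cols >= 1, rows == round(rows), cols == round(cols),
            pitch_mm > 0, height_mm > 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch_mm = pitch_mm, height_mm = height_mm),
            class = "led_grid")
}

#' @export
print.led_grid <- function(x, ...) {
  cat("LED grid:", x$rows, "x", x$cols, " pitch", x$pitch_mm, "mm",
      " height", x$height_mm, "mm  (", n_leds(x), "LEDs )\n")
  invisible(x)
}

#' Number of LEDs in the grid
#' @param grid a `led_grid`
#' @export
n_leds <- function(grid) grid$rows * grid$cols

#' Raster index <-> (row, col) of an LED
#'
#' LEDs are enumerated row-major: index 1 is (row 1, col 1), index `cols` is
#' (row 1, col `cols`), and so on. These two helpers are exact inverses.
#'
#' @param grid a `led_grid`
#' @param row,col 1-based grid coordinates
#' @export
led_index <- function(grid, row, col) {
  stopifnot(row >= 1, row <= grid$rows, col >= 1, col <= grid$cols)
  (as.integer(row) - 1L) * grid$cols + as.integer(col)
}

#' @rdname led_index
#' @param index 1-based raster index
#' @export
led_rowcol <- function(grid, index) {
  stopifnot(index >= 1, index <= n_leds(grid))
  index <- as.integer(index)
  c(row = (index - 1L) %/% grid$cols + 1L,
    col = (index - 1L) %% grid$cols + 1L)
}

#' Illumination wave vectors of every LED
#'
#' For the LED at lateral offset (ox, oy) from the axis, the direction sines
#' are sin(alpha_x) = ox / sqrt(ox^2 + oy^2 + h^2) (and likewise for y), so
#' the wave-vector magnitude equals 2 pi sin(atan(r/h)) / lambda with r the
#' radial offset. The central LED of an odd x odd grid is exactly on axis.
#'
#' @param grid a `led_grid`
#' @param wavelength wavelength in micrometers
#' @return an `n_leds x 2` matrix of (k_x, k_y) in rad/um, raster (row-major)
#'   order
#' @export
led_wave_vectors <- function(grid, wavelength) {
  stopifnot(inherits(grid, "led_grid"), wavelength > 0)
  rc <- expand.grid(col = seq_len(grid$cols), row = seq_len(grid$rows))
  ox <- (rc$col - (grid$cols + 1) / 2) * grid$pitch_mm
  oy <- (rc$row - (grid$rows + 1) / 2) * grid$pitch_mm
  h <- grid$height_mm
  rr <- sqrt(ox^2 + oy^2 + h^2)
  sin_x <- ox / rr
  sin_y <- oy / rr
  s <- sqrt(sin_x^2 + sin_y^2)
  # direction sines of a physical LED are < 1 by construction; reject
  # effectively grazing geometry (> 87.4 deg) where the model is meaningless
  if (any(s > 0.999))
    stop("LED geometry reaches grazing incidence (|sin alpha| ~ 1)",
         call. = FALSE)
  k <- cbind(kx = 2 * pi * sin_x / wavelength,
             ky = 2 * pi * sin_y / wavelength)
  rownames(k) <- NULL
  k
}

#' Center-outward LED sweep order
#'
#' Returns the permutation of raster indices sorted by increasing wave-vector
#' magnitude (low spatial frequencies first), ties broken by raster index.
#' This is the sweep order used by both the reconstruction and the input
#' synthesis.
#'
#' @inheritParams led_wave_vectors
#' @export
led_order <- function(grid, wavelength) {
  k <- led_wave_vectors(grid, wavelength)
  order(sqrt(k[, 1]^2 + k[, 2]^2), seq_len(nrow(k)))
}

#' Ideal coherent transfer function (pupil) on the sensor frequency grid
#'
#' A binary disk of radius NA * 2 pi / lambda centered on DC. Frequencies are
#' sampled at 2 pi / (side * sensor_pixel) so the sensor grid and the
#' high-resolution grid share one frequency step.
#'
#' @param optics an `fpm_optics`
#' @param sensor_side sensor image side in pixels (>= 2)
#' @param strict if `TRUE`, a cutoff beyond the frequency-grid Nyquist bound
#'   is an error; if `FALSE` it is a warning
#' @return an object of class `pupil_ctf` with fields `mask` (0/1 matrix),
#'   `cutoff` (rad/um), `dk` (frequency step, rad/um) and `side`
#' @export
make_ctf <- function(optics, sensor_side, strict = TRUE) {
  stopifnot(inherits(optics, "fpm_optics"),
            sensor_side >= 2, sensor_side == round(sensor_side))
  sensor_side <- as.integer(sensor_side)
  sensor_pixel <- optics$object_pixel_um * optics$upsample_factor
  kc <- ctf_cutoff(optics)
  ax <- freq_axis(sensor_side, sensor_pixel)
  nyq <- max(abs(ax))
  if (kc > nyq) {
    msg <- sprintf(
      "pupil cutoff %.3f rad/um exceeds the sensor frequency-grid bound %.3f",
      kc, nyq)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  k2 <- outer(ax^2, ax^2, "+")  # rows: ky, cols: kx (symmetric either way)
  mask <- (k2 <= kc^2) * 1
  structure(list(mask = mask, cutoff = kc, dk = 2 * pi / (sensor_side * sensor_pixel),
                 side = sensor_side),
            class = "pupil_ctf")
}

#' @export
print.pupil_ctf <- function(x, ...) {
  cat("Pupil CTF:", x$side, "x", x$side, " cutoff", format(x$cutoff, digits = 4),
      "rad/um  (", sum(x$mask), "passband bins )\n")
  invisible(x)
}
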