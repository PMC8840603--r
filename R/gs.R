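# Alternating-projection (Gerchberg-Saxton) phase retrieval. Each sweep
# visits every LED once: the current high-resolution spectrum predicts the
# low-resolution field for that illumination, the measured intensity replaces
# its amplitude, and the transform of the corrected field overwrites the
# pupil-selected sub-spectrum. Sweeps repeat to convergence.

#' Configuration of the alternating-projection reconstruction
#'
#' @param max_rounds maximum number of full sweeps over the LED set
#' @param init_phase initial phase guess phi0 (radians), default 0
#' @param convergence_tol relative Frobenius change of the spectrum between
#'   rounds below which iteration stops; 0 disables the stopping rule and the
#'   algorithm always runs `max_rounds` sweeps
#' @param led_order sweep policy: `"spiral"` (center-outward by wave-vector
#'   magnitude, the default) or `"raster"`
#' @export
gs_config <- function(max_rounds = 50L, init_phase = 0,
                      convergence_tol = 1e-6, led_order = c("spiral", "raster")) {
  stopifnot(max_rounds >= 1, max_rounds == round(max_rounds),
            convergence_tol >= 0)
  led_order <- match.arg(led_order)
  structure(list(max_rounds = as.integer(max_rounds), init_phase = init_phase,
                 convergence_tol = convergence_tol, led_order = led_order),
            class = "gs_config")
}

#' Initial high-resolution spectrum from the normal-incidence capture
#'
#' The amplitude of the central (k = 0) image, bilinearly upsampled to the
#' high-resolution grid, with constant phase `init_phase`, transformed to the
#' frequency domain.
#'
#' @param stack a `lowres_stack` containing the normal-incidence capture
#' @param ctf the sensor-grid `pupil_ctf`
#' @param cfg a `gs_config`
#' @param optics the `fpm_optics` used for acquisition
#' @return an object of class `spectrum_estimate` with fields `spectrum`,
#'   `round`, `last_led`, `residual_history`
#' @export
initialize_spectrum <- function(stack, ctf, cfg, optics) {
  stopifnot(inherits(stack, "lowres_stack"), inherits(ctf, "pupil_ctf"),
            inherits(cfg, "gs_config"), inherits(optics, "fpm_optics"))
  ic <- central_led_index(stack)
  amp <- bilinear_upsample(sqrt(pmax(stack$images[[ic]], 0)),
                           optics$upsample_factor)
  field <- amp * exp(1i * cfg$init_phase)
  structure(list(spectrum = ft2(field), round = 0L, last_led = 0L,
                 residual_history = numeric(0)),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat("Spectrum estimate:", nrow(x$spectrum), "x", ncol(x$spectrum),
      " round", x$round, "\n")
  invisible(x)
}

#' Predicted low-resolution field for one illumination angle
#'
#' Crops the pupil-selected sub-spectrum for wave vector `k_xy`, filters by
#' the CTF and inverse-transforms to the sensor plane.
#'
#' @param est a `spectrum_estimate`
#' @param ctf a `pupil_ctf`
#' @param k_xy length-2 wave vector (rad/um)
#' @param optics the `fpm_optics`
#' @return complex sensor-grid matrix
#' @export
forward_lowres_estimate <- function(est, ctf, k_xy, optics) {
  stopifnot(inherits(est, "spectrum_estimate"), inherits(ctf, "pupil_ctf"))
  if (nrow(est$spectrum) != ctf$side * optics$upsample_factor)
    stop("spectrum / ctf shape mismatch", call. = FALSE)
  lowres_field_from_spectrum(est$spectrum, ctf, k_xy, optics$upsample_factor)
}

#' Replace the amplitude of an estimated field by the measured one
#'
#' Keeps the phase of `g`, substitutes the square root of the measured
#' intensity for its amplitude. Where `|g|` vanishes (below 1e-12) the unit
#' phasor is used, i.e. the measured amplitude is taken with zero phase.
#'
#' @param g complex matrix (estimated sensor field)
#' @param measured nonnegative intensity image of the same shape
#' @return complex matrix with `Mod(.)^2 == measured`
#' @export
replace_amplitude <- function(g, measured) {
  if (!all(dim(g) == dim(measured)))
    stop("shape mismatch between estimate and measurement", call. = FALSE)
  if (any(measured < 0))
    stop("measured intensities must be nonnegative", call. = FALSE)
  m <- Mod(g)
  phasor <- ifelse(m < 1e-12, 1 + 0i, g / m)
  sqrt(measured) * phasor
}

#' Write a corrected low-resolution field back into the sub-spectrum
#'
#' Only the pupil-selected pixels of the high-resolution spectrum change:
#' outside the shifted pupil the spectrum is bit-identical to before.
#'
#' @param est a `spectrum_estimate`
#' @param g_bar corrected complex sensor field
#' @param ctf a `pupil_ctf`
#' @param k_xy length-2 wave vector (rad/um)
#' @param optics the `fpm_optics`
#' @return the updated `spectrum_estimate`
#' @export
update_subspectrum <- function(est, g_bar, ctf, k_xy, optics) {
  stopifnot(inherits(est, "spectrum_estimate"), inherits(ctf, "pupil_ctf"))
  win <- subspectrum_window(nrow(est$spectrum), ctf$side, k_xy, ctf$dk)
  G <- ft2(g_bar) * optics$upsample_factor
  sub <- est$spectrum[win$rows, win$cols]
  est$spectrum[win$rows, win$cols] <- sub * (1 - ctf$mask) + G * ctf$mask
  est
}

# Mean relative amplitude mismatch over the stack for a given spectrum.
gs_residual <- function(est, stack, ctf, optics, order) {
  vals <- vapply(order, function(n) {
    g <- forward_lowres_estimate(est, ctf, stack$wave_vectors[n, ], optics)
    a <- sqrt(pmax(stack$images[[n]], 0))
    sum((Mod(g) - a)^2) / max(sum(a^2), .Machine$double.eps)
  }, numeric(1))
  mean(vals)
}

#' Reconstruct a high-resolution complex field by alternating projections
#'
#' Runs full sweeps of amplitude replacement and sub-spectrum updates over
#' all LEDs (center-outward by default) until `max_rounds` sweeps are done or
#' the relative spectrum change drops below `convergence_tol`. The residual
#' history records, after every sweep, the mean over LEDs of
#' `||Mod(g_n) - sqrt(I_n)||^2 / ||sqrt(I_n)||^2`.
#'
#' @param stack a `lowres_stack`
#' @param optics the `fpm_optics` used for acquisition
#' @param cfg a `gs_config`
#' @param grid optional `led_grid`; unused except for sanity checks
#' @return an object of class `fpm_recon` with components `field` (a
#'   `complex_field`), `spectrum`, `residuals`, `rounds`, `config`, `optics`
#' @examples
#' optics <- fpm_optics(upsample_factor = 2, object_pixel_um = 0.8)
#' grid <- led_grid(3, 3)
#' amp <- 0.5 + 0.5 * outer(sin(seq(0, pi, length.out = 32)),
#'                          cos(seq(0, pi, length.out = 32)))
#' sample <- field_from_images(amp, pixel_um = 0.8)
#' stack <- simulate_capture(sample, optics, grid)
#' rec <- fpm_reconstruct(stack, optics, gs_config(max_rounds = 5))
#' rec
#' @export
fpm_reconstruct <- function(stack, optics, cfg = gs_config(), grid = NULL) {
  stopifnot(inherits(stack, "lowres_stack"), inherits(optics, "fpm_optics"),
            inherits(cfg, "gs_config"))
  if (length(stack$images) == 0) stop("empty stack", call. = FALSE)
  ctf <- make_ctf(optics, stack$side)
  est <- initialize_spectrum(stack, ctf, cfg, optics)
  k <- stack$wave_vectors
  order <- if (cfg$led_order == "spiral") {
    order(sqrt(k[, 1]^2 + k[, 2]^2), seq_len(nrow(k)))
  } else seq_len(nrow(k))
  residuals <- numeric(0)
  for (round in seq_len(cfg$max_rounds)) {
    prev <- est$spectrum
    for (n in order) {
      g <- forward_lowres_estimate(est, ctf, k[n, ], optics)
      g_bar <- replace_amplitude(g, stack$images[[n]])
      est <- update_subspectrum(est, g_bar, ctf, k[n, ], optics)
      est$last_led <- n
    }
    est$round <- round
    residuals <- c(residuals, gs_residual(est, stack, ctf, optics, order))
    rel_change <- sqrt(sum(Mod(est$spectrum - prev)^2)) /
      max(sqrt(sum(Mod(prev)^2)), .Machine$double.eps)
    if (cfg$convergence_tol > 0 && rel_change < cfg$convergence_tol) break
  }
  est$residual_history <- residuals
  field <- complex_field(ift2(est$spectrum), optics$object_pixel_um)
  structure(list(field = field, spectrum = est$spectrum,
                 residuals = residuals, rounds = est$round,
                 config = cfg, optics = optics),
            class = "fpm_recon")
}

#' @export
print.fpm_recon <- function(x, ...) {
  cat("FPM alternating-projection reconstruction\n")
  cat("  field:", x$field$side, "x", x$field$side, "px  (",
      x$field$pixel_um, "um/px )\n")
  cat("  rounds:", x$rounds, "  final residual:",
      format(utils::tail(x$residuals, 1), digits = 4), "\n")
  invisible(x)
}

#' @export
summary.fpm_recon <- function(object, ...) {
  res <- object$residuals
  cat("FPM reconstruction after", object$rounds, "sweeps\n")
  cat("  residual: start", format(res[1], digits = 4),
      " end", format(utils::tail(res, 1), digits = 4), "\n")
  cat("  amplitude range [", format(min(Mod(object$field$values)), digits = 4),
      ",", format(max(Mod(object$field$values)), digits = 4), "]\n")
  cat("  phase range [", format(min(Arg(object$field$values)), digits = 4),
      ",", format(max(Arg(object$field$values)), digits = 4), "] rad\n")
  invisible(object)
}

#' @export
residuals.fpm_recon <- function(object, ...) object$residuals

#' Plot a reconstruction: amplitude, phase and the residual history
#' @param x an `fpm_recon`
#' @param ... unused
#' @export
plot.fpm_recon <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  img <- function(m, main) {
    graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256),
                    axes = FALSE, main = main, useRaster = TRUE)
  }
  img(Mod(x$field$values), "amplitude")
  img(Arg(x$field$values), "phase")
  graphics::plot(seq_along(x$residuals), x$residuals, type = "b", log = "y",
                 xlab = "sweep", ylab = "residual", main = "data mismatch")
  invisible(x)
}

#' Intensity and phase images of a reconstructed (or true) field
#' @param field a `complex_field`
#' @export
field_intensity <- function(field) Mod(field$values)^2

#' @rdname field_intensity
#' @export
field_phase <- function(field) Arg(field$values)
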