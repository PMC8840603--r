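# Non-iterative dual-channel input synthesis: one Fourier-domain pass fuses
# the whole low-resolution stack into a single complex image at the
# high-resolution grid size; its intensity and phase are the two network
# input channels. This compresses an arbitrary number of LED captures into a
# fixed two-channel representation.

#' Synthesize the dual-channel network input from a low-resolution stack
#'
#' Starting from the normal-incidence initialization, each LED's measured
#' image is transformed on the sensor grid and written into the
#' pupil-selected sub-spectrum — exactly one update per LED, in the
#' center-outward order, with no amplitude/phase projection iterations. The
#' inverse transform of the fused spectrum yields a complex image whose
#' intensity and phase form the two channels.
#'
#' The update literally uses the measured intensity image; physically the
#' amplitude is its square root, and that is the default. `amplitude_mode =
#' "literal"` transforms the intensity itself instead.
#'
#' @param stack a `lowres_stack`
#' @param optics the `fpm_optics` used for acquisition
#' @param amplitude_mode `"sqrt"` (default; transform of sqrt(I)) or
#'   `"literal"` (transform of I)
#' @return an object of class `fpm_input` with fields `intensity` (>= 0),
#'   `phase` (in (-pi, pi]) and `side`; attribute `n_updates` counts
#'   sub-spectrum writes (always the number of LEDs)
#' @export
synthesize_input <- function(stack, optics, amplitude_mode = c("sqrt", "literal")) {
  stopifnot(inherits(stack, "lowres_stack"), inherits(optics, "fpm_optics"))
  if (length(stack$images) == 0) stop("empty stack", call. = FALSE)
  amplitude_mode <- match.arg(amplitude_mode)
  ctf <- make_ctf(optics, stack$side)
  cfg <- gs_config(max_rounds = 1L)
  est <- initialize_spectrum(stack, ctf, cfg, optics)
  k <- stack$wave_vectors
  order <- order(sqrt(k[, 1]^2 + k[, 2]^2), seq_len(nrow(k)))
  n_updates <- 0L
  for (n in order) {
    a <- if (amplitude_mode == "sqrt") sqrt(pmax(stack$images[[n]], 0))
         else stack$images[[n]]
    est <- update_subspectrum(est, a + 0i, ctf, k[n, ], optics)
    n_updates <- n_updates + 1L
  }
  o <- ift2(est$spectrum)
  out <- dual_channel(Mod(o)^2, Arg(o))
  attr(out, "n_updates") <- n_updates
  out
}

#' Dual-channel (intensity, phase) image container
#'
#' @param intensity nonnegative square matrix
#' @param phase matrix of the same shape with values in (-pi, pi]
#' @export
dual_channel <- function(intensity, phase) {
  stopifnot(is.matrix(intensity), is.matrix(phase),
            all(dim(intensity) == dim(phase)),
            nrow(intensity) == ncol(intensity))
  if (any(intensity < 0))
    stop("intensity channel must be nonnegative", call. = FALSE)
  if (any(phase <= -pi - 1e-12) || any(phase > pi + 1e-12))
    stop("phase channel must be wrapped to (-pi, pi]", call. = FALSE)
  structure(list(intensity = intensity, phase = phase, side = nrow(intensity)),
            class = "fpm_input")
}

#' @export
print.fpm_input <- function(x, ...) {
  cat("Dual-channel input:", x$side, "x", x$side, "x 2 (intensity, phase)\n")
  invisible(x)
}

#' Convert a dual-channel image to / from an H x W x 2 array
#'
#' Channel 1 is intensity, channel 2 phase — the layout consumed by the
#' reconstruction network.
#'
#' @param x an `fpm_input`
#' @export
as_input_array <- function(x) {
  stopifnot(inherits(x, "fpm_input"))
  array(c(x$intensity, x$phase), dim = c(x$side, x$side, 2L))
}

#' @rdname as_input_array
#' @param arr an H x W x 2 array
#' @param clamp if `TRUE` (default), clip channel 1 at 0 and wrap channel 2
#'   to (-pi, pi] so arbitrary network output becomes a valid dual-channel
#'   image
#' @export
input_from_array <- function(arr, clamp = TRUE) {
  stopifnot(length(dim(arr)) == 3, dim(arr)[3] == 2)
  intensity <- arr[, , 1]
  phase <- arr[, , 2]
  if (clamp) {
    intensity <- pmax(intensity, 0)
    phase <- Arg(exp(1i * phase))
  }
  dual_channel(intensity, phase)
}

#' The complex field represented by a dual-channel image
#' @param x an `fpm_input`
#' @param pixel_um pixel pitch of the represented field
#' @export
field_from_input <- function(x, pixel_um) {
  stopifnot(inherits(x, "fpm_input"))
  complex_field(sqrt(x$intensity) * exp(1i * x$phase), pixel_um)
}
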