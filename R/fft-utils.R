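# Centered, orthonormal 2-D transforms and grid helpers shared by the forward
# model, the reconstruction and the input synthesis. All spectra in this
# package have DC at the array center (row floor(n/2)+1) and unit Frobenius
# norm preservation (Parseval without rescaling).

#' Swap quadrants so the DC bin moves from corner to center
#'
#' @param x matrix
#' @return matrix with the zero-frequency bin at `floor(dim/2) + 1`
#' @keywords internal
fftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq_len(d[1] - d[1] %/% 2) + d[1] %/% 2, seq_len(d[1] %/% 2))
  j <- c(seq_len(d[2] - d[2] %/% 2) + d[2] %/% 2, seq_len(d[2] %/% 2))
  # forward shift: index k maps center -> origin ordering
  x[order(i), order(j), drop = FALSE]
}

#' @rdname fftshift2
#' @keywords internal
ifftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq_len(d[1] - d[1] %/% 2) + d[1] %/% 2, seq_len(d[1] %/% 2))
  j <- c(seq_len(d[2] - d[2] %/% 2) + d[2] %/% 2, seq_len(d[2] %/% 2))
  x[i, j, drop = FALSE]
}

#' Orthonormal centered 2-D Fourier transform
#'
#' `ft2` maps a centered spatial field to a centered spectrum; `ift2` is its
#' exact inverse. Both preserve the Frobenius norm, so Parseval checks need no
#' rescaling.
#'
#' @param x square complex (or numeric) matrix
#' @return complex matrix of the same size
#' @export
ft2 <- function(x) {
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  fftshift2(stats::fft(ifftshift2(x))) / nrow(x)
}

#' @rdname ft2
#' @export
ift2 <- function(x) {
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / nrow(x)
}

#' Index of the DC bin on a centered grid of side n
#' @keywords internal
dc_index <- function(n) n %/% 2L + 1L

#' Centered frequency coordinates (rad per unit) for side n and pitch dx
#' @keywords internal
freq_axis <- function(n, pixel) {
  (seq_len(n) - dc_index(n)) * 2 * pi / (n * pixel)
}

#' Bilinear upsampling by an integer factor
#'
#' Interpolates on pixel-center coordinates: output pixel i sits at input
#' coordinate (i - 0.5)/factor + 0.5, clamped at the borders; factor 1 is the
#' identity. This is the `B` operator used to place a sensor-grid amplitude on
#' the high-resolution grid.
#'
#' @param x numeric matrix
#' @param factor integer >= 1
#' @return matrix of side `factor * nrow(x)`
#' @export
bilinear_upsample <- function(x, factor) {
  stopifnot(is.matrix(x), factor >= 1, factor == round(factor))
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  interp_axis <- function(n_in, n_out) {
    pos <- (seq_len(n_out) - 0.5) / factor + 0.5
    pos <- pmin(pmax(pos, 1), n_in)
    lo <- pmin(floor(pos), n_in - 1L)
    list(lo = as.integer(lo), w = pos - lo)
  }
  r <- interp_axis(nrow(x), nrow(x) * factor)
  c_ <- interp_axis(ncol(x), ncol(x) * factor)
  # rows then columns; separable
  xr <- x[r$lo, , drop = FALSE] * (1 - r$w) + x[r$lo + 1L, , drop = FALSE] * r$w
  xr[, c_$lo, drop = FALSE] * rep(1 - c_$w, each = nrow(xr)) +
    xr[, c_$lo + 1L, drop = FALSE] * rep(c_$w, each = nrow(xr))
}

#' Row/column ranges of the sensor-sized sub-spectrum window for one LED
#'
#' The window of side `sensor_side` is centered at the DC bin of the high-res
#' grid minus the integer pixel shift of the illumination wave vector
#' (the pupil H(k + k_n) is centered at -k_n). Sub-pixel residuals of the
#' shift are discarded; the rounded shift and residual are returned so callers
#' can log them.
#'
#' @keywords internal
subspectrum_window <- function(hi_side, sensor_side, k_xy, dk) {
  shift <- round(k_xy / dk)
  resid <- k_xy / dk - shift
  c_hi <- dc_index(hi_side)
  c_lo <- dc_index(sensor_side)
  rows <- (c_hi - shift[2]) - c_lo + seq_len(sensor_side)
  cols <- (c_hi - shift[1]) - c_lo + seq_len(sensor_side)
  if (rows[1] < 1L || cols[1] < 1L || rows[sensor_side] > hi_side ||
      cols[sensor_side] > hi_side) {
    stop("illumination shift of (", k_xy[1], ", ", k_xy[2],
         ") rad/um moves the pupil window outside the high-resolution ",
         "spectrum extent", call. = FALSE)
  }
  list(rows = rows, cols = cols, shift = shift, residual = resid)
}
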