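# Reconstruction quality scores: mean squared error, peak signal-to-noise
# ratio and structural similarity. SSIM here is the whole-image
# (global-statistics) form with population variances; an 11x11
# Gaussian-windowed variant is available behind a flag for comparison with
# common practice.

check_same_shape <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
    stop("images must be matrices of identical shape", call. = FALSE)
}

#' Mean squared error between two images
#'
#' `(1/(m n)) * sum((a - b)^2)` over all pixels.
#'
#' @param a,b numeric matrices of identical shape
#' @export
img_mse <- function(a, b) {
  check_same_shape(a, b)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `20 * log10(max_i / sqrt(MSE))`. Identical images give `Inf` (serialized
#' as the string "inf" by the report writer).
#'
#' @param a,b numeric matrices of identical shape
#' @param max_i dynamic-range constant MAX_I; if `NULL`, 1 when both images
#'   lie in [0, 1] and 255 otherwise
#' @export
img_psnr <- function(a, b, max_i = NULL) {
  check_same_shape(a, b)
  if (is.null(max_i)) max_i <- infer_dynamic_range(a, b)
  if (max_i <= 0) stop("`max_i` must be positive", call. = FALSE)
  m <- img_mse(a, b)
  if (m == 0) return(Inf)
  20 * log10(max_i / sqrt(m))
}

infer_dynamic_range <- function(a, b) {
  if (max(a, b) <= 1 + 1e-9 && min(a, b) >= -1e-9) 1 else 255
}

#' Structural similarity between two images
#'
#' The global form: whole-image means, population standard deviations and
#' covariance combined as
#' `((2 mu_x mu_y + C1)(2 sigma_xy + C2)) / ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`
#' with `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` (and `C3 = C2 / 2` in the
#' luminance-contrast-structure factorization, which this simplified form
#' equals exactly). With `windowed = TRUE` the statistics are computed under
#' a sliding 11x11 Gaussian window (sigma 1.5) and the local values averaged.
#'
#' @param a,b numeric matrices of identical shape
#' @param l dynamic range L; if `NULL`, inferred as for [img_psnr()]
#' @param windowed use the Gaussian-windowed local form instead of global
#'   statistics
#' @export
img_ssim <- function(a, b, l = NULL, windowed = FALSE) {
  check_same_shape(a, b)
  if (is.null(l)) l <- infer_dynamic_range(a, b)
  if (l <= 0) stop("`l` must be positive", call. = FALSE)
  c1 <- (0.01 * l)^2
  c2 <- (0.03 * l)^2
  if (!windowed) {
    mu_x <- mean(a); mu_y <- mean(b)
    var_x <- mean(a^2) - mu_x^2         # population variance
    var_y <- mean(b^2) - mu_y^2
    cov_xy <- mean(a * b) - mu_x * mu_y
    ((2 * mu_x * mu_y + c1) * (2 * cov_xy + c2)) /
      ((mu_x^2 + mu_y^2 + c1) * (var_x + var_y + c2))
  } else {
    w <- gaussian_window(11L, 1.5)
    mu_x <- filter2_same(a, w); mu_y <- filter2_same(b, w)
    var_x <- filter2_same(a * a, w) - mu_x^2
    var_y <- filter2_same(b * b, w) - mu_y^2
    cov_xy <- filter2_same(a * b, w) - mu_x * mu_y
    s <- ((2 * mu_x * mu_y + c1) * (2 * cov_xy + c2)) /
      ((mu_x^2 + mu_y^2 + c1) * (var_x + var_y + c2))
    mean(s)
  }
}

gaussian_window <- function(side, sigma) {
  ax <- seq_len(side) - (side + 1) / 2
  w <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  w / sum(w)
}

# Same-size 2-D correlation with zero padding (small kernels only).
filter2_same <- function(x, w) {
  side <- nrow(w)
  half <- side %/% 2
  xp <- matrix(0, nrow(x) + 2 * half, ncol(x) + 2 * half)
  xp[half + seq_len(nrow(x)), half + seq_len(ncol(x))] <- x
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(side)) {
    for (j in seq_len(side)) {
      if (w[i, j] == 0) next
      out <- out + w[i, j] *
        xp[(i - 1) + seq_len(nrow(x)), (j - 1) + seq_len(ncol(x))]
    }
  }
  out
}

#' Score a reconstructed dual-channel image against the truth
#'
#' Computes MSE, PSNR and SSIM per channel. Phase channels are scored as
#' plain images on their wrapped values (no unwrapping); their dynamic range
#' defaults to `2 * pi`.
#'
#' @param pred,truth `fpm_input` objects (or H x W x 2 arrays)
#' @param max_i,l dynamic-range constants for the intensity channel;
#'   inferred when `NULL`
#' @return an object of class `quality_report`: a list with per-channel
#'   `mse`, `psnr`, `ssim` and the constants used
#' @export
quality_report <- function(pred, truth, max_i = NULL, l = NULL) {
  if (is.array(pred) && !inherits(pred, "fpm_input"))
    pred <- input_from_array(pred)
  if (is.array(truth) && !inherits(truth, "fpm_input"))
    truth <- input_from_array(truth)
  stopifnot(inherits(pred, "fpm_input"), inherits(truth, "fpm_input"))
  if (pred$side != truth$side) stop("side mismatch", call. = FALSE)
  mi <- if (is.null(max_i)) infer_dynamic_range(pred$intensity, truth$intensity) else max_i
  li <- if (is.null(l)) mi else l
  lp <- 2 * pi
  rep_ <- list(
    intensity = list(mse = img_mse(pred$intensity, truth$intensity),
                     psnr = img_psnr(pred$intensity, truth$intensity, mi),
                     ssim = img_ssim(pred$intensity, truth$intensity, li)),
    phase = list(mse = img_mse(pred$phase, truth$phase),
                 psnr = img_psnr(pred$phase, truth$phase, lp),
                 ssim = img_ssim(pred$phase, truth$phase, lp)),
    constants = list(max_i = mi, l = li, phase_l = lp,
                     c1 = (0.01 * li)^2, c2 = (0.03 * li)^2,
                     c3 = (0.03 * li)^2 / 2))
  class(rep_) <- "quality_report"
  rep_
}

#' @export
print.quality_report <- function(x, ...) {
  fmt <- function(ch, v)
    cat(sprintf("  %-9s MSE %.4g  PSNR %s dB  SSIM %.4f\n", ch, v$mse,
                if (is.infinite(v$psnr)) "inf" else sprintf("%.2f", v$psnr),
                v$ssim))
  cat("Quality report (MAX_I =", x$constants$max_i,
      ", L =", x$constants$l, ")\n")
  fmt("intensity", x$intensity)
  fmt("phase", x$phase)
  invisible(x)
}

#' Serialize a quality report to JSON
#'
#' Infinite PSNR (identical images) is written as the string `"inf"`.
#'
#' @param x a `quality_report`
#' @param path output file; `NULL` returns the JSON string
#' @export
write_quality_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "quality_report"))
  enc <- function(v) lapply(v, function(z)
    if (is.numeric(z) && length(z) == 1 && is.infinite(z)) "inf" else z)
  obj <- list(intensity = enc(x$intensity), phase = enc(x$phase),
              constants = x$constants)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
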