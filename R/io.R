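# Image and stack readers/writers. Stacks are serialized as multi-page
# 32-bit TIFF plus a JSON sidecar; the TIFF writer clamps to [0, 1], so
# pages are stored on a recorded global intensity scale. Single images go
# through PNG (8/16-bit) or TIFF; internal representation is float in [0, 1].

#' Write a low-resolution stack to multi-page TIFF + JSON sidecar
#'
#' @param stack a `lowres_stack`
#' @param path output TIFF path; the sidecar is `paste0(path, ".json")`
#' @param provenance optional named list (e.g. config hash and seed) stored
#'   in the sidecar
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path, provenance = NULL) {
  stopifnot(inherits(stack, "lowres_stack"))
  scale <- max(vapply(stack$images, max, numeric(1)), .Machine$double.eps)
  tiff::writeTIFF(lapply(stack$images, function(im) im / scale), path,
                  bits.per.sample = 32L, compression = "none", reduce = FALSE)
  sidecar <- list(kind = "fpm_lowres_stack", n = length(stack$images),
                  side = stack$side, intensity_scale = scale,
                  noise_sigma = stack$noise_sigma,
                  wave_vectors = unname(stack$wave_vectors),
                  provenance = provenance)
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' @param path TIFF path with its JSON sidecar alongside
#' @return a `lowres_stack`
#' @export
read_stack <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing sidecar: ", sidecar_path, call. = FALSE)
  meta <- jsonlite::fromJSON(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$kind) || meta$kind != "fpm_lowres_stack")
    stop("not an fpm stack sidecar: ", sidecar_path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  images <- lapply(pages, function(p) p * meta$intensity_scale)
  lowres_stack(images, matrix(meta$wave_vectors, ncol = 2),
               noise_sigma = meta$noise_sigma)
}

#' Read a grayscale image (PNG or TIFF) as a float matrix in [0, 1]
#'
#' Multi-channel images are averaged to one channel.
#'
#' @param path file path ending in .png, .tif or .tiff
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)
  x
}

#' Write a float matrix in [0, 1] as a grayscale image
#'
#' @param img numeric matrix; values are clipped to [0, 1]
#' @param path output path ending in .png, .tif or .tiff
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 32L,
                                        compression = "none", reduce = FALSE),
         stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Write a dual-channel image to multi-page TIFF + JSON sidecar
#'
#' Page 1 is intensity, page 2 phase; both rescaled to [0, 1] with the
#' affine constants in the sidecar.
#'
#' @param x an `fpm_input`
#' @param path output TIFF path
#' @param provenance optional named list recorded in the sidecar
#' @export
write_dual_channel <- function(x, path, provenance = NULL) {
  stopifnot(inherits(x, "fpm_input"))
  pages <- list(x$intensity, x$phase)
  sc <- lapply(pages, function(p) {
    rng <- range(p)
    list(offset = rng[1], scale = max(rng[2] - rng[1], .Machine$double.eps))
  })
  tiff::writeTIFF(Map(function(p, s) (p - s$offset) / s$scale, pages, sc),
                  path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  writeLines(jsonlite::toJSON(list(kind = "fpm_dual_channel", pages = sc,
                                   provenance = provenance),
                              auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_dual_channel
#' @export
read_dual_channel <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = FALSE)
  if (is.null(meta$kind) || meta$kind != "fpm_dual_channel")
    stop("not a dual-channel sidecar", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- Map(function(p, s) p * s$scale + s$offset, pages, meta$pages)
  dual_channel(pmax(pages[[1]], 0), wrap_phase(pages[[2]]))
}
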