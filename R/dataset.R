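# Synthetic training-set construction: procedural amplitude/phase source
# images, random intensity/phase pairing into ground-truth complex
# amplitudes, forward simulation + input synthesis, noise, aligned random
# crops and a seeded train/test split.
#
# The builder is manifest-first: the full example manifest (pairings, crop
# offsets, noise seeds, split labels) is computed deterministically up front,
# and pixel data are rendered on demand with materialize_example() /
# write_dataset(). This keeps full-scale manifests (tens of thousands of
# groups) cheap while any individual example is reproducible in isolation.

# Deterministic sub-seed derivation so every stage draws from its own stream.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Generate procedural tissue-like source images
#'
#' Each image is a weighted sum of band-pass filtered Gaussian noise at three
#' spatial scales (broad blobs, mid-scale texture, fine grain), min-max
#' rescaled to [0, 1]. These stand in for collected high-resolution slide
#' images when building synthetic datasets; they emulate multi-scale texture,
#' not any particular stain or tissue type.
#'
#' @param n number of images (>= 1)
#' @param side image side in pixels
#' @param seed integer seed; the same seed reproduces the same images
#' @return a list of `n` matrices with values in [0, 1]
#' @export
generate_synthetic_sources <- function(n, side = 224L, seed = 1L) {
  stopifnot(n >= 1, side >= 16)
  side <- as.integer(side)
  ax <- freq_axis(side, 1)          # arbitrary units; only ratios matter
  k2 <- outer(ax^2, ax^2, "+")
  kmax2 <- max(ax)^2
  band <- function(lo, hi) exp(-k2 / (hi^2 * kmax2)) - exp(-k2 / (lo^2 * kmax2))
  masks <- list(band(1e-6, 0.02), band(0.02, 0.12), band(0.12, 0.6))
  weights <- c(0.55, 0.3, 0.15)
  with_seed(seed, lapply(seq_len(n), function(i) {
    z <- ft2(matrix(stats::rnorm(side^2), side, side))
    img <- Reduce(`+`, Map(function(m, w) w * Re(ift2(z * m)), masks, weights))
    rng <- range(img)
    (img - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  }))
}

#' Pair source images into ground-truth complex amplitudes
#'
#' Every source image serves as an amplitude map and is paired with
#' `multiplicity` distinct randomly chosen phase sources (possibly reused
#' across different amplitudes), giving `length(images) * multiplicity`
#' truth fields. The pairing plan is returned; individual complex fields are
#' rendered with [truth_field()].
#'
#' @param images list of source matrices in [0, 1]
#' @param multiplicity truth pairs per amplitude source (>= 1, and at most
#'   the number of images when `pairing = "random"`)
#' @param seed integer seed
#' @param phase_range numeric length-2; source values are mapped affinely
#'   onto this phase interval (radians)
#' @param pairing `"random"` (default) or `"self"` (each image paired with
#'   its own phase; requires `multiplicity = 1`)
#' @return an object of class `truth_pairs` with a `pairs` data frame
#'   (`amp_idx`, `phase_idx`)
#' @export
build_truth_pairs <- function(images, multiplicity = 4L, seed = 1L,
                              phase_range = c(-pi / 2, pi / 2),
                              pairing = c("random", "self")) {
  stopifnot(is.list(images), length(images) >= 1, multiplicity >= 1,
            length(phase_range) == 2, phase_range[1] < phase_range[2])
  pairing <- match.arg(pairing)
  n <- length(images)
  if (pairing == "self") {
    if (multiplicity != 1)
      stop("self pairing requires multiplicity 1", call. = FALSE)
    pairs <- data.frame(amp_idx = seq_len(n), phase_idx = seq_len(n))
  } else {
    if (multiplicity > n)
      stop("multiplicity cannot exceed the number of source images",
           call. = FALSE)
    pairs <- with_seed(derive_seed(seed, 2L), do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(amp_idx = i, phase_idx = sample.int(n, multiplicity))
    })))
  }
  structure(list(pairs = pairs, images = images, phase_range = phase_range),
            class = "truth_pairs")
}

#' @export
length.truth_pairs <- function(x) nrow(x$pairs)

#' @export
print.truth_pairs <- function(x, ...) {
  cat("Truth pairs:", nrow(x$pairs), "complex amplitudes from",
      length(x$images), "sources; phase range [",
      format(x$phase_range[1], digits = 3), ",",
      format(x$phase_range[2], digits = 3), "] rad\n")
  invisible(x)
}

#' Render one ground-truth complex field from a pairing plan
#'
#' @param tp a `truth_pairs` object
#' @param k pair index (1-based row of `tp$pairs`)
#' @param pixel_um pixel pitch of the rendered field
#' @export
truth_field <- function(tp, k, pixel_um) {
  stopifnot(inherits(tp, "truth_pairs"), k >= 1, k <= nrow(tp$pairs))
  amp <- tp$images[[tp$pairs$amp_idx[k]]]
  ph_src <- tp$images[[tp$pairs$phase_idx[k]]]
  ph <- tp$phase_range[1] + ph_src * diff(tp$phase_range)
  field_from_images(amp, ph, pixel_um)
}

#' Dataset construction parameters
#'
#' Defaults reproduce the full study-scale bookkeeping: 400 sources x 4 pairings
#' x 16 crops = 25,600 groups split 90/10 into 23,040 / 2,560.
#'
#' @param n_sources number of source images
#' @param multiplicity truth pairs per source
#' @param crops_per_pair aligned random crops per truth pair
#' @param crop_side crop side in pixels (<= `source_side`)
#' @param source_side side of the generated source images; must be divisible
#'   by the optics upsample factor
#' @param train_fraction fraction of groups labelled train, in (0, 1)
#' @param noise_sigma Gaussian noise sigma applied to the low-resolution
#'   intensities (peak-normalized scale) before input synthesis
#' @param seed master seed for the whole build
#' @export
dataset_spec <- function(n_sources = 400L, multiplicity = 4L,
                         crops_per_pair = 16L, crop_side = 192L,
                         source_side = 224L, train_fraction = 0.9,
                         noise_sigma = 3e-4, seed = 1L) {
  stopifnot(n_sources >= 1, multiplicity >= 1, crops_per_pair >= 1,
            crop_side >= 1, source_side >= crop_side,
            train_fraction > 0, train_fraction < 1, noise_sigma >= 0)
  structure(list(n_sources = as.integer(n_sources),
                 multiplicity = as.integer(multiplicity),
                 crops_per_pair = as.integer(crops_per_pair),
                 crop_side = as.integer(crop_side),
                 source_side = as.integer(source_side),
                 train_fraction = train_fraction,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "dataset_spec")
}

#' Build a synthetic FPM dataset (manifest + on-demand pixel data)
#'
#' Generates the source images and pairing plan, then lays out the complete
#' example manifest: one record per (truth pair, crop) group carrying the
#' pairing indices, crop offset, per-pair noise seed and train/test label.
#' The split is a seeded uniform shuffle followed by a contiguous cut at
#' `round(train_fraction * total)`. Rebuilding with the same spec yields a
#' byte-identical manifest.
#'
#' @param spec a `dataset_spec`
#' @param optics an `fpm_optics` (the source side must be a multiple of its
#'   upsample factor)
#' @param grid a `led_grid`
#' @return an object of class `fpm_dataset`: `spec`, `optics`, `grid`,
#'   `sources`, `pairs`, `manifest` (data frame), `counts`
#' @export
build_dataset <- function(spec, optics, grid) {
  stopifnot(inherits(spec, "dataset_spec"), inherits(optics, "fpm_optics"),
            inherits(grid, "led_grid"))
  if (spec$source_side %% optics$upsample_factor != 0)
    stop("source side must be divisible by the optics upsample factor",
         call. = FALSE)
  sources <- generate_synthetic_sources(spec$n_sources, spec$source_side,
                                        derive_seed(spec$seed, 1L))
  pairs <- build_truth_pairs(sources, spec$multiplicity, spec$seed)
  n_pairs <- nrow(pairs$pairs)
  total <- n_pairs * spec$crops_per_pair
  max_off <- spec$source_side - spec$crop_side + 1L
  manifest <- with_seed(derive_seed(spec$seed, 3L), {
    m <- data.frame(
      group_id = seq_len(total),
      pair_id = rep(seq_len(n_pairs), each = spec$crops_per_pair),
      crop_row = sample.int(max_off, total, replace = TRUE),
      crop_col = sample.int(max_off, total, replace = TRUE))
    m$amp_idx <- pairs$pairs$amp_idx[m$pair_id]
    m$phase_idx <- pairs$pairs$phase_idx[m$pair_id]
    m$noise_seed <- derive_seed(spec$seed, 100L + m$pair_id)
    perm <- sample.int(total)
    n_train <- round(spec$train_fraction * total)
    split <- character(total)
    split[perm[seq_len(n_train)]] <- "train"
    split[perm[-seq_len(n_train)]] <- "test"
    m$split <- split
    m
  })
  counts <- list(total = total,
                 train = sum(manifest$split == "train"),
                 test = sum(manifest$split == "test"))
  structure(list(spec = spec, optics = optics, grid = grid,
                 sources = sources, pairs = pairs, manifest = manifest,
                 counts = counts),
            class = "fpm_dataset")
}

#' @export
print.fpm_dataset <- function(x, ...) {
  cat("FPM synthetic dataset:", x$counts$total, "groups (",
      x$counts$train, "train /", x$counts$test, "test )\n")
  cat("  ", x$spec$n_sources, "sources x", x$spec$multiplicity, "pairings x",
      x$spec$crops_per_pair, "crops;", x$spec$crop_side, "px crops from",
      x$spec$source_side, "px fields; noise sigma", x$spec$noise_sigma, "\n")
  invisible(x)
}

#' Render the full-size input/truth images of one truth pair
#'
#' Runs the forward simulation for the pair's complex field, applies the
#' spec's Gaussian noise with the pair's manifest seed, synthesizes the
#' dual-channel input, and returns both the input and the truth as
#' `fpm_input` objects at the full source side.
#'
#' @param ds an `fpm_dataset`
#' @param pair_id 1-based truth pair index
#' @export
materialize_pair <- function(ds, pair_id) {
  stopifnot(inherits(ds, "fpm_dataset"))
  field <- truth_field(ds$pairs, pair_id, ds$optics$object_pixel_um)
  stack <- simulate_capture(field, ds$optics, ds$grid)
  if (ds$spec$noise_sigma > 0) {
    seed <- ds$manifest$noise_seed[match(pair_id, ds$manifest$pair_id)]
    stack <- add_gaussian_noise(stack, ds$spec$noise_sigma, seed)
  }
  input <- synthesize_input(stack, ds$optics)
  truth <- dual_channel(field_intensity(field), field_phase(field))
  list(input = input, truth = truth)
}

#' Render one input/truth example group (an aligned crop of its pair)
#'
#' @param ds an `fpm_dataset`
#' @param group_id 1-based group (manifest row) index
#' @param pair optional precomputed [materialize_pair()] result, to amortize
#'   the simulation across the crops of one pair
#' @return a list with `input` and `truth` `fpm_input` objects of side
#'   `crop_side`, plus the manifest `record`
#' @export
materialize_example <- function(ds, group_id, pair = NULL) {
  stopifnot(inherits(ds, "fpm_dataset"),
            group_id >= 1, group_id <= nrow(ds$manifest))
  rec <- ds$manifest[group_id, ]
  if (is.null(pair)) pair <- materialize_pair(ds, rec$pair_id)
  rows <- rec$crop_row + seq_len(ds$spec$crop_side) - 1L
  cols <- rec$crop_col + seq_len(ds$spec$crop_side) - 1L
  crop <- function(x) dual_channel(x$intensity[rows, cols],
                                   x$phase[rows, cols])
  list(input = crop(pair$input), truth = crop(pair$truth), record = rec)
}

#' Write dataset examples to disk (multi-page TIFF shards + JSON manifest)
#'
#' Each group becomes one 4-page 32-bit TIFF (input intensity, input phase,
#' truth intensity, truth phase); pages are affinely rescaled to [0, 1] and
#' the scale/offset stored in `manifest.json` so loading is lossless to
#' float precision.
#'
#' @param ds an `fpm_dataset`
#' @param dir output directory (created if missing)
#' @param groups manifest rows to write; default all
#' @export
write_dataset <- function(ds, dir, groups = ds$manifest$group_id) {
  stopifnot(inherits(ds, "fpm_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- ds$manifest[ds$manifest$group_id %in% groups, ]
  files <- list()
  for (pid in unique(recs$pair_id)) {
    pair <- materialize_pair(ds, pid)
    for (gid in recs$group_id[recs$pair_id == pid]) {
      ex <- materialize_example(ds, gid, pair = pair)
      fn <- sprintf("group_%06d.tif", gid)
      pages <- list(ex$input$intensity, ex$input$phase,
                    ex$truth$intensity, ex$truth$phase)
      sc <- lapply(pages, function(p) {
        rng <- range(p)
        span <- max(rng[2] - rng[1], .Machine$double.eps)
        list(offset = rng[1], scale = span)
      })
      tiff::writeTIFF(Map(function(p, s) (p - s$offset) / s$scale, pages, sc),
                      file.path(dir, fn), bits.per.sample = 32L,
                      compression = "none", reduce = FALSE)
      files[[as.character(gid)]] <- list(file = fn, pages = sc)
    }
  }
  manifest <- list(kind = "fpm_dataset_shards",
                   crop_side = ds$spec$crop_side,
                   records = recs, files = files)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"),
             file.path(dir, "manifest.json"))
  invisible(file.path(dir, "manifest.json"))
}

#' Load an externally acquired (or re-saved) dataset directory
#'
#' Reads real-acquisition fine-tuning pairs — or any dataset written by
#' [write_dataset()] — back into the manifest-plus-examples schema. No data
#' generation happens here. An empty directory yields an empty dataset.
#'
#' @param path dataset directory
#' @return a list with `manifest` (data frame, possibly 0 rows) and
#'   `examples` (named list of `input`/`truth` pairs)
#' @export
load_finetune_stub <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    if (length(list.files(path)) == 0)
      return(list(manifest = data.frame(), examples = list()))
    stop("directory has files but no manifest.json: not a dataset layout",
         call. = FALSE)
  }
  manifest <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  if (is.null(manifest$kind) || manifest$kind != "fpm_dataset_shards")
    stop("manifest.json is not an fpm dataset manifest", call. = FALSE)
  recs <- do.call(rbind, lapply(manifest$records, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(recs)) recs <- data.frame()
  examples <- list()
  for (gid in names(manifest$files)) {
    entry <- manifest$files[[gid]]
    fp <- file.path(path, entry$file)
    if (!file.exists(fp)) stop("missing shard file: ", entry$file, call. = FALSE)
    pages <- tiff::readTIFF(fp, all = TRUE)
    pages <- Map(function(p, s) p * s$scale + s$offset, pages, entry$pages)
    examples[[gid]] <- list(
      input = dual_channel(pmax(pages[[1]], 0), wrap_phase(pages[[2]])),
      truth = dual_channel(pmax(pages[[3]], 0), wrap_phase(pages[[4]])))
  }
  list(manifest = recs, examples = examples)
}

wrap_phase <- function(p) Arg(exp(1i * p))

#' Train/test counts of a dataset
#' @param ds an `fpm_dataset`
#' @export
dataset_counts <- function(ds) ds$counts
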