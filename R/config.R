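# Run configuration: one YAML/JSON file with optics / led_grid / gs /
# dataset / train sections, validated through the module constructors before
# any computation runs, plus the pipeline dispatcher behind the command-line
# entry point.

config_sections <- function() list(
  optics = names(formals(fpm_optics)),
  led_grid = names(formals(led_grid)),
  gs = names(formals(gs_config)),
  dataset = names(formals(dataset_spec)),
  train = names(formals(train_config)))

# FNV-1a over the canonical JSON of the raw config; hex string.
config_hash <- function(raw) {
  bytes <- as.integer(charToRaw(as.character(
    jsonlite::toJSON(raw, auto_unbox = TRUE, digits = NA))))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON file with any of the sections `optics`, `led_grid`,
#' `gs`, `dataset`, `train` and an optional top-level `seed`. Missing
#' sections take the package defaults; unknown sections or keys are rejected
#' by name, and all schema violations are reported together.
#'
#' @param path path to a .yaml/.yml or .json file
#' @return an object of class `fpm_config` with validated `optics`, `grid`,
#'   `gs`, `dataset`, `train`, `seed`, the raw section list and a config
#'   `hash`
#' @export
fpm_load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop("config must be YAML or JSON, got .", ext, call. = FALSE))
  if (is.null(raw)) raw <- list()
  fpm_config(raw)
}

#' @rdname fpm_load_config
#' @param raw a named list with the same structure as the config file
#' @export
fpm_config <- function(raw = list()) {
  errors <- character(0)
  sections <- config_sections()
  unknown_top <- setdiff(names(raw), c(names(sections), "seed"))
  if (length(unknown_top))
    errors <- c(errors, paste0("unknown config section: ",
                               paste(unknown_top, collapse = ", ")))
  build <- function(section, constructor) {
    sec <- raw[[section]]
    if (is.null(sec)) sec <- list()
    bad <- setdiff(names(sec), sections[[section]])
    if (length(bad)) {
      errors <<- c(errors, paste0("unknown key in ", section, ": ",
                                  paste(bad, collapse = ", ")))
      return(NULL)
    }
    tryCatch(do.call(constructor, sec), error = function(e) {
      errors <<- c(errors, paste0(section, ": ", conditionMessage(e)))
      NULL
    })
  }
  optics <- build("optics", fpm_optics)
  grid <- build("led_grid", led_grid)
  gs <- build("gs", gs_config)
  dataset <- build("dataset", dataset_spec)
  train <- build("train", train_config)
  seed <- raw$seed
  if (is.null(seed)) seed <- 1L
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    errors <- c(errors, "seed: must be a single integer")
  if (length(errors))
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  structure(list(optics = optics, grid = grid, gs = gs, dataset = dataset,
                 train = train, seed = as.integer(seed), raw = raw,
                 hash = config_hash(raw)),
            class = "fpm_config")
}

#' @export
print.fpm_config <- function(x, ...) {
  cat("FPM run configuration (hash", x$hash, ", seed", x$seed, ")\n")
  print(x$optics); print(x$grid)
  invisible(x)
}

#' Save a configuration back to YAML or JSON
#'
#' Writes the raw section list, so a save/load round trip reproduces the
#' config (including its hash).
#'
#' @param cfg an `fpm_config`
#' @param path output .yaml/.yml or .json path
#' @export
fpm_save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "fpm_config"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = , yml = yaml::write_yaml(cfg$raw, path),
         json = writeLines(jsonlite::toJSON(cfg$raw, auto_unbox = TRUE,
                                            digits = NA), path),
         stop("config must be YAML or JSON, got .", ext, call. = FALSE))
  invisible(path)
}

provenance_of <- function(cfg, seed) list(config_hash = cfg$hash, seed = seed)

#' Run one pipeline stage
#'
#' Dispatches a validated configuration to the module operations. Inputs and
#' outputs are in-memory objects; commands that produce artifacts write them
#' when `out` is given, stamped with the config hash and seed. Inputs are
#' never mutated.
#'
#' Commands: `"simulate"` (needs `sample`, a `complex_field`; optional
#' `noise_sigma`), `"reconstruct"` (needs `stack`), `"synthesize-input"`
#' (needs `stack`), `"build-dataset"`, `"evaluate"` (needs `pred` and
#' `truth`), `"train"` (needs `data`, optional `validation`), `"predict"`
#' (needs `model` and `input`), and `"demo"` — the closed loop
#' simulate -> reconstruct -> evaluate on a generated scene, returning its
#' quality report.
#'
#' @param cfg an `fpm_config`
#' @param command one of the tokens above
#' @param out optional output path (file or directory, per command)
#' @param seed overrides `cfg$seed` when given
#' @param ... command-specific inputs, see Details
#' @return the stage result (invisible for pure writers)
#' @export
fpm_run <- function(cfg, command, out = NULL, seed = NULL, ...) {
  stopifnot(inherits(cfg, "fpm_config"))
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  args <- list(...)
  commands <- c("simulate", "reconstruct", "synthesize-input",
                "build-dataset", "evaluate", "train", "predict", "demo")
  if (!command %in% commands)
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "), call. = FALSE)
  switch(
    command,
    "simulate" = {
      sample <- args$sample
      if (is.null(sample)) stop("simulate needs a `sample` complex_field",
                                call. = FALSE)
      stack <- simulate_capture(sample, cfg$optics, cfg$grid)
      if (!is.null(args$noise_sigma) && args$noise_sigma > 0)
        stack <- add_gaussian_noise(stack, args$noise_sigma, seed)
      if (!is.null(out)) write_stack(stack, out, provenance_of(cfg, seed))
      stack
    },
    "reconstruct" = {
      if (is.null(args$stack)) stop("reconstruct needs a `stack`", call. = FALSE)
      rec <- fpm_reconstruct(args$stack, cfg$optics, cfg$gs)
      if (!is.null(out))
        write_dual_channel(dual_channel(field_intensity(rec$field),
                                        field_phase(rec$field)),
                           out, provenance_of(cfg, seed))
      rec
    },
    "synthesize-input" = {
      if (is.null(args$stack)) stop("synthesize-input needs a `stack`",
                                    call. = FALSE)
      inp <- synthesize_input(args$stack, cfg$optics)
      if (!is.null(out)) write_dual_channel(inp, out, provenance_of(cfg, seed))
      inp
    },
    "build-dataset" = {
      spec <- cfg$dataset
      spec$seed <- seed
      ds <- build_dataset(do.call(dataset_spec, unclass(spec)),
                          cfg$optics, cfg$grid)
      if (!is.null(out)) {
        groups <- args$groups
        if (is.null(groups)) groups <- ds$manifest$group_id
        write_dataset(ds, out, groups)
      }
      ds
    },
    "evaluate" = {
      if (is.null(args$pred) || is.null(args$truth))
        stop("evaluate needs `pred` and `truth`", call. = FALSE)
      rep_ <- quality_report(args$pred, args$truth)
      if (!is.null(out)) {
        js <- jsonlite::fromJSON(write_quality_report(rep_),
                                 simplifyVector = TRUE)
        js$provenance <- provenance_of(cfg, seed)
        writeLines(jsonlite::toJSON(js, auto_unbox = TRUE, digits = NA), out)
      }
      rep_
    },
    "train" = {
      if (is.null(args$data)) stop("train needs `data`", call. = FALSE)
      tc <- cfg$train
      tc$seed <- seed
      model <- args$model
      if (is.null(model)) model <- fpm_network(seed = seed)
      fpm_train(model, args$data, do.call(train_config, unclass(tc)),
                validation = args$validation)
    },
    "predict" = {
      if (is.null(args$model) || is.null(args$input))
        stop("predict needs `model` and `input`", call. = FALSE)
      pred <- predict(args$model, args$input)
      if (!is.null(out)) write_dual_channel(pred, out, provenance_of(cfg, seed))
      pred
    },
    "demo" = fpm_demo(cfg, seed, out, sensor_side = args$sensor_side)
  )
}

# Closed loop on a generated scene: synthetic amplitude/phase pair ->
# simulate -> alternating-projection reconstruction -> quality report.
fpm_demo <- function(cfg, seed, out = NULL, sensor_side = NULL) {
  if (is.null(sensor_side)) sensor_side <- 24L
  side <- sensor_side * cfg$optics$upsample_factor
  src <- generate_synthetic_sources(2L, side, seed)
  truth <- field_from_images(0.2 + 0.8 * src[[1]],
                             (src[[2]] - 0.5) * pi / 2,
                             cfg$optics$object_pixel_um)
  stack <- simulate_capture(truth, cfg$optics, cfg$grid)
  rec <- fpm_reconstruct(stack, cfg$optics, cfg$gs)
  pred <- dual_channel(field_intensity(rec$field), field_phase(rec$field))
  ref <- dual_channel(field_intensity(truth), field_phase(truth))
  report <- quality_report(pred, ref, max_i = max(ref$intensity),
                           l = max(ref$intensity))
  if (!is.null(out)) {
    js <- jsonlite::fromJSON(write_quality_report(report),
                             simplifyVector = TRUE)
    js$provenance <- provenance_of(cfg, seed)
    writeLines(jsonlite::toJSON(js, auto_unbox = TRUE, digits = NA), out)
  }
  list(report = report, reconstruction = rec, truth = truth, stack = stack)
}
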