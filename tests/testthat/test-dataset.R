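test_that("synthetic sources are deterministic, in range, and well exposed", {
  imgs <- generate_synthetic_sources(8, side = 64, seed = 10)
  expect_length(imgs, 8)
  expect_identical(imgs, generate_synthetic_sources(8, side = 64, seed = 10))
  expect_false(identical(imgs[[1]], imgs[[2]]))
  for (im in imgs) {
    expect_true(all(im >= 0 & im <= 1))
    expect_gt(mean(im), 0.2)
    expect_lt(mean(im), 0.8)
  }
})

test_that("pairing plan: counts, tuple uniqueness, self-pairing degenerate case", {
  imgs <- generate_synthetic_sources(10, side = 32, seed = 11)
  tp <- build_truth_pairs(imgs, multiplicity = 4, seed = 3)
  expect_length(tp, 40)
  expect_false(any(duplicated(tp$pairs[, c("amp_idx", "phase_idx")])))
  # self pairing: o = a * exp(i * s(a))
  tp_self <- build_truth_pairs(imgs, multiplicity = 1, pairing = "self")
  f <- truth_field(tp_self, 3, pixel_um = 0.5)
  a <- imgs[[3]]
  expected <- a * exp(1i * (-pi / 2 + a * pi))
  expect_equal(f$values, expected, tolerance = 1e-12)
  expect_error(build_truth_pairs(imgs, multiplicity = 2, pairing = "self"),
               "multiplicity 1")
  expect_error(build_truth_pairs(imgs, multiplicity = 11), "exceed")
})

test_that("truth fields respect the configured phase range", {
  imgs <- generate_synthetic_sources(4, side = 32, seed = 12)
  tp <- build_truth_pairs(imgs, multiplicity = 2, seed = 4,
                          phase_range = c(-0.3, 0.7))
  for (k in 1:4) {
    f <- truth_field(tp, k, pixel_um = 0.5)
    ph <- Arg(f$values)
    expect_gte(min(ph), -0.3 - 1e-9)
    expect_lte(max(ph), 0.7 + 1e-9)
  }
})

test_that("manifest count algebra and split sizes hold at small scale", {
  spec <- dataset_spec(n_sources = 5, multiplicity = 3, crops_per_pair = 4,
                       crop_side = 24, source_side = 32, seed = 5)
  ds <- build_dataset(spec, tiny_optics(), led_grid(3, 3))
  counts <- dataset_counts(ds)
  expect_equal(counts$total, 5 * 3 * 4)
  expect_equal(counts$train, round(0.9 * counts$total))
  expect_equal(counts$train + counts$test, counts$total)
  expect_equal(nrow(ds$manifest), counts$total)
  expect_setequal(ds$manifest$split, c("train", "test"))
  # crop offsets always keep the window inside the field
  expect_true(all(ds$manifest$crop_row + spec$crop_side - 1 <= spec$source_side))
  expect_true(all(ds$manifest$crop_col + spec$crop_side - 1 <= spec$source_side))
})

test_that("rebuilding with one spec gives a byte-identical manifest", {
  spec <- dataset_spec(n_sources = 4, multiplicity = 2, crops_per_pair = 3,
                       crop_side = 16, source_side = 32, seed = 6)
  ds1 <- build_dataset(spec, tiny_optics(), led_grid(3, 3))
  ds2 <- build_dataset(spec, tiny_optics(), led_grid(3, 3))
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(ds1$sources, ds2$sources)
  expect_identical(ds1$pairs$pairs, ds2$pairs$pairs)
})

test_that("input and truth crops cover the same spatial window", {
  spec <- dataset_spec(n_sources = 3, multiplicity = 1, crops_per_pair = 2,
                       crop_side = 16, source_side = 32, noise_sigma = 0,
                       seed = 7)
  ds <- build_dataset(spec, tiny_optics(), led_grid(3, 3))
  ex <- materialize_example(ds, 1)
  expect_equal(ex$input$side, 16)
  expect_equal(ex$truth$side, 16)
  # the truth crop must equal the directly cropped truth field
  f <- truth_field(ds$pairs, ex$record$pair_id, 0.5)
  rows <- ex$record$crop_row + 0:15
  cols <- ex$record$crop_col + 0:15
  expect_equal(ex$truth$intensity, Mod(f$values[rows, cols])^2,
               tolerance = 1e-12)
  expect_equal(ex$truth$phase, Arg(f$values[rows, cols]), tolerance = 1e-12)
})

test_that("noise in the pipeline is seeded per pair and reproducible", {
  spec <- dataset_spec(n_sources = 2, multiplicity = 1, crops_per_pair = 1,
                       crop_side = 16, source_side = 32, noise_sigma = 1e-3,
                       seed = 8)
  ds <- build_dataset(spec, tiny_optics(), led_grid(3, 3))
  e1 <- materialize_example(ds, 1)
  e2 <- materialize_example(ds, 1)
  expect_identical(e1$input$intensity, e2$input$intensity)
})

test_that("written shards round-trip through the fine-tune loader", {
  spec <- dataset_spec(n_sources = 2, multiplicity = 2, crops_per_pair = 2,
                       crop_side = 16, source_side = 32, noise_sigma = 0,
                       seed = 9)
  ds <- build_dataset(spec, tiny_optics(), led_grid(3, 3))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir, groups = 1:4)
  back <- load_finetune_stub(dir)
  expect_equal(nrow(back$manifest), 4)
  expect_length(back$examples, 4)
  for (gid in 1:4) {
    ex <- materialize_example(ds, gid)
    got <- back$examples[[as.character(gid)]]
    expect_equal(got$input$intensity, ex$input$intensity, tolerance = 1e-6)
    expect_equal(got$truth$phase, ex$truth$phase, tolerance = 1e-6)
  }
})

test_that("the fine-tune loader handles empty and labelled datasets", {
  empty <- withr::local_tempdir()
  res <- load_finetune_stub(empty)
  expect_equal(nrow(res$manifest), 0)
  expect_length(res$examples, 0)
  # a 450-record manifest split 400/50 keeps its labels on load
  dir <- withr::local_tempdir()
  recs <- data.frame(group_id = 1:450,
                     split = rep(c("train", "test"), c(400, 50)))
  writeLines(jsonlite::toJSON(list(kind = "fpm_dataset_shards", crop_side = 8,
                                   records = recs, files = list()),
                              auto_unbox = TRUE, dataframe = "rows"),
             file.path(dir, "manifest.json"))
  back <- load_finetune_stub(dir)
  expect_equal(sum(back$manifest$split == "train"), 400)
  expect_equal(sum(back$manifest$split == "test"), 50)
  # junk layouts are a format error
  junk <- withr::local_tempdir()
  writeLines("x", file.path(junk, "stray.txt"))
  expect_error(load_finetune_stub(junk), "manifest")
})
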