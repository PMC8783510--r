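test_that("non-chalky grains have no chalk and chalky grains always do", {
  g <- generate_grain(grain_spec(chalk_present = FALSE, rng_seed = 3))
  expect_equal(g$truth$label, "non-chalky")
  expect_false(any(g$truth$chalk_mask))
  expect_null(g$truth$chalk_polygon)

  g2 <- generate_grain(grain_spec(chalk_present = TRUE, chalk_fraction = 0.3,
                                  rng_seed = 3))
  expect_equal(g2$truth$label, "chalky")
  expect_true(any(g2$truth$chalk_mask))
  # chalk inside grain
  expect_true(all(g2$truth$grain_mask[g2$truth$chalk_mask]))
})

test_that("identical spec and seed give byte-identical grains", {
  s <- grain_spec(chalk_present = TRUE, chalk_fraction = 0.25, rng_seed = 42)
  expect_identical(generate_grain(s), generate_grain(s))
})

test_that("rendered chalk area tracks the requested fraction", {
  s <- grain_spec(chalk_present = TRUE, chalk_fraction = 0.3,
                  blur_sigma = 2, rng_seed = 7)
  g <- generate_grain(s)
  frac <- sum(g$truth$chalk_mask) / sum(g$truth$grain_mask)
  expect_gte(frac, 0.2)
  expect_lte(frac, 0.4)
})

test_that("invalid grain specs are rejected", {
  expect_error(grain_spec(chalk_present = FALSE, chalk_fraction = 0.2),
               class = "chalkcam_validation_error")
  expect_error(grain_spec(chalk_fraction = 1),
               class = "chalkcam_validation_error")
  expect_error(grain_spec(grain_axes = c(-1, 10)),
               class = "chalkcam_validation_error")
})

test_that("chalk pixels are strictly brighter than non-chalk grain pixels pre-noise", {
  # checked on the continuous rendering, before noise and 8-bit quantization
  for (seed in 1:5) {
    s <- grain_spec(chalk_present = TRUE,
                    chalk_fraction = 0.2 + 0.05 * seed,
                    noise_sd = 0, rng_seed = seed)
    r <- withr::with_seed(seed, chalkcam:::render_grain(s))
    chalk <- r$chalk_mask
    plain <- r$grain_mask & !chalk
    expect_gt(min(r$image[chalk]), max(r$image[plain]))
  }
})

test_that("plates place grains disjointly away from the border", {
  lay <- plate_layout(n_grains = 25, rng_seed = 1)
  pl <- generate_plate(lay, sample_grain_specs(25, seed = 2))
  boxes <- t(vapply(pl$grains, function(g) g$box, numeric(4)))
  expect_equal(nrow(boxes), 25)
  # none touching the border
  expect_true(all(boxes[, 1] > 0 & boxes[, 2] > 0))
  expect_true(all(boxes[, 3] < lay$plate_size[2]))
  expect_true(all(boxes[, 4] < lay$plate_size[1]))
  # pairwise disjoint
  for (i in 1:24) for (j in (i + 1):25) {
    a <- boxes[i, ]; b <- boxes[j, ]
    expect_true(a[1] >= b[3] || b[1] >= a[3] || a[2] >= b[4] || b[2] >= a[4])
  }
  # boxes exactly enclose each grain's rendered foreground
  for (g in pl$grains) {
    expect_equal(unname(g$box[["x1"]] - g$box[["x0"]]),
                 ncol(g$truth$grain_mask))
    expect_equal(unname(g$box[["y1"]] - g$box[["y0"]]),
                 nrow(g$truth$grain_mask))
    expect_true(any(g$truth$grain_mask[1, ]) &&
                  any(g$truth$grain_mask[nrow(g$truth$grain_mask), ]) &&
                  any(g$truth$grain_mask[, 1]) &&
                  any(g$truth$grain_mask[, ncol(g$truth$grain_mask)]))
  }
})

test_that("an empty plate is empty and truncation clips one grain", {
  pl0 <- generate_plate(plate_layout(n_grains = 0),
                        list())
  expect_length(pl0$grains, 0)
  expect_equal(dim(pl0$image)[3], 3)

  lay <- plate_layout(n_grains = 5, allow_border_truncation = TRUE,
                      rng_seed = 4)
  pl <- generate_plate(lay, sample_grain_specs(5, seed = 4))
  touches <- vapply(pl$grains, function(g)
    g$box[["x0"]] <= 0 || g$box[["y0"]] <= 0, TRUE)
  expect_gte(sum(touches), 1)
  expect_true(pl$grains[[1]]$truncated)
})

test_that("overcrowded layouts raise a capacity error", {
  lay <- plate_layout(plate_size = c(300, 300), n_grains = 12, rng_seed = 1)
  expect_error(generate_plate(lay, sample_grain_specs(12, seed = 1),
                              max_tries = 20),
               class = "chalkcam_capacity_error")
})

test_that("generated datasets split 2:1:1, annotate every chalky grain, and are reproducible", {
  td <- withr::local_tempdir()
  ds <- generate_dataset(16, layout = plate_layout(n_grains = 25),
                         out_dir = file.path(td, "a"), seed = 5)
  m <- ds$manifest
  expect_equal(nrow(m), 400)
  counts <- table(m$split)
  expect_lte(abs(counts[["train"]] - 200), 2)
  expect_lte(abs(counts[["dev"]] - 100), 2)
  expect_lte(abs(counts[["test"]] - 100), 2)
  # split disjointness: every grain appears exactly once
  expect_equal(anyDuplicated(m$path), 0)
  # every chalky manifest row has a polygon entry in the VIA JSON
  annos <- read_via_annotations(ds$via_path)
  anno_ids <- vapply(annos, `[[`, "", "image_id")
  chalky_files <- basename(m$path[m$label == "chalky"])
  expect_setequal(chalky_files, anno_ids)
  expect_true(all(vapply(annos, function(a) length(a$polygons) > 0, TRUE)))
  # determinism: re-run with the same seed gives an identical manifest
  ds2 <- generate_dataset(16, layout = plate_layout(n_grains = 25),
                          out_dir = file.path(td, "b"), seed = 5)
  expect_identical(ds$manifest, ds2$manifest)
  # crops exist and load at the box dimensions
  img <- read_image(file.path(td, "a", m$path[1]))
  expect_equal(dim(img)[1:2],
               c(m$box_y1[1] - m$box_y0[1], m$box_x1[1] - m$box_x0[1]))
})
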