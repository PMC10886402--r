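test_that("phantom generation is deterministic and index-addressable", {
  cfg <- tiny_phantom_config(seed = 0L)
  a <- generate_phantom(cfg, 3)
  b <- generate_phantom(cfg, 3)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$live_weight, b$live_weight)
  expect_identical(a$breast_muscle_weight, b$breast_muscle_weight)
  # a different index gives a different sample
  expect_false(identical(generate_phantom(cfg, 4)$mask, a$mask))
  expect_error(generate_phantom(cfg, 13), "out of range")
  expect_error(phantom_config(muscle_area_range = c(0.1, 0.1)), "min < max")
  expect_error(phantom_config(noise_sigma = -1), "non-negative")
})

test_that("breast-muscle weight follows the generative affine relation", {
  cfg <- tiny_phantom_config(n = 10L, seed = 2L,
                             weight_coeffs = c(10, 0.3, 0.02),
                             weight_noise_sigma = 0)
  for (i in c(1, 5, 10)) {
    s <- generate_phantom(cfg, i)
    expect_equal(s$breast_muscle_weight,
                 10 + 0.3 * s$live_weight + 0.02 * sum(s$mask))
  }
})

test_that("masks satisfy the geometric contract", {
  cfg <- tiny_phantom_config(n = 10L, side = 96L, seed = 4L)
  for (i in seq_len(10)) {
    s <- generate_phantom(cfg, i)
    area_frac <- sum(s$mask) / cfg$image_side^2
    expect_gte(area_frac, cfg$muscle_area_range[1])
    expect_lte(area_frac, cfg$muscle_area_range[2])
    # single 8-connected component, fully inside the frame
    lab <- maefnet:::cpp_label8(s$mask)
    expect_equal(max(lab), 1L)
    expect_true(all(s$mask[1, ] == 0) && all(s$mask[cfg$image_side, ] == 0))
    expect_true(all(s$mask[, 1] == 0) && all(s$mask[, cfg$image_side] == 0))
    expect_gt(s$breast_muscle_weight, 0)
    # every generated mask is measurable
    expect_silent(geom <- extract_geometry(s$mask))
    expect_length(compute_features(geom), 15)
  }
})

test_that("datasets split 7:2:1 and round-trip losslessly through PNG", {
  cfg <- tiny_phantom_config(n = 10L, seed = 6L)
  dir <- withr::local_tempdir()
  ds <- generate_dataset(cfg, dir)
  expect_equal(unname(table(ds$manifest$split)[c("train", "val", "test")]),
               c(7L, 2L, 1L), ignore_attr = TRUE)

  cfg100 <- tiny_phantom_config(n = 100L, side = 48L, seed = 6L)
  ds100 <- generate_dataset(cfg100)
  expect_equal(unname(table(ds100$manifest$split)[c("train", "val", "test")]),
               c(70L, 20L, 10L), ignore_attr = TRUE)

  re <- load_phantom_dataset(dir)
  for (id in ds$manifest$sample_id) {
    expect_identical(re$samples[[id]]$mask, ds$samples[[id]]$mask)
    expect_identical(re$samples[[id]]$image, ds$samples[[id]]$image)
  }
  expect_equal(re$manifest$breast_muscle_weight_g,
               ds$manifest$breast_muscle_weight_g, tolerance = 1e-12)

  # bitwise dataset determinism
  ds2 <- generate_dataset(cfg)
  expect_identical(lapply(ds2$samples, `[[`, "image"),
                   lapply(ds$samples, `[[`, "image"))
  expect_identical(ds2$manifest, ds$manifest)
})
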