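# Synthetic scene generator, paired augmentation, splitting, and PNG I/O.

test_that("scenes are seeded, binary-masked and range-valid", {
  spec <- scene_spec(side = 64)
  a <- generate_scene(spec, seed = 42)
  b <- generate_scene(spec, seed = 42)
  expect_identical(a, b)
  c <- generate_scene(spec, seed = 43)
  expect_false(identical(a$image, c$image))
  expect_true(all(a$mask %in% c(0, 1)))
  expect_true(min(a$image) >= 0 && max(a$image) <= 1)
  expect_equal(dim(a$image), c(64L, 64L, 3L))
  expect_equal(dim(a$mask), c(64L, 64L))
})

test_that("single-blob foreground fraction matches the analytic ellipse area", {
  spec <- scene_spec(side = 64, n_blobs = c(1, 1), radius = c(0.2, 0.2))
  for (seed in 1:10) {
    s <- generate_scene(spec, seed = seed)
    frac <- mean(s$mask)
    expect_gt(frac, 0.08)
    expect_lt(frac, 0.17)
  }
})

test_that("foreground fraction over many seeds matches expectation within 3 SE", {
  spec <- scene_spec(side = 64, n_blobs = c(1, 1), radius = c(0.08, 0.25))
  fracs <- vapply(1:300, function(i) mean(generate_scene(spec, i)$mask),
                  numeric(1))
  r <- spec$radius
  expected <- pi * (r[1]^2 + r[1] * r[2] + r[2]^2) / 3
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected), 3 * se + 2 / 64^2)
})

test_that("noiseless binary scene thresholds back to its mask away from soft edges", {
  spec <- scene_spec(side = 64, n_blobs = c(1, 1), radius = c(0.15, 0.25),
                     bg_intensity = 0, fg_intensity = 1, noise_sd = 0,
                     edge_softness = 0.5)
  s <- generate_scene(spec, seed = 3)
  lum <- (s$image[, , 1] / 1.15 + s$image[, , 2] / 0.95 + s$image[, , 3] / 0.9) / 3
  thresholded <- (lum > 0.5) + 0
  # exclude a 2-pixel band around the mask boundary
  interior <- s$mask
  exterior <- 1 - s$mask
  for (rep in 1:2) {
    interior <- interior *
      rbind(interior[-1, ], 0) * rbind(0, interior[-64, ]) *
      cbind(interior[, -1], 0) * cbind(0, interior[, -64])
    exterior <- exterior *
      rbind(exterior[-1, ], 0) * rbind(0, exterior[-64, ]) *
      cbind(exterior[, -1], 0) * cbind(0, exterior[, -64])
  }
  expect_true(all(thresholded[interior == 1] == 1))
  expect_true(all(thresholded[exterior == 1] == 0))
})

test_that("identity augmentation returns the sample unchanged", {
  s <- generate_scene(scene_spec(side = 32), seed = 1)
  a <- augment_sample(s, identity_augmentation_config(), seed = 9)
  expect_equal(a$image, s$image)
  expect_equal(a$mask, s$mask)
})

test_that("augmentation is bit-identical under a fixed seed", {
  s <- generate_scene(scene_spec(side = 32), seed = 2)
  cfg <- augmentation_config()
  a <- augment_sample(s, cfg, seed = 123)
  b <- augment_sample(s, cfg, seed = 123)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- augment_sample(s, cfg, seed = 124)
  expect_false(identical(a$image, c$image))
})

test_that("augmented output stays binary-masked and range-clipped", {
  s <- generate_scene(scene_spec(side = 32), seed = 5)
  cfg <- augmentation_config()
  for (seed in 1:8) {
    a <- augment_sample(s, cfg, seed = seed)
    expect_true(all(a$mask %in% c(0, 1)))
    expect_true(min(a$image) >= 0 && max(a$image) <= 1)
    expect_equal(dim(a$image), dim(s$image))
  }
})

test_that("a pure horizontal flip mirrors the mask centroid", {
  s <- generate_scene(scene_spec(side = 64, n_blobs = c(1, 1)), seed = 7)
  cfg <- augmentation_config(brightness = c(0, 0), zoom = c(1, 1),
                             flip_prob = 1, shift = 0, rotation = c(0, 0),
                             channel_shift = 0)
  a <- augment_sample(s, cfg, seed = 1)
  cols <- matrix(rep(seq_len(64), each = 64), 64, 64)
  cx <- sum(cols * s$mask) / sum(s$mask)
  cx_flipped <- sum(cols * a$mask) / sum(a$mask)
  expect_equal(cx_flipped, 65 - cx, tolerance = 1e-10)
  expect_equal(sum(a$mask), sum(s$mask))
})

test_that("mask and image share one geometric transform path", {
  s <- generate_scene(scene_spec(side = 32), seed = 4)
  cfg <- augmentation_config()
  a <- augment_sample(s, cfg, seed = 55)
  par <- attr(a, "params")
  redone <- mbffnet:::cpp_affine_sample(array(s$mask, c(32, 32, 1)),
                                        par$affine, FALSE, FALSE)[, , 1]
  redone <- (redone >= 0.5) + 0
  inter <- sum(redone * a$mask)
  union <- sum((redone + a$mask) > 0)
  expect_equal(inter / max(union, 1), 1)
})

test_that("split is seeded, disjoint and exhaustive with round(0.8 n) train", {
  samples <- as.list(1:10)
  sp <- split_samples(samples, 0.8, seed = 3)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_setequal(c(unlist(sp$train), unlist(sp$test)), 1:10)
  sp2 <- split_samples(samples, 0.8, seed = 3)
  expect_identical(sp, sp2)
  expect_equal(round(0.8 * 1450), 1160)
  expect_error(split_samples(list(1), 0.8, 1), "at least 2")
})

test_that("PNG pairs round-trip through load_sample with binarization and resizing", {
  dir <- withr::local_tempdir()
  s <- generate_scene(scene_spec(side = 48), seed = 6)
  ip <- file.path(dir, "img.png")
  mp <- file.path(dir, "msk.png")
  png::writePNG(s$image, ip)
  png::writePNG(s$mask, mp)
  back <- load_sample(ip, mp)
  expect_equal(back$mask, s$mask)
  expect_equal(back$image, s$image, tolerance = 1 / 255)
  resized <- load_sample(ip, mp, size = 32)
  expect_equal(dim(resized$image), c(32L, 32L, 3L))
  expect_equal(dim(resized$mask), c(32L, 32L))
  expect_true(all(resized$mask %in% c(0, 1)))
  # mismatched mask size is a dimension error
  png::writePNG(matrix(0, 24, 24), file.path(dir, "bad.png"))
  expect_error(load_sample(ip, file.path(dir, "bad.png")), "dimension error")
  expect_error(load_sample(file.path(dir, "nope.png"), mp), "not found")
})

test_that("dataset directories round-trip through write_dataset/load_dataset", {
  dir <- withr::local_tempdir()
  scenes <- generate_dataset(3, scene_spec(side = 32), seed = 11)
  write_dataset(scenes, dir)
  back <- load_dataset(dir)
  expect_length(back, 3)
  expect_equal(back[[2]]$mask, scenes[[2]]$mask)
})
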