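# Architecture contracts: encoder pyramid, multiplicative fusion, pyramid
# branch, full forward pass, and analytic-vs-numeric gradients.

test_that("encoder produces five halving stages with configured widths", {
  cfg <- tiny_mbff_config(64)
  m <- build_mbffnet(cfg, seed = 1)
  pyr <- encode(m, random_image(64))
  sides <- vapply(pyr$stages, function(s) dim(s)[1], numeric(1))
  chans <- vapply(pyr$stages, function(s) dim(s)[3], numeric(1))
  expect_equal(sides, c(64, 32, 16, 8, 4))
  expect_equal(chans, as.numeric(cfg$encoder_widths))

  pyr32 <- encode(m, random_image(32))
  expect_equal(vapply(pyr32$stages, function(s) dim(s)[1], numeric(1)),
               c(32, 16, 8, 4, 2))
})

test_that("default configuration has the stated stage widths and pyramid concat width", {
  cfg <- mbff_config()
  expect_equal(cfg$encoder_widths, c(64L, 128L, 256L, 512L, 512L))
  expect_equal(sum(cfg$encoder_widths), 1472L)
  arch <- mbff_architecture(cfg)
  expect_equal(arch$ci[arch$name == "pyr_compress"], 1472L)
})

test_that("invalid input geometry raises a dimension error naming the axis", {
  m <- build_mbffnet(tiny_mbff_config(32), seed = 1)
  bad <- array(runif(40 * 40 * 3), c(40, 40, 3))
  expect_error(forward(m, bad), "height 40 not divisible by 16")
  rect <- array(runif(32 * 48 * 3), c(32, 48, 3))
  expect_error(forward(m, rect), "not square")
  expect_error(mbff_config(input_size = 250), "not divisible by 16")
  gray <- array(runif(32 * 32), c(32, 32, 1))
  expect_error(forward(m, gray), "3-channel")
})

test_that("multiplicative fusion honours shape, identity and annihilation", {
  set.seed(2)
  deep <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  skip <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  out <- multiplicative_fuse(deep, skip, out_channels = 6, seed = 4)
  expect_equal(dim(out), c(8L, 8L, 6L))
  expect_error(multiplicative_fuse(deep, array(0, c(9, 9, 5)), 6), "shape")

  # identity normalization with zero projection weights and bias 1/0 makes
  # the attention exactly one/zero
  layers <- list(
    proj = list(W = matrix(0, 5, 3 * 9), b = rep(1, 5), k = 3L),
    refine1 = mbffnet:::new_conv_layer("r1", 5, 6, 3)
  )
  ones <- multiplicative_fuse(deep, skip, 6, normalization = "identity",
                              layers = layers)
  expect_equal(attr(ones, "product"), skip)
  refined_skip <- mbffnet:::relu(mbffnet:::conv_fw(layers$refine1, skip))
  expect_equal(as.numeric(ones), as.numeric(refined_skip))

  layers$proj$b <- rep(0, 5)
  zeros <- multiplicative_fuse(deep, skip, 6, normalization = "identity",
                               layers = layers)
  expect_true(all(attr(zeros, "product") == 0))
})

test_that("sigmoid attention weights are bounded in (0, 1)", {
  m <- build_mbffnet(tiny_mbff_config(32), seed = 5)
  set.seed(6)
  deep <- array(rnorm(8 * 8 * 8, sd = 3), c(8, 8, 8))
  skip <- array(rnorm(16 * 16 * 8, sd = 3), c(16, 16, 8))
  out <- multiplicative_fuse(deep, skip, 8, normalization = "sigmoid",
                             seed = 6)
  att <- attr(out, "attention")
  expect_true(all(att >= 0 & att <= 1))
})

test_that("decode_main and pyramid_branch have the contracted shapes", {
  cfg <- tiny_mbff_config(64)
  m <- build_mbffnet(cfg, seed = 1)
  pyr <- encode(m, random_image(64))
  dm <- decode_main(m, pyr)
  expect_equal(dim(dm), c(64L, 64L, cfg$decoder_widths[4]))
  pb <- pyramid_branch(m, pyr)
  expect_equal(dim(pb), c(32L, 32L, cfg$pyramid_channels))
  # a pyramid with a stage removed violates the contract
  broken <- structure(list(stages = pyr$stages[-3]), class = "encoder_pyramid")
  expect_error(decode_main(m, broken), "shape error")
})

test_that("pyramid branch maps constant stages to per-channel constants before the nonlinearity", {
  cfg <- tiny_mbff_config(32)
  m <- build_mbffnet(cfg, seed = 8)
  stages <- lapply(1:5, function(s)
    array(0.5, c(32 / 2^(s - 1), 32 / 2^(s - 1), cfg$encoder_widths[s])))
  pyr <- structure(list(stages = stages), class = "encoder_pyramid")
  pb <- pyramid_branch(m, pyr)
  for (c in seq_len(dim(pb)[3]))
    expect_lt(diff(range(pb[, , c])), 1e-10)
})

test_that("forward conserves shape and yields probabilities, deterministically", {
  for (side in c(32, 64)) {
    m <- build_mbffnet(tiny_mbff_config(side), seed = 2)
    img <- random_image(side, seed = side)
    p1 <- forward(m, img)
    expect_equal(dim(p1), c(side, side, 1L))
    expect_true(all(p1 > 0 & p1 < 1))
    p2 <- forward(m, img)
    expect_identical(p1, p2)
  }
})

test_that("the reference unet conserves shape and probability range", {
  m <- build_unet(tiny_unet_config(32), seed = 3)
  p <- forward(m, random_image(32))
  expect_equal(dim(p), c(32L, 32L, 1L))
  expect_true(all(p > 0 & p < 1))
  # concat width at the first decoder step: deep channels + stage-4 skip
  arch <- unet_architecture(tiny_unet_config(32))
  expect_equal(arch$ci[arch$name == "up1_conv1"],
               tail(tiny_unet_config(32)$encoder_widths, 1) +
                 tiny_unet_config(32)$encoder_widths[4])
  # seeded initialization is reproducible
  m2 <- build_unet(tiny_unet_config(32), seed = 3)
  expect_identical(m$layers, m2$layers)
})

test_that("analytic gradients match finite differences", {
  for (setup in list(
    list(build = build_mbffnet, cfg = tiny_mbff_config(32)),
    list(build = build_mbffnet, cfg = tiny_mbff_config(32, "softmax")),
    list(build = build_unet, cfg = tiny_unet_config(32))
  )) {
    m <- setup$build(setup$cfg, seed = 7)
    smp <- generate_scene(scene_spec(side = 32), seed = 5)
    g <- mbffnet:::loss_and_grad(m, smp)$grads
    set.seed(20)
    for (nm in sample(names(m$layers), 6)) {
      idx <- sample(length(m$layers[[nm]]$W), 2)
      for (i in idx) {
        h <- 1e-5
        up <- m; up$layers[[nm]]$W[i] <- up$layers[[nm]]$W[i] + h
        dn <- m; dn$layers[[nm]]$W[i] <- dn$layers[[nm]]$W[i] - h
        num <- (mbffnet:::loss_and_grad(up, smp)$loss -
                  mbffnet:::loss_and_grad(dn, smp)$loss) / (2 * h)
        rel <- abs(g[[nm]]$dW[i] - num) / (abs(g[[nm]]$dW[i]) + abs(num) + 1e-6)
        expect_lt(rel, 2e-3)
      }
    }
  }
})

test_that("every trainable tensor receives a nonzero gradient", {
  for (m in list(build_mbffnet(tiny_mbff_config(32), seed = 9),
                 build_unet(tiny_unet_config(32), seed = 9))) {
    smp <- generate_scene(scene_spec(side = 32), seed = 6)
    g <- mbffnet:::loss_and_grad(m, smp)$grads
    expect_setequal(names(g), names(m$layers))
    for (nm in names(m$layers))
      expect_gt(max(abs(g[[nm]]$dW)), 0)
  }
})

test_that("checkpoints round-trip through save and load", {
  m <- build_mbffnet(tiny_mbff_config(32), seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  img <- random_image(32)
  expect_identical(forward(m, img), forward(back, img))
  expect_error(load_checkpoint(tempfile()), "not found")
})
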