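# Closed-form convolutional parameter / FLOP accounting.

test_that("layer_params and layer_flops follow the closed forms", {
  expect_equal(layer_params(conv_layer_spec("a", 3, 64, 3, 3, 256, 256)), 1728)
  expect_equal(layer_params(conv_layer_spec("b", 1, 1, 1, 1, 1, 1)), 1)
  expect_equal(layer_flops(conv_layer_spec("a", 3, 64, 3, 3, 256, 256)),
               113246208)
  expect_equal(layer_flops(conv_layer_spec("b", 1, 1, 1, 1, 1, 1)), 1)
})

test_that("flops / params equals the output area for any layer", {
  set.seed(42)
  for (i in 1:20) {
    spec <- conv_layer_spec(paste0("l", i), sample(1:64, 1), sample(1:64, 1),
                            sample(c(1, 3), 1), sample(c(1, 3), 1),
                            sample(1:128, 1), sample(1:128, 1))
    expect_equal(layer_flops(spec) / layer_params(spec),
                 spec$lwo * spec$lho)
  }
})

test_that("the 13 standard VGG16 convolutions sum per the double-loop oracle", {
  widths <- c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512, 512)
  ci <- c(3, widths[-13])
  vgg <- do.call(rbind, lapply(seq_along(widths), function(i)
    conv_layer_spec(paste0("conv", i), ci[i], widths[i], 3, 3, 1, 1)))
  # independent oracle: explicit per-layer double loop over the table
  oracle <- 0
  for (i in seq_along(widths)) oracle <- oracle + ci[i] * widths[i] * 3 * 3
  expect_equal(oracle, 14710464)
  expect_equal(sum(layer_params(vgg)), oracle)
})

test_that("model totals are exact sums and M/B renderings round to 2 dp", {
  two <- rbind(conv_layer_spec("a", 3, 64, 3, 3, 8, 8),
               conv_layer_spec("b", 3, 64, 3, 3, 8, 8))
  rep2 <- model_complexity(two)
  expect_equal(rep2$total_params, 3456)
  expect_equal(rep2$total_params, sum(rep2$layers$params))
  expect_equal(rep2$total_flops, sum(rep2$layers$flops))
  expect_equal(rep2$params_m, round(3456 / 1e6, 2))
  expect_error(model_complexity(two[0, ]), "empty")
})

test_that("doubling output extents quadruples flops, params unchanged", {
  base <- mbff_architecture(tiny_mbff_config(), input_size = 32)
  dbl <- base
  dbl$lwo <- dbl$lwo * 2L
  dbl$lho <- dbl$lho * 2L
  a <- model_complexity(base)
  b <- model_complexity(dbl)
  expect_equal(b$total_flops, 4 * a$total_flops)
  expect_equal(b$total_params, a$total_params)
})

test_that("analytic totals match hand loop and instantiated weights on random architectures", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    e <- sort(sample(c(2, 4, 8, 16), 4, replace = TRUE))
    e <- as.integer(c(e, e[4]))
    mk <- if (seed %% 2 == 0) {
      cfg <- unet_config(input_size = 32, encoder_widths = e,
                         decoder_widths = as.integer(sample(c(2, 4, 8), 4,
                                                            replace = TRUE)))
      list(cfg = cfg, model = build_unet(cfg, seed = seed),
           arch = unet_architecture(cfg, input_size = 32))
    } else {
      cfg <- mbff_config(input_size = 32, encoder_widths = e,
                         decoder_widths = as.integer(sample(c(2, 4, 8), 4,
                                                            replace = TRUE)),
                         pyramid_channels = sample(c(2L, 4L), 1),
                         head_channels = sample(c(2L, 4L), 1))
      list(cfg = cfg, model = build_mbffnet(cfg, seed = seed),
           arch = mbff_architecture(cfg, input_size = 32))
    }
    # (a) hand-written per-layer double loop
    hand_params <- 0
    hand_flops <- 0
    for (r in seq_len(nrow(mk$arch))) {
      row <- mk$arch[r, ]
      hand_params <- hand_params + row$ci * row$co * row$kw * row$kh
      hand_flops <- hand_flops + row$ci * row$co * row$kw * row$kh *
        row$lwo * row$lho
    }
    rep_ <- model_complexity(mk$arch)
    expect_identical(rep_$total_params, hand_params)
    expect_identical(rep_$total_flops, hand_flops)
    # (b) the instantiated network's trainable conv-weight count, exactly
    expect_identical(count_conv_weights(mk$model), rep_$total_params)
  }
})

test_that("complexity_compare reports ratios and percent reductions", {
  a <- model_complexity(conv_layer_spec("a", 2, 2, 3, 3, 4, 4))
  b <- model_complexity(conv_layer_spec("b", 4, 4, 3, 3, 4, 4))
  cmp <- complexity_compare(a, b)
  expect_equal(cmp$param_ratio, 0.25)
  expect_equal(cmp$flop_reduction_pct, 75)
  self <- complexity_compare(a, a)
  expect_equal(self$param_reduction_pct, 0)
  expect_equal(self$flop_reduction_pct, 0)
})

test_that("architecture JSON round-trips through the exchange format", {
  arch <- mbff_architecture(tiny_mbff_config(), input_size = 32)
  path <- withr::local_tempfile(fileext = ".json")
  write_architecture_json(arch, path)
  back <- read_architecture_json(path)
  expect_equal(back, arch)
  expect_equal(model_complexity(back)$total_params,
               model_complexity(arch)$total_params)
})

test_that("invalid layer specifications are rejected", {
  expect_error(conv_layer_spec("bad", 0, 1, 1, 1, 1, 1), "positive")
  expect_error(conv_layer_spec("bad", 1, 1, 1.5, 1, 1, 1), "positive")
})
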