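# MBFFNet and the reference U-Net: weight instantiation, forward pass, and
# hand-written reverse-mode gradients over the Rcpp convolution engine.
# Both networks are fully convolutional, so a built model accepts any square
# input with side divisible by 16, independent of the configured size.

#' Build an MBFFNet model
#'
#' Instantiates every convolution of the configuration with He-uniform
#' weights under a fixed seed.
#'
#' @param config an [mbff_config()]
#' @param seed RNG seed for weight initialization
#' @return an object of class `"mbff_model"`
#' @export
build_mbffnet <- function(config = mbff_config(), seed = 1L) {
  stopifnot(identical(config$arch, "mbffnet"))
  build_model(config, seed)
}

#' Build the reference U-Net model
#'
#' @param config a [unet_config()]
#' @param seed RNG seed for weight initialization
#' @return an object of class `"mbff_model"`
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  stopifnot(identical(config$arch, "unet"))
  build_model(config, seed)
}

build_model <- function(config, seed) {
  plan <- model_plan(config)
  layers <- with_seed(seed, {
    out <- list()
    for (r in plan) out[[r$name]] <- new_conv_layer(r$name, r$ci, r$co, r$k)
    out
  })
  structure(list(config = config, layers = layers, seed = as.integer(seed)),
            class = "mbff_model")
}

#' @export
print.mbff_model <- function(x, ...) {
  cat(sprintf("<%s> %d conv layers, %.0f conv weights, input %dx%d\n",
              x$config$arch, length(x$layers), count_conv_weights(x),
              x$config$input_size, x$config$input_size))
  invisible(x)
}

validate_image <- function(x) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[3] != 3L)
    stop(sprintf("expected a 3-channel image, got %d channels", d[3]))
  if (d[1] != d[2])
    stop(sprintf("image is not square: height %d != width %d", d[1], d[2]))
  if (d[1] %% 16L != 0L)
    stop(sprintf("height %d not divisible by 16", d[1]))
  if (d[2] %% 16L != 0L)
    stop(sprintf("width %d not divisible by 16", d[2]))
  if (min(x) < -1e-8 || max(x) > 1 + 1e-8)
    stop("image values must be scaled to [0, 1]")
  x
}

validate_pyramid <- function(pyr) {
  stages <- if (inherits(pyr, "encoder_pyramid")) pyr$stages else pyr
  if (!is.list(stages) || length(stages) != 5L)
    stop("shape error: encoder pyramid must have exactly 5 stages")
  for (s in 2:5) {
    d0 <- dim(stages[[s - 1]])
    d1 <- dim(stages[[s]])
    if (d1[1] != d0[1] %/% 2L || d1[2] != d0[2] %/% 2L)
      stop(sprintf(
        "shape error: stage %d side %dx%d is not half of stage %d side %dx%d",
        s, d1[1], d1[2], s - 1, d0[1], d0[2]))
  }
  stages
}

# ---- pass environment -------------------------------------------------------

new_pass <- function(model, keep) {
  E <- new.env(parent = emptyenv())
  E$L <- model$layers
  E$keep <- keep
  E$cache <- list()
  E$grads <- list()
  E$n_refine <- model$config$n_refine %||% 2L
  E$norm_act <- switch(model$config$normalization %||% "sigmoid",
                       sigmoid = "sigmoid", softmax = "softmax",
                       identity = "none")
  E
}

fw_conv <- function(E, nm, x, act) {
  l <- E$L[[nm]]
  y <- cpp_conv2d_fw(x, l$W, l$b, l$k)
  out <- switch(act,
    relu = relu(y), none = y, sigmoid = sigmoid(y),
    softmax = softmax_pixels(y))
  if (E$keep) E$cache[[nm]] <- list(x = x, out = out, act = act)
  out
}

bw_conv <- function(E, nm, dout) {
  cc <- E$cache[[nm]]
  dout <- switch(cc$act,
    relu = dout * (cc$out > 0),
    none = dout,
    sigmoid = dout * cc$out * (1 - cc$out),
    softmax = {
      a <- cc$out
      r <- a
      for (c in seq_len(dim(a)[3]))
        r[, , c] <- a[, , c] * (dout[, , c] - sum(dout[, , c] * a[, , c]))
      r
    })
  l <- E$L[[nm]]
  g <- cpp_conv2d_bw(cc$x, l$W, dout, l$k)
  if (is.null(E$grads[[nm]])) {
    E$grads[[nm]] <- list(dW = g$dw, db = as.numeric(g$db))
  } else {
    E$grads[[nm]]$dW <- E$grads[[nm]]$dW + g$dw
    E$grads[[nm]]$db <- E$grads[[nm]]$db + as.numeric(g$db)
  }
  g$dx
}

# ---- encoder ----------------------------------------------------------------

.stage_convs <- c(2L, 2L, 3L, 3L, 3L)

encoder_fw <- function(E, x) {
  stages <- vector("list", 5L)
  h <- x
  for (s in 1:5) {
    if (s > 1L) {
      mp <- cpp_maxpool2_fw(h)
      if (E$keep)
        E$cache[[sprintf("pool%d", s - 1L)]] <-
          list(idx = mp$idx, H = dim(h)[1], W = dim(h)[2])
      h <- mp$y
    }
    for (v in seq_len(.stage_convs[s]))
      h <- fw_conv(E, sprintf("enc%d_%d", s, v), h, "relu")
    stages[[s]] <- h
  }
  stages
}

encoder_bw <- function(E, dstages) {
  d <- dstages[[5]]
  for (s in 5:1) {
    for (v in rev(seq_len(.stage_convs[s])))
      d <- bw_conv(E, sprintf("enc%d_%d", s, v), d)
    if (s > 1L) {
      pc <- E$cache[[sprintf("pool%d", s - 1L)]]
      d <- cpp_maxpool2_bw(d, pc$idx, pc$H, pc$W)
      if (!is.null(dstages[[s - 1L]])) d <- d + dstages[[s - 1L]]
    }
  }
  invisible(d)
}

# ---- multiplicative fusion --------------------------------------------------

fuse_fw <- function(E, j, deep, skip) {
  u <- cpp_upsample2_fw(deep)
  att <- fw_conv(E, sprintf("dec%d_proj", j), u, E$norm_act)
  m <- att * skip
  if (E$keep) E$cache[[sprintf("dec%d_mul", j)]] <- list(att = att, skip = skip)
  h <- fw_conv(E, sprintf("dec%d_refine1", j), m, "relu")
  if (E$n_refine == 2L) h <- fw_conv(E, sprintf("dec%d_refine2", j), h, "relu")
  h
}

fuse_bw <- function(E, j, dh) {
  if (E$n_refine == 2L) dh <- bw_conv(E, sprintf("dec%d_refine2", j), dh)
  dm <- bw_conv(E, sprintf("dec%d_refine1", j), dh)
  mc <- E$cache[[sprintf("dec%d_mul", j)]]
  du <- bw_conv(E, sprintf("dec%d_proj", j), dm * mc$skip)
  list(ddeep = cpp_upsample2_bw(du), dskip = dm * mc$att)
}

# ---- pyramid branch ---------------------------------------------------------

pyramid_fw <- function(E, stages) {
  p1 <- fw_conv(E, "pyr_pre", stages[[1]], "relu")
  mp <- cpp_maxpool2_fw(p1)
  if (E$keep)
    E$cache[["pool_pyr"]] <- list(idx = mp$idx, H = dim(p1)[1], W = dim(p1)[2])
  p3 <- cpp_upsample2_fw(stages[[3]])
  p4 <- cpp_upsample2_fw(cpp_upsample2_fw(stages[[4]]))
  p5 <- cpp_upsample2_fw(cpp_upsample2_fw(cpp_upsample2_fw(stages[[5]])))
  cat <- cat_channels(mp$y, stages[[2]], p3, p4, p5)
  fw_conv(E, "pyr_compress", cat, "relu")
}

pyramid_bw <- function(E, dpy, widths) {
  dcat <- bw_conv(E, "pyr_compress", dpy)
  ends <- cumsum(widths)
  starts <- c(1L, ends[-5] + 1L)
  slice <- function(i) dcat[, , starts[i]:ends[i], drop = FALSE]
  pc <- E$cache[["pool_pyr"]]
  dp1 <- cpp_maxpool2_bw(slice(1), pc$idx, pc$H, pc$W)
  list(
    d1 = bw_conv(E, "pyr_pre", dp1),
    d2 = slice(2),
    d3 = cpp_upsample2_bw(slice(3)),
    d4 = cpp_upsample2_bw(cpp_upsample2_bw(slice(4))),
    d5 = cpp_upsample2_bw(cpp_upsample2_bw(cpp_upsample2_bw(slice(5))))
  )
}

# ---- full networks ----------------------------------------------------------

mbff_fw <- function(E, x) {
  stages <- encoder_fw(E, x)
  h <- stages[[5]]
  for (j in 1:4) h <- fuse_fw(E, j, h, stages[[5L - j]])
  py <- pyramid_fw(E, stages)
  pu <- cpp_upsample2_fw(py)
  hcat <- cat_channels(h, pu)
  hf <- fw_conv(E, "head_fuse", hcat, "relu")
  logit <- fw_conv(E, "head_logit", hf, "none")
  if (E$keep) E$cache[["split_head"]] <- dim(h)[3]
  sigmoid(logit)
}

mbff_bw <- function(E, dlogit, widths) {
  dhf <- bw_conv(E, "head_logit", dlogit)
  dhcat <- bw_conv(E, "head_fuse", dhf)
  w4 <- E$cache[["split_head"]]
  ddec <- dhcat[, , seq_len(w4), drop = FALSE]
  dpu <- dhcat[, , (w4 + 1L):dim(dhcat)[3], drop = FALSE]
  dpy <- cpp_upsample2_bw(dpu)
  dp <- pyramid_bw(E, dpy, widths)
  dstages <- list(dp$d1, dp$d2, dp$d3, dp$d4, dp$d5)
  d <- ddec
  for (j in 4:1) {
    r <- fuse_bw(E, j, d)
    dstages[[5L - j]] <- dstages[[5L - j]] + r$dskip
    d <- r$ddeep
  }
  dstages[[5]] <- dstages[[5]] + d
  encoder_bw(E, dstages)
}

unet_fw <- function(E, x) {
  stages <- encoder_fw(E, x)
  h <- stages[[5]]
  for (j in 1:4) {
    u <- cpp_upsample2_fw(h)
    skip <- stages[[5L - j]]
    if (E$keep) E$cache[[sprintf("split%d", j)]] <- dim(u)[3]
    h <- fw_conv(E, sprintf("up%d_conv1", j), cat_channels(u, skip), "relu")
    h <- fw_conv(E, sprintf("up%d_conv2", j), h, "relu")
  }
  logit <- fw_conv(E, "head_logit", h, "none")
  sigmoid(logit)
}

unet_bw <- function(E, dlogit) {
  d <- bw_conv(E, "head_logit", dlogit)
  dstages <- vector("list", 5L)
  for (j in 4:1) {
    d <- bw_conv(E, sprintf("up%d_conv2", j), d)
    dcat <- bw_conv(E, sprintf("up%d_conv1", j), d)
    cu <- E$cache[[sprintf("split%d", j)]]
    du <- dcat[, , seq_len(cu), drop = FALSE]
    dstages[[5L - j]] <- dcat[, , (cu + 1L):dim(dcat)[3], drop = FALSE]
    d <- cpp_upsample2_bw(du)
  }
  dstages[[5]] <- d
  encoder_bw(E, dstages)
}

net_fw <- function(E, model, x) {
  if (model$config$arch == "mbffnet") mbff_fw(E, x) else unet_fw(E, x)
}

net_bw <- function(E, model, dlogit) {
  if (model$config$arch == "mbffnet") {
    mbff_bw(E, dlogit, model$config$encoder_widths)
  } else {
    unet_bw(E, dlogit)
  }
}

# ---- public operations ------------------------------------------------------

#' Encode an image into the five-stage feature pyramid
#'
#' Runs the VGG16-style encoder: stage `i` has spatial side
#' `side / 2^(i-1)` and the configured channel width.
#'
#' @param model a built model
#' @param image H x W x 3 array, square, side divisible by 16, values in
#'   \\[0, 1\\]
#' @return an object of class `"encoder_pyramid"` with element `stages`, a
#'   list of five feature maps
#' @export
encode <- function(model, image) {
  stopifnot(inherits(model, "mbff_model"))
  image <- validate_image(image)
  E <- new_pass(model, keep = FALSE)
  structure(list(stages = encoder_fw(E, image)), class = "encoder_pyramid")
}

#' Stepwise multiplicative-fusion decoding
#'
#' Applies the four multiplicative fusion steps, pairing stage 5 with stage
#' 4, then the result with stages 3, 2, 1, and returns a full-resolution
#' feature map with the last decoder width.
#'
#' @param model a built MBFFNet
#' @param pyramid an `"encoder_pyramid"` from [encode()]
#' @return a feature map at the input resolution
#' @export
decode_main <- function(model, pyramid) {
  stopifnot(inherits(model, "mbff_model"),
            identical(model$config$arch, "mbffnet"))
  stages <- validate_pyramid(pyramid)
  E <- new_pass(model, keep = FALSE)
  h <- stages[[5]]
  for (j in 1:4) h <- fuse_fw(E, j, h, stages[[5L - j]])
  h
}

#' Hourglass pyramid branch
#'
#' Resizes all five encoder stages to the stage-2 reference resolution
#' (stage 1 through a 1x1 convolution and 2x2 max pooling; stage 2
#' unchanged; stages 3-5 by repeated bilinear doubling), concatenates them
#' along channels and compresses with a convolution + ReLU.
#'
#' @inheritParams decode_main
#' @return a feature map at half the input resolution with the configured
#'   pyramid compression width
#' @export
pyramid_branch <- function(model, pyramid) {
  stopifnot(inherits(model, "mbff_model"),
            identical(model$config$arch, "mbffnet"))
  stages <- validate_pyramid(pyramid)
  E <- new_pass(model, keep = FALSE)
  pyramid_fw(E, stages)
}

#' Full forward pass
#'
#' Produces the per-pixel polyp probability map at the input resolution.
#'
#' @inheritParams encode
#' @return an H x W x 1 array with values strictly in (0, 1)
#' @export
forward <- function(model, image) {
  stopifnot(inherits(model, "mbff_model"))
  image <- validate_image(image)
  E <- new_pass(model, keep = FALSE)
  net_fw(E, model, image)
}

#' Predict a probability map or binary mask
#'
#' @param object a built model
#' @param image input image as in [encode()]
#' @param type `"prob"` for the probability map, `"mask"` for the
#'   thresholded binary mask
#' @param threshold binarization threshold for `type = "mask"`
#' @param ... unused
#' @return probability array or 0/1 integer matrix
#' @export
predict.mbff_model <- function(object, image, type = c("prob", "mask"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  p <- forward(object, image)
  if (type == "prob") return(p)
  (p[, , 1] >= threshold) + 0L
}

#' Multiplicative attention fusion of two feature maps
#'
#' The elementary decoder operation: the deeper map is up-sampled by a
#' factor of 2 (bilinear), projected by a convolution to the skip map's
#' channel count, normalized to attention weights, multiplied element-wise
#' with the skip map (pixel-level attention), and refined by convolution +
#' ReLU to `out_channels`.
#'
#' @param deep feature map with half the spatial side of `skip`
#' @param skip skip feature map
#' @param out_channels channels of the fused output
#' @param normalization `"sigmoid"`, `"softmax"` or `"identity"`
#' @param proj_kernel kernel of the projection convolution
#' @param n_refine number of refinement convolutions (1 or 2)
#' @param layers optional named list with layers `proj`, `refine1`,
#'   (`refine2`) from [new_conv_layer()]; freshly initialized when `NULL`
#' @param seed seed for fresh layer initialization
#' @return the fused feature map, with attributes `"attention"` (the
#'   normalized weights) and `"product"` (the pre-refinement element-wise
#'   product)
#' @export
multiplicative_fuse <- function(deep, skip, out_channels,
                                normalization = c("sigmoid", "softmax",
                                                  "identity"),
                                proj_kernel = 3L, n_refine = 2L,
                                layers = NULL, seed = 1L) {
  normalization <- match.arg(normalization)
  deep <- as_feature_map(deep)
  skip <- as_feature_map(skip)
  dd <- dim(deep)
  ds <- dim(skip)
  if (ds[1] != 2L * dd[1] || ds[2] != 2L * dd[2])
    stop(sprintf("shape error: skip side %dx%d is not twice deep side %dx%d",
                 ds[1], ds[2], dd[1], dd[2]))
  if (is.null(layers)) {
    layers <- with_seed(seed, list(
      proj = new_conv_layer("proj", dd[3], ds[3], proj_kernel),
      refine1 = new_conv_layer("refine1", ds[3], out_channels, 3L),
      refine2 = if (n_refine == 2L)
        new_conv_layer("refine2", out_channels, out_channels, 3L)
    ))
  }
  u <- cpp_upsample2_fw(deep)
  pre <- conv_fw(layers$proj, u)
  att <- switch(normalization, sigmoid = sigmoid(pre),
                softmax = softmax_pixels(pre), identity = pre)
  m <- att * skip
  h <- relu(conv_fw(layers$refine1, m))
  if (!is.null(layers$refine2)) h <- relu(conv_fw(layers$refine2, h))
  attr(h, "attention") <- att
  attr(h, "product") <- m
  h
}

# ---- checkpoints ------------------------------------------------------------

#' Save or load model weights
#'
#' Checkpoints store the configuration and all layer weights in R's native
#' serialization format.
#'
#' @param model a built model
#' @param path checkpoint file path
#' @return `load_checkpoint()` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mbff_model"))
  saveRDS(list(config = model$config, layers = model$layers,
               seed = model$seed), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  x <- readRDS(path)
  structure(list(config = x$config, layers = x$layers, seed = x$seed),
            class = "mbff_model")
}
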