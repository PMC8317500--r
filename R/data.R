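# Paired image/mask I/O, augmentation, splitting, and the seeded synthetic
# polyp-scene generator. Scenes emulate the geometry of endoscopic polyp
# frames at desk scale: a textured background and one or more bright,
# soft-edged elliptical blobs with a paired binary ground-truth mask.

#' Synthetic scene specification
#'
#' Parameters of the seeded scene generator. Defaults describe the
#' desk-scale study condition: 64-pixel frames with one to three bright
#' elliptical blobs over a textured darker background.
#'
#' Blob semi-axes are `r*sqrt(e)` and `r/sqrt(e)` for a radius fraction `r`
#' and eccentricity ratio `e`, so the ellipse area is exactly `pi * r^2`
#' (in units of the squared side) regardless of eccentricity, and the
#' expected single-blob foreground fraction has the closed form
#' `pi * (rmin^2 + rmin*rmax + rmax^2) / 3`.
#'
#' @param side square frame side in pixels (at least 32)
#' @param n_blobs integer range `c(min, max)` of blob count
#' @param radius range of blob radius as a fraction of the side, within
#'   (0, 0.5)
#' @param eccentricity range of the axis-ratio `e >= 1`
#' @param bg_intensity,fg_intensity background and blob base luminance
#' @param noise_sd standard deviation of the Gaussian texture noise
#' @param edge_softness width in pixels of the soft blob edge
#' @param seed default seed consumed by [generate_scene()]
#' @return a list of class `"scene_spec"`
#' @export
scene_spec <- function(side = 64L, n_blobs = c(1L, 3L),
                       radius = c(0.08, 0.25), eccentricity = c(1, 2),
                       bg_intensity = 0.35, fg_intensity = 0.75,
                       noise_sd = 0.05, edge_softness = 1.5, seed = 1L) {
  stopifnot(side >= 32L, length(radius) == 2L,
            radius[1] > 0, radius[2] < 0.5, radius[1] <= radius[2],
            all(eccentricity >= 1), n_blobs[1] >= 1L)
  structure(list(side = as.integer(side), n_blobs = as.integer(n_blobs),
                 radius = radius, eccentricity = eccentricity,
                 bg_intensity = bg_intensity, fg_intensity = fg_intensity,
                 noise_sd = noise_sd, edge_softness = edge_softness,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

new_seg_sample <- function(image, mask) {
  image <- as_feature_map(image)
  mask <- as.matrix(mask)
  if (!identical(dim(image)[1:2], dim(mask)))
    stop(sprintf("dimension error: image %dx%d vs mask %dx%d",
                 dim(image)[1], dim(image)[2], dim(mask)[1], dim(mask)[2]))
  if (!all(mask %in% c(0, 1))) stop("mask values must be 0/1")
  structure(list(image = image, mask = mask), class = "seg_sample")
}

# slight fixed per-channel gains (mean 1) give scenes a reddish mucosa tint
.channel_gains <- c(1.15, 0.95, 0.90)

#' Generate one synthetic polyp scene
#'
#' Renders 1..k soft-edged rotated elliptical blobs with an intensity
#' offset over a textured background (low-frequency texture plus per-pixel
#' Gaussian noise). The mask is the union of the exact elliptical supports
#' before edge softening. The output is fully determined by the seed.
#'
#' @param spec a [scene_spec()]
#' @param seed RNG seed; defaults to the spec's own
#' @return a `"seg_sample"`: list with `image` (side x side x 3, values in
#'   \\[0, 1\\]) and `mask` (side x side 0/1 matrix)
#' @export
generate_scene <- function(spec = scene_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$side
  with_seed(seed, {
    # low-frequency texture: coarse noise grid up-sampled bilinearly
    coarse_n <- max(4L, n %/% 8L)
    coarse <- array(rnorm(coarse_n^2, sd = spec$noise_sd), c(coarse_n, coarse_n, 1L))
    tex <- cpp_resize(coarse, n, n, TRUE)[, , 1]
    fine <- matrix(rnorm(n * n, sd = spec$noise_sd), n, n)

    k <- if (spec$n_blobs[1] >= spec$n_blobs[2]) spec$n_blobs[1] else
      sample(spec$n_blobs[1]:spec$n_blobs[2], 1L)
    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column coordinate
    ys <- matrix(rep(seq_len(n), times = n), n, n)  # row coordinate
    mask <- matrix(0, n, n)
    alpha <- matrix(0, n, n)
    for (b in seq_len(k)) {
      r <- runif(1, spec$radius[1], spec$radius[2]) * n
      e <- runif(1, spec$eccentricity[1], spec$eccentricity[2])
      a_ax <- r * sqrt(e)
      b_ax <- r / sqrt(e)
      th <- runif(1, 0, pi)
      margin <- min(a_ax + 1, (n - 1) / 2)
      cx <- runif(1, margin, n - 1 - margin) + 1
      cy <- runif(1, margin, n - 1 - margin) + 1
      dx <- xs - cx
      dy <- ys - cy
      u <- cos(th) * dx + sin(th) * dy
      v <- -sin(th) * dx + cos(th) * dy
      d <- sqrt((u / a_ax)^2 + (v / b_ax)^2)
      mask[d <= 1] <- 1
      # signed distance approximation in pixels, smoothed over edge_softness
      sd_px <- (1 - d) * b_ax
      alpha_b <- clamp01(sd_px / max(spec$edge_softness, 1e-6) + 0.5)
      alpha <- pmax(alpha, alpha_b)
    }
    gray <- spec$bg_intensity + alpha * (spec$fg_intensity - spec$bg_intensity) +
      tex + fine
    img <- array(0, c(n, n, 3L))
    for (c in 1:3) img[, , c] <- clamp01(gray * .channel_gains[c])
    new_seg_sample(img, mask)
  })
}

#' Generate a list of seeded scenes
#'
#' Scene `i` uses a child seed derived deterministically from `seed` and
#' `i`, so any prefix of the dataset is reproducible.
#'
#' @param n number of scenes
#' @param spec a [scene_spec()]
#' @param seed base seed
#' @return list of `"seg_sample"` objects
#' @export
generate_dataset <- function(n, spec = scene_spec(), seed = 1L) {
  lapply(seq_len(n), function(i) generate_scene(spec, child_seed(seed, i)))
}

#' Write a synthetic dataset in the standard directory layout
#'
#' Writes `images/scene_%04d.png` and `masks/scene_%04d.png` pairs.
#'
#' @param samples list of `"seg_sample"` objects
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_dataset <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(samples)) {
    stem <- sprintf("scene_%04d.png", i)
    png::writePNG(samples[[i]]$image, file.path(dir, "images", stem))
    png::writePNG(samples[[i]]$mask, file.path(dir, "masks", stem))
  }
  invisible(dir)
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("file not found: ", path)
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading JPEG requires the EBImage package")
    img <- EBImage::imageData(EBImage::readImage(path))
    img <- if (length(dim(img)) == 2L) t(img) else aperm(img, c(2L, 1L, 3L))
  } else {
    stop("unsupported image format: ", ext)
  }
  img
}

#' Load a paired image and mask
#'
#' Reads PNG (or JPEG, via EBImage) files, scales the image to \\[0, 1\\]
#' with three channels, binarizes the mask at intensity 128 (of 255), and
#' optionally resamples both to a target side (bilinear for the image,
#' nearest for the mask).
#'
#' @param image_path,mask_path file paths; the mask must match the image's
#'   spatial size
#' @param size optional target side in pixels
#' @return a `"seg_sample"`
#' @export
load_sample <- function(image_path, mask_path, size = NULL) {
  img <- read_image_file(image_path)
  msk <- read_image_file(mask_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  if (length(dim(msk)) == 3L) msk <- msk[, , 1]
  if (!identical(dim(img)[1:2], dim(msk)))
    stop(sprintf("dimension error: image %dx%d vs mask %dx%d",
                 dim(img)[1], dim(img)[2], dim(msk)[1], dim(msk)[2]))
  msk <- (msk >= 128 / 255) + 0
  if (!is.null(size)) {
    img <- cpp_resize(img, size, size, TRUE)
    msk <- cpp_resize(array(msk, c(dim(msk), 1L)), size, size, FALSE)[, , 1]
  }
  new_seg_sample(clamp01(img), msk)
}

#' Load a dataset directory
#'
#' Expects `images/` and `masks/` subdirectories with matching file stems.
#'
#' @param dir dataset directory
#' @param size optional target side passed to [load_sample()]
#' @return list of `"seg_sample"` objects
#' @export
load_dataset <- function(dir, size = NULL) {
  imgs <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  if (length(imgs) == 0L) stop("no images found under ", dir)
  lapply(imgs, function(ip) {
    stem <- tools::file_path_sans_ext(basename(ip))
    mp <- list.files(file.path(dir, "masks"), pattern = paste0("^", stem, "\\."),
                     full.names = TRUE)
    if (length(mp) == 0L) stop("no mask for image ", basename(ip))
    load_sample(ip, mp[1], size = size)
  })
}

# ---- augmentation -----------------------------------------------------------

#' Augmentation configuration
#'
#' The training-time augmentation family: brightness offset, zoom,
#' horizontal flip, translation, rotation and per-channel intensity shift.
#' Geometric transforms are applied identically to image and mask through
#' one shared affine map; photometric transforms touch the image only.
#'
#' Conventions: `zoom` is a scale-factor range (values > 1 magnify);
#' `flip_prob` is a probability; `shift` is the maximum translation as a
#' fraction of the side, sampled uniformly in `[-shift, shift]` per axis;
#' `rotation` is a range in radians; `channel_shift` is the maximum
#' per-channel intensity offset on the 0-255 scale.
#'
#' @param brightness additive luminance offset range
#' @param zoom scale-factor range
#' @param flip_prob horizontal flip probability
#' @param shift maximum translation fraction
#' @param rotation rotation range in radians
#' @param channel_shift maximum per-channel shift (0-255 scale)
#' @return a list of class `"aug_config"`
#' @export
augmentation_config <- function(brightness = c(-0.2, 0.2),
                                zoom = c(0.75, 2),
                                flip_prob = 0.5,
                                shift = 0.5,
                                rotation = c(-0.5, 0.5),
                                channel_shift = 10) {
  stopifnot(flip_prob >= 0, flip_prob <= 1, diff(brightness) >= 0,
            diff(zoom) >= 0, zoom[1] > 0, diff(rotation) >= 0, shift >= 0)
  structure(list(brightness = brightness, zoom = zoom, flip_prob = flip_prob,
                 shift = shift, rotation = rotation,
                 channel_shift = channel_shift),
            class = "aug_config")
}

#' @rdname augmentation_config
#' @export
identity_augmentation_config <- function() {
  augmentation_config(brightness = c(0, 0), zoom = c(1, 1), flip_prob = 0,
                      shift = 0, rotation = c(0, 0), channel_shift = 0)
}

#' Augment a paired sample
#'
#' Draws one parameter per transform under the given seed and applies the
#' geometric transforms (zoom, flip, shift, rotation) through a single
#' affine map to both image and mask (bilinear with reflection padding for
#' the image; nearest with zero padding for the mask, re-binarized), then
#' the photometric transforms (brightness, channel shift) to the image
#' only. Output size is unchanged; the image is clipped back to \\[0, 1\\].
#'
#' @param sample a `"seg_sample"`
#' @param cfg an [augmentation_config()]
#' @param seed RNG seed; a fixed seed gives bit-identical output
#' @return the augmented `"seg_sample"`, with the drawn parameters attached
#'   as attribute `"params"` (including the inverse affine map `"affine"`)
#' @export
augment_sample <- function(sample, cfg = augmentation_config(), seed = 1L) {
  stopifnot(inherits(sample, "seg_sample"), inherits(cfg, "aug_config"))
  d <- dim(sample$image)
  par <- with_seed(seed, list(
    brightness = runif(1, cfg$brightness[1], cfg$brightness[2]),
    zoom = runif(1, cfg$zoom[1], cfg$zoom[2]),
    flip = runif(1) < cfg$flip_prob,
    shift_r = runif(1, -cfg$shift, cfg$shift) * d[1],
    shift_c = runif(1, -cfg$shift, cfg$shift) * d[2],
    theta = runif(1, cfg$rotation[1], cfg$rotation[2]),
    channel = runif(3, -cfg$channel_shift, cfg$channel_shift) / 255
  ))
  identity_geom <- par$zoom == 1 && !par$flip && par$shift_r == 0 &&
    par$shift_c == 0 && par$theta == 0
  img <- sample$image
  msk <- sample$mask
  ainv <- NULL
  if (!identity_geom) {
    ainv <- inverse_affine(d[1], d[2], par)
    img <- cpp_affine_sample(img, ainv, TRUE, TRUE)
    msk <- cpp_affine_sample(array(msk, c(d[1:2], 1L)), ainv, FALSE, FALSE)[, , 1]
    msk <- (msk >= 0.5) + 0
  }
  img <- img + par$brightness
  for (c in 1:3) img[, , c] <- img[, , c] + par$channel[c]
  out <- new_seg_sample(clamp01(img), msk)
  par$affine <- ainv
  attr(out, "params") <- par
  out
}

# inverse affine map (output pixel -> input pixel, 0-based row/col) for
# rotate(theta) . scale(z) . flip about the image centre, then translate
inverse_affine <- function(H, W, par) {
  cr <- (H - 1) / 2
  cc <- (W - 1) / 2
  rot <- matrix(c(cos(par$theta), sin(par$theta),
                  -sin(par$theta), cos(par$theta)), 2, 2)
  flp <- diag(c(1, if (par$flip) -1 else 1))
  fwd <- rot %*% (par$zoom * flp)   # forward linear part
  inv <- solve(fwd)
  # out = fwd %*% (in - c) + c + t  =>  in = inv %*% (out - c - t) + c
  off <- c(cr, cc) - inv %*% (c(cr, cc) + c(par$shift_r, par$shift_c))
  cbind(inv, off)
}

#' Seeded train/test split
#'
#' Disjoint, exhaustive, seeded shuffle with `round(ratio * n)` training
#' samples.
#'
#' @param samples list of samples (length at least 2)
#' @param ratio training fraction
#' @param seed shuffle seed
#' @return list with elements `train` and `test`
#' @export
split_samples <- function(samples, ratio = 0.8, seed = 1L) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples to split")
  idx <- with_seed(seed, sample.int(n))
  n_train <- round(ratio * n)
  list(train = samples[idx[seq_len(n_train)]],
       test = samples[idx[setdiff(seq_len(n), seq_len(n_train))]])
}
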