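#' Model configuration for MBFFNet
#'
#' Defines the frozen default architecture: a five-stage VGG16-style encoder
#' (widths 64, 128, 256, 512, 512, two/two/three/three/three 3x3
#' convolutions per stage with 2x2 max pooling in between), a stepwise
#' decoder that fuses each deeper map with the matching encoder skip by
#' pixel-level multiplicative attention, and an hourglass pyramid branch that
#' resizes all five stages to the stage-2 reference resolution.
#'
#' The decoder widths, the pyramid compression width and the head width are
#' calibration constants: they were fixed once so that the closed-form
#' parameter/FLOP totals of the default architecture reproduce the published
#' complexity figures (see the methods vignette), and they are not meant to
#' be tuned per dataset. Width-reduced configurations (for desk-scale
#' training experiments) keep the architecture but shrink every channel
#' count.
#'
#' @param input_size square input side in pixels; must be divisible by 16
#' @param encoder_widths five channel counts, non-decreasing through stage 4
#' @param decoder_widths four channel counts, the outputs of the four fusion
#'   steps (deepest first)
#' @param pyramid_channels channels after compressing the concatenated
#'   hourglass pyramid
#' @param head_channels channels of the fusion head before the 1x1 logit
#' @param proj_kernel kernel size of the attention projection convolution
#' @param n_refine refinement convolutions per fusion step (1 or 2)
#' @param compress_kernel kernel size of the pyramid compression convolution
#' @param normalization attention weight normalization: `"sigmoid"`
#'   (per-pixel, per-channel logistic; the default), `"softmax"` (softmax
#'   over pixels within each channel) or `"identity"` (no squashing; only
#'   useful for testing the multiplicative-fusion algebra)
#' @param classes number of foreground classes (1 = polyp vs background)
#' @return a list of class `"mbff_config"`
#' @seealso [build_mbffnet()], [mbff_architecture()]
#' @export
mbff_config <- function(input_size = 256L,
                        encoder_widths = c(64L, 128L, 256L, 512L, 512L),
                        decoder_widths = c(448L, 224L, 112L, 56L),
                        pyramid_channels = 48L,
                        head_channels = 128L,
                        proj_kernel = 3L,
                        n_refine = 2L,
                        compress_kernel = 1L,
                        normalization = c("sigmoid", "softmax", "identity"),
                        classes = 1L) {
  normalization <- match.arg(normalization)
  check_input_size(input_size)
  if (length(encoder_widths) != 5L)
    stop("encoder_widths must have exactly 5 entries")
  if (any(diff(encoder_widths[1:4]) < 0))
    stop("encoder widths must be non-decreasing through stage 4")
  if (length(decoder_widths) != 4L)
    stop("decoder_widths must have exactly 4 entries")
  stopifnot(n_refine %in% c(1L, 2L), proj_kernel %in% c(1L, 3L),
            compress_kernel %in% c(1L, 3L), classes >= 1L)
  structure(list(
    arch = "mbffnet",
    input_size = as.integer(input_size),
    encoder_widths = as.integer(encoder_widths),
    decoder_widths = as.integer(decoder_widths),
    pyramid_channels = as.integer(pyramid_channels),
    head_channels = as.integer(head_channels),
    proj_kernel = as.integer(proj_kernel),
    n_refine = as.integer(n_refine),
    compress_kernel = as.integer(compress_kernel),
    normalization = normalization,
    classes = as.integer(classes)
  ), class = "mbff_config")
}

#' Model configuration for the reference U-Net
#'
#' The concat-skip baseline: the same VGG16-style encoder as
#' [mbff_config()], a decoder with four bilinear x2 up-sampling steps that
#' concatenate the same-resolution encoder stage and apply two 3x3
#' convolutions, and a 1x1 logit head. Used for the efficiency comparison
#' and as an optional training baseline.
#'
#' @inheritParams mbff_config
#' @param decoder_widths four channel counts after each up-sample step
#' @return a list of class `"mbff_config"`
#' @export
unet_config <- function(input_size = 256L,
                        encoder_widths = c(64L, 128L, 256L, 512L, 512L),
                        decoder_widths = c(512L, 256L, 128L, 64L),
                        classes = 1L) {
  check_input_size(input_size)
  if (length(encoder_widths) != 5L)
    stop("encoder_widths must have exactly 5 entries")
  if (length(decoder_widths) != 4L)
    stop("decoder_widths must have exactly 4 entries")
  structure(list(
    arch = "unet",
    input_size = as.integer(input_size),
    encoder_widths = as.integer(encoder_widths),
    decoder_widths = as.integer(decoder_widths),
    classes = as.integer(classes)
  ), class = "mbff_config")
}

#' Width-reduced MBFFNet preset for desk-scale training
#'
#' Keeps the full multi-branch architecture (five encoder stages,
#' multiplicative fusion, pyramid branch) but shrinks every channel count so
#' the model trains in minutes on one CPU core. This is the configuration
#' used by the synthetic-scene learnability experiments.
#'
#' @param input_size square input side, divisible by 16
#' @return an `"mbff_config"`
#' @export
mbff_small_config <- function(input_size = 64L) {
  mbff_config(
    input_size = input_size,
    encoder_widths = c(8L, 16L, 32L, 32L, 32L),
    decoder_widths = c(32L, 16L, 16L, 8L),
    pyramid_channels = 16L,
    head_channels = 16L
  )
}

check_input_size <- function(input_size) {
  if (length(input_size) != 1L || input_size < 16L || input_size %% 16L != 0L)
    stop(sprintf("input_size %s is not divisible by 16", input_size))
  invisible(input_size)
}

#' Read or write a model configuration as YAML
#'
#' @param config an `"mbff_config"`
#' @param path file path
#' @return `read_config()` returns the configuration; `write_config()` the
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (identical(x$arch, "unet")) {
    unet_config(x$input_size, unlist(x$encoder_widths),
                unlist(x$decoder_widths), x$classes)
  } else {
    mbff_config(x$input_size, unlist(x$encoder_widths),
                unlist(x$decoder_widths), x$pyramid_channels,
                x$head_channels, x$proj_kernel, x$n_refine,
                x$compress_kernel, x$normalization, x$classes)
  }
}
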