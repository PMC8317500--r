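# Layer plans: the single source of truth for which convolutions each
# architecture contains. Both weight instantiation (build_*) and the
# closed-form complexity dump (mbff_architecture / unet_architecture) are
# derived from the same plan, so the analytic parameter count always matches
# the instantiated weight count.

# Each plan row: name, ci, co, k, div (output side = input_size / div).
encoder_plan <- function(e) {
  n_convs <- c(2L, 2L, 3L, 3L, 3L)
  rows <- list()
  ci <- 3L
  for (s in 1:5) {
    for (v in seq_len(n_convs[s])) {
      rows[[length(rows) + 1L]] <- list(
        name = sprintf("enc%d_%d", s, v), ci = ci, co = e[s], k = 3L,
        div = 2L^(s - 1L))
      ci <- e[s]
    }
  }
  rows
}

mbff_plan <- function(config) {
  e <- config$encoder_widths
  w <- config$decoder_widths
  rows <- encoder_plan(e)
  skip_ch <- e[4:1]                  # fusion steps pair stage 5..2 with 4..1
  deep_ch <- c(e[5], w[1], w[2], w[3])
  for (j in 1:4) {
    div <- 2L^(4L - j)               # output side of fusion step j
    rows[[length(rows) + 1L]] <- list(
      name = sprintf("dec%d_proj", j), ci = deep_ch[j], co = skip_ch[j],
      k = config$proj_kernel, div = div)
    rows[[length(rows) + 1L]] <- list(
      name = sprintf("dec%d_refine1", j), ci = skip_ch[j], co = w[j],
      k = 3L, div = div)
    if (config$n_refine == 2L)
      rows[[length(rows) + 1L]] <- list(
        name = sprintf("dec%d_refine2", j), ci = w[j], co = w[j],
        k = 3L, div = div)
  }
  rows[[length(rows) + 1L]] <- list(
    name = "pyr_pre", ci = e[1], co = e[1], k = 1L, div = 1L)
  rows[[length(rows) + 1L]] <- list(
    name = "pyr_compress", ci = sum(e), co = config$pyramid_channels,
    k = config$compress_kernel, div = 2L)
  rows[[length(rows) + 1L]] <- list(
    name = "head_fuse", ci = w[4] + config$pyramid_channels,
    co = config$head_channels, k = 3L, div = 1L)
  rows[[length(rows) + 1L]] <- list(
    name = "head_logit", ci = config$head_channels, co = config$classes,
    k = 1L, div = 1L)
  rows
}

unet_plan <- function(config) {
  e <- config$encoder_widths
  u <- config$decoder_widths
  rows <- encoder_plan(e)
  skip_ch <- e[4:1]
  deep_ch <- c(e[5], u[1], u[2], u[3])
  for (j in 1:4) {
    div <- 2L^(4L - j)
    rows[[length(rows) + 1L]] <- list(
      name = sprintf("up%d_conv1", j), ci = deep_ch[j] + skip_ch[j],
      co = u[j], k = 3L, div = div)
    rows[[length(rows) + 1L]] <- list(
      name = sprintf("up%d_conv2", j), ci = u[j], co = u[j], k = 3L, div = div)
  }
  rows[[length(rows) + 1L]] <- list(
    name = "head_logit", ci = u[4], co = config$classes, k = 1L, div = 1L)
  rows
}

model_plan <- function(config) {
  switch(config$arch,
    mbffnet = mbff_plan(config),
    unet = unet_plan(config),
    stop("unknown architecture: ", config$arch))
}

plan_to_specs <- function(plan, input_size) {
  do.call(rbind, lapply(plan, function(r) {
    side <- as.integer(input_size / r$div)
    conv_layer_spec(r$name, r$ci, r$co, r$k, r$k, side, side)
  }))
}

#' Architecture dump of the default (or any) MBFFNet configuration
#'
#' Enumerates every convolution of the network as a `ConvLayerSpec` table
#' (one row per layer: input/output channels, kernel extents, output spatial
#' extents) at the given spatial accounting size. This table is the input to
#' the closed-form complexity accounting ([model_complexity()]).
#'
#' @param config an MBFFNet configuration from [mbff_config()]
#' @param input_size spatial side at which output extents are filled in;
#'   defaults to the configuration's own input size
#' @return a data frame of layer specifications (see [conv_layer_spec()])
#' @examples
#' arch <- mbff_architecture()
#' model_complexity(arch)
#' @export
mbff_architecture <- function(config = mbff_config(),
                              input_size = config$input_size) {
  stopifnot(identical(config$arch, "mbffnet"))
  check_input_size(input_size)
  plan_to_specs(mbff_plan(config), input_size)
}

#' Architecture dump of the reference U-Net configuration
#'
#' @param config a U-Net configuration from [unet_config()]
#' @inheritParams mbff_architecture
#' @return a data frame of layer specifications
#' @export
unet_architecture <- function(config = unet_config(),
                              input_size = config$input_size) {
  stopifnot(identical(config$arch, "unet"))
  check_input_size(input_size)
  plan_to_specs(unet_plan(config), input_size)
}

#' Architecture dump of a built model
#'
#' @param model a model from [build_mbffnet()] or [build_unet()]
#' @param input_size accounting side, default the model's configured input
#' @return a data frame of layer specifications
#' @export
dump_architecture <- function(model, input_size = model$config$input_size) {
  plan_to_specs(model_plan(model$config), input_size)
}

#' Write or read an architecture dump as JSON
#'
#' The JSON form (a list of ConvLayerSpec records) is the exchange format
#' between the model definitions and the complexity accounting.
#'
#' @param layers a layer-specification data frame
#' @param path file path
#' @return `read_architecture_json()` returns the layer data frame.
#' @export
write_architecture_json <- function(layers, path) {
  jsonlite::write_json(layers, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_architecture_json
#' @export
read_architecture_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  validate_layer_specs(df)
}
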