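# Convolution layer store and optimizer. A layer is a plain list holding the
# weight matrix in im2col form (co x ci*k*k), a bias vector, and its shape
# metadata; a model is a named list of such layers plus its config.

# He-uniform initialization: U(-sqrt(6/fan_in), sqrt(6/fan_in)), fan_in = ci*k^2
new_conv_layer <- function(name, ci, co, k) {
  stopifnot(ci >= 1, co >= 1, k %in% c(1L, 3L))
  limit <- sqrt(6 / (ci * k * k))
  list(
    name = name, ci = as.integer(ci), co = as.integer(co), k = as.integer(k),
    W = matrix(runif(co * ci * k * k, -limit, limit), nrow = co),
    b = numeric(co)
  )
}

conv_fw <- function(layer, x) {
  cpp_conv2d_fw(x, layer$W, layer$b, layer$k)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# softmax over all pixels, independently per channel
softmax_pixels <- function(x) {
  d <- dim(x)
  for (c in seq_len(d[3])) {
    v <- x[, , c]
    e <- exp(v - max(v))
    x[, , c] <- e / sum(e)
  }
  x
}

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x
}

# concatenate feature maps along the channel axis
cat_channels <- function(...) {
  maps <- lapply(list(...), as_feature_map)
  d <- dim(maps[[1]])[1:2]
  for (m in maps) {
    if (!identical(dim(m)[1:2], d))
      stop("channel concatenation requires equal spatial sizes")
  }
  array(unlist(maps, use.names = FALSE),
        dim = c(d, sum(vapply(maps, function(m) dim(m)[3], 1L))))
}

# number of trainable convolution weights (biases excluded) in a model
#' Count instantiated convolution weights
#'
#' Sums the lengths of every convolution weight array held by a built model.
#' Biases are not counted, so for any model this equals the sum of
#' [layer_params()] over the model's architecture dump.
#'
#' @param model a model built by [build_mbffnet()] or [build_unet()]
#' @return integer-valued count of convolution weights
#' @export
count_conv_weights <- function(model) {
  sum(vapply(model$layers, function(l) length(l$W), numeric(1)))
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mW = matrix(0, nrow(l$W), ncol(l$W)), vW = matrix(0, nrow(l$W), ncol(l$W)),
    mb = numeric(length(l$b)), vb = numeric(length(l$b))
  ))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(layers)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    layers[[nm]]$W <- layers[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    layers[[nm]]$b <- layers[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(layers = layers, state = state)
}
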