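# Shared fixtures: tiny configurations that keep the full multi-branch
# architecture but run in milliseconds.

tiny_mbff_config <- function(input_size = 32L, normalization = "sigmoid") {
  mbff_config(input_size = input_size,
              encoder_widths = c(4L, 4L, 8L, 8L, 8L),
              decoder_widths = c(8L, 8L, 4L, 4L),
              pyramid_channels = 4L, head_channels = 4L,
              normalization = normalization)
}

tiny_unet_config <- function(input_size = 32L) {
  unet_config(input_size = input_size,
              encoder_widths = c(4L, 4L, 8L, 8L, 8L),
              decoder_widths = c(8L, 8L, 4L, 4L))
}

random_image <- function(side, seed = 1L) {
  set.seed(seed)
  array(runif(side * side * 3), c(side, side, 3L))
}

# brute-force double-loop tally of the (k+1)x(k+1) pixel confusion matrix;
# the independent oracle for the vectorized implementation
brute_confusion <- function(pred, truth, k) {
  p <- matrix(0L, k + 1L, k + 1L)
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(ncol(truth))) {
      p[truth[i, j] + 1L, pred[i, j] + 1L] <-
        p[truth[i, j] + 1L, pred[i, j] + 1L] + 1L
    }
  }
  p
}

brute_miou <- function(p) {
  ious <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    tp <- p[i, i]
    u <- sum(p[i, ]) + sum(p[, i]) - tp
    ious[i] <- if (u == 0) 1 else tp / u
  }
  mean(ious)
}
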