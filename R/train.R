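# Mini-batch Adam training of the Dice + cross-entropy objective, and
# evaluation of trained checkpoints on sample lists.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001, fixed: no
#'   schedule)
#' @param batch_size mini-batch size
#' @param epochs number of passes over the training set (at least 1)
#' @param seed seed controlling shuffling and augmentation draws
#' @param checkpoint optional path where the final weights are written
#' @return a list of class `"train_config"`
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 8L,
                         epochs = 10L, seed = 1L, checkpoint = NULL) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 checkpoint = checkpoint),
            class = "train_config")
}

loss_and_grad <- function(model, sample) {
  E <- new_pass(model, keep = TRUE)
  prob <- net_fw(E, model, sample$image)
  loss <- dice_ce_loss(sample$mask, prob)
  dlogit <- array(dice_ce_grad_logit(sample$mask, prob), dim = dim(prob))
  net_bw(E, model, dlogit)
  list(loss = loss, grads = E$grads)
}

accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) {
    acc[[nm]]$dW <- acc[[nm]]$dW + g[[nm]]$dW
    acc[[nm]]$db <- acc[[nm]]$db + g[[nm]]$db
  }
  acc
}

scale_grads <- function(g, f) {
  for (nm in names(g)) {
    g[[nm]]$dW <- g[[nm]]$dW * f
    g[[nm]]$db <- g[[nm]]$db * f
  }
  g
}

#' Train a segmentation model
#'
#' Runs seeded mini-batch Adam optimization of the Dice + cross-entropy
#' loss. With a fixed seed and single-threaded BLAS the run is
#' deterministic. When `augment` is supplied, each training sample is
#' augmented with a per-sample seed derived from the training seed, epoch
#' and sample index.
#'
#' @param model a built model from [build_mbffnet()] or [build_unet()]
#' @param samples non-empty list of `"seg_sample"` training data
#' @param config a [train_config()]
#' @param val optional list of held-out samples; mean validation mIOU is
#'   logged per epoch
#' @param augment optional [augmentation_config()] applied on the fly
#' @param verbose print one line per epoch
#' @return a list of class `"mbff_fit"` with elements `model` (trained) and
#'   `history` (per-epoch data frame: `epoch`, `train_loss`, `val_miou`)
#' @export
train_model <- function(model, samples, config = train_config(), val = NULL,
                        augment = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "mbff_model"), inherits(config, "train_config"))
  if (length(samples) == 0L) stop("empty training set")
  state <- adam_init(model$layers)
  t <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_miou = numeric())
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(child_seed(config$seed, ep), sample.int(length(samples)))
    losses <- numeric(0)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bt in batches) {
      acc <- NULL
      for (i in bt) {
        smp <- samples[[i]]
        if (!is.null(augment))
          smp <- augment_sample(smp, augment, child_seed(config$seed, ep, i))
        lg <- loss_and_grad(model, smp)
        losses <- c(losses, lg$loss)
        acc <- accumulate_grads(acc, lg$grads)
      }
      acc <- scale_grads(acc, 1 / length(bt))
      t <- t + 1L
      upd <- adam_step(model$layers, acc, state, config$learning_rate, t)
      model$layers <- upd$layers
      state <- upd$state
    }
    vm <- if (is.null(val)) NA_real_ else
      mean(vapply(val, function(s) {
        pm <- predict(model, s$image, type = "mask")
        miou(confusion_counts(pm, s$mask, 1L))
      }, numeric(1)))
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(losses),
                                         val_miou = vm))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f%s", ep, mean(losses),
                      if (is.na(vm)) "" else sprintf(", val mIOU %.4f", vm)))
  }
  if (!is.null(config$checkpoint)) save_checkpoint(model, config$checkpoint)
  structure(list(model = model, history = history), class = "mbff_fit")
}

#' Evaluate a model on a sample list
#'
#' Computes per-image and mean mIOU, F-score and Dice + cross-entropy loss
#' at the given binarization threshold.
#'
#' @param model a built (usually trained) model, or a checkpoint path
#' @param samples list of `"seg_sample"` objects
#' @param threshold probability binarization threshold
#' @param beta F-score beta
#' @return a list with `per_image` (data frame) and `mean` (named list of
#'   the column means)
#' @export
evaluate_model <- function(model, samples, threshold = 0.5, beta = 1) {
  if (is.character(model)) model <- load_checkpoint(model)
  stopifnot(inherits(model, "mbff_model"))
  if (length(samples) == 0L) stop("empty evaluation set")
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    prob <- forward(model, s$image)
    pm <- (prob[, , 1] >= threshold) + 0L
    mb <- metric_bundle(pm, s$mask, prob = prob[, , 1], beta = beta)
    data.frame(image = i, miou = mb$miou, precision = mb$precision,
               recall = mb$recall, f_score = mb$f_score, dice_ce = mb$dice_ce)
  })
  per_image <- do.call(rbind, rows)
  list(per_image = per_image,
       mean = list(miou = mean(per_image$miou),
                   f_score = mean(per_image$f_score),
                   dice_ce = mean(per_image$dice_ce)))
}

#' Desk-scale learnability experiment on synthetic scenes
#'
#' The end-to-end training study used by the package's own validation:
#' generate seeded synthetic scenes, split 8:2, train a width-reduced
#' MBFFNet, and report the held-out mean mIOU before and after training.
#'
#' @param n_scenes number of synthetic scenes
#' @param side scene side in pixels
#' @param epochs training epochs
#' @param seed master seed for scenes, weights and optimization
#' @param config model configuration; default [mbff_small_config()]
#' @param verbose print per-epoch progress
#' @return a list with `miou_untrained`, `miou_trained`, `fit`
#' @export
learnability_run <- function(n_scenes = 200L, side = 64L, epochs = 15L,
                             seed = 1L, config = mbff_small_config(side),
                             verbose = FALSE) {
  scenes <- generate_dataset(n_scenes, scene_spec(side = side),
                             seed = child_seed(seed, 1))
  sp <- split_samples(scenes, ratio = 0.8, seed = child_seed(seed, 2))
  model <- build_mbffnet(config, seed = child_seed(seed, 3))
  before <- evaluate_model(model, sp$test)$mean$miou
  fit <- train_model(model, sp$train,
                     train_config(epochs = epochs, seed = child_seed(seed, 4)),
                     val = NULL, verbose = verbose)
  after <- evaluate_model(fit$model, sp$test)$mean$miou
  list(miou_untrained = before, miou_trained = after, fit = fit)
}
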