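#' Training configuration
#'
#' Optimization protocol: mini-batch Adam at a constant base learning rate.
#'
#' @param batch_size mini-batch size (>= 1; default 24).
#' @param learning_rate Adam step size (> 0; default 0.001).
#' @param max_epochs number of passes over the training set.
#' @param seed master seed covering weight initialization, data order and
#'   augmentation draws.
#' @param val_every validate (and consider checkpointing) every this many
#'   epochs; the best-by-validation-mIoU weights are restored at the end.
#' @param verbose print one line per epoch.
#' @return an object of class \code{train_config}.
#' @export
train_config <- function(batch_size = 24L, learning_rate = 1e-3,
                         max_epochs = 50L, seed = 1L, val_every = 5L,
                         verbose = FALSE) {
  if (batch_size < 1) stop("train_config: batch_size must be >= 1",
                           call. = FALSE)
  if (learning_rate <= 0) stop("train_config: learning_rate must be > 0",
                               call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 val_every = as.integer(val_every),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

## one random crop (current RNG state, unlike crop_patches which seeds
## itself), used for per-epoch patch sampling inside the training loop
.random_crop <- function(s, pcfg) {
  H <- dim(s$image)[1]; W <- dim(s$image)[2]
  if (H <= pcfg$crop_min && W <= pcfg$crop_min) return(s)
  pick <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)
  ph <- pick(pcfg$crop_min, min(pcfg$crop_max, H))
  pw <- pick(pcfg$crop_min, min(pcfg$crop_max, W))
  r0 <- pick(0L, H - ph)
  c0 <- pick(0L, W - pw)
  rows <- (r0 + 1):(r0 + ph); cols <- (c0 + 1):(c0 + pw)
  list(image = s$image[rows, cols, , drop = FALSE],
       mask = if (!is.null(s$mask)) s$mask[rows, cols, drop = FALSE],
       source_id = s$source_id)
}

## model-ready (x, mask) from a raw 8-bit sample: per-epoch random crop,
## augmentation, then resizing/normalization
.prepare_one <- function(s, pcfg, augment) {
  if (!is.null(s$x)) return(s) # already model-ready
  if (augment) {
    s <- .random_crop(s, pcfg)
    s <- augment_sample(s, pcfg)
  }
  preprocess_sample(s, pcfg)
}

#' Train FPN-Mask with the focal loss
#'
#' Runs mini-batch Adam on the focal loss. Samples may be raw 8-bit
#' image/mask pairs (then \code{pcfg} drives per-epoch augmentation and
#' preprocessing, re-drawn every epoch as in standard training practice) or
#' already model-ready lists with \code{x} in [0, 1] and \code{mask}.
#' Everything is seeded from \code{tcfg$seed}: weight initialization, data
#' order and augmentation draws, so identical calls give identical loss
#' histories.
#'
#' @param model an \code{fpn_mask} model, or \code{NULL} to build one from
#'   \code{mcfg}.
#' @param train_samples nonempty list of samples with masks.
#' @param val_samples optional list of model-ready validation samples; when
#'   given, pixel accuracy and mean IoU are recorded every
#'   \code{tcfg$val_every} epochs and the best-mIoU weights are kept.
#' @param tcfg a \code{\link{train_config}}.
#' @param lcfg a \code{\link{loss_config}}; a \code{NULL} alpha is replaced
#'   by inverse pixel-frequency weights of the training masks.
#' @param mcfg a \code{\link{model_config}} used when \code{model} is NULL.
#' @param pcfg a \code{\link{preprocess_config}} for raw samples;
#'   augmentation uses its \code{augmentations} set.
#' @return list with \code{model} (trained; best validation weights when a
#'   validation set was given) and \code{history} (data.frame: epoch, loss,
#'   val_pa, val_miou).
#' @export
train_fpn_mask <- function(model = NULL, train_samples, val_samples = NULL,
                           tcfg = train_config(), lcfg = loss_config(),
                           mcfg = model_config(), pcfg = NULL) {
  if (length(train_samples) == 0)
    stop("train_fpn_mask: empty training set", call. = FALSE)
  has_mask <- vapply(train_samples, function(s) !is.null(s$mask), logical(1))
  if (!all(has_mask))
    stop("train_fpn_mask: every training sample needs a mask", call. = FALSE)
  set.seed(tcfg$seed)
  if (is.null(model)) model <- build_fpn_mask(mcfg)
  alpha <- lcfg$alpha
  if (is.null(alpha))
    alpha <- inverse_frequency_alpha(lapply(train_samples, `[[`, "mask"))
  n <- length(train_samples)
  bs <- min(tcfg$batch_size, n)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_pa = numeric(0), val_miou = numeric(0))
  best <- list(miou = -Inf, state = NULL)
  step <- 0L
  for (epoch in seq_len(tcfg$max_epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    n_batches <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      batch <- lapply(train_samples[idx], .prepare_one, pcfg = pcfg,
                      augment = !is.null(pcfg))
      xs <- lapply(batch, `[[`, "x")
      ms <- lapply(batch, `[[`, "mask")
      fwd <- fpn_forward(model, xs, training = TRUE)
      dm <- dim(ms[[1]])
      targets <- array(unlist(ms, use.names = FALSE),
                       dim = c(dm[1], dm[2], length(ms)))
      lg <- focal_loss_grad(fwd$logits_bt, targets, lcfg$gamma, alpha)
      bl <- lg$loss
      if (!is.finite(bl))
        stop("train_fpn_mask: non-finite loss at epoch ", epoch,
             " (diverged); lower the learning rate", call. = FALSE)
      zero_grads(model)
      fpn_backward(model, fwd$cache, lg$grad)
      step <- step + 1L
      adam_step(model, tcfg$learning_rate, step)
      epoch_loss <- epoch_loss + bl
      n_batches <- n_batches + 1L
    }
    epoch_loss <- epoch_loss / n_batches
    val_pa <- NA_real_; val_miou <- NA_real_
    if (!is.null(val_samples) &&
        (epoch %% tcfg$val_every == 0L || epoch == tcfg$max_epochs)) {
      vm <- .validate(model, val_samples)
      val_pa <- vm$pa; val_miou <- vm$miou
      if (val_miou >= best$miou) {
        best$miou <- val_miou
        best$state <- model_state(model)
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = epoch_loss,
                                         val_pa = val_pa,
                                         val_miou = val_miou))
    if (tcfg$verbose)
      message(sprintf("epoch %3d  loss %.5f  val_pa %s  val_miou %s",
                      epoch, epoch_loss,
                      ifelse(is.na(val_pa), "-", sprintf("%.4f", val_pa)),
                      ifelse(is.na(val_miou), "-", sprintf("%.4f", val_miou))))
  }
  if (!is.null(best$state)) model <- model_from_state(best$state)
  list(model = model, history = history)
}

.validate <- function(model, val_samples) {
  cm <- matrix(0, 3, 3)
  for (s in val_samples) {
    pred <- predict_mask(predict_probmap(model, s$x))
    cm <- cm + confusion_matrix(pred, s$mask)
  }
  list(pa = pixel_accuracy(cm), miou = mean_iou(cm))
}
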