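#' Scaled-down synthetic benchmark of the full segmentation pipeline
#'
#' The package's reference experiment: generate synthetic canopies with the
#' default scene configuration, train a reduced FPN-Mask (16 pyramid
#' channels) on 64 x 64 training samples, and evaluate per-class pixel
#' accuracy, mean IoU and one-vs-rest ROC-AUC on held-out full-resolution
#' scenes. Used by the reproduction script and the test suite; all
#' randomness derives from \code{seed}.
#'
#' @param seed master seed (dataset generation, weight initialization, data
#'   order, augmentation).
#' @param n_train,n_test number of training and held-out test scenes.
#' @param epochs training epochs.
#' @param stage_channels pyramid width of the reduced model.
#' @param train_size side length of the training patches: each epoch takes a
#'   fresh random crop of this size from every training scene, so
#'   supervision stays at native resolution.
#' @param scene a \code{\link{scene_config}} for the canopies.
#' @param batch_size,learning_rate,gamma optimization protocol (defaults:
#'   mini-batch 24, Adam at 0.001, focal loss with gamma 2 and
#'   inverse-frequency class weights).
#' @param val_fraction fraction of training scenes held out for checkpoint
#'   selection.
#' @param verbose print per-epoch progress.
#' @return list with \code{model}, \code{history}, \code{metrics} (a
#'   \code{metrics_report} on the pooled test pixels), \code{records}
#'   (per-test-image LPR records from predicted masks) and the
#'   configurations used.
#' @export
synthetic_benchmark <- function(seed = 1L, n_train = 200L, n_test = 50L,
                                epochs = 30L, stage_channels = 16L,
                                train_size = 64L, scene = scene_config(),
                                batch_size = 24L, learning_rate = 1e-3,
                                gamma = 2, val_fraction = 0.1,
                                verbose = FALSE) {
  seed <- as.integer(seed)
  train_ds <- generate_dataset(scene, n_train, seed = seed)
  test_ds <- generate_dataset(scene, n_test, seed = seed + 1L)
  ## fixed-size crops: the resize in preprocess_sample is then the identity,
  ## so training masks are exact at native resolution
  pcfg <- preprocess_config(target_size = as.integer(train_size),
                            crop_min = as.integer(train_size),
                            crop_max = as.integer(train_size),
                            augmentations = c("hflip", "vflip", "rot90"))
  raw <- lapply(train_ds$scenes, function(s)
    list(image = s$image$pixels, mask = s$mask, source_id = s$image$id))
  n_val <- max(1L, round(val_fraction * n_train))
  ## validation at the scenes' native resolution, like the final evaluation
  val <- lapply(raw[seq_len(n_val)], function(s)
    list(x = s$image / 255, mask = s$mask))
  trn <- raw[-seq_len(n_val)]
  tcfg <- train_config(batch_size = batch_size,
                       learning_rate = learning_rate,
                       max_epochs = as.integer(epochs), seed = seed,
                       val_every = 5L, verbose = verbose)
  mcfg <- model_config(input_size = as.integer(train_size),
                       stage_channels = as.integer(stage_channels),
                       backbone_depth = 2L)
  fit <- train_fpn_mask(NULL, trn, val_samples = val, tcfg = tcfg,
                        lcfg = loss_config(gamma = gamma), mcfg = mcfg,
                        pcfg = pcfg)
  truths <- lapply(test_ds$scenes, `[[`, "mask")
  probmaps <- lapply(test_ds$scenes, function(s)
    predict_probmap(fit$model, s$image$pixels / 255))
  preds <- lapply(probmaps, predict_mask)
  metrics <- evaluate_masks(preds, truths, probmaps)
  names(preds) <- test_ds$metadata$image_id
  records <- lpr_records(preds, metadata = test_ds$metadata)
  list(model = fit$model, history = fit$history, metrics = metrics,
       records = records, scene = scene,
       protocol = list(seed = seed, n_train = n_train, n_test = n_test,
                       epochs = epochs, stage_channels = stage_channels,
                       train_size = train_size, batch_size = batch_size,
                       learning_rate = learning_rate, gamma = gamma))
}
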