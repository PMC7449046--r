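# shared fixtures: everything is generated in code, nothing read from disk

tiny_scene_config <- function(seed = 1L, ...) {
  args <- list(height = 64, width = 64, n_leaves = c(3L, 6L),
               n_panicles = c(2L, 4L), panicle_extent = c(8, 15),
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scene_config, args)
}

tiny_model_config <- function(input_size = 32L)
  model_config(input_size = input_size, stage_channels = 8L,
               backbone_depth = 1L)

## deterministic random mask pair
random_masks <- function(seed, h = 16, w = 16) {
  set.seed(seed)
  list(truth = matrix(sample(0:2, h * w, TRUE), h, w),
       pred = matrix(sample(0:2, h * w, TRUE), h, w))
}

## brute-force metric oracles: per-pixel loops over all label pairs
oracle_confusion <- function(pred, truth) {
  cm <- matrix(0, 3, 3)
  for (i in seq_along(truth))
    cm[truth[i] + 1, pred[i] + 1] <- cm[truth[i] + 1, pred[i] + 1] + 1
  cm
}

oracle_pixel_accuracy <- function(pred, truth) {
  ok <- 0
  for (i in seq_along(truth)) if (pred[i] == truth[i]) ok <- ok + 1
  ok / length(truth)
}

oracle_iou <- function(pred, truth) {
  sapply(0:2, function(k) {
    inter <- sum(pred == k & truth == k)
    uni <- sum(pred == k | truth == k)
    if (uni == 0) NA_real_ else inter / uni
  })
}

oracle_class_accuracy <- function(pred, truth) {
  sapply(0:2, function(k) {
    n <- sum(truth == k)
    if (n == 0) NA_real_ else sum(pred == k & truth == k) / n
  })
}

## Mann-Whitney AUC by explicit pair counting (ties count 1/2)
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## permutation test for a difference in two group means
perm_test_two_groups <- function(x, y, n_perm = 10000, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  n <- length(x)
  hits <- 0
  for (b in seq_len(n_perm)) {
    idx <- sample(length(pooled), n)
    if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12)
      hits <- hits + 1
  }
  hits / n_perm
}
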