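#' Pixel confusion matrix between predicted and true class masks
#'
#' Entry \code{[i, j]} counts pixels of true class \code{i - 1} predicted as
#' class \code{j - 1} (classes 0 = background, 1 = leaf, 2 = panicle).
#' Confusions are additive: the matrix of a concatenated image set equals
#' the sum of per-image matrices.
#'
#' @param pred,truth H x W integer matrices with labels in \{0, 1, 2\} and
#'   identical dimensions.
#' @return 3 x 3 numeric matrix of pixel counts.
#' @export
confusion_matrix <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("confusion_matrix: shape mismatch", call. = FALSE)
  if (!all(pred %in% 0:2) || !all(truth %in% 0:2))
    stop("confusion_matrix: labels outside {0, 1, 2}", call. = FALSE)
  cm <- table(factor(truth, levels = 0:2), factor(pred, levels = 0:2))
  m <- matrix(as.numeric(cm), 3, 3)
  dimnames(m) <- list(truth = c("background", "leaf", "panicle"),
                      pred = c("background", "leaf", "panicle"))
  m
}

#' Pixel accuracy from a confusion matrix
#'
#' Proportion of correctly classified pixels: trace over total.
#'
#' @param cm 3 x 3 confusion matrix (true class in rows).
#' @return value in [0, 1].
#' @export
pixel_accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("pixel_accuracy: empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / tot
}

#' Mean intersection-over-union from a confusion matrix
#'
#' Per class i, IoU_i = p_ii / (row_i + col_i - p_ii); the mean is taken
#' over the classes present in truth or prediction (classes absent from
#' both are excluded rather than counted as 0 or 1).
#'
#' @param cm 3 x 3 confusion matrix (true class in rows).
#' @return mean IoU in [0, 1].
#' @export
mean_iou <- function(cm) {
  if (sum(cm) == 0) stop("mean_iou: empty confusion matrix", call. = FALSE)
  ious <- iou_per_class(cm)
  mean(ious, na.rm = TRUE)
}

#' Per-class intersection-over-union
#'
#' @param cm 3 x 3 confusion matrix (true class in rows).
#' @return length-3 vector; NA for classes absent from both truth and
#'   prediction.
#' @export
iou_per_class <- function(cm) {
  denom <- rowSums(cm) + colSums(cm) - diag(cm)
  ifelse(denom > 0, diag(cm) / denom, NA_real_)
}

#' Per-class accuracy (recall) from a confusion matrix
#'
#' p_ii over the true pixel count of class i; NA (undefined) for classes
#' absent from truth.
#'
#' @param cm 3 x 3 confusion matrix (true class in rows).
#' @return named length-3 vector in [0, 1] (NA where undefined).
#' @export
per_class_accuracy <- function(cm) {
  n_true <- rowSums(cm)
  out <- ifelse(n_true > 0, diag(cm) / n_true, NA_real_)
  names(out) <- c("background", "leaf", "panicle")
  out
}

## Mann-Whitney AUC with midpoint tie handling: pooled pixel scores for one
## class against the rest
.auc_rank <- function(scores, positive) {
  n1 <- as.numeric(sum(positive)) # doubles: pixel counts overflow integers
  n0 <- length(positive) - n1
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores) # average ranks = midpoint tie convention
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## ROC curve points (FPR, TPR) over score thresholds, ties merged
.roc_points <- function(scores, positive, max_points = 512L) {
  o <- order(scores, decreasing = TRUE)
  pos <- positive[o]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  keep <- c(diff(scores[o]) != 0, TRUE) # threshold boundaries only
  tpr <- c(0, tp[keep] / max(tp[length(tp)], 1))
  fpr <- c(0, fp[keep] / max(fp[length(fp)], 1))
  if (length(tpr) > max_points) {
    pick <- unique(round(seq(1, length(tpr), length.out = max_points)))
    tpr <- tpr[pick]; fpr <- fpr[pick]
  }
  data.frame(fpr = fpr, tpr = tpr)
}

#' One-vs-rest ROC curves and AUC over pooled pixels
#'
#' For each class, every pixel of every image contributes its predicted
#' probability for that class as a score and its true membership as the
#' label; the AUC is the Mann-Whitney statistic (ties at the midpoint),
#' identical to trapezoidal integration of the ROC curve. The macro AUC
#' averages the per-class AUCs, excluding classes absent from the pooled
#' truth (their AUC is undefined, reported as NA).
#'
#' @param probmaps list of H x W x 3 probability arrays.
#' @param truths list of matching H x W label matrices.
#' @return list with \code{curves} (per class, data.frames of fpr/tpr),
#'   \code{auc_per_class} (length 3, NA where undefined) and
#'   \code{auc_macro}.
#' @export
roc_auc <- function(probmaps, truths) {
  if (length(probmaps) != length(truths))
    stop("roc_auc: probmaps and truths must align", call. = FALSE)
  for (i in seq_along(probmaps))
    if (!all(dim(probmaps[[i]])[1:2] == dim(truths[[i]])))
      stop("roc_auc: shape mismatch at image ", i, call. = FALSE)
  scores <- lapply(1:3, function(k)
    unlist(lapply(probmaps, function(p) as.vector(p[, , k])),
           use.names = FALSE))
  labels <- unlist(lapply(truths, as.vector), use.names = FALSE)
  auc <- numeric(3)
  curves <- vector("list", 3)
  names(curves) <- c("background", "leaf", "panicle")
  for (k in 1:3) {
    pos <- labels == (k - 1L)
    auc[k] <- .auc_rank(scores[[k]], pos)
    curves[[k]] <- if (!is.na(auc[k])) .roc_points(scores[[k]], pos)
  }
  names(auc) <- names(curves)
  list(curves = curves, auc_per_class = auc,
       auc_macro = mean(auc, na.rm = TRUE))
}

#' Full segmentation metrics report
#'
#' Pools the confusion matrix over all image pairs and reports pixel
#' accuracy, per-class accuracy, per-class and mean IoU, and (when
#' probability maps are supplied) one-vs-rest AUC per class and macro AUC.
#'
#' @param preds list of predicted H x W label matrices.
#' @param truths list of matching ground-truth matrices.
#' @param probmaps optional list of H x W x 3 probability arrays for AUC.
#' @return list of class \code{metrics_report}.
#' @export
evaluate_masks <- function(preds, truths, probmaps = NULL) {
  if (length(preds) != length(truths))
    stop("evaluate_masks: preds and truths must align", call. = FALSE)
  cm <- matrix(0, 3, 3)
  for (i in seq_along(preds))
    cm <- cm + confusion_matrix(preds[[i]], truths[[i]])
  rep_ <- list(
    confusion = cm,
    pixel_accuracy = pixel_accuracy(cm),
    per_class_accuracy = per_class_accuracy(cm),
    iou_per_class = iou_per_class(cm),
    mean_iou = mean_iou(cm)
  )
  if (!is.null(probmaps)) {
    ra <- roc_auc(probmaps, truths)
    rep_$auc_per_class <- ra$auc_per_class
    rep_$auc_macro <- ra$auc_macro
  }
  structure(rep_, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics (pooled over",
      format(sum(x$confusion), big.mark = ","), "pixels)\n")
  cat(sprintf("  pixel accuracy: %.4f   mean IoU: %.4f\n",
              x$pixel_accuracy, x$mean_iou))
  cls <- c("background", "leaf", "panicle")
  for (k in 1:3)
    cat(sprintf("  %-10s acc %.4f  IoU %.4f%s\n", cls[k],
                x$per_class_accuracy[k], x$iou_per_class[k],
                if (!is.null(x$auc_per_class))
                  sprintf("  AUC %.4f", x$auc_per_class[k]) else ""))
  if (!is.null(x$auc_macro)) cat(sprintf("  macro AUC: %.4f\n", x$auc_macro))
  invisible(x)
}
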