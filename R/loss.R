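#' Focal loss configuration
#'
#' The multi-class focal loss down-weights well-classified pixels by the
#' modulating factor (1 - p)^gamma and re-balances classes with per-class
#' weights alpha, countering the heavy pixel imbalance between background,
#' leaf and panicle.
#'
#' @param gamma focusing exponent (>= 0); 0 reduces the loss to weighted
#'   cross-entropy.
#' @param alpha per-class weights (length 3, nonnegative, not all zero), or
#'   \code{NULL} to use inverse pixel-frequency weights of the training set,
#'   normalized to mean 1 (computed by \code{\link{train_fpn_mask}}).
#' @return an object of class \code{loss_config}.
#' @export
loss_config <- function(gamma = 2, alpha = NULL) {
  if (gamma < 0) stop("loss_config: gamma must be >= 0", call. = FALSE)
  if (!is.null(alpha)) {
    if (length(alpha) != 3 || any(alpha < 0) || all(alpha == 0))
      stop("loss_config: alpha must be 3 nonnegative weights, not all zero",
           call. = FALSE)
  }
  structure(list(gamma = gamma, alpha = alpha), class = "loss_config")
}

## loss and gradient with respect to the logits, mean over pixels; accepts
## per-image (H, W, C) logits with an (H, W) target, or a whole-batch
## (H, W, N, C) tensor with an (H, W, N) target
focal_loss_grad <- function(logits, target, gamma = 2, alpha = c(1, 1, 1)) {
  d <- dim(logits)
  nc <- d[length(d)]
  if (is.null(d) || length(d) < 3L ||
      prod(dim(target)) * nc != prod(d))
    stop("focal_loss: logits must be H x W x C with a matching H x W target",
         call. = FALSE)
  if (!all(target %in% 0:(nc - 1L)))
    stop("focal_loss: target labels outside {0, ..., C-1}", call. = FALSE)
  n <- prod(d) / nc
  z <- matrix(logits, n, nc)
  zmax <- z[, 1]
  for (j in 2:nc) zmax <- pmax(zmax, z[, j])
  e <- exp(z - zmax)
  p <- e / rowSums(e)
  ti <- as.integer(target) + 1L
  idx <- cbind(seq_len(n), ti)
  pt <- p[idx]
  pt_c <- pmax(pt, 1e-12) # clamp inside the log only
  at <- alpha[ti]
  one_m <- 1 - pt
  loss <- mean(-at * one_m^gamma * log(pt_c))
  ## dL/dp_t; the gamma term vanishes identically when gamma = 0
  dldp <- if (gamma > 0)
    at * (gamma * one_m^(gamma - 1) * log(pt_c) - one_m^gamma / pt_c)
  else
    -at / pt_c
  ## chain through softmax: dp_t/dz_j = p_t (1[j = t] - p_j)
  gz <- -p * (dldp * pt)
  gz[idx] <- gz[idx] + dldp * pt
  gz <- gz / n
  grad <- array(gz, dim = d)
  list(loss = loss, grad = grad)
}

#' Multi-class focal loss
#'
#' Mean over pixels of \code{-alpha[c] * (1 - p_c)^gamma * log(p_c)}, where
#' c is the true class of the pixel and p_c its softmax probability under
#' the logits. The logarithm is clamped at 1e-12, so the result is always
#' finite and nonnegative. With \code{gamma = 0} and uniform \code{alpha}
#' this is exactly the mean multi-class cross-entropy.
#'
#' @param logits H x W x 3 array of unnormalized scores.
#' @param target H x W integer matrix of true labels in \{0, 1, 2\}.
#' @param gamma focusing exponent (>= 0).
#' @param alpha per-class weights, length 3.
#' @return scalar loss.
#' @export
focal_loss <- function(logits, target, gamma = 2, alpha = c(1, 1, 1)) {
  focal_loss_grad(logits, target, gamma, alpha)$loss
}

#' Inverse-frequency class weights from training masks
#'
#' @param masks list of H x W label matrices.
#' @return length-3 weight vector proportional to inverse pixel frequency,
#'   normalized to mean 1; classes absent from the masks get the largest
#'   observed weight.
#' @export
inverse_frequency_alpha <- function(masks) {
  counts <- Reduce(`+`, lapply(masks, function(m) tabulate(m + 1L, nbins = 3L)))
  freq <- counts / sum(counts)
  w <- ifelse(freq > 0, 1 / freq, NA)
  w[is.na(w)] <- max(w, na.rm = TRUE)
  w / mean(w)
}
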