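#' Model configuration for FPN-Mask
#'
#' The network is a residual backbone with four stages C2..C5 whose
#' cumulative down-sampling rates are \{1, 2, 4, 8\} (the usual stride-4 stem
#' and global pooling before C2 are removed so fine spatial detail survives),
#' a top-down feature pyramid with lateral 1x1 connections producing P2..P5
#' at the same rates, and a fusion head: P3..P5 are up-sampled to full
#' resolution by bilinear interpolation, each refined by a 1x1 convolution,
#' concatenated with P2, passed through a 3x3 convolution with batch
#' normalization and rectified-linear activation, and mapped to 3 channels
#' (background, leaf, panicle) by a final 1x1 convolution.
#'
#' @param input_size training input side length in pixels; must be divisible
#'   by 8. The network is fully convolutional, so inference may use any
#'   size divisible by 8.
#' @param stage_channels feature maps per backbone stage and pyramid level
#'   (uniform width; the lateral connections require a common channel count).
#' @param backbone_depth residual blocks per stage (2 gives the 18-layer
#'   style backbone with basic two-convolution blocks).
#' @param n_classes fixed at 3.
#' @param zero_init_bn initialize batch-norm scales to 0 instead of 1
#'   (a literal reading of "weight sigma = 0" initialization; the standard
#'   scale-1 initialization is the default).
#' @return an object of class \code{fpn_config}.
#' @export
model_config <- function(input_size = 256L, stage_channels = 32L,
                         backbone_depth = 2L, n_classes = 3L,
                         zero_init_bn = FALSE) {
  if (input_size %% 8L != 0L)
    stop("model_config: input_size must be divisible by 8", call. = FALSE)
  if (n_classes != 3L)
    stop("model_config: n_classes is fixed at 3", call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 stage_channels = as.integer(stage_channels),
                 backbone_depth = as.integer(backbone_depth),
                 n_classes = 3L,
                 stage_strides = c(C2 = 1L, C3 = 2L, C4 = 2L, C5 = 2L),
                 zero_init_bn = isTRUE(zero_init_bn)),
            class = "fpn_config")
}

#' Build an FPN-Mask model
#'
#' Weights are drawn from the current RNG state (He variance-scaling for
#' convolutions; batch-norm scale 1 / shift 0 unless \code{zero_init_bn}),
#' so seed the session for reproducible initialization.
#'
#' @param config a \code{\link{model_config}}.
#' @return a model object (environment) consumed by \code{\link{fpn_forward}},
#'   \code{\link{train_fpn_mask}} and \code{\link{predict_probmap}}.
#' @export
build_fpn_mask <- function(config) {
  stopifnot(inherits(config, "fpn_config"))
  sc <- config$stage_channels
  zb <- config$zero_init_bn
  L <- list()
  ## stem: 3x3 stride-1 convolution (C2's rate is 1, so no pooling, no
  ## strided stem)
  L$stem_conv <- new_conv(3, 3, sc, 1)
  L$stem_bn <- new_bn(sc, zero_init = FALSE) # stem BN always scale-1
  for (s in 2:5) {
    for (b in seq_len(config$backbone_depth)) {
      stride <- if (s > 2 && b == 1) 2L else 1L
      pre <- sprintf("s%db%d", s, b)
      L[[paste0(pre, "_conv1")]] <- new_conv(3, sc, sc, stride)
      L[[paste0(pre, "_bn1")]] <- new_bn(sc, zero_init = zb)
      L[[paste0(pre, "_conv2")]] <- new_conv(3, sc, sc, 1)
      L[[paste0(pre, "_bn2")]] <- new_bn(sc, zero_init = zb)
      if (stride == 2L) {
        L[[paste0(pre, "_proj_conv")]] <- new_conv(1, sc, sc, 2L)
        L[[paste0(pre, "_proj_bn")]] <- new_bn(sc, zero_init = zb)
      }
    }
  }
  for (s in 2:5) L[[sprintf("lateral_%d", s)]] <- new_conv(1, sc, sc, 1)
  for (s in 3:5) L[[sprintf("head_up%d_conv", s)]] <- new_conv(1, sc, sc, 1)
  L$head_fuse_conv <- new_conv(3, 4L * sc, 4L * sc, 1)
  L$head_fuse_bn <- new_bn(4L * sc, zero_init = FALSE)
  L$head_out_conv <- new_conv(1, 4L * sc, 3L, 1)
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$layers <- L
  class(model) <- "fpn_mask"
  model
}

## basic residual block forward; returns (out, cache)
block_fwd <- function(L, pre, B, training, has_proj) {
  c1 <- conv_fwd(L[[paste0(pre, "_conv1")]], B)
  b1 <- bn_fwd(L[[paste0(pre, "_bn1")]], c1$out, training)
  r1 <- relu_fwd(b1$out)
  c2 <- conv_fwd(L[[paste0(pre, "_conv2")]], r1$out)
  b2 <- bn_fwd(L[[paste0(pre, "_bn2")]], c2$out, training)
  if (has_proj) {
    pc <- conv_fwd(L[[paste0(pre, "_proj_conv")]], B)
    pb <- bn_fwd(L[[paste0(pre, "_proj_bn")]], pc$out, training)
    short <- pb$out
  } else {
    pc <- NULL; pb <- NULL
    short <- B
  }
  r2 <- relu_fwd(b2$out + short)
  list(out = r2$out,
       cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2,
                    pc = pc, pb = pb, r2 = r2, has_proj = has_proj))
}

block_bwd <- function(L, pre, cache, G) {
  g <- relu_bwd(cache$r2$cache, G)
  ## g flows to both the residual branch and the shortcut
  gb2 <- bn_bwd(L[[paste0(pre, "_bn2")]], cache$b2$cache, g)
  gc2 <- conv_bwd(L[[paste0(pre, "_conv2")]], cache$c2$cache, gb2)
  gr1 <- relu_bwd(cache$r1$cache, gc2)
  gb1 <- bn_bwd(L[[paste0(pre, "_bn1")]], cache$b1$cache, gr1)
  gmain <- conv_bwd(L[[paste0(pre, "_conv1")]], cache$c1$cache, gb1)
  if (cache$has_proj) {
    gpb <- bn_bwd(L[[paste0(pre, "_proj_bn")]], cache$pb$cache, g)
    gshort <- conv_bwd(L[[paste0(pre, "_proj_conv")]], cache$pc$cache, gpb)
  } else {
    gshort <- g
  }
  gmain + gshort
}

#' Forward pass of FPN-Mask
#'
#' @param model a model from \code{\link{build_fpn_mask}}.
#' @param xs a batch: list of H x W x 3 double arrays (shared size, values
#'   in [0, 1], H and W divisible by 8), a single such array, or an
#'   (H, W, N, 3) batch tensor.
#' @param training use batch statistics and record caches for the backward
#'   pass (\code{TRUE}) or running statistics (\code{FALSE}; deterministic).
#' @return list with \code{logits} (list of H x W x 3 arrays, one per
#'   image) and, when \code{training}, \code{cache} for
#'   \code{fpn_backward}; also exposes the pyramid levels \code{p2}..
#'   \code{p5} as batch tensors for inspection.
#' @export
fpn_forward <- function(model, xs, training = FALSE) {
  if (is.list(xs)) B <- bt_stack(xs)
  else if (length(dim(xs)) == 3L) B <- bt_stack(list(xs))
  else B <- xs
  d <- dim(B)
  if (length(d) != 4L || d[4] != 3L || d[1] %% 8L != 0L || d[2] %% 8L != 0L)
    stop("fpn_forward: inputs must be H x W x 3 with H, W divisible by 8",
         call. = FALSE)
  L <- model$layers
  depth <- model$config$backbone_depth
  sc_ <- conv_fwd(L$stem_conv, B)
  sb <- bn_fwd(L$stem_bn, sc_$out, training)
  sr <- relu_fwd(sb$out)
  cur <- sr$out
  stages <- list()
  blocks <- list()
  for (s in 2:5) {
    for (b in seq_len(depth)) {
      pre <- sprintf("s%db%d", s, b)
      has_proj <- (s > 2 && b == 1)
      bl <- block_fwd(L, pre, cur, training, has_proj)
      blocks[[pre]] <- bl$cache
      cur <- bl$out
    }
    stages[[paste0("C", s)]] <- cur
  }
  lat <- lapply(2:5, function(s)
    conv_fwd(L[[sprintf("lateral_%d", s)]], stages[[paste0("C", s)]]))
  names(lat) <- paste0("l", 2:5)
  p5 <- lat$l5$out
  p4 <- lat$l4$out + up2_fwd(p5)
  p3 <- lat$l3$out + up2_fwd(p4)
  p2 <- lat$l2$out + up2_fwd(p3)
  u3 <- bilinear_up_fwd(p3, 2L)
  u4 <- bilinear_up_fwd(p4, 4L)
  u5 <- bilinear_up_fwd(p5, 8L)
  h3 <- conv_fwd(L$head_up3_conv, u3)
  h4 <- conv_fwd(L$head_up4_conv, u4)
  h5 <- conv_fwd(L$head_up5_conv, u5)
  cat_ <- concat_channels(list(p2, h3$out, h4$out, h5$out))
  fc <- conv_fwd(L$head_fuse_conv, cat_)
  fb <- bn_fwd(L$head_fuse_bn, fc$out, training)
  fr <- relu_fwd(fb$out)
  oc <- conv_fwd(L$head_out_conv, fr$out)
  cache <- if (training)
    list(sc = sc_, sb = sb, sr = sr, blocks = blocks, lat = lat,
         h3 = h3, h4 = h4, h5 = h5, fc = fc, fb = fb, fr = fr, occ = oc)
  list(logits = bt_unstack(oc$out), logits_bt = oc$out, cache = cache,
       p2 = p2, p3 = p3, p4 = p4, p5 = p5)
}

## backward pass: accumulates parameter gradients into the layers and
## returns nothing useful (input gradients are discarded); glogits is an
## (H, W, N, 3) batch tensor of loss gradients
fpn_backward <- function(model, cache, glogits) {
  L <- model$layers
  depth <- model$config$backbone_depth
  g <- conv_bwd(L$head_out_conv, cache$occ$cache, glogits)
  g <- relu_bwd(cache$fr$cache, g)
  g <- bn_bwd(L$head_fuse_bn, cache$fb$cache, g)
  g <- conv_bwd(L$head_fuse_conv, cache$fc$cache, g)
  sc <- model$config$stage_channels
  parts <- split_channels(g, rep(sc, 4))
  gp2 <- parts[[1]]
  gu3 <- conv_bwd(L$head_up3_conv, cache$h3$cache, parts[[2]])
  gu4 <- conv_bwd(L$head_up4_conv, cache$h4$cache, parts[[3]])
  gu5 <- conv_bwd(L$head_up5_conv, cache$h5$cache, parts[[4]])
  gp3 <- bilinear_up_bwd(gu3, 2L)
  gp4 <- bilinear_up_bwd(gu4, 4L)
  gp5 <- bilinear_up_bwd(gu5, 8L)
  ## top-down pathway, reversed: P2 = l2 + up2(P3), etc.
  gl2 <- gp2
  gp3 <- gp3 + up2_bwd(gp2)
  gl3 <- gp3
  gp4 <- gp4 + up2_bwd(gp3)
  gl4 <- gp4
  gp5 <- gp5 + up2_bwd(gp4)
  gl5 <- gp5
  gstage <- list(
    C2 = conv_bwd(L$lateral_2, cache$lat$l2$cache, gl2),
    C3 = conv_bwd(L$lateral_3, cache$lat$l3$cache, gl3),
    C4 = conv_bwd(L$lateral_4, cache$lat$l4$cache, gl4),
    C5 = conv_bwd(L$lateral_5, cache$lat$l5$cache, gl5)
  )
  g <- gstage$C5
  for (s in 5:2) {
    for (b in rev(seq_len(depth))) {
      pre <- sprintf("s%db%d", s, b)
      g <- block_bwd(L, pre, cache$blocks[[pre]], g)
    }
    if (s > 2) g <- g + gstage[[paste0("C", s - 1L)]]
  }
  g <- relu_bwd(cache$sr$cache, g)
  g <- bn_bwd(L$stem_bn, cache$sb$cache, g)
  conv_bwd(L$stem_conv, cache$sc$cache, g)
  invisible(NULL)
}

#' Per-pixel class probabilities for one image
#'
#' Runs the network in evaluation mode (running batch-norm statistics;
#' deterministic) and applies a per-pixel softmax.
#'
#' @param model a trained \code{fpn_mask} model.
#' @param x H x W x 3 double array in [0, 1], H and W divisible by 8.
#' @return H x W x 3 array of class probabilities summing to 1 per pixel
#'   (channel order: background, leaf, panicle).
#' @export
predict_probmap <- function(model, x) {
  logits <- fpn_forward(model, list(x), training = FALSE)$logits[[1]]
  softmax3(logits)
}

## numerically stable per-pixel softmax over the class (last) axis
softmax3 <- function(logits) {
  d <- dim(logits)
  nc <- d[length(d)]
  z <- matrix(logits, prod(d) / nc, nc)
  zmax <- z[, 1]
  for (j in 2:nc) zmax <- pmax(zmax, z[, j])
  e <- exp(z - zmax)
  p <- e / rowSums(e)
  array(p, dim = d)
}

#' Hard class mask from a probability map
#'
#' Per-pixel argmax over the class channels; ties break toward the lowest
#' class index (background).
#'
#' @param probmap H x W x 3 probability (or score) array.
#' @return H x W integer matrix with labels 0/1/2.
#' @export
predict_mask <- function(probmap) {
  d <- dim(probmap)
  m <- matrix(probmap, d[1] * d[2], d[3])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}

#' Save and restore FPN-Mask weights
#'
#' \code{model_state} extracts a plain list (configuration, weights,
#' batch-norm statistics) suitable for serialization; \code{model_from_state}
#' rebuilds the model. \code{save_fpn_mask}/\code{load_fpn_mask} wrap them
#' with \code{saveRDS}/\code{readRDS} into a single checkpoint file with the
#' configuration embedded.
#'
#' @param model an \code{fpn_mask} model.
#' @param state a list produced by \code{model_state}.
#' @param path checkpoint file path.
#' @return \code{model_state}: a list; the others: a model (or the path for
#'   \code{save_fpn_mask}, invisibly).
#' @name checkpoint
NULL

#' @rdname checkpoint
#' @export
model_state <- function(model) {
  fields <- c("W", "b", "gamma", "beta", "running_mean", "running_var")
  layers <- lapply(model$layers, function(ly) {
    out <- list()
    for (f in fields) if (!is.null(ly[[f]])) out[[f]] <- ly[[f]]
    out
  })
  list(config = model$config, layers = layers)
}

#' @rdname checkpoint
#' @export
model_from_state <- function(state) {
  model <- build_fpn_mask(state$config)
  for (nm in names(state$layers)) {
    for (f in names(state$layers[[nm]]))
      model$layers[[nm]][[f]] <- state$layers[[nm]][[f]]
  }
  model
}

#' @rdname checkpoint
#' @export
save_fpn_mask <- function(model, path) {
  saveRDS(model_state(model), path)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_fpn_mask <- function(path) model_from_state(readRDS(path))
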