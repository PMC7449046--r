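# Minimal fully-convolutional NN engine. A batch of activations is a single
# array with dim = (H, W, N, C) — rows, cols, images, channels — so the
# (H*W*N) x C matrix view is copy-free, convolution over the whole batch is
# one im2col (C++) + one BLAS GEMM, and batch norm / ReLU / the loss
# vectorize over the batch. im2col is recomputed in the backward pass
# instead of cached, trading FLOPs for memory. Layers are environments so
# parameters, gradients and optimizer state update in place.

## stack a list of (H, W, C) arrays into an (H, W, N, C) batch tensor
bt_stack <- function(xs) {
  d <- dim(xs[[1]])
  n <- length(xs)
  out <- array(0, dim = c(d[1], d[2], n, d[3]))
  for (i in seq_len(n)) out[, , i, ] <- xs[[i]]
  out
}

## split a batch tensor back into a list of (H, W, C) arrays
bt_unstack <- function(B) {
  d <- dim(B)
  lapply(seq_len(d[3]), function(i) {
    x <- B[, , i, , drop = FALSE]
    dim(x) <- d[c(1, 2, 4)]
    x
  })
}

## the copy-free (H*W*N) x C matrix view and its inverse
bt_mat <- function(B) {
  d <- dim(B)
  dim(B) <- c(d[1] * d[2] * d[3], d[4])
  B
}

new_conv <- function(k, cin, cout, stride = 1L, bias = TRUE) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv"
  ly$k <- as.integer(k); ly$cin <- as.integer(cin); ly$cout <- as.integer(cout)
  ly$stride <- as.integer(stride)
  ly$pad <- as.integer((k - 1L) %/% 2L)
  ## He (variance-scaling) initialization for the rectified-linear nonlinearity
  ly$W <- matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                 k * k * cin, cout)
  ly$b <- if (bias) numeric(cout) else NULL
  ly
}

new_bn <- function(c, zero_init = FALSE, momentum = 0.1, eps = 1e-5) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "bn"
  ly$gamma <- rep(if (zero_init) 0 else 1, c)
  ly$beta <- numeric(c)
  ly$running_mean <- numeric(c)
  ly$running_var <- rep(1, c)
  ly$momentum <- momentum
  ly$eps <- eps
  ly
}

conv_fwd <- function(ly, B) {
  d <- dim(B)
  k <- ly$k; s <- ly$stride
  if (k == 1L && s == 1L) {
    o <- bt_mat(B) %*% ly$W
    if (!is.null(ly$b)) o <- o + rep(ly$b, each = nrow(o))
    dim(o) <- c(d[1], d[2], d[3], ly$cout)
  } else {
    o <- .cpp_conv_fwd(B, dim(B), ly$W, ly$b, k, s, ly$pad)
  }
  list(out = o, cache = B)
}

conv_bwd <- function(ly, cache, G) {
  d <- dim(cache)
  k <- ly$k; s <- ly$stride
  if (k == 1L && s == 1L) {
    gm <- bt_mat(G)
    if (!is.null(ly$b)) {
      gb <- colSums(gm)
      ly$gb <- if (is.null(ly$gb)) gb else ly$gb + gb
    }
    gW <- crossprod(bt_mat(cache), gm)
    gx <- gm %*% t(ly$W)
    dim(gx) <- d
    ly$gW <- if (is.null(ly$gW)) gW else ly$gW + gW
    return(gx)
  }
  r <- .cpp_conv_bwd(cache, dim(cache), ly$W, G, !is.null(ly$b), k, s,
                     ly$pad)
  ly$gW <- if (is.null(ly$gW)) r$gW else ly$gW + r$gW
  if (!is.null(ly$b))
    ly$gb <- if (is.null(ly$gb)) r$gb else ly$gb + r$gb
  r$gx
}

## batch norm: statistics pooled across all pixels of all images in the batch
bn_fwd <- function(ly, B, training) {
  d <- dim(B)
  n <- d[1] * d[2] * d[3]
  C <- d[4]
  if (training) {
    mom <- .cpp_col_moments(B, n, C)
    mu <- mom$mean
    v <- mom$var
    ly$running_mean <- (1 - ly$momentum) * ly$running_mean + ly$momentum * mu
    ly$running_var <- (1 - ly$momentum) * ly$running_var + ly$momentum * v
  } else {
    mu <- ly$running_mean
    v <- ly$running_var
  }
  inv_sd <- 1 / sqrt(v + ly$eps)
  r <- .cpp_bn_fwd(B, n, C, mu, inv_sd, ly$gamma, ly$beta)
  o <- r$out
  dim(o) <- d
  list(out = o, cache = list(xhat = r$xhat, inv_sd = inv_sd, d = d,
                             training = training))
}

bn_bwd <- function(ly, cache, G) {
  d <- cache$d
  n <- d[1] * d[2] * d[3]
  r <- .cpp_bn_bwd(G, cache$xhat, n, d[4], ly$gamma, cache$inv_sd,
                   cache$training)
  ly$ggamma <- if (is.null(ly$ggamma)) r$dgamma else ly$ggamma + r$dgamma
  ly$gbeta <- if (is.null(ly$gbeta)) r$dbeta else ly$gbeta + r$dbeta
  gx <- r$gx
  dim(gx) <- d
  gx
}

relu_fwd <- function(B) {
  o <- .cpp_relu(B)
  dim(o) <- dim(B)
  list(out = o, cache = o) # gradient mask is out > 0
}

relu_bwd <- function(cache, G) {
  gx <- .cpp_relu_grad(cache, G)
  dim(gx) <- dim(G)
  gx
}

## nearest-neighbor 2x upsampling and its adjoint (2x2 sum pooling),
## operating on the flattened image-x-channel planes
up2_fwd <- function(B) {
  d <- dim(B)
  o <- .cpp_up2_nn(B, d[1], d[2], d[3] * d[4])
  dim(o) <- c(2L * d[1], 2L * d[2], d[3], d[4])
  o
}

up2_bwd <- function(G) {
  d <- dim(G)
  o <- .cpp_up2_nn_grad(G, d[1], d[2], d[3] * d[4])
  dim(o) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
  o
}

bilinear_up_fwd <- function(B, factor) {
  d <- dim(B)
  o <- .cpp_resize_bilinear(B, d[1], d[2], d[3] * d[4],
                            as.integer(d[1] * factor),
                            as.integer(d[2] * factor))
  dim(o) <- c(d[1] * factor, d[2] * factor, d[3], d[4])
  o
}

bilinear_up_bwd <- function(G, factor) {
  d <- dim(G)
  o <- .cpp_resize_bilinear_grad(G, d[1], d[2], d[3] * d[4],
                                 as.integer(d[1] / factor),
                                 as.integer(d[2] / factor))
  dim(o) <- c(d[1] %/% factor, d[2] %/% factor, d[3], d[4])
  o
}

## concatenate batch tensors along the channel axis
concat_channels <- function(parts) {
  d <- dim(parts[[1]])
  cs <- vapply(parts, function(p) dim(p)[4], integer(1))
  o <- array(0, dim = c(d[1], d[2], d[3], sum(cs)))
  at <- 0L
  for (p in parts) {
    o[, , , (at + 1L):(at + dim(p)[4])] <- p
    at <- at + dim(p)[4]
  }
  o
}

split_channels <- function(G, sizes) {
  lapply(seq_along(sizes), function(k) {
    at <- c(0L, cumsum(sizes))[k]
    G[, , , (at + 1L):(at + sizes[k]), drop = FALSE]
  })
}

## parameter/gradient field pairs a layer exposes to the optimizer
layer_param_fields <- function(ly) {
  if (ly$type == "conv") {
    f <- c(W = "gW")
    if (!is.null(ly$b)) f <- c(f, b = "gb")
    f
  } else c(gamma = "ggamma", beta = "gbeta")
}

zero_grads <- function(model) {
  for (ly in model$layers)
    for (gf in layer_param_fields(ly)) ly[[gf]] <- NULL
  invisible(model)
}

## one Adam update over every parameter in the model; t is the step counter
adam_step <- function(model, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (ly in model$layers) {
    pf <- layer_param_fields(ly)
    for (pn in names(pf)) {
      g <- ly[[pf[[pn]]]]
      if (is.null(g)) next
      mkey <- paste0("adam_m_", pn); vkey <- paste0("adam_v_", pn)
      if (is.null(ly[[mkey]])) {
        ly[[mkey]] <- g * 0
        ly[[vkey]] <- g * 0
      }
      ly[[mkey]] <- beta1 * ly[[mkey]] + (1 - beta1) * g
      ly[[vkey]] <- beta2 * ly[[vkey]] + (1 - beta2) * g * g
      mhat <- ly[[mkey]] / (1 - beta1^t)
      vhat <- ly[[vkey]] / (1 - beta2^t)
      ly[[pn]] <- ly[[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(model)
}
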