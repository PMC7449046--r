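test_that("pyramid resolutions follow the {1,2,4,8} down-sampling contract", {
  set.seed(1)
  m <- build_fpn_mask(model_config(input_size = 256L, stage_channels = 8L,
                                   backbone_depth = 1L))
  x <- array(runif(256 * 256 * 3), c(256, 256, 3))
  f <- fpn_forward(m, x)
  expect_equal(dim(f$p2)[1:2], c(256, 256))
  expect_equal(dim(f$p3)[1:2], c(128, 128))
  expect_equal(dim(f$p4)[1:2], c(64, 64))
  expect_equal(dim(f$p5)[1:2], c(32, 32))
  expect_equal(dim(f$logits[[1]]), c(256, 256, 3))
})

test_that("every pyramid level carries stage_channels feature maps", {
  set.seed(2)
  m <- build_fpn_mask(model_config(input_size = 64L, stage_channels = 32L,
                                   backbone_depth = 1L))
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  f <- fpn_forward(m, x)
  for (p in list(f$p2, f$p3, f$p4, f$p5))
    expect_equal(dim(p)[4], 32L)
})

test_that("configuration invariants are enforced", {
  expect_error(model_config(input_size = 100L), "divisible by 8")
  expect_error(model_config(n_classes = 2L), "fixed at 3")
  expect_equal(unname(model_config()$stage_strides), c(1L, 2L, 2L, 2L))
  set.seed(1)
  m <- build_fpn_mask(tiny_model_config())
  expect_error(fpn_forward(m, array(0, c(30, 32, 3))), "divisible by 8")
})

test_that("probabilities are a softmax: nonnegative and summing to one", {
  set.seed(3)
  m <- build_fpn_mask(tiny_model_config())
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p <- predict_probmap(m, x)
  expect_equal(dim(p), c(32, 32, 3))
  expect_gte(min(p), 0)
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-6)
})

test_that("evaluation-mode forward passes are deterministic and finite", {
  set.seed(4)
  m <- build_fpn_mask(tiny_model_config())
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  f1 <- fpn_forward(m, x)$logits[[1]]
  f2 <- fpn_forward(m, x)$logits[[1]]
  expect_identical(f1, f2)
  expect_true(all(is.finite(f1)))
})

test_that("the same weights run at any input size divisible by 8", {
  set.seed(5)
  m <- build_fpn_mask(tiny_model_config(input_size = 32L))
  for (s in c(32L, 64L, 88L)) {
    x <- array(runif(s * s * 3), c(s, s, 3))
    f <- fpn_forward(m, x)
    expect_equal(dim(f$logits[[1]]), c(s, s, 3))
    expect_true(all(is.finite(f$logits[[1]])))
  }
})

test_that("predict_mask takes the argmax and breaks ties toward background", {
  pm <- array(0, c(2, 2, 3))
  pm[1, 1, ] <- c(0.2, 0.5, 0.3)
  pm[1, 2, ] <- c(1, 0, 0)
  pm[2, 1, ] <- c(1 / 3, 1 / 3, 1 / 3) # tie -> background
  pm[2, 2, ] <- c(0.1, 0.1, 0.8)
  expect_equal(predict_mask(pm), matrix(c(1L, 0L, 0L, 2L), 2, 2))
  ## one-hot probabilities recover the hot index everywhere
  set.seed(6)
  truth <- matrix(sample(0:2, 64, TRUE), 8, 8)
  onehot <- array(0, c(8, 8, 3))
  for (k in 1:3) onehot[, , k] <- (truth == k - 1) * 1
  expect_equal(predict_mask(onehot), truth)
})

test_that("analytic parameter gradients match finite differences", {
  set.seed(42)
  m <- build_fpn_mask(model_config(input_size = 16L, stage_channels = 4L,
                                   backbone_depth = 1L))
  xs <- lapply(1:2, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  targets <- array(sample(0:2, 16 * 16 * 2, TRUE), c(16, 16, 2))
  alpha <- c(1, 1.5, 0.7)
  loss_of <- function() {
    f <- fpn_forward(m, xs, training = TRUE)
    lprseg:::focal_loss_grad(f$logits_bt, targets, 2, alpha)$loss
  }
  f <- fpn_forward(m, xs, training = TRUE)
  lg <- lprseg:::focal_loss_grad(f$logits_bt, targets, 2, alpha)
  lprseg:::zero_grads(m)
  lprseg:::fpn_backward(m, f$cache, lg$grad)
  eps <- 1e-5
  check <- function(lname, pname, gname, n_checks = 3) {
    ly <- m$layers[[lname]]
    set.seed(7)
    for (i in sample(length(ly[[pname]]), n_checks)) {
      orig <- ly[[pname]][i]
      ly[[pname]][i] <- orig + eps; lp <- loss_of()
      ly[[pname]][i] <- orig - eps; lm <- loss_of()
      ly[[pname]][i] <- orig
      num <- (lp - lm) / (2 * eps)
      ana <- ly[[gname]][i]
      expect_equal(ana, num, tolerance = 1e-4,
                   label = paste0(lname, "$", pname, "[", i, "] analytic"),
                   expected.label = "numerical gradient")
    }
  }
  check("stem_conv", "W", "gW")
  check("s3b1_proj_conv", "W", "gW")
  check("s5b1_bn1", "gamma", "ggamma", 2)
  check("head_fuse_conv", "W", "gW")
  check("head_fuse_bn", "beta", "gbeta", 2)
  check("head_out_conv", "b", "gb", 2)
  check("lateral_2", "W", "gW", 2)
  check("head_up5_conv", "W", "gW", 2)
})

test_that("checkpoints round-trip through model_state and files", {
  set.seed(8)
  m <- build_fpn_mask(tiny_model_config())
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  before <- fpn_forward(m, x)$logits[[1]]
  f <- tempfile(fileext = ".rds")
  save_fpn_mask(m, f)
  m2 <- load_fpn_mask(f)
  expect_identical(fpn_forward(m2, x)$logits[[1]], before)
  unlink(f)
})

test_that("zero-scale batch-norm initialization is available behind the flag", {
  set.seed(9)
  mz <- build_fpn_mask(model_config(input_size = 32L, stage_channels = 8L,
                                    backbone_depth = 1L, zero_init_bn = TRUE))
  expect_true(all(mz$layers$s2b1_bn1$gamma == 0))
  set.seed(9)
  ms <- build_fpn_mask(tiny_model_config())
  expect_true(all(ms$layers$s2b1_bn1$gamma == 1))
})

test_that("fused convolution agrees with explicit im2col + GEMM", {
  set.seed(10)
  B <- array(rnorm(12 * 16 * 2 * 5), c(12, 16, 2, 5)) # H, W, N, C
  W <- matrix(rnorm(3 * 3 * 5 * 4), 3 * 3 * 5, 4)
  b <- rnorm(4)
  for (stride in c(1L, 2L)) {
    fused <- lprseg:::.cpp_conv_fwd(B, dim(B), W, b, 3L, stride, 1L)
    col <- lprseg:::.cpp_im2col(B, 12L, 16L, 2L, 5L, 3L, stride, 1L)
    ref <- col %*% W
    ref <- sweep(ref, 2, b, "+")
    expect_equal(as.vector(fused), as.vector(ref), tolerance = 1e-12)
    ## and the adjoint: col2im of the weight-projected gradient
    G <- array(rnorm(length(fused)), dim = dim(fused))
    bwd <- lprseg:::.cpp_conv_bwd(B, dim(B), W, G, TRUE, 3L, stride, 1L)
    gm <- matrix(G, prod(dim(G)[1:3]), 4)
    expect_equal(as.vector(bwd$gx),
                 as.vector(lprseg:::.cpp_col2im(gm %*% t(W), 12L, 16L, 2L,
                                                5L, 3L, stride, 1L)),
                 tolerance = 1e-12)
    expect_equal(bwd$gW, crossprod(col, gm), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(as.vector(bwd$gb), colSums(gm), tolerance = 1e-12)
  }
})
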