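# The reverse-mode engine is the foundation of every trainable module, so
# its gradients are checked against central finite differences on composite
# graphs covering all layer types used in the package.

fd_check <- function(fwd, params, n_probe = 5, eps = 1e-6) {
  L <- fwd()
  ag_zero_grad(params)
  ag_backward(L)
  maxerr <- 0
  for (p in params) {
    for (i in sample(length(p$value), min(n_probe, length(p$value)))) {
      v0 <- p$value[i]
      p$value[i] <- v0 + eps; Lp <- fwd()$value
      p$value[i] <- v0 - eps; Lm <- fwd()$value
      p$value[i] <- v0
      fd <- (Lp - Lm) / (2 * eps)
      maxerr <- max(maxerr, abs(fd - p$grad[i]) / max(1e-6, abs(fd)))
    }
  }
  maxerr
}

test_that("gradients of the convolutional path match finite differences", {
  set.seed(1)
  w1 <- init_conv_w(3, 2, 4); b1 <- init_bias(4)
  g1 <- ag_param(rep(1, 4)); be1 <- ag_param(rep(0, 4))
  wd <- init_dense_w(4, 3); bd <- init_bias(3)
  x0 <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  fwd <- function() {
    ag_tape_reset()
    h <- ag_conv2d(ag_const(x0), w1, b1)
    h <- ag_chan_norm(h, g1, be1)
    h <- ag_leaky_relu(h)
    h <- ag_avgpool2(h)
    r <- ag_roi_resize(h, c(0.5, 0.3, 2.5, 2.2), 4, 4)
    p <- ag_global_meanpool(r)
    s <- ag_softmax_rows(ag_add_bias_cols(ag_matmul(p, wd), bd))
    ag_mean(ag_square(ag_sub(s, matrix(c(1, 0, 0), 1))))
  }
  expect_lt(fd_check(fwd, list(w1, b1, g1, be1, wd, bd)), 1e-5)
})

test_that("gradients of upsample/tile/concat/layernorm path match finite differences", {
  set.seed(2)
  xw <- ag_param(array(rnorm(4 * 4 * 3), c(4, 4, 3)))
  e <- ag_param(matrix(rnorm(2), 1))
  gl <- ag_param(rep(1, 5)); bl <- ag_param(rep(0, 5))
  wm <- ag_param(matrix(rnorm(25), 5))
  fwd <- function() {
    ag_tape_reset()
    z <- ag_concat_chan(ag_upsample2(xw), ag_tile_vec(e, 8, 8))
    m <- ag_layernorm_rows(ag_global_meanpool(z), gl, bl)
    ag_sum(ag_abs(ag_tanh(ag_matmul_t(m, wm))))
  }
  expect_lt(fd_check(fwd, list(xw, e, gl, bl, wm)), 1e-5)
})

test_that("strided 4x4 convolution gradients match finite differences", {
  set.seed(3)
  ws <- init_conv_w(4, 1, 2); bs <- init_bias(2)
  x1 <- array(rnorm(36), c(6, 6, 1))
  fwd <- function() {
    ag_tape_reset()
    ag_mean(ag_square(ag_conv2d(ag_const(x1), ws, bs, k = 4, stride = 2,
                                pad = 1)))
  }
  expect_lt(fd_check(fwd, list(ws, bs), n_probe = 8), 1e-5)
})

test_that("softplus and sigmoid are numerically stable at extremes", {
  x <- ag_const(c(-50, 0, 50))
  expect_equal(ag_softplus(x)$value, c(0, log(2), 50), tolerance = 1e-10)
  expect_equal(ag_sigmoid(x)$value, c(0, 0.5, 1), tolerance = 1e-10)
})

test_that("adam reduces a simple quadratic", {
  set.seed(4)
  p <- ag_param(c(5, -3))
  st <- adam_init(list(p))
  for (i in 1:300) {
    ag_tape_reset()
    ag_zero_grad(list(p))
    L <- ag_sum(ag_square(p))
    ag_backward(L)
    st <- adam_step(list(p), st, lr = 0.1)
  }
  expect_lt(sum(p$value^2), 1e-4)
})
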