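test_that("depth loss reproduces hand-computed values and the printed sum form", {
  # 2x2: D = 0, I with unit x-steps, alpha = 0.1, lambda = 0.5, sum
  # semantics -> smooth = 0.5 * 2 * 0.1^2 = 0.01
  D <- matrix(0, 2, 2)
  I <- matrix(c(0, 0, 1, 1), 2)
  l <- depth_loss(D, matrix(0, 2, 2), I, depth_net_config(literal_sum = TRUE))
  expect_equal(l$smooth, 0.01, tolerance = 1e-12)
  expect_equal(l$data, 0)
  expect_equal(l$total, l$data + l$smooth)
  expect_error(depth_loss(D, matrix(0, 3, 3), I, depth_net_config()), "mismatch")
})

test_that("smoothing term vanishes iff depth gradients equal alpha times IR gradients", {
  set.seed(5)
  I <- matrix(runif(64), 8)
  D <- 0.1 * I + 2          # gradients match exactly (alpha = 0.1)
  l <- depth_loss(D, D, I, depth_net_config())
  expect_lt(l$total, 1e-20)
  l2 <- depth_loss(D + outer(1:8, 1:8) * 1e-3, D, I, depth_net_config())
  expect_gt(l2$smooth, 0)
  expect_gt(l2$data, 0)
})

test_that("contour attention keeps non-negative features within [F, 2F]", {
  set.seed(6)
  model <- make_depth_model(depth_net_config())
  ag_tape_reset()
  feats <- list(ag_const(array(abs(rnorm(8 * 8 * 4)), c(8, 8, 4))),
                ag_const(array(abs(rnorm(4 * 4 * 4)), c(4, 4, 4))))
  model$att <- model$att[1:2]
  prior <- ag_const(array(runif(64), c(8, 8, 1)))
  out <- apply_contour_attention(feats, prior, model)
  for (s in 1:2) {
    expect_true(all(out[[s]]$value >= feats[[s]]$value - 1e-12))
    expect_true(all(out[[s]]$value <= 2 * feats[[s]]$value + 1e-12))
    expect_identical(dim(out[[s]]$value), dim(feats[[s]]$value))
  }
  ag_tape_reset()
})

test_that("contour prior is flat on constant input and strong on a step edge", {
  set.seed(7)
  model <- make_depth_model(depth_net_config())
  ag_tape_reset()
  flat <- extract_contour_prior(matrix(0.5, 24, 24), model)$value[, , 1]
  # the zero-padded borders induce edge responses reaching 4 px inward
  # (Sobel + three 3x3 refinement layers); the true interior is constant
  expect_lt(stats::sd(flat[6:19, 6:19]), 1e-10)
  # Sobel magnitude of a vertical step peaks on the edge columns
  step <- matrix(rep(c(0, 0, 0, 1, 1, 1), each = 6), 6)
  sob <- ag_conv2d(ag_const(array(step, c(6, 6, 1))),
                   ag_const(sobel_wm()), ag_const(c(0, 0)), k = 3)
  mag <- sqrt(sob$value[, , 1]^2 + sob$value[, , 2]^2)
  expect_true(all(mag[2:5, 3] >= mag[2:5, 2]))
  # hand Sobel of a unit step, away from the padded border rows
  expect_equal(max(mag[2:5, ]), 4)
  ag_tape_reset()
})

test_that("predictions stay inside the configured metric range", {
  set.seed(8)
  model <- make_depth_model(depth_net_config())
  d <- predict_depth(matrix(runif(48 * 48), 48), model)
  expect_true(all(d >= 0 & d <= 5))
  expect_identical(dim(d), c(48L, 48L))
})

test_that("the loss propagates gradients into both the depth and contour heads", {
  set.seed(9)
  clip <- small_clip()
  model <- make_depth_model(depth_net_config())
  params <- ag_collect_params(model)
  ag_tape_reset()
  ag_zero_grad(params)
  D <- aquavol:::depth_forward(clip$ir[[1]], model)
  l <- depth_loss(D, clip$truth$depth[[1]], clip$ir[[1]], model$cfg)
  ag_backward(l$node)
  expect_gt(sum(abs(model$out$w$grad)), 0)
  expect_gt(sum(abs(model$contour$w1$grad)), 0)
  expect_gt(sum(abs(model$att[[1]]$w$grad)), 0)
  ag_tape_reset()
})
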