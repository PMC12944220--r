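test_that("water term matches scalar evaluation and vanishes on the physical target", {
  ir <- matrix(0.8, 8, 8); D <- matrix(2, 8, 8)
  R <- array(0.5, c(8, 8, 3))
  l <- water_adaptive_loss(R, ir, D, cfg = gen_config())
  expect_equal(l$water, 0.3 * abs(0.5 - 0.8 * exp(-0.1)), tolerance = 1e-12)
  R0 <- array(0, c(8, 8, 3))
  for (ch in 1:3) R0[, , ch] <- ir * exp(-0.05 * D)
  expect_equal(water_adaptive_loss(R0, ir, D, cfg = gen_config())$water, 0)
  expect_error(water_adaptive_loss(R, ir, D - 5, cfg = gen_config()),
               "negative")
})

test_that("water term grows monotonically with the residual magnitude", {
  set.seed(10)
  ir <- matrix(runif(64), 8); D <- matrix(runif(64, 1, 2), 8)
  tgt <- array(0, c(8, 8, 3))
  for (ch in 1:3) tgt[, , ch] <- ir * exp(-0.05 * D)
  resid <- array(rnorm(192), c(8, 8, 3))
  vals <- sapply(c(0.5, 1, 2, 4), function(s)
    water_adaptive_loss(tgt + s * resid, ir, D, cfg = gen_config())$water)
  expect_true(all(diff(vals) > 0))
})

test_that("texture embedding is 128-long, deterministic and order-invariant", {
  set.seed(11)
  models <- make_gan_models()
  p1 <- matrix(runif(1024), 32); p2 <- matrix(runif(1024), 32)
  ag_tape_reset()
  e12 <- extract_texture_embedding(list(p1, p2), models)$value
  e21 <- extract_texture_embedding(list(p2, p1), models)$value
  e12b <- extract_texture_embedding(list(p1, p2), models)$value
  ag_tape_reset()
  expect_length(e12, 128)
  expect_equal(e12, e21, tolerance = 1e-12)
  expect_identical(e12, e12b)
  expect_warning(z <- extract_texture_embedding(list(), models), "zero")
  expect_true(all(z$value == 0))
})

test_that("texture injection preserves spatial size and concatenates 128 channels", {
  set.seed(12)
  models <- make_gan_models()
  ag_tape_reset()
  E <- ag_const(matrix(rnorm(128), 1))
  f <- ag_const(array(rnorm(4 * 6 * 16), c(4, 6, 16)))
  tiled <- ag_tile_vec(E, 4, 6)
  expect_identical(dim(ag_concat_chan(f, tiled)$value), c(4L, 6L, 144L))
  # every spatial location of the tile holds the identical vector
  expect_true(all(apply(tiled$value, 3, function(s) max(s) - min(s)) == 0))
  out <- inject_texture(f, E, models$gen$inj)
  expect_identical(dim(out$value)[1:2], c(4L, 6L))
  ag_tape_reset()
})

test_that("discriminator emits a spatial logit map (70-px receptive field pattern)", {
  set.seed(13)
  models <- make_gan_models()
  ag_tape_reset()
  d <- disc_forward(matrix(runif(4096), 64), array(runif(64 * 64 * 3), c(64, 64, 3)),
                    models)
  expect_length(dim(d$value), 3)
  expect_gt(prod(dim(d$value)[1:2]), 1)   # map, not a scalar
  ag_tape_reset()
})

test_that("an adversarial step returns finite non-negative components", {
  set.seed(14)
  clip <- small_clip(n_fish = 4, image_size = c(48, 48), focal_px = 45,
                     clip_len = 4, seed = 21)
  models <- make_gan_models()
  res <- train_gan_step(models, clip$ir[[1]], clip$rgb[[1]],
                        clip$truth$depth[[1]], clip$truth$boxes[[1]])
  expect_true(all(is.finite(res$record)))
  expect_gte(res$record["l1"], 0)
  expect_gte(res$record["water"], 0)
  expect_error(train_gan_step(models, clip$ir[[1]], NULL,
                              clip$truth$depth[[1]]), "unpaired")
})
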