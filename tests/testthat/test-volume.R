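test_that("sinusoidal positional encodings match the closed form", {
  pe <- sinusoidal_pe(3, 8)
  expect_equal(pe[1, ], rep(c(0, 1), 4))          # t = 0: sin 0, cos 0
  for (t in 0:2) for (i in 1:4) {
    f <- 1 / 10000^(2 * (i - 1) / 8)
    expect_equal(pe[t + 1, 2 * i - 1], sin(t * f), tolerance = 1e-12)
    expect_equal(pe[t + 1, 2 * i], cos(t * f), tolerance = 1e-12)
  }
})

test_that("a single depth token receives attention weight exactly 1", {
  set.seed(26)
  model <- make_tdt_model(tdt_config_tiny())
  ag_tape_reset()
  et <- ag_const(matrix(rnorm(5 * 64), 5))
  ed <- ag_const(matrix(rnorm(64), 1))
  blk <- model$blocks[[1]]
  A <- ag_softmax_rows(ag_scale(
    ag_matmul_t(ag_matmul(et, blk$Wq[[1]]), ag_matmul(ed, blk$Wk[[1]])), 1 / 4))
  expect_true(all(A$value == 1))
  ag_tape_reset()
})

test_that("the TDT forward pass matches an explicit loop implementation", {
  set.seed(27)
  maxdiff <- 0
  for (k in 1:50) {
    cfg1 <- tdt_config(layers = 1, heads = 1, hidden = 4)
    m1 <- make_tdt_model(cfg1, head_bias_init = rnorm(1, 5))
    et <- matrix(rnorm(8), 2); ed <- matrix(rnorm(4), 1)
    ag_tape_reset()
    ours <- as.numeric(tdt_forward(ag_const(et), ag_const(ed), m1)$value)
    ag_tape_reset()
    blk <- m1$blocks[[1]]
    ln <- function(x, g, b) {
      mu <- mean(x); s <- sqrt(mean((x - mu)^2) + 1e-5); (x - mu) / s * g + b
    }
    att <- brute_attention(et, ed, blk$Wq[[1]]$value, blk$Wk[[1]]$value,
                           blk$Wv[[1]]$value, blk$Wo$value, 1)
    a <- sweep(att, 2, blk$bo$value, "+")
    f <- t(apply(a + et, 1, ln, g = blk$ln1g$value, b = blk$ln1b$value))
    ffh <- pmax(sweep(f %*% blk$ff1$w$value, 2, blk$ff1$b$value, "+"), 0)
    ffo <- sweep(ffh %*% blk$ff2$w$value, 2, blk$ff2$b$value, "+")
    x2 <- t(apply(f + ffo, 1, ln, g = blk$ln2g$value, b = blk$ln2b$value))
    hh <- pmax(colMeans(x2) %*% m1$head$w1$value + m1$head$b1$value, 0)
    o <- as.numeric(hh %*% m1$head$w2$value + m1$head$b2$value)
    ref <- if (o > 30) o else log1p(exp(o))
    maxdiff <- max(maxdiff, abs(ours - ref))
  }
  expect_lt(maxdiff, 1e-6)
})

test_that("refraction correction factor is exact, monotone, and cubic", {
  out0 <- refraction_correct(10, 0)
  expect_equal(out0$factor, 1)
  expect_equal(out0$V, 10)
  # theta = 10 deg, n_w = 1.33: independent closed-form evaluation
  th10 <- 10 * pi / 180
  f10 <- 1.33 / sqrt(1.33^2 - sin(th10)^2)
  out10 <- refraction_correct(10, th10)
  expect_equal(out10$factor, f10, tolerance = 1e-9)
  expect_equal(out10$V, 10 * f10^3, tolerance = 1e-9)
  # strictly increasing on [0, pi/2)
  th <- seq(0, 1.4, length.out = 40)
  expect_true(all(diff(refract_depth_factor(th)) > 0))
  # V / V_pre is the cubed factor for every record
  expect_equal(out10$V / 10, out10$factor^3, tolerance = 1e-12)
  expect_error(refraction_correct(10, pi / 2), "theta")
  # the printed small-angle expansion carries the spurious n_w factor
  expect_equal(refract_depth_factor(0, approx_as_printed = TRUE), 1.33)
})

test_that("volume loss reproduces hand arithmetic and constant-offset analysis", {
  expect_equal(volume_loss(c(10, 10), c(10, 10)), 0)
  expect_equal(volume_loss(c(12, 12, 12), c(10, 10, 10), 0.1), 2)
  V <- c(10, 12, 11); Vg <- c(10, 10, 10)
  expect_equal(volume_loss(V, Vg, 0.1),
               mean(abs(V - Vg)) + 0.1 * mean((diff(V) - diff(Vg))^2))
  expect_error(volume_loss(1:3, 1:4), "mismatch")
  expect_error(volume_loss(1, 1), "short")
})

test_that("incidence angle is zero on-axis and matches hand trigonometry at a corner", {
  traj <- rbind(c(79.5, 79.5), c(0, 0))
  th <- estimate_incidence(traj, c(160, 160), 150)
  expect_equal(th[1], 0)
  expect_equal(th[2], atan(sqrt(2 * 79.5^2) / 150), tolerance = 1e-12)
  expect_error(estimate_incidence(traj, NULL, NULL), "calibration")
})

test_that("depth-region embedding has width d and is sensitive to depth scale", {
  set.seed(28)
  model <- make_tdt_model(tdt_config_tiny())
  dr <- matrix(0, 48, 48); dr[20:28, 20:24] <- 1.3
  ag_tape_reset()
  e1 <- embed_depth_region(dr, model)$value
  e2 <- embed_depth_region(dr * 2, model)$value
  e1b <- embed_depth_region(dr, model)$value
  ag_tape_reset()
  expect_length(e1, 64)
  expect_identical(e1, e1b)
  expect_gt(max(abs(e1 - e2)), 1e-6)   # no accidental scale invariance
  expect_warning(embed_depth_region(matrix(0, 48, 48), model), "zero")
})

test_that("trajectory embedding rejects single-frame input", {
  set.seed(29)
  model <- make_tdt_model(tdt_config_tiny())
  expect_error(embed_trajectory(matrix(1, 1, 4), model), "2 frames")
})
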