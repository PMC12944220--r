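test_that("simulation is deterministic and carries persistent ids", {
  cfg <- tank_config(n_fish = 8, image_size = c(96, 96), focal_px = 90,
                     clip_len = 12, seed = 42)
  c1 <- simulate_clip(cfg)
  c2 <- simulate_clip(cfg)
  expect_identical(c1, c2)
  expect_length(c1$ir, 12)
  expect_length(c1$truth$ids, 8)
  expect_identical(c1$truth$ids, 1:8)
})

test_that("boxes are the tight bounding boxes of their masks", {
  clip <- small_clip(n_fish = 6, image_size = c(96, 96), focal_px = 90,
                     clip_len = 8, seed = 7)
  for (t in c(1, 5, 8)) {
    for (i in seq_len(6)) {
      m <- truth_mask(clip$truth, t, i)
      b <- clip$truth$boxes[[t]][i, ]
      if (!any(m)) { expect_equal(b[3], 0); next }
      rc <- which(m, arr.ind = TRUE)
      expect_identical(unname(b),
                       c(min(rc[, 2]) - 1, min(rc[, 1]) - 1,
                         diff(range(rc[, 2])) + 1, diff(range(rc[, 1])) + 1))
    }
  }
})

test_that("analytic volume is the ellipsoid formula and constant over the clip", {
  clip <- small_clip(n_fish = 6, image_size = c(96, 96), focal_px = 90,
                     clip_len = 8, seed = 7)
  f <- clip$truth$fish
  expect_equal(clip$truth$volumes, 4 / 3 * pi * f$a * f$b * f$c)
  # volumes are per-fish constants; mask areas meanwhile vary with bending
  areas <- sapply(1:8, function(t) length(clip$truth$masks[[t]][[1]]))
  expect_length(clip$truth$volumes, 6)
  expect_gt(stats::sd(areas), 0)
})

test_that("zero-speed fish stay in place", {
  cfg <- tank_config(n_fish = 1, image_size = c(96, 96), focal_px = 90,
                     clip_len = 10, seed = 3, speed_range = c(0, 0),
                     turn_rate_range = c(0, 0))
  clip <- simulate_clip(cfg)
  tr <- clip$truth$traj
  expect_equal(max(abs(diff(tr$cx))), 0, tolerance = 1e-9)
  expect_equal(max(abs(diff(tr$cy))), 0, tolerance = 1e-9)
})

test_that("overcrowded configurations are rejected", {
  cfg <- tank_config(n_fish = 16, tank_size = c(0.12, 0.12, 0.5),
                     image_size = c(64, 64), focal_px = 60, clip_len = 2,
                     seed = 1, fish_len_range = c(14, 15))
  suppressWarnings(expect_error(simulate_clip(cfg), "footprint"))
})

test_that("ripple warp matches its closed form and is identity at A = 0", {
  img <- matrix(runif(400), 20, 20)
  expect_identical(ripple_warp(img, 0, 0.05), img)
  # A = 5, f = 0.05, phase = 0 at output pixel (x = 0, y = 5):
  # x-offset = 5 sin(pi/2) = 5, y-offset = 5 sin(0) = 0 -> input(5, 5)
  delta <- matrix(0, 20, 20); delta[6, 6] <- 1   # (x, y) = (5, 5)
  out <- ripple_warp(delta, 5, 0.05, 0)
  expect_equal(out[6, 1], 1)                      # (x, y) = (0, 5)
})

test_that("Beer-Lambert attenuation matches scalar evaluation", {
  rgb <- array(0.8, c(4, 4, 3)); D <- matrix(2, 4, 4)
  expect_identical(attenuate_color(rgb, D, 0), rgb)
  out <- attenuate_color(rgb, D, 0.05)
  expect_equal(out[1, 1, 1], 0.8 * exp(-0.1), tolerance = 1e-12)
  expect_error(attenuate_color(rgb, D - 5, 0.05), "negative")
})

test_that("apparent depth inverts the refraction correction exactly", {
  th <- c(0, 5, 10) * pi / 180
  d <- 1.3
  expect_equal(correct_depth(apparent_depth(d, th), th), rep(d, 3),
               tolerance = 1e-12)
  expect_equal(apparent_depth(d, 0), d)
  # theta = 10 deg, n_w = 1.33: d_app/d_real = sqrt(n^2 - sin^2)/n
  expect_equal(apparent_depth(1, 10 * pi / 180) ,
               sqrt(1.33^2 - sin(10 * pi / 180)^2) / 1.33,
               tolerance = 1e-9)
  expect_error(apparent_depth(1, pi / 2), "theta")
})

test_that("depth channels honor the camera geometry", {
  clip <- small_clip(n_fish = 6, image_size = c(96, 96), focal_px = 90,
                     clip_len = 8, seed = 7)
  cfg <- clip$config
  rng <- range(unlist(lapply(clip$truth$depth, range)))
  expect_gte(rng[1], cfg$camera_height)
  expect_lte(rng[2], cfg$camera_height + cfg$tank_size[3])
  # apparent depth is shallower off-axis, equal on-axis
  expect_true(all(clip$depth[[1]] <= clip$truth$depth[[1]] + 1e-12))
})
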