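test_that("keypoints of a 40x8 rectangle are collinear with quarter-length spacing", {
  m <- matrix(FALSE, 20, 60); m[7:14, 11:50] <- TRUE
  kp <- skeleton_keypoints(m, 5)
  expect_identical(dim(kp$points), c(5L, 2L))
  seg <- sqrt(rowSums(diff(kp$points)^2))
  expect_lt(max(abs(seg - seg[1])), 1e-9)        # equal arc-length spacing
  expect_lt(max(abs(kp$points[, 2] - kp$points[1, 2])), 1.5)  # collinear
  expect_gt(seg[1], (40 - 10) / 4 * 0.8)         # spans most of the long axis
  # head end: larger projection on the +x principal axis
  expect_gt(kp$points[1, 1], kp$points[5, 1])
})

test_that("keypoints are deterministic and equivariant to integer translation", {
  m <- matrix(FALSE, 20, 60); m[7:14, 11:50] <- TRUE
  m2 <- matrix(FALSE, 30, 70); m2[12:19, 16:55] <- TRUE   # shifted by (5, 5)
  kp <- skeleton_keypoints(m, 5); kp2 <- skeleton_keypoints(m2, 5)
  expect_equal(kp2$points, kp$points + 5, tolerance = 1e-9)
  expect_identical(skeleton_keypoints(m, 5)$points, kp$points)
})

test_that("the disk path passes the center; degenerate masks behave", {
  mm <- matrix(FALSE, 31, 31)
  for (r in 1:31) for (cc in 1:31)
    if ((r - 16)^2 + (cc - 16)^2 <= 144) mm[r, cc] <- TRUE
  kp <- skeleton_keypoints(mm, 5)
  expect_lt(sqrt(sum((kp$points[3, ] - c(15, 15))^2)), 3)
  expect_error(skeleton_keypoints(matrix(FALSE, 4, 4)), "empty")
  one <- matrix(FALSE, 5, 5); one[3, 2] <- TRUE
  kp1 <- skeleton_keypoints(one, 5)
  expect_true(all(kp1$points[, 1] == 1 & kp1$points[, 2] == 2))
})

test_that("deformation loss reproduces hand logarithms; components are non-negative", {
  M <- matrix(c(0.9, 0.2), 1); gt <- matrix(c(1, 0), 1)
  kp0 <- structure(list(points = matrix(0, 5, 2), theta = NULL),
                   class = "keypoint_set")
  l <- deformation_loss(M, gt, kp0, kp0, seg_config())
  expect_equal(l$ce, -log(0.9) - log(0.8), tolerance = 1e-9)
  expect_equal(l$prior, 0)
  expect_equal(l$total, l$ce + l$prior)
  # perfect clamped prediction with matching keypoints -> ~0
  Mp <- ifelse(gt == 1, 1 - 1e-7, 1e-7)
  expect_lt(deformation_loss(Mp, gt, kp0, kp0, seg_config())$total, 1e-5)
  # prior is zero iff keypoints coincide
  kp1 <- structure(list(points = matrix(1, 5, 2), theta = NULL),
                   class = "keypoint_set")
  l2 <- deformation_loss(M, gt, kp1, kp0, seg_config())
  expect_gt(l2$prior, 0)
  kbad <- structure(list(points = matrix(0, 4, 2), theta = NULL),
                    class = "keypoint_set")
  expect_error(deformation_loss(M, gt, kbad, kp0, seg_config()), "keypoint")
})

test_that("ROI fusion is a pure residual when the perceptron is zeroed", {
  set.seed(24)
  model <- make_seg_model()
  model$fuse$w2$value[] <- 0; model$fuse$b2$value[] <- 0
  ag_tape_reset()
  ri <- ag_const(array(rnorm(14 * 14 * 8), c(14, 14, 8)))
  rd <- ag_const(array(rnorm(14 * 14 * 8), c(14, 14, 8)))
  out <- fuse_roi(ri, rd, model)
  expect_lt(max(abs(out$value - ri$value)), 1e-12)
  expect_identical(dim(out$value), dim(ri$value))
  rbad <- ag_const(array(0, c(7, 7, 8)))
  expect_error(fuse_roi(ri, rbad, model), "mismatch")
  ag_tape_reset()
})

test_that("segment_frame yields DR only inside the binarized mask; empty input is not an error", {
  set.seed(25)
  clip <- small_clip(n_fish = 3, image_size = c(64, 64), focal_px = 110,
                     clip_len = 8, seed = 5)
  model <- make_seg_model()
  sm <- segment_frame(clip$ir[[1]], clip$truth$depth[[1]], model,
                      clip$truth$boxes[[1]])
  for (k in seq_along(sm$masks)) {
    expect_true(all(sm$DR[[k]][sm$masks[[k]] < 0.5] == 0))
    dr_sum <- sum(sm$DR[[k]])
    b <- clip$truth$boxes[[1]][k, ]
    # DR mass bounded by depth mass over the (padded) box footprint
    expect_lte(dr_sum, sum(clip$truth$depth[[1]]))
  }
  empty <- segment_frame(clip$ir[[1]], clip$truth$depth[[1]], model,
                         matrix(numeric(0), 0, 4))
  expect_length(empty$masks, 0)
})
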