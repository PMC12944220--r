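test_that("hungarian assignment matches brute-force enumeration", {
  set.seed(15)
  for (trial in 1:25) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    cost <- matrix(runif(n * m), n, m)
    asg <- hungarian_assign(cost)
    tot <- sum(cost[cbind(which(!is.na(asg)), asg[!is.na(asg)])])
    expect_equal(tot, brute_assignment_cost(cost), tolerance = 1e-9)
  }
})

test_that("cross-modal attention equals the double-loop oracle on 50 instances", {
  set.seed(16)
  maxdiff <- 0
  for (k in 1:50) {
    n <- sample(2:6, 1); d <- 8
    w <- make_fusion_weights(d = d, d_k = 4, heads = 2)
    fi <- matrix(rnorm(n * d), n); fr <- matrix(rnorm(n * d), n)
    ours <- fuse_crossmodal(fi, fr, w)
    ref <- brute_attention(fi, fr, w$W_Q, w$W_K, w$W_V, w$W_O, 2)
    maxdiff <- max(maxdiff, max(abs(ours - ref)))
  }
  expect_lt(maxdiff, 1e-5)
})

test_that("identical keys give uniform attention: every output is the value mean", {
  set.seed(17)
  w <- make_fusion_weights(d = 8, d_k = 4, heads = 2)
  fi <- matrix(rnorm(24), 3)
  fr <- matrix(rep(rnorm(8), 3), 3, byrow = TRUE)
  out <- fuse_crossmodal(fi, fr, w)
  expect_lt(max(abs(sweep(out, 2, out[1, ]))), 1e-12)
  # head-width must divide the projection width
  wbad <- w; wbad$heads <- 3
  expect_error(fuse_crossmodal(fi, fr, wbad), "divisible")
})

test_that("behavior constraints clamp speed and turn radius", {
  cfg <- kf_config()
  st <- list(x = c(0, 0, 2, 1.5, 0, 0), P = diag(6) * 0.01)
  out <- kf_predict(st, 1 / 30, cfg)
  expect_equal(sqrt(sum(out$x[4:5]^2)), 1, tolerance = 1e-9)
  expect_gt(out$x[4], 0)   # direction preserved
  st2 <- list(x = c(0, 0, 2, 0.2, 0, 10), P = diag(6) * 0.01)
  expect_equal(kf_predict(st2, 1 / 30, cfg)$x[6], 4, tolerance = 1e-6)
  # at rest the position is unchanged and P grows by Q then clips
  st3 <- list(x = c(0.3, 0.4, 2, 0, 0, 0), P = diag(6) * 0.01)
  out3 <- kf_predict(st3, 1 / 30, cfg)
  expect_equal(out3$x[1:2], c(0.3, 0.4))
  expect_true(all(diag(out3$P) >= diag(st3$P)))
  expect_error(kf_predict(list(x = rep(0, 6), P = -diag(6)), 1 / 30, cfg),
               "semidefinite")
})

test_that("zero-innovation updates leave the mean unchanged; gating matches the quadratic form", {
  cfg <- kf_config()
  st <- kf_init(c(0.5, 0.5, 2), cfg)
  z <- c(0.5, 0.5, 2)
  out <- kf_update(st, z, cfg)
  expect_equal(out$x[1:3], z, tolerance = 1e-9)
  g0 <- mahalanobis_gate(st, z, cfg)
  expect_equal(g0$distance, 0)
  expect_true(g0$accept)
  # identity innovation covariance, offset (3, 0, 0): distance 9 > 7.815
  cfg1 <- kf_config(r_meas = c(0.5, 0.5, 0.5), p0 = rep(0.5, 6))
  stg <- list(x = rep(0, 6), P = diag(6) * 0.5)
  g <- mahalanobis_gate(stg, c(3, 0, 0), cfg1)
  expect_equal(g$distance, 9, tolerance = 1e-9)
  expect_false(g$accept)
})

test_that("repeated identical measurements converge the position monotonically", {
  cfg <- kf_config()
  st <- list(x = c(0, 0, 2, 0, 0, 0), P = diag(6) * cfg$P_max)
  target <- c(0.3, 0, 2)
  errs <- numeric(10)
  for (k in 1:10) {
    st <- kf_update(st, target, cfg)
    errs[k] <- abs(st$x[1] - 0.3)
    st$P <- diag(6) * max(diag(st$P))   # hold covariance up, as in the 1-D oracle
  }
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[10], errs[1])
})

test_that("constraint invariants hold over a 1000-step randomized filter run", {
  set.seed(18)
  cfg <- kf_config()
  st <- kf_init(c(0.5, 0.5, 2), cfg)
  for (k in 1:1000) {
    st <- kf_predict(st, cfg$dt, cfg)
    sp <- sqrt(sum(st$x[4:5]^2))
    expect_lte(sp, 1 + 1e-9)
    if (sp > 1e-9) expect_gte(sp / max(abs(st$x[6]), 1e-12), 0.05 - 1e-9)
    ev <- eigen(st$P, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(ev), cfg$P_max + 1e-6)
    expect_gte(min(ev), cfg$P_min - 1e-9)
    if (k %% 3 == 0)
      st <- kf_update(st, c(runif(1), runif(1), runif(1, 0.5, 4)), cfg)
    if (k %% 7 == 0) st$x[4:5] <- rnorm(2, sd = 1)   # inject wild velocity
  }
})

test_that("two parallel non-crossing fish keep their identities for 90 frames", {
  cfg <- tank_config(n_fish = 2, image_size = c(160, 160), focal_px = 150,
                     clip_len = 90, seed = 19, turn_rate_range = c(0, 0))
  clip <- simulate_clip(cfg)
  set.seed(19)
  det <- oracle_detections(clip, jitter_sd = 2, occl_drop = 0.5)
  fw <- make_fusion_weights()
  kcfg <- kf_config(m_per_px = (cfg$camera_height + 0.25) / cfg$focal_px)
  ts <- track_clip(det, kcfg, fw)
  expect_identical(clear_mot_switches(ts, clip$truth, 90), 0L)
  expect_lte(length(unique(ts$id)), 3)
})

test_that("tracks never outnumber the detections seen", {
  clip <- small_clip(n_fish = 4, image_size = c(96, 96), focal_px = 90,
                     clip_len = 20, seed = 23)
  set.seed(23)
  det <- oracle_detections(clip, jitter_sd = 2)
  ts <- track_clip(det, kf_config(m_per_px = 1.25 / 90), make_fusion_weights())
  expect_lte(length(unique(ts$id)), sum(sapply(det, function(d) nrow(d$boxes))))
})
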