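# Synthetic tank simulator: paired IR / RGB / depth clips of multi-fish
# scenes with complete ground truth (per-fish masks, tight boxes, persistent
# ids, metric depth, trajectories, analytic volumes).
#
# Fish bodies are ellipsoid-based tubes: elliptical cross-sections of
# semi-axes b(u) = b sqrt(1-u^2), c(u) = c sqrt(1-u^2) strung along a spine
# of half-length a. Tail bending displaces cross-sections laterally without
# altering them, so the volume stays exactly (4/3) pi a b c in every frame.

#' Tank scene configuration
#'
#' Defaults reproduce the acquisition geometry the package emulates: a
#' 1 m x 1 m x 0.5 m top-view tank, camera 1 m above the water surface,
#' 30 FPS, 90-frame (3 s) clips, 8-16 goldfish of 5-15 cm body length
#' swimming at 0.1-0.4 m/s, 1280 x 720 frames.
#'
#' @param tank_size c(width, length, depth) in meters.
#' @param camera_height camera height above the water surface, meters.
#' @param fps frames per second.
#' @param clip_len frames per clip.
#' @param n_fish number of fish (>= 1; the emulated protocol uses 8-16).
#' @param image_size c(H, W) pixels.
#' @param focal_px pinhole focal length in pixels (principal point at the
#'   image center).
#' @param seed RNG seed; identical configs give byte-identical clips.
#' @param speed_range swimming speed range, m/s, within [0, 1].
#' @param turn_rate_range turn-rate range, rad/s.
#' @param ripple list(A = amplitude px, f = cycles/px, phase = radians)
#'   applied to IR/RGB frames when A > 0. Defaults to A = 0 (still water;
#'   masks then align pixel-exactly with the frames). Use
#'   \code{\link{ripple_warp}} for the A = 5, f = 0.05 augmentation regime.
#' @param kappa Beer-Lambert attenuation coefficient, 1/m.
#' @param refractive_index water refractive index n_w.
#' @param noise_sd Gaussian sensor noise s.d. on IR/RGB intensities.
#' @param fish_len_range body length range in cm.
#' @param scenario "free" (independent swimmers) or "crossing" (two scripted
#'   head-on crossing events with brief occlusions, for tracking stress
#'   tests).
#' @return object of class \code{tank_config}.
#' @export
tank_config <- function(tank_size = c(1, 1, 0.5), camera_height = 1,
                        fps = 30, clip_len = 90, n_fish = 12,
                        image_size = c(720, 1280), focal_px = 700,
                        seed = 1, speed_range = c(0.1, 0.4),
                        turn_rate_range = c(-0.8, 0.8),
                        ripple = list(A = 0, f = 0.05, phase = 0),
                        kappa = 0.05, refractive_index = 1.33,
                        noise_sd = 0.02, fish_len_range = c(5, 15),
                        scenario = "free") {
  cfg <- list(tank_size = tank_size, camera_height = camera_height,
              fps = fps, clip_len = as.integer(clip_len),
              n_fish = as.integer(n_fish), image_size = as.integer(image_size),
              focal_px = focal_px, seed = seed, speed_range = speed_range,
              turn_rate_range = turn_rate_range, ripple = ripple,
              kappa = kappa, refractive_index = refractive_index,
              noise_sd = noise_sd, fish_len_range = fish_len_range,
              scenario = scenario)
  class(cfg) <- "tank_config"
  validate_tank_config(cfg)
  cfg
}

validate_tank_config <- function(cfg) {
  stopifnot(cfg$n_fish >= 1L, cfg$clip_len >= 2L,
            all(cfg$tank_size > 0), cfg$camera_height > 0, cfg$fps > 0,
            all(cfg$image_size > 0), cfg$focal_px > 0,
            all(cfg$speed_range >= 0), all(cfg$speed_range <= 1),
            cfg$kappa >= 0, cfg$refractive_index > 1, cfg$ripple$A >= 0)
  invisible(cfg)
}

#' Sinusoidal ripple warp
#'
#' Water-surface ripple distortion of a frame:
#' \code{out(x, y) = in(x + A sin(2 pi f y + phase), y + A sin(2 pi f x +
#' phase))} with bilinear sampling and edge clamping; pixel coordinates are
#' 0-based.
#'
#' @param image 2-D numeric matrix (rows = y).
#' @param A amplitude in pixels (>= 0; A = 0 returns the input unchanged).
#' @param f spatial frequency in cycles/pixel.
#' @param phase phase offset in radians.
#' @return warped matrix, same size.
#' @export
ripple_warp <- function(image, A, f, phase = 0) {
  stopifnot(is.matrix(image), length(image) > 0, A >= 0)
  if (A == 0) return(image)
  H <- nrow(image); W <- ncol(image)
  X <- matrix(rep(0:(W - 1L), each = H), H)   # x = column index, 0-based
  Y <- matrix(rep(0:(H - 1L), times = W), H)
  sx <- X + A * sin(2 * pi * f * Y + phase)
  sy <- Y + A * sin(2 * pi * f * X + phase)
  bilinear_sample(image, sx, sy)
}

# bilinear sampling at 0-based (sx, sy), clamped to the border
bilinear_sample <- function(image, sx, sy) {
  H <- nrow(image); W <- ncol(image)
  sx <- pmin(pmax(sx, 0), W - 1)
  sy <- pmin(pmax(sy, 0), H - 1)
  x0 <- pmin(floor(sx), W - 2); y0 <- pmin(floor(sy), H - 2)
  if (W == 1) x0 <- sx * 0
  if (H == 1) y0 <- sy * 0
  fx <- sx - x0; fy <- sy - y0
  i00 <- (y0 + 1) + H * x0
  i10 <- i00 + 1 * (H > 1)
  i01 <- i00 + H * (W > 1)
  i11 <- i01 + 1 * (H > 1)
  v <- (1 - fy) * (1 - fx) * image[i00] + fy * (1 - fx) * image[i10] +
    (1 - fy) * fx * image[i01] + fy * fx * image[i11]
  matrix(v, H, W)
}

#' Beer-Lambert color attenuation
#'
#' Multiplies every channel by \code{exp(-kappa * D)} pixelwise: the
#' simulator's ground-truth water absorption, and the physical target the
#' generator's water-adaptive loss assumes.
#'
#' @param rgb H x W x 3 array in [0, 1].
#' @param depth H x W metric depth map, meters, non-negative.
#' @param kappa attenuation coefficient, 1/m (>= 0).
#' @return attenuated H x W x 3 array.
#' @export
attenuate_color <- function(rgb, depth, kappa = 0.05) {
  stopifnot(length(dim(rgb)) == 3, kappa >= 0)
  if (any(depth < 0)) stop("negative depth")
  if (!all(dim(rgb)[1:2] == dim(depth))) stop("rgb/depth size mismatch")
  att <- exp(-kappa * depth)
  out <- rgb
  for (ch in 1:3) out[, , ch] <- rgb[, , ch] * att
  out
}

# per-pixel incidence angle of the camera ray, flat-surface pinhole model
incidence_map <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  X <- matrix(rep(0:(W - 1L), each = H), H)
  Y <- matrix(rep(0:(H - 1L), times = W), H)
  atan(sqrt((X - cx)^2 + (Y - cy)^2) / cfg$focal_px)
}

goldfish_palette <- function() {
  rbind(c(0.95, 0.55, 0.15),   # common orange
        c(0.90, 0.35, 0.10),   # comet red-orange
        c(0.92, 0.80, 0.55),   # pale fantail
        c(0.85, 0.20, 0.12))   # lionhead red
}

init_fish <- function(cfg) {
  n <- cfg$n_fish
  L <- stats::runif(n, cfg$fish_len_range[1], cfg$fish_len_range[2])  # cm
  a <- L / 2
  b <- a * stats::runif(n, 0.18, 0.25)       # half-width: slender body
  cc <- b * stats::runif(n, 1.0, 1.2)        # deeper than wide, goldfish-like
  marg <- pmax(0.06, 1.2 * a / 100)
  pal <- goldfish_palette()
  fish <- data.frame(
    a = a, b = b, c = cc,
    x = stats::runif(n, marg, cfg$tank_size[1] - marg),
    y = stats::runif(n, marg, cfg$tank_size[2] - marg),
    z = stats::runif(n, 0.15, 0.85) * cfg$tank_size[3],
    heading = stats::runif(n, 0, 2 * pi),
    speed = stats::runif(n, cfg$speed_range[1], cfg$speed_range[2]),
    turn_rate = stats::runif(n, cfg$turn_rate_range[1], cfg$turn_rate_range[2]),
    bend_freq = stats::runif(n, 1.5, 3.5),
    bend_phase = stats::runif(n, 0, 2 * pi),
    bend_amp = 0.10 * L / 100,               # meters
    emissivity = stats::runif(n, 0.55, 0.95),
    variety = sample.int(4L, n, replace = TRUE,
                         prob = c(0.3, 0.2, 0.3, 0.2)))
  fish$r <- pal[fish$variety, 1]; fish$g <- pal[fish$variety, 2]
  fish$bl <- pal[fish$variety, 3]
  fish$volume <- 4 / 3 * pi * fish$a * fish$b * fish$c   # cm^3, exact
  if (sum(4 * (fish$a / 100) * (fish$b / 100)) >
        0.6 * cfg$tank_size[1] * cfg$tank_size[2])
    stop("fish footprint exceeds 60% of the tank floor; reduce n_fish or sizes")
  if (cfg$scenario == "crossing" && n >= 4) {
    # two head-on crossing pairs meeting mid-clip at slightly different
    # depths, producing brief occlusions
    T_s <- cfg$clip_len / cfg$fps
    v <- 0.25
    reach <- v * T_s / 2
    set_pair <- function(f, i, j, yc, t_frac) {
      xc <- cfg$tank_size[1] / 2
      off <- reach * (2 * t_frac - 1)
      f$x[i] <- xc - reach + off; f$y[i] <- yc;        f$heading[i] <- 0
      f$x[j] <- xc + reach + off; f$y[j] <- yc + 0.004; f$heading[j] <- pi
      f$speed[c(i, j)] <- v; f$turn_rate[c(i, j)] <- 0
      f$z[i] <- 0.18 * cfg$tank_size[3]; f$z[j] <- 0.45 * cfg$tank_size[3]
      f
    }
    fish <- set_pair(fish, 1L, 2L, 0.35 * cfg$tank_size[2], 0.45)
    fish <- set_pair(fish, 3L, 4L, 0.65 * cfg$tank_size[2], 0.65)
  }
  fish
}

step_fish <- function(fish, cfg) {
  dt <- 1 / cfg$fps
  fish$heading <- fish$heading + fish$turn_rate * dt
  # smooth wall avoidance: steer inward when within reach of a wall, so
  # headings change continuously (fish slow-turn away rather than bounce)
  avoid <- 0.10
  marg0 <- pmax(0.05, 1.1 * fish$a / 100)
  px <- pmax(0, marg0 + avoid - fish$x) -
    pmax(0, fish$x - (cfg$tank_size[1] - marg0 - avoid))
  py <- pmax(0, marg0 + avoid - fish$y) -
    pmax(0, fish$y - (cfg$tank_size[2] - marg0 - avoid))
  steer <- px != 0 | py != 0
  if (any(steer)) {
    dx <- cos(fish$heading[steer]) + 25 * px[steer]
    dy <- sin(fish$heading[steer]) + 25 * py[steer]
    tgt <- atan2(dy, dx)
    dh <- atan2(sin(tgt - fish$heading[steer]), cos(tgt - fish$heading[steer]))
    fish$heading[steer] <- fish$heading[steer] +
      pmax(pmin(dh, 4 * dt), -4 * dt)   # bounded turn rate near walls
  }
  fish$x <- fish$x + fish$speed * cos(fish$heading) * dt
  fish$y <- fish$y + fish$speed * sin(fish$heading) * dt
  fish$bend_phase <- fish$bend_phase + 2 * pi * fish$bend_freq * dt
  marg <- pmax(0.05, 1.1 * fish$a / 100)
  # reflective walls
  lo <- fish$x < marg; hi <- fish$x > cfg$tank_size[1] - marg
  fish$heading[lo | hi] <- pi - fish$heading[lo | hi]
  fish$x[lo] <- marg[lo]; fish$x[hi] <- (cfg$tank_size[1] - marg)[hi]
  lo <- fish$y < marg; hi <- fish$y > cfg$tank_size[2] - marg
  fish$heading[lo | hi] <- -fish$heading[lo | hi]
  fish$y[lo] <- marg[lo]; fish$y[hi] <- (cfg$tank_size[2] - marg)[hi]
  fish
}

# rasterize one fish: returns integer pixel indices (column-major into H x W)
rasterize_fish <- function(f, cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  Z <- cfg$camera_height + f$z
  sc <- cfg$focal_px / Z                      # px per meter at fish depth
  n_st <- 25L
  u <- seq(-1, 1, length.out = n_st)
  a_m <- f$a / 100; b_m <- f$b / 100
  s <- u * a_m
  off <- f$bend_amp * ((1 - u) / 2)^2 * sin(f$bend_phase)  # tail at u = -1
  ch <- cos(f$heading); sh <- sin(f$heading)
  wx <- f$x + ch * s - sh * off
  wy <- f$y + sh * s + ch * off
  px <- cx + (wx - cfg$tank_size[1] / 2) * sc
  py <- cy + (wy - cfg$tank_size[2] / 2) * sc
  rb <- pmax(b_m * sqrt(pmax(0, 1 - u^2)) * sc, 0.45)
  ra <- pmax(1.3 * (a_m * sc) / (n_st - 1), rb * 0.8, 0.45)
  x0 <- max(0L, floor(min(px - ra))); x1 <- min(W - 1L, ceiling(max(px + ra)))
  y0 <- max(0L, floor(min(py - ra))); y1 <- min(H - 1L, ceiling(max(py + ra)))
  if (x1 < x0 || y1 < y0) return(integer(0))
  gx <- x0:x1; gy <- y0:y1
  GX <- matrix(rep(gx, each = length(gy)), length(gy))
  GY <- matrix(rep(gy, times = length(gx)), length(gy))
  inside <- matrix(FALSE, length(gy), length(gx))
  for (k in seq_len(n_st)) {
    dx <- GX - px[k]; dy <- GY - py[k]
    lon <- (dx * ch + dy * sh) / ra[k]
    lat <- (-dx * sh + dy * ch) / rb[k]
    inside <- inside | (lon * lon + lat * lat <= 1)
  }
  rc <- which(inside, arr.ind = TRUE)
  if (nrow(rc) == 0L) return(integer(0))
  (gy[rc[, 1]] + 1L) + H * (gx[rc[, 2]] + 1L - 1L)
}

box_from_idx <- function(idx, H) {
  if (length(idx) == 0L) return(c(NA, NA, 0, 0))
  r <- (idx - 1L) %% H       # 0-based row (y)
  cl <- (idx - 1L) %/% H     # 0-based col (x)
  c(min(cl), min(r), max(cl) - min(cl) + 1L, max(r) - min(r) + 1L)
}

#' Simulate a multi-fish tank clip
#'
#' Generates \code{clip_len} paired IR / RGB / depth frames with complete
#' ground truth. Fish follow constant-speed, constant-turn-rate kinematics
#' with reflective walls and volume-preserving tail undulation. The IR frame
#' is an emissivity-weighted projection over a noisy background; the RGB
#' frame applies per-fish goldfish coloring and Beer-Lambert attenuation;
#' the returned depth stack carries the refraction-distorted apparent depth
#' (what a sensor observing through the interface registers), while the
#' truth stack keeps the undistorted metric depth. Deterministic given the
#' config seed.
#'
#' @param config a \code{\link{tank_config}}.
#' @return list of class \code{aquavol_clip} with elements \code{ir}
#'   (list of H x W matrices in [0,1]), \code{rgb} (H x W x 3 arrays),
#'   \code{depth} (apparent-depth maps, meters), \code{truth} (masks as
#'   pixel-index vectors, boxes, ids, true depth maps, per-fish occluded
#'   fraction, trajectory table, analytic volumes in cm^3) and
#'   \code{config}.
#' @export
simulate_clip <- function(config) {
  validate_tank_config(config)
  set.seed(config$seed)
  H <- config$image_size[1]; W <- config$image_size[2]
  n <- config$n_fish; T_ <- config$clip_len
  fish <- init_fish(config)
  theta_px <- incidence_map(config)
  app_factor <- 1 / refract_depth_factor(theta_px, config$refractive_index)
  d_bottom <- config$camera_height + config$tank_size[3]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  sc_att <- NULL
  ir <- vector("list", T_); rgb <- vector("list", T_)
  depth <- vector("list", T_); depth_true <- vector("list", T_)
  masks <- vector("list", T_); boxes <- vector("list", T_)
  occluded <- matrix(0, T_, n)
  traj <- data.frame(frame = integer(), id = integer(), cx = numeric(),
                     cy = numeric(), vx = numeric(), vy = numeric(),
                     x_m = numeric(), y_m = numeric(), z_m = numeric())
  for (t in seq_len(T_)) {
    if (t > 1L) fish <- step_fish(fish, config)
    dt_map <- matrix(d_bottom, H, W)
    zbuf <- matrix(Inf, H, W)
    owner <- matrix(0L, H, W)
    fr_masks <- vector("list", n)
    ord <- order(fish$z)  # shallowest (closest to camera) wins ties naturally
    for (i in seq_len(n)) {
      fr_masks[[i]] <- rasterize_fish(fish[i, ], config)
    }
    for (i in seq_len(n)) {
      idx <- fr_masks[[i]]
      if (length(idx) == 0L) next
      zf <- config$camera_height + fish$z[i] - fish$c[i] / 100
      vis <- idx[zf < zbuf[idx]]
      zbuf[vis] <- zf
      owner[vis] <- i
      dt_map[vis] <- zf
      occluded[t, i] <- 1 - length(vis) / length(idx)
    }
    # occlusion flag refresh: a pixel may have been taken back by a closer
    # fish processed later; recompute visibility from the owner map
    for (i in seq_len(n)) {
      idx <- fr_masks[[i]]
      if (length(idx) > 0L)
        occluded[t, i] <- 1 - sum(owner[idx] == i) / length(idx)
    }
    ir_f <- matrix(0.12 + stats::rnorm(H * W, sd = config$noise_sd), H, W)
    rgb_f <- array(0, c(H, W, 3))
    base <- c(0.10, 0.32, 0.38)
    for (ch in 1:3)
      rgb_f[, , ch] <- base[ch] + stats::rnorm(H * W, sd = config$noise_sd)
    for (i in seq_len(n)) {
      vis <- fr_masks[[i]][owner[fr_masks[[i]]] == i]
      if (length(vis) == 0L) next
      ir_f[vis] <- fish$emissivity[i] + stats::rnorm(length(vis), sd = config$noise_sd)
      col <- c(fish$r[i], fish$g[i], fish$bl[i])
      for (ch in 1:3)
        rgb_f[vis + (ch - 1L) * H * W] <- col[ch] + stats::rnorm(length(vis), sd = config$noise_sd)
    }
    rgb_f <- attenuate_color(pmin(pmax(rgb_f, 0), 1), dt_map, config$kappa)
    ir_f <- pmin(pmax(ir_f, 0), 1)
    if (config$ripple$A > 0) {
      ir_f <- ripple_warp(ir_f, config$ripple$A, config$ripple$f, config$ripple$phase)
      for (ch in 1:3)
        rgb_f[, , ch] <- ripple_warp(rgb_f[, , ch], config$ripple$A,
                                     config$ripple$f, config$ripple$phase)
    }
    ir[[t]] <- ir_f
    rgb[[t]] <- rgb_f
    depth_true[[t]] <- dt_map
    depth[[t]] <- dt_map * app_factor
    masks[[t]] <- fr_masks
    boxes[[t]] <- t(vapply(fr_masks, box_from_idx, numeric(4), H = H))
    sc <- config$focal_px / (config$camera_height + fish$z)
    traj <- rbind(traj, data.frame(
      frame = t, id = seq_len(n),
      cx = cx + (fish$x - config$tank_size[1] / 2) * sc,
      cy = cy + (fish$y - config$tank_size[2] / 2) * sc,
      vx = fish$speed * cos(fish$heading) / config$fps * sc,
      vy = fish$speed * sin(fish$heading) / config$fps * sc,
      x_m = fish$x, y_m = fish$y, z_m = fish$z))
  }
  truth <- list(masks = masks, boxes = boxes, ids = seq_len(n),
                depth = depth_true, volumes = fish$volume,
                occluded = occluded, traj = traj,
                fish = fish[, c("a", "b", "c", "emissivity", "volume")])
  structure(list(ir = ir, rgb = rgb, depth = depth, truth = truth,
                 config = config),
            class = "aquavol_clip")
}

#' Ground-truth mask of one fish in one frame
#'
#' @param truth the \code{truth} element of a simulated clip.
#' @param t frame index (1-based).
#' @param i fish index.
#' @param image_size c(H, W); taken from the stored depth map if omitted.
#' @return logical H x W matrix.
#' @export
truth_mask <- function(truth, t, i, image_size = dim(truth$depth[[1]])) {
  m <- matrix(FALSE, image_size[1], image_size[2])
  m[truth$masks[[t]][[i]]] <- TRUE
  m
}
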