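# Volume regression: trajectory-depth transformer (TDT). Trajectory tokens
# (positions + velocities with sinusoidal positional encodings) cross-attend
# to a pooled masked-depth-region embedding; the pooled output regresses a
# preliminary volume, and a physics-based refraction correction scales it by
# the cubed depth factor at the fish's incidence angle.

#' TDT configuration
#'
#' @param layers transformer blocks (paper-scale default 4; use 2 for the
#'   tiny CPU model).
#' @param heads attention heads (default 8); \code{hidden} must be
#'   divisible by it, with per-head width \code{d_k = hidden / heads}.
#' @param hidden model width d (default 256).
#' @param pe add sinusoidal positional encodings (default TRUE).
#' @param lam_smooth temporal-smoothness weight lambda in the volume loss
#'   (default 0.1).
#' @param n_w water refractive index (default 1.33).
#' @param camera_height camera height above the surface, meters.
#' @param dr_size resampled DR crop side fed to the depth encoder.
#' @param dr_window fixed metric-preserving crop window side in pixels
#'   (the crop is always this window resampled to \code{dr_size}, so
#'   apparent size information survives the resize).
#' @return list of class \code{tdt_config}.
#' @export
tdt_config <- function(layers = 4L, heads = 8L, hidden = 256L, pe = TRUE,
                       lam_smooth = 0.1, n_w = 1.33, camera_height = 1,
                       dr_size = 48L, dr_window = 48L) {
  stopifnot(hidden %% heads == 0, lam_smooth >= 0, n_w > 1)
  structure(list(layers = as.integer(layers), heads = as.integer(heads),
                 hidden = as.integer(hidden), pe = pe,
                 lam_smooth = lam_smooth, n_w = n_w,
                 camera_height = camera_height, dr_size = as.integer(dr_size),
                 dr_window = as.integer(dr_window)),
            class = "tdt_config")
}

#' Tiny CPU-scale TDT configuration
#' @param ... overrides passed to \code{\link{tdt_config}}.
#' @export
tdt_config_tiny <- function(...) {
  tdt_config(layers = 2L, heads = 4L, hidden = 64L, ...)
}

#' Sinusoidal positional encoding table
#'
#' \code{PE[t, 2i-1] = sin(t / 10000^(2(i-1)/d))}, \code{PE[t, 2i] =
#' cos(...)}, t starting at 0, so row 1 is \code{(0, 1, 0, 1, ...)}.
#'
#' @param T_ sequence length.
#' @param d embedding width (even).
#' @return T x d matrix.
#' @export
sinusoidal_pe <- function(T_, d) {
  t_ <- 0:(T_ - 1)
  pe <- matrix(0, T_, d)
  for (i in seq_len(d %/% 2)) {
    f <- 1 / 10000^(2 * (i - 1) / d)
    pe[, 2 * i - 1] <- sin(t_ * f)
    pe[, 2 * i] <- cos(t_ * f)
  }
  pe
}

#' Build a TDT model
#'
#' @param cfg a \code{\link{tdt_config}}.
#' @param head_bias_init initial bias of the volume head before softplus,
#'   placing the untrained output near a plausible fish volume.
#' @return model list.
#' @export
make_tdt_model <- function(cfg = tdt_config_tiny(), head_bias_init = 25) {
  d <- cfg$hidden; h <- cfg$heads; dk <- d %/% h
  layer <- function() list(
    Wq = lapply(seq_len(h), function(i) init_dense_w(d, dk)),
    Wk = lapply(seq_len(h), function(i) init_dense_w(d, dk)),
    Wv = lapply(seq_len(h), function(i) init_dense_w(d, dk)),
    Wo = init_dense_w(d, d), bo = init_bias(d),
    ln1g = ag_param(rep(1, d)), ln1b = ag_param(rep(0, d)),
    ff1 = list(w = init_dense_w(d, 2 * d), b = init_bias(2 * d)),
    ff2 = list(w = init_dense_w(2 * d, d), b = init_bias(d)),
    ln2g = ag_param(rep(1, d)), ln2b = ag_param(rep(0, d)))
  list(cfg = cfg,
       traj_mlp = list(w1 = init_dense_w(4, d), b1 = init_bias(d),
                       w2 = init_dense_w(d, d), b2 = init_bias(d)),
       dr_cnn = list(
         c1 = list(w = init_conv_w(3, 1, 8), b = init_bias(8)),
         c2 = list(w = init_conv_w(3, 8, 16), b = init_bias(16)),
         c3 = list(w = init_conv_w(3, 16, 32), b = init_bias(32)),
         fc = list(w = init_dense_w(32, d), b = init_bias(d))),
       blocks = lapply(seq_len(cfg$layers), function(i) layer()),
       head = list(w1 = init_dense_w(d, 32), b1 = init_bias(32),
                   w2 = init_dense_w(32, 1),
                   b2 = ag_param(head_bias_init)))
}

#' Embed a trajectory as transformer tokens
#'
#' Positionwise two-layer perceptron lift of (position, velocity) rows to
#' width d, plus sinusoidal positional encodings.
#'
#' @param traj T x 4 matrix of (p_x, p_y, v_x, v_y), pixels and
#'   pixels/frame, T >= 2.
#' @param model TDT model.
#' @return autodiff node, T x d.
#' @export
embed_trajectory <- function(traj, model) {
  if (is.null(nrow(traj)) || nrow(traj) < 2L)
    stop("trajectory needs at least 2 frames (velocity is undefined at T = 1)")
  d <- model$cfg$hidden
  x <- cbind(traj[, 1:2] / 200, traj[, 3:4] / 2)  # scale to O(1)
  h <- ag_relu(ag_add_bias_cols(ag_matmul(ag_const(x), model$traj_mlp$w1),
                                model$traj_mlp$b1))
  e <- ag_add_bias_cols(ag_matmul(h, model$traj_mlp$w2), model$traj_mlp$b2)
  if (model$cfg$pe) e <- ag_add(e, ag_const(sinusoidal_pe(nrow(traj), d)))
  e
}

#' Embed a masked depth region
#'
#' Convolutional encoder with global pooling over the resampled DR crop;
#' depth values are fed in meters (no normalization, so depth magnitude
#' information is preserved).
#'
#' @param dr \code{dr_size} x \code{dr_size} matrix (masked depth crop).
#' @param model TDT model.
#' @return autodiff node, 1 x d.
#' @export
embed_depth_region <- function(dr, model) {
  if (all(dr == 0)) warning("all-zero depth region; embedding carries no depth information")
  cn <- model$dr_cnn
  x <- ag_const(array(dr, c(dim(dr), 1L)))
  h <- ag_relu(ag_conv2d(x, cn$c1$w, cn$c1$b)); h <- ag_avgpool2(h)
  h <- ag_relu(ag_conv2d(h, cn$c2$w, cn$c2$b)); h <- ag_avgpool2(h)
  h <- ag_relu(ag_conv2d(h, cn$c3$w, cn$c3$b))
  ag_add_bias_cols(ag_matmul(ag_global_meanpool(h), cn$fc$w), cn$fc$b)
}

#' TDT forward pass
#'
#' Per block: multi-head cross-attention with queries from the trajectory
#' tokens and keys/values from the depth embedding (softmax scaled by
#' sqrt(d_k), d_k = d/heads), residual + layer norm, then a feed-forward
#' sublayer with its own residual + layer norm. The mean-pooled token goes
#' through a perceptron head with a softplus, so the output volume is
#' non-negative.
#'
#' @param e_traj trajectory token node (T x d).
#' @param e_depth depth embedding node (1 x d or k x d for a multi-token
#'   variant).
#' @param model TDT model.
#' @return autodiff scalar node, preliminary volume in cm^3.
#' @export
tdt_forward <- function(e_traj, e_depth, model) {
  cfg <- model$cfg
  d <- cfg$hidden
  if (ncol(e_traj$value) != d || ncol(e_depth$value) != d)
    stop("embedding width mismatch")
  dk <- d %/% cfg$heads
  x <- e_traj
  for (blk in model$blocks) {
    heads <- vector("list", cfg$heads)
    for (i in seq_len(cfg$heads)) {
      Q <- ag_matmul(x, blk$Wq[[i]])
      K <- ag_matmul(e_depth, blk$Wk[[i]])
      V <- ag_matmul(e_depth, blk$Wv[[i]])
      A <- ag_softmax_rows(ag_scale(ag_matmul_t(Q, K), 1 / sqrt(dk)))
      heads[[i]] <- ag_matmul(A, V)
    }
    cat_ <- heads[[1]]
    if (cfg$heads > 1L)
      for (i in 2:cfg$heads) cat_ <- ag_concat_cols(cat_, heads[[i]])
    a <- ag_add_bias_cols(ag_matmul(cat_, blk$Wo), blk$bo)
    f <- ag_layernorm_rows(ag_add(a, x), blk$ln1g, blk$ln1b)
    ff <- ag_add_bias_cols(ag_matmul(ag_relu(
      ag_add_bias_cols(ag_matmul(f, blk$ff1$w), blk$ff1$b)), blk$ff2$w),
      blk$ff2$b)
    x <- ag_layernorm_rows(ag_add(f, ff), blk$ln2g, blk$ln2b)
  }
  pooled <- ag_mean_rows(x)
  hh <- ag_relu(ag_add_bias_cols(ag_matmul(pooled, model$head$w1),
                                 model$head$b1))
  out <- ag_add(ag_matmul(hh, model$head$w2), model$head$b2)
  ag_softplus(out)
}

#' Volume loss with temporal smoothness
#'
#' \code{mean |V - V_gt| + lam * mean (dV - dV_gt)^2} with d the forward
#' temporal difference.
#'
#' @param V,V_gt aligned volume series (length >= 2).
#' @param lam smoothness weight.
#' @return scalar.
#' @export
volume_loss <- function(V, V_gt, lam = 0.1) {
  if (length(V) != length(V_gt)) stop("series length mismatch")
  if (length(V) < 2L) stop("series too short")
  mean(abs(V - V_gt)) + lam * mean((diff(V) - diff(V_gt))^2)
}

#' Incidence angle of a tracked fish
#'
#' Geometric mode (default): the angle of the camera ray through the
#' fish's pixel, \code{theta = atan(r_px / focal_px)} with r_px the radial
#' distance from the principal point — the flat-surface incidence angle of
#' a downward-looking pinhole camera. A trajectory-tilt mode using the
#' velocity direction is available behind \code{mode}.
#'
#' @param traj_px T x 2 (or T x 4) matrix of pixel centroids.
#' @param image_size c(H, W).
#' @param focal_px pinhole focal length in pixels.
#' @param mode "geometric" or "tilt".
#' @return numeric vector of theta per frame, radians.
#' @export
estimate_incidence <- function(traj_px, image_size, focal_px,
                               mode = "geometric") {
  if (is.null(focal_px) || is.null(image_size)) stop("missing calibration")
  cx <- (image_size[2] - 1) / 2; cy <- (image_size[1] - 1) / 2
  r <- sqrt((traj_px[, 1] - cx)^2 + (traj_px[, 2] - cy)^2)
  if (mode == "geometric") return(atan(r / focal_px))
  # trajectory tilt: angle between the velocity direction and the radial
  # direction modulates the geometric angle (small effect in top view)
  th <- atan(r / focal_px)
  if (ncol(traj_px) >= 4) {
    sp <- sqrt(traj_px[, 3]^2 + traj_px[, 4]^2)
    th <- th * (1 + 0.1 * sp / (1 + sp))
  }
  th
}

#' Fixed-window DR crop around a centroid
#'
#' The crop window has constant pixel size (\code{dr_window}) and is
#' resampled by a constant factor to \code{dr_size}, so the apparent area
#' of the fish is preserved through the resize; out-of-frame regions are
#' zero.
#'
#' @param DR full-frame masked-depth matrix.
#' @param cx,cy centroid, pixels (0-based).
#' @param cfg a \code{\link{tdt_config}}.
#' @return \code{dr_size} x \code{dr_size} matrix.
#' @export
extract_dr_crop <- function(DR, cx, cy, cfg) {
  H <- nrow(DR); W <- ncol(DR)
  win <- cfg$dr_window; out <- cfg$dr_size
  half <- win / 2
  # integer source grid with zero padding outside the frame; when the
  # window equals the output size the copy is exact (area-preserving)
  if (win == out) {
    xs <- (round(cx) - half):(round(cx) + half - 1L)
    ys <- (round(cy) - half):(round(cy) + half - 1L)
  } else {
    xs <- round(cx - half + (seq_len(out) - 0.5) * win / out)
    ys <- round(cy - half + (seq_len(out) - 0.5) * win / out)
  }
  m <- matrix(0, out, out)
  okx <- xs >= 0 & xs <= W - 1; oky <- ys >= 0 & ys <= H - 1
  m[oky, okx] <- DR[ys[oky] + 1L, xs[okx] + 1L]
  m
}

#' Predict the volume series of one track
#'
#' One pooled depth token per clip: the DR crop is taken at the frame
#' where the fish mask is largest (least occluded), the trajectory
#' supplies the tokens, and the TDT emits one preliminary volume that is
#' refraction-corrected per frame.
#'
#' @param traj T x 4 trajectory (pixel centers + velocities).
#' @param dr_crop DR crop from \code{\link{extract_dr_crop}}.
#' @param theta incidence angle per frame (radians).
#' @param model TDT model.
#' @return data frame \code{frame, theta_deg, v_pre_cm3, v_cm3}.
#' @export
tdt_predict_series <- function(traj, dr_crop, theta, model) {
  ag_tape_reset()
  e_t <- embed_trajectory(traj, model)
  e_d <- embed_depth_region(dr_crop, model)
  v_pre <- as.numeric(tdt_forward(e_t, e_d, model)$value)
  ag_tape_reset()
  corr <- refraction_correct(v_pre, theta, model$cfg$n_w)
  data.frame(frame = seq_len(nrow(traj)), theta_deg = theta * 180 / pi,
             v_pre_cm3 = rep(as.numeric(v_pre), nrow(traj)), v_cm3 = corr$V)
}

#' Train the TDT on (trajectory, DR, volume) samples
#'
#' @param samples list of samples, each \code{list(traj, dr, v_gt)}.
#' @param model TDT model.
#' @param epochs passes over the samples.
#' @param lr initial learning rate.
#' @param lr_decay per-epoch multiplicative decay.
#' @return list with updated \code{model} and per-epoch mean absolute
#'   error \code{trace}.
#' @export
train_tdt <- function(samples, model, epochs = 35, lr = 1.5e-3,
                      lr_decay = 0.93) {
  params <- ag_collect_params(model)
  st <- adam_init(params)
  trace <- numeric(epochs)
  n <- length(samples)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    errs <- numeric(n)
    for (ii in seq_len(n)) {
      s <- samples[[ord[ii]]]
      ag_tape_reset()
      ag_zero_grad(params)
      v <- tdt_forward(embed_trajectory(s$traj, model),
                       embed_depth_region(s$dr, model), model)
      l <- ag_abs(ag_sub(v, ag_const(s$v_gt)))
      ag_backward(l)
      st <- adam_step(params, st, lr = lr)
      errs[ii] <- l$value
    }
    lr <- lr * lr_decay
    trace[ep] <- mean(errs)
  }
  ag_tape_reset()
  list(model = model, trace = trace)
}

#' Build TDT training samples from simulated clips (oracle mode)
#'
#' Per fish per clip: the ground-truth trajectory, a DR crop built from
#' the true mask and the clip's (apparent or true) depth at the frame of
#' maximal visibility, and the analytic volume.
#'
#' @param clip simulated clip.
#' @param cfg a \code{\link{tdt_config}}.
#' @param use_apparent_depth build DR from the refraction-distorted depth
#'   stack (TRUE) or the true depth (FALSE).
#' @return list of samples \code{list(traj, dr, v_gt, theta)}.
#' @export
tdt_samples_from_clip <- function(clip, cfg, use_apparent_depth = FALSE) {
  T_ <- length(clip$ir)
  n <- length(clip$truth$ids)
  H <- nrow(clip$ir[[1]]); W <- ncol(clip$ir[[1]])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- clip$truth$traj[clip$truth$traj$id == i, ]
    traj <- as.matrix(tr[, c("cx", "cy", "vx", "vy")])
    sizes <- vapply(seq_len(T_), function(t) length(clip$truth$masks[[t]][[i]]),
                    numeric(1))
    vis <- (1 - clip$truth$occluded[, i]) * sizes
    tbest <- which.max(vis)
    dsrc <- if (use_apparent_depth) clip$depth[[tbest]] else clip$truth$depth[[tbest]]
    DR <- matrix(0, H, W)
    idx <- clip$truth$masks[[tbest]][[i]]
    DR[idx] <- dsrc[idx]
    dr <- extract_dr_crop(DR, traj[tbest, 1], traj[tbest, 2], cfg)
    theta <- estimate_incidence(traj, c(H, W), clip$config$focal_px)
    out[[i]] <- list(traj = traj, dr = dr, v_gt = clip$truth$volumes[i],
                     theta = theta)
  }
  out
}
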