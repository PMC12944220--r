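# IR-to-depth: encoder-decoder with contour-guided attention, trained with
# an L1 data term plus a gradient-alignment smoothing term that ties depth
# gradients to IR intensity gradients.

#' Depth network configuration
#'
#' @param encoder_channels widths per scale of the U-Net-style encoder;
#'   the default tiny net (8/16/32) runs comfortably on one CPU.
#' @param n_scales number of scales (>= 2); must match
#'   \code{encoder_channels}.
#' @param alpha gradient-alignment weight tying depth gradients to IR
#'   gradients (default 0.1).
#' @param lam smoothing-term weight lambda (default 0.5).
#' @param depth_range metric output range in meters (default 0-5); the
#'   network's sigmoid output is affinely mapped into it, so predictions
#'   are in range by construction.
#' @param literal_sum if TRUE the smoothing term is the un-normalized sum
#'   over pixels as printed; the default divides by the pixel count so the
#'   weight is resolution-invariant.
#' @return list of class \code{depth_net_config}.
#' @export
depth_net_config <- function(encoder_channels = c(8, 16, 32),
                             n_scales = length(encoder_channels),
                             alpha = 0.1, lam = 0.5,
                             depth_range = c(0, 5), literal_sum = FALSE) {
  stopifnot(n_scales >= 2, alpha >= 0, lam >= 0,
            length(encoder_channels) == n_scales)
  structure(list(encoder_channels = encoder_channels, n_scales = n_scales,
                 alpha = alpha, lam = lam, depth_range = depth_range,
                 literal_sum = literal_sum),
            class = "depth_net_config")
}

sobel_wm <- function() {
  gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3)   # d/dx (columns)
  gy <- t(gx)
  w4 <- array(0, c(3, 3, 1, 2))
  w4[, , 1, 1] <- gx
  w4[, , 1, 2] <- gy
  conv_weight_from_array(w4)
}

#' Build a depth network
#'
#' Tiny U-Net-style encoder-decoder with a Sobel-seeded contour branch and
#' per-scale contour attention gates. Parameters are drawn from the
#' current RNG stream.
#'
#' @param cfg a \code{\link{depth_net_config}}.
#' @return model list (parameters + config).
#' @export
make_depth_model <- function(cfg = depth_net_config()) {
  ch <- cfg$encoder_channels
  m <- list(cfg = cfg)
  # contour branch: Sobel magnitude -> 3x3 convs 16 -> 32 -> 1
  m$contour <- list(
    w1 = init_conv_w(3, 1, 16), b1 = init_bias(16),
    w2 = init_conv_w(3, 16, 32), b2 = init_bias(32),
    w3 = init_conv_w(3, 32, 1), b3 = init_bias(1))
  # per-scale 1x1 attention gates on the contour prior
  m$att <- lapply(seq_len(cfg$n_scales), function(s)
    list(w = init_conv_w(1, 1, 1), b = init_bias(1)))
  # encoder (input replicated to 3 channels)
  m$enc <- list(
    list(w = init_conv_w(3, 3, ch[1]), b = init_bias(ch[1])),
    list(w = init_conv_w(3, ch[1], ch[2]), b = init_bias(ch[2])),
    list(w = init_conv_w(3, ch[2], ch[3]), b = init_bias(ch[3])))
  # decoder with skip connections
  m$dec <- list(
    list(w = init_conv_w(3, ch[3] + ch[2], ch[2]), b = init_bias(ch[2])),
    list(w = init_conv_w(3, ch[2] + ch[1], ch[1]), b = init_bias(ch[1])))
  m$out <- list(w = init_conv_w(3, ch[1], 1), b = init_bias(1))
  m$sobel <- sobel_wm()
  m
}

#' Extract a probabilistic contour prior from an IR frame
#'
#' Sobel gradient magnitude refined by a three-layer convolutional head
#' (3x3 kernels, widths 16-32-1) with a final logistic squashing to [0, 1].
#'
#' @param ir H x W matrix in [0, 1] (or an autodiff node).
#' @param model from \code{\link{make_depth_model}} (its contour branch is
#'   used).
#' @return autodiff node holding the H x W x 1 contour probability map;
#'   take \code{$value} for the numeric map.
#' @export
extract_contour_prior <- function(ir, model) {
  irn <- if (is_ag(ir)) ir else ag_const(ir)
  v <- irn$value
  if (is.matrix(v)) {
    irn <- ag_node(array(v, c(dim(v), 1L)), track = irn$track,
                   backfn = if (irn$track) function(nd) ag_accum(irn, nd$grad[, , 1]))
  } else if (length(dim(v)) != 3L) stop("ir must be a 2-D frame")
  sob <- ag_conv2d(irn, ag_const(model$sobel), ag_const(c(0, 0)), k = 3)
  g2 <- sob$value^2
  magn <- ag_node(array(sqrt(g2[, , 1] + g2[, , 2] + 1e-12),
                        c(dim(g2)[1], dim(g2)[2], 1L)),
                  backfn = local({
                    s <- sob
                    function(nd) {
                      m <- sqrt(g2[, , 1] + g2[, , 2] + 1e-12)
                      gr <- array(0, dim(g2))
                      gr[, , 1] <- nd$grad[, , 1] * s$value[, , 1] / m
                      gr[, , 2] <- nd$grad[, , 1] * s$value[, , 2] / m
                      ag_accum(s, gr)
                    }
                  }))
  h <- ag_relu(ag_conv2d(magn, model$contour$w1, model$contour$b1))
  h <- ag_relu(ag_conv2d(h, model$contour$w2, model$contour$b2))
  ag_sigmoid(ag_conv2d(h, model$contour$w3, model$contour$b3))
}

#' Apply contour-guided attention to per-scale features
#'
#' \code{A_s = sigmoid(conv1x1(resize_s(C)))}; \code{F'_s = F_s * A_s +
#' F_s}. Shape-preserving at every scale; with non-negative features the
#' output lies elementwise in \code{[F, 2F]}.
#'
#' @param features list of per-scale feature nodes (scale s downsampled by
#'   \code{2^(s-1)}).
#' @param prior contour prior node (full resolution, H x W x 1).
#' @param model depth model (its \code{att} gates are used).
#' @return list of modulated feature nodes.
#' @export
apply_contour_attention <- function(features, prior, model) {
  out <- vector("list", length(features))
  cs <- prior
  for (s in seq_along(features)) {
    fd <- dim(features[[s]]$value)
    if (!all(dim(cs$value)[1:2] == fd[1:2]))
      stop("contour prior does not resize to scale ", s)
    a <- ag_sigmoid(ag_conv2d(cs, model$att[[s]]$w, model$att[[s]]$b,
                              k = 1, pad = 0))
    av <- a$value
    gate <- ag_node(features[[s]]$value * as.vector(av),
                    backfn = local({
                      f <- features[[s]]; aa <- a; avl <- av
                      function(nd) {
                        ag_accum(f, nd$grad * as.vector(avl))
                        ag_accum(aa, array(rowSums(matrix(nd$grad * f$value,
                                                          length(avl))),
                                           dim(avl)))
                      }
                    }))
    out[[s]] <- ag_add(gate, features[[s]])
    if (s < length(features)) cs <- ag_avgpool2(cs)
  }
  out
}

depth_forward <- function(ir, model, with_attention = TRUE) {
  cfg <- model$cfg
  irn <- if (is_ag(ir)) ir else ag_const(ir)
  v <- irn$value
  x3 <- ag_node(array(rep(as.vector(v), 3L), c(dim(v), 3L)),
                track = irn$track,
                backfn = if (irn$track) function(nd)
                  ag_accum(irn, nd$grad[, , 1] + nd$grad[, , 2] + nd$grad[, , 3]))
  e1 <- ag_relu(ag_conv2d(x3, model$enc[[1]]$w, model$enc[[1]]$b))
  e2 <- ag_relu(ag_conv2d(ag_avgpool2(e1), model$enc[[2]]$w, model$enc[[2]]$b))
  e3 <- ag_relu(ag_conv2d(ag_avgpool2(e2), model$enc[[3]]$w, model$enc[[3]]$b))
  if (with_attention) {
    prior <- extract_contour_prior(irn, model)
    mod <- apply_contour_attention(list(e1, e2, e3), prior, model)
    e1 <- mod[[1]]; e2 <- mod[[2]]; e3 <- mod[[3]]
  }
  d2 <- ag_relu(ag_conv2d(ag_concat_chan(ag_upsample2(e3), e2),
                          model$dec[[1]]$w, model$dec[[1]]$b))
  d1 <- ag_relu(ag_conv2d(ag_concat_chan(ag_upsample2(d2), e1),
                          model$dec[[2]]$w, model$dec[[2]]$b))
  o <- ag_sigmoid(ag_conv2d(d1, model$out$w, model$out$b))
  lo <- cfg$depth_range[1]; hi <- cfg$depth_range[2]
  dep <- ag_scale(o, hi - lo)
  if (lo != 0) dep <- ag_add(dep, ag_const(array(lo, dim(o$value))))
  # drop the channel axis to an H x W matrix node
  ag_node(dep$value[, , 1], track = TRUE,
          backfn = local({ dd <- dep
            function(nd) ag_accum(dd, array(nd$grad, c(dim(nd$grad), 1L)))
          }))
}

#' Predict a metric depth map from an IR frame
#'
#' @param ir H x W matrix in [0, 1].
#' @param model from \code{\link{make_depth_model}} (trained or not; the
#'   sigmoid head keeps outputs inside the configured metric range either
#'   way).
#' @return H x W depth matrix in meters.
#' @export
predict_depth <- function(ir, model) {
  ag_tape_reset()
  out <- depth_forward(ir, model)$value
  ag_tape_reset()
  out
}

#' Depth loss: L1 data term plus gradient-alignment smoothing
#'
#' \code{data = mean |D - D_gt|}; \code{smooth = lam * sum[(grad_x D -
#' alpha grad_x I)^2 + (grad_y D - alpha grad_y I)^2]} with forward
#' differences (last column/row excluded), divided by the pixel count
#' unless \code{cfg$literal_sum}; \code{total = data + smooth}.
#'
#' @param D predicted depth (matrix or node).
#' @param D_gt ground-truth depth matrix.
#' @param ir IR frame matrix.
#' @param cfg a \code{\link{depth_net_config}}.
#' @return list with numeric \code{total}, \code{data}, \code{smooth} and
#'   the autodiff \code{node} of the total (for training).
#' @export
depth_loss <- function(D, D_gt, ir, cfg = depth_net_config()) {
  Dn <- if (is_ag(D)) D else ag_const(D)
  if (!all(dim(Dn$value) == dim(D_gt)) || !all(dim(D_gt) == dim(ir)))
    stop("size mismatch between D, D_gt and ir")
  H <- nrow(D_gt); W <- ncol(D_gt)
  data_t <- ag_mean(ag_abs(ag_sub(Dn, ag_const(D_gt))))
  dxI <- ir[, 2:W, drop = FALSE] - ir[, 1:(W - 1), drop = FALSE]
  dyI <- ir[2:H, , drop = FALSE] - ir[1:(H - 1), , drop = FALSE]
  dxD <- ag_sub(ag_mat_slice(Dn, 1:H, 2:W), ag_mat_slice(Dn, 1:H, 1:(W - 1)))
  dyD <- ag_sub(ag_mat_slice(Dn, 2:H, 1:W), ag_mat_slice(Dn, 1:(H - 1), 1:W))
  sx <- ag_sum(ag_square(ag_sub(dxD, ag_const(cfg$alpha * dxI))))
  sy <- ag_sum(ag_square(ag_sub(dyD, ag_const(cfg$alpha * dyI))))
  smooth_t <- ag_scale(ag_add(sx, sy),
                       if (cfg$literal_sum) cfg$lam else cfg$lam / (H * W))
  total <- ag_add(data_t, smooth_t)
  list(total = total$value, data = data_t$value, smooth = smooth_t$value,
       node = total)
}

#' Train the depth network
#'
#' Adam on the combined depth loss over (IR, depth) frame pairs, one frame
#' per step, cycling deterministically.
#'
#' @param frames list of IR matrices.
#' @param depths list of matching depth matrices.
#' @param model from \code{\link{make_depth_model}}.
#' @param steps optimizer steps.
#' @param lr learning rate.
#' @return list with the updated \code{model} and the per-step \code{loss}
#'   trace.
#' @export
train_depth <- function(frames, depths, model, steps = 200, lr = 1e-2) {
  params <- ag_collect_params(model)
  st <- adam_init(params)
  trace <- numeric(steps)
  n <- length(frames)
  for (k in seq_len(steps)) {
    i <- (k - 1L) %% n + 1L
    ag_tape_reset()
    ag_zero_grad(params)
    D <- depth_forward(frames[[i]], model)
    l <- depth_loss(D, depths[[i]], frames[[i]], model$cfg)
    ag_backward(l$node)
    st <- adam_step(params, st, lr = lr)
    trace[k] <- l$total
  }
  ag_tape_reset()
  list(model = model, loss = trace)
}
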