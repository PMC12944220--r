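# Instance segmentation: depth-guided ROI fusion, a small mask head
# (4 convolutions + deconvolution), a deterministic medial-axis keypoint
# operator, and the deformation-adaptive loss (pixel cross-entropy plus a
# skeleton topology penalty).

#' Segmentation model configuration
#'
#' @param c_feat channels of the per-stream feature stems.
#' @param roi_size ROI-aligned patch resolution (default 14).
#' @param mu skeleton-prior regularization weight (default 0.2).
#' @param K spine keypoints (default 5).
#' @param ce_mean use per-pixel mean cross-entropy instead of the printed
#'   sum.
#' @return list of class \code{seg_config}.
#' @export
seg_config <- function(c_feat = 8L, roi_size = 14L, mu = 0.2, K = 5L,
                       ce_mean = FALSE) {
  structure(list(c_feat = as.integer(c_feat), roi_size = as.integer(roi_size),
                 mu = mu, K = as.integer(K), ce_mean = ce_mean),
            class = "seg_config")
}

#' Build the segmentation model
#'
#' Two-convolution stems for the IR and depth streams, a positionwise
#' two-layer perceptron fusing the ROI-aligned features with a residual
#' back onto the IR stream, and a mask head of four 3x3 convolutions plus
#' one deconvolution (2x upsample + convolution) ending in a 1x1 sigmoid.
#'
#' @param cfg a \code{\link{seg_config}}.
#' @return model list.
#' @export
make_seg_model <- function(cfg = seg_config()) {
  cf <- cfg$c_feat
  list(cfg = cfg,
       ir_stem = list(
         c1 = list(w = init_conv_w(3, 1, cf), b = init_bias(cf)),
         c2 = list(w = init_conv_w(3, cf, cf), b = init_bias(cf))),
       d_stem = list(
         c1 = list(w = init_conv_w(3, 1, cf), b = init_bias(cf)),
         c2 = list(w = init_conv_w(3, cf, cf), b = init_bias(cf))),
       fuse = list(
         w1 = init_conv_w(1, 2 * cf, 2 * cf), b1 = init_bias(2 * cf),
         w2 = init_conv_w(1, 2 * cf, cf), b2 = init_bias(cf)),
       head = list(
         c1 = list(w = init_conv_w(3, cf, cf), b = init_bias(cf)),
         c2 = list(w = init_conv_w(3, cf, cf), b = init_bias(cf)),
         c3 = list(w = init_conv_w(3, cf, cf), b = init_bias(cf)),
         c4 = list(w = init_conv_w(3, cf, cf), b = init_bias(cf)),
         up = list(w = init_conv_w(3, cf, cf), b = init_bias(cf)),
         out = list(w = init_conv_w(1, cf, 1), b = init_bias(1))))
}

stem_forward <- function(x, stem) {
  h <- ag_relu(ag_conv2d(ag_const(array(x, c(dim(x), 1L))), stem$c1$w, stem$c1$b))
  ag_relu(ag_conv2d(h, stem$c2$w, stem$c2$b))
}

#' Fuse IR and depth ROI features
#'
#' \code{Z = concat(ROI_IR, ROI_D)} channelwise; \code{Y} is a two-layer
#' perceptron applied positionwise (1x1 convolutions); the output is the
#' residual \code{Y + ROI_IR}, so its channel count equals the IR
#' stream's.
#'
#' @param roi_ir,roi_d ROI feature nodes of equal spatial size.
#' @param model segmentation model (its \code{fuse} block is used).
#' @return fused ROI feature node.
#' @export
fuse_roi <- function(roi_ir, roi_d, model) {
  if (!all(dim(roi_ir$value)[1:2] == dim(roi_d$value)[1:2]))
    stop("ROI resolution mismatch")
  z <- ag_concat_chan(roi_ir, roi_d)
  y <- ag_relu(ag_conv2d(z, model$fuse$w1, model$fuse$b1, k = 1, pad = 0))
  y <- ag_conv2d(y, model$fuse$w2, model$fuse$b2, k = 1, pad = 0)
  ag_add(y, roi_ir)
}

mask_head_forward <- function(roi, model) {
  h <- ag_relu(ag_conv2d(roi, model$head$c1$w, model$head$c1$b))
  h <- ag_relu(ag_conv2d(h, model$head$c2$w, model$head$c2$b))
  h <- ag_relu(ag_conv2d(h, model$head$c3$w, model$head$c3$b))
  h <- ag_relu(ag_conv2d(h, model$head$c4$w, model$head$c4$b))
  h <- ag_relu(ag_conv2d(ag_upsample2(h), model$head$up$w, model$head$up$b))
  ag_sigmoid(ag_conv2d(h, model$head$out$w, model$head$out$b, k = 1, pad = 0))
}

# soft 28 x 28 mask node for one box (shared by training and inference)
seg_instance_forward <- function(feat_ir, feat_d, box, model) {
  rs <- model$cfg$roi_size
  roi_ir <- ag_roi_resize(feat_ir, box, rs, rs)
  roi_d <- ag_roi_resize(feat_d, box, rs, rs)
  mask_head_forward(fuse_roi(roi_ir, roi_d, model), model)
}

#' Segment one frame into per-instance soft masks and depth regions
#'
#' Per detection box: ROI features from the IR and depth streams, fusion,
#' mask head, and bilinear paste of the soft mask back into frame
#' coordinates. \code{DR = M * D} where the binarized mask (threshold 0.5)
#' is set, 0 elsewhere.
#'
#' @param ir IR frame matrix.
#' @param D depth matrix (meters).
#' @param model from \code{\link{make_seg_model}}.
#' @param boxes n x 4 matrix of [x, y, w, h] detections (may be empty).
#' @param ids instance ids (default seq).
#' @return list of class \code{instance_mask_set}: \code{masks} (full-frame
#'   soft matrices), \code{boxes}, \code{ids}, \code{DR} (masked depth
#'   matrices).
#' @export
segment_frame <- function(ir, D, model, boxes,
                          ids = seq_len(if (is.null(nrow(boxes))) 0L else nrow(boxes))) {
  H <- nrow(ir); W <- ncol(ir)
  n <- if (is.null(nrow(boxes))) 0L else nrow(boxes)
  out <- list(masks = list(), boxes = boxes, ids = ids, DR = list())
  class(out) <- "instance_mask_set"
  if (n == 0L) return(out)
  valid <- apply(boxes, 1L, function(b) all(is.finite(b)) && b[3] > 0 && b[4] > 0)
  if (any(boxes[valid, 1] < -boxes[valid, 3] | boxes[valid, 2] < -boxes[valid, 4] |
            boxes[valid, 1] > W | boxes[valid, 2] > H))
    stop("box outside frame bounds")
  ag_tape_reset()
  fi <- stem_forward(ir, model$ir_stem)
  fd <- stem_forward(D / max(D), model$d_stem)
  for (k in seq_len(n)) {
    if (!valid[k]) {
      out$masks[[k]] <- matrix(0, H, W)
      out$DR[[k]] <- matrix(0, H, W)
      next
    }
    m28 <- seg_instance_forward(fi, fd, boxes[k, ], model)$value[, , 1]
    full <- paste_mask(m28, boxes[k, ], H, W)
    dr <- ifelse(full >= 0.5, full * D, 0)
    out$masks[[k]] <- full
    out$DR[[k]] <- dr
  }
  ag_tape_reset()
  out
}

# bilinear resample of the 28 x 28 soft mask into the box footprint
paste_mask <- function(m, box, H, W) {
  full <- matrix(0, H, W)
  x0 <- max(0L, floor(box[1])); x1 <- min(W - 1L, ceiling(box[1] + box[3]))
  y0 <- max(0L, floor(box[2])); y1 <- min(H - 1L, ceiling(box[2] + box[4]))
  if (x1 < x0 || y1 < y0) return(full)
  xs <- x0:x1; ys <- y0:y1
  mh <- nrow(m); mw <- ncol(m)
  u <- (xs - box[1]) / box[3] * mw + 0.5   # continuous mask coords, 1-based
  v <- (ys - box[2]) / box[4] * mh + 0.5
  cu <- pmin(pmax(u, 1), mw); cv <- pmin(pmax(v, 1), mh)
  j0 <- pmin(floor(cu), mw - 1); i0 <- pmin(floor(cv), mh - 1)
  fx <- cu - j0; fy <- cv - i0
  inside_x <- xs >= box[1] & xs <= box[1] + box[3]
  inside_y <- ys >= box[2] & ys <= box[2] + box[4]
  blk <- outer((1 - fy), (1 - fx)) * m[cbind(rep(i0, length(j0)), rep(j0, each = length(i0)))] +
    outer(fy, (1 - fx)) * m[cbind(rep(i0 + 1, length(j0)), rep(j0, each = length(i0)))] +
    outer((1 - fy), fx) * m[cbind(rep(i0, length(j0)), rep(j0 + 1, each = length(i0)))] +
    outer(fy, fx) * m[cbind(rep(i0 + 1, length(j0)), rep(j0 + 1, each = length(i0)))]
  blk <- blk * outer(inside_y, inside_x)
  full[ys + 1L, xs + 1L] <- blk
  full
}

# ---- medial-axis keypoints ----

label_largest_component <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  best <- NULL; best_n <- 0L
  idx_all <- which(mask)
  for (s in idx_all) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s; lab[s] <- cur; comp <- s
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1L) %% H + 1L; cl <- (p - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
          q <- rr + H * (cc - 1L)
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q); comp <- c(comp, q) }
        }
      }
    }
    if (length(comp) > best_n) { best_n <- length(comp); best <- comp }
  }
  out <- matrix(FALSE, H, W)
  out[best] <- TRUE
  out
}

# Zhang-Suen thinning to a 1-px-wide skeleton
thin_mask <- function(mask) {
  m <- mask * 1L
  H <- nrow(m); W <- ncol(m)
  if (H < 3 || W < 3) return(mask)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad
      r <- 2:(H + 1); cl <- 2:(W + 1)
      P2 <- p[r - 1, cl];     P3 <- p[r - 1, cl + 1]
      P4 <- p[r, cl + 1];     P5 <- p[r + 1, cl + 1]
      P6 <- p[r + 1, cl];     P7 <- p[r + 1, cl - 1]
      P8 <- p[r, cl - 1];     P9 <- p[r - 1, cl - 1]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (step == 1) {
        cond <- p[r, cl] == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- p[r, cl] == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) {
        changed <- TRUE
        sub <- pad[r, cl]; sub[cond] <- 0L; pad[r, cl] <- sub
      }
    }
    if (!changed) break
  }
  pad[2:(H + 1), 2:(W + 1)] == 1L
}

# Dijkstra over skeleton pixels (8-neighborhood, diagonal weight sqrt(2))
skel_farthest <- function(pts, from) {
  n <- nrow(pts)
  key <- paste(pts[, 1], pts[, 2])
  lut <- new.env(parent = emptyenv())
  for (i in seq_len(n)) assign(key[i], i, envir = lut)
  dist <- rep(Inf, n); dist[from] <- 0
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      k2 <- paste(pts[u, 1] + dr, pts[u, 2] + dc)
      v <- if (exists(k2, envir = lut, inherits = FALSE)) get(k2, envir = lut) else NA
      if (!is.na(v) && !done[v]) {
        w <- if (dr != 0 && dc != 0) sqrt(2) else 1
        if (dist[u] + w < dist[v]) { dist[v] <- dist[u] + w; prev[v] <- u }
      }
    }
  }
  list(dist = dist, prev = prev)
}

#' Spine keypoints from a binary mask
#'
#' Medial-axis skeleton (morphological thinning of the largest connected
#' component), longest geodesic path across it, and K points interpolated
#' at equal arc-length fractions. The head end is the path endpoint with
#' the larger projection on the mask's principal axis (sign fixed toward
#' positive x, then positive y), making the operator deterministic and
#' translation-equivariant.
#'
#' @param mask logical or 0/1 matrix with at least one foreground pixel.
#' @param K number of keypoints (default 5).
#' @return list of class \code{keypoint_set}: \code{points}, a K x 2
#'   matrix of (x, y) 0-based pixel coordinates ordered head to tail, and
#'   \code{theta}, an opaque deformation descriptor slot (NULL).
#' @export
skeleton_keypoints <- function(mask, K = 5L) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  if (sum(mask) == 1L) {
    rc <- which(mask, arr.ind = TRUE)
    pts <- matrix(rep(c(rc[1, 2] - 1, rc[1, 1] - 1), each = K), K, 2)
    colnames(pts) <- c("x", "y")
    return(structure(list(points = pts[, c(1, 2)], theta = NULL),
                     class = "keypoint_set"))
  }
  comp <- label_largest_component(mask)
  sk <- thin_mask(comp)
  if (!any(sk)) sk <- comp
  rc <- which(sk, arr.ind = TRUE)
  pts <- cbind(rc[, 1], rc[, 2])   # row, col
  d1 <- skel_farthest(pts, 1L)
  e1 <- which.max(ifelse(is.finite(d1$dist), d1$dist, -1))
  d2 <- skel_farthest(pts, e1)
  e2 <- which.max(ifelse(is.finite(d2$dist), d2$dist, -1))
  # path e1 -> e2 via predecessors
  path <- e2
  while (!is.na(d2$prev[path[1]])) path <- c(d2$prev[path[1]], path)
  pxy <- cbind(pts[path, 2] - 1, pts[path, 1] - 1)  # (x, y), 0-based
  # principal axis of the mask, sign toward +x (then +y)
  rcm <- which(comp, arr.ind = TRUE)
  xy <- cbind(rcm[, 2] - 1, rcm[, 1] - 1)
  xy <- sweep(xy, 2, colMeans(xy))
  ev <- eigen(crossprod(xy) / nrow(xy), symmetric = TRUE)$vectors[, 1]
  if (ev[1] < 0 || (ev[1] == 0 && ev[2] < 0)) ev <- -ev
  if (sum(pxy[1, ] * ev) < sum(pxy[nrow(pxy), ] * ev))
    pxy <- pxy[rev(seq_len(nrow(pxy))), , drop = FALSE]
  # arc-length parameterization, K points at fractions 0, 1/(K-1), ..., 1
  seg <- sqrt(rowSums((pxy[-1, , drop = FALSE] -
                         pxy[-nrow(pxy), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  fr <- seq(0, 1, length.out = K) * total
  pts_out <- matrix(0, K, 2)
  for (k in seq_len(K)) {
    if (total == 0) { pts_out[k, ] <- pxy[1, ]; next }
    i <- findInterval(fr[k], cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(pxy) - 1L)
    t_ <- if (seg[i] > 0) (fr[k] - cum[i]) / seg[i] else 0
    pts_out[k, ] <- (1 - t_) * pxy[i, ] + t_ * pxy[i + 1, ]
  }
  colnames(pts_out) <- c("x", "y")
  structure(list(points = pts_out, theta = NULL), class = "keypoint_set")
}

#' Deformation-adaptive segmentation loss
#'
#' \code{ce}: binary cross-entropy summed over pixels (per the printed
#' form; \code{cfg$ce_mean} switches to the mean), probabilities clamped
#' to \code{[1e-7, 1 - 1e-7]}. \code{prior}: \code{mu / K * sum ||S_k -
#' S_prior,k||^2} with coordinates normalized to [0, 1] by image size.
#' \code{total = ce + prior}.
#'
#' @param M soft mask (matrix or node) in [0, 1].
#' @param M_gt binary ground-truth mask, same size.
#' @param S keypoints of the (binarized) prediction.
#' @param S_prior prior keypoints (same K).
#' @param cfg a \code{\link{seg_config}}.
#' @return list with numeric \code{total}, \code{ce}, \code{prior} and the
#'   autodiff \code{node} of the cross-entropy term (the prior term is a
#'   non-differentiable regularizer evaluated per step).
#' @export
deformation_loss <- function(M, M_gt, S, S_prior, cfg = seg_config()) {
  Mn <- if (is_ag(M)) M else ag_const(M)
  if (!all(dim(Mn$value) == dim(M_gt))) stop("mask size mismatch")
  if (nrow(S$points) != nrow(S_prior$points)) stop("keypoint count mismatch")
  eps <- 1e-7
  p <- ag_clamp(Mn, eps, 1 - eps)
  gt <- M_gt != 0
  pos <- ag_scale(ag_sum(ag_mul(ag_log(p), ag_const(gt * 1))), -1)
  neg <- ag_scale(ag_sum(ag_mul(ag_log(ag_sub(ag_const(array(1, dim(p$value))), p)),
                                ag_const((!gt) * 1))), -1)
  ce_t <- ag_add(pos, neg)
  if (cfg$ce_mean) ce_t <- ag_scale(ce_t, 1 / length(M_gt))
  sz <- c(ncol(M_gt), nrow(M_gt))   # (W, H) for (x, y)
  dS <- sweep(S$points - S_prior$points, 2, sz, "/")
  prior <- cfg$mu * mean(rowSums(dS^2)) # mean = (1/K) sum
  list(total = ce_t$value + prior, ce = ce_t$value, prior = prior,
       node = ce_t)
}

#' Train the segmentation model on simulator frames
#'
#' Steps cycle over (frame, instance) pairs; the target is the
#' ground-truth mask resampled to the 28 x 28 head resolution over the
#' box. The cross-entropy term carries the gradients; the skeleton prior
#' is evaluated and recorded each step.
#'
#' @param clip simulated clip.
#' @param model from \code{\link{make_seg_model}}.
#' @param frames frame indices to train on.
#' @param steps optimizer steps.
#' @param lr learning rate.
#' @return list with updated \code{model} and loss \code{trace}
#'   (columns total, ce, prior).
#' @export
train_seg <- function(clip, model, frames = seq_along(clip$ir), steps = 300,
                      lr = 5e-3) {
  params <- ag_collect_params(model)
  st <- adam_init(params)
  trace <- matrix(0, steps, 3, dimnames = list(NULL, c("total", "ce", "prior")))
  H <- nrow(clip$ir[[1]]); W <- ncol(clip$ir[[1]])
  n_fish <- length(clip$truth$ids)
  cases <- expand.grid(f = frames, i = seq_len(n_fish))
  dmax <- max(clip$truth$depth[[frames[1]]])
  for (k in seq_len(steps)) {
    cs <- cases[(k - 1L) %% nrow(cases) + 1L, ]
    t <- cs$f; i <- cs$i
    box <- clip$truth$boxes[[t]][i, ]
    if (!all(is.finite(box)) || box[3] <= 0 || box[4] <= 0) next
    gt_full <- truth_mask(clip$truth, t, i, c(H, W))
    g <- roi_grid(box, H, W, 28L, 28L)
    v <- as.vector(gt_full * 1)
    gt28 <- matrix(v[g$idx[, 1]] * g$w[, 1] + v[g$idx[, 2]] * g$w[, 2] +
                     v[g$idx[, 3]] * g$w[, 3] + v[g$idx[, 4]] * g$w[, 4],
                   28, 28) >= 0.5
    ag_tape_reset()
    ag_zero_grad(params)
    fi <- stem_forward(clip$ir[[t]], model$ir_stem)
    fd <- stem_forward(clip$truth$depth[[t]] / dmax, model$d_stem)
    m28 <- seg_instance_forward(fi, fd, box, model)
    msk <- m28$value[, , 1]
    S <- if (any(msk >= 0.5)) skeleton_keypoints(msk >= 0.5, model$cfg$K)
    else NULL
    Sp <- if (any(gt28)) skeleton_keypoints(gt28, model$cfg$K) else NULL
    m2d <- ag_node(m28$value[, , 1], backfn = local({ mm <- m28
      function(nd) ag_accum(mm, array(nd$grad, c(dim(nd$grad), 1L))) }))
    if (is.null(S) || is.null(Sp)) {
      S <- Sp <- structure(list(points = matrix(0, model$cfg$K, 2), theta = NULL),
                           class = "keypoint_set")
    }
    l <- deformation_loss(m2d, gt28 * 1, S, Sp, model$cfg)
    ag_backward(l$node)
    st <- adam_step(params, st, lr = lr)
    trace[k, ] <- c(l$total, l$ce, l$prior)
  }
  ag_tape_reset()
  list(model = model, trace = trace)
}

#' Mean IoU of predicted masks against simulator truth
#'
#' @param clip simulated clip.
#' @param model segmentation model.
#' @param frames frames to evaluate.
#' @param threshold binarization threshold.
#' @return mean IoU over all (frame, instance) pairs.
#' @export
seg_mean_iou <- function(clip, model, frames, threshold = 0.5) {
  H <- nrow(clip$ir[[1]]); W <- ncol(clip$ir[[1]])
  ious <- c()
  for (t in frames) {
    sm <- segment_frame(clip$ir[[t]], clip$truth$depth[[t]], model,
                        clip$truth$boxes[[t]], clip$truth$ids)
    for (i in seq_along(sm$masks)) {
      gt <- truth_mask(clip$truth, t, i, c(H, W))
      pr <- sm$masks[[i]] >= threshold
      u <- sum(pr | gt)
      if (u > 0) ious <- c(ious, sum(pr & gt) / u)
    }
  }
  mean(ious)
}
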