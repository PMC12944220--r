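# IR-to-pseudo-RGB translation: conditional U-Net generator with
# texture-conditioned feature injection, a 70-pixel-receptive-field patch
# discriminator, and a water-adaptive term that anchors the output to the
# Beer-Lambert attenuated IR intensity.

#' Generator configuration
#'
#' @param beta L1 reconstruction weight (default 1).
#' @param gamma water-term weight (default 0.3).
#' @param kappa Beer-Lambert coefficient used by the water term, 1/m
#'   (default 0.05); may be a length-3 per-channel vector.
#' @param embed_dim texture embedding length (default 128).
#' @param patch_size side of the fish-local crops fed to the texture
#'   extractor (default 32).
#' @param widths generator encoder widths (tiny default 8/16/32).
#' @param disc_widths discriminator widths; the layer pattern (three
#'   stride-2 4x4 convolutions + two stride-1) fixes a 70 x 70 receptive
#'   field regardless of width.
#' @return list of class \code{gen_config}.
#' @export
gen_config <- function(beta = 1, gamma = 0.3, kappa = 0.05, embed_dim = 128L,
                       patch_size = 32L, widths = c(8, 16, 32),
                       disc_widths = c(8, 16, 32, 32)) {
  stopifnot(beta >= 0, gamma >= 0, all(kappa >= 0))
  structure(list(beta = beta, gamma = gamma, kappa = kappa,
                 embed_dim = as.integer(embed_dim),
                 patch_size = as.integer(patch_size), widths = widths,
                 disc_widths = disc_widths),
            class = "gen_config")
}

#' Build the generator, texture extractor and discriminator
#'
#' @param cfg a \code{\link{gen_config}}.
#' @return list with \code{gen}, \code{tex}, \code{disc} parameter sets
#'   and the config.
#' @export
make_gan_models <- function(cfg = gen_config()) {
  w <- cfg$widths; ed <- cfg$embed_dim
  gen <- list(
    e1 = list(w = init_conv_w(3, 1, w[1]), b = init_bias(w[1])),
    e2 = list(w = init_conv_w(3, w[1], w[2]), b = init_bias(w[2])),
    bott = list(w = init_conv_w(3, w[2], w[3]), b = init_bias(w[3])),
    d2 = list(w = init_conv_w(3, w[3] + w[2], w[2]), b = init_bias(w[2])),
    inj = list(w = init_conv_w(3, w[2] + ed, w[2]), b = init_bias(w[2]),
               gamma = ag_param(rep(1, w[2])), beta = ag_param(rep(0, w[2]))),
    d1 = list(w = init_conv_w(3, w[2] + w[1], w[1]), b = init_bias(w[1])),
    out = list(w = init_conv_w(3, w[1], 3), b = init_bias(3)))
  tex <- list(
    c1 = list(w = init_conv_w(3, 1, 8), b = init_bias(8)),
    c2 = list(w = init_conv_w(3, 8, 16), b = init_bias(16)),
    c3 = list(w = init_conv_w(3, 16, 32), b = init_bias(32)),
    fc = list(w = init_dense_w(32, ed), b = init_bias(ed)))
  dw <- cfg$disc_widths
  disc <- list(
    l1 = list(w = init_conv_w(4, 4, dw[1]), b = init_bias(dw[1])),
    l2 = list(w = init_conv_w(4, dw[1], dw[2]), b = init_bias(dw[2])),
    l3 = list(w = init_conv_w(4, dw[2], dw[3]), b = init_bias(dw[3])),
    l4 = list(w = init_conv_w(4, dw[3], dw[4]), b = init_bias(dw[4])),
    l5 = list(w = init_conv_w(4, dw[4], 1), b = init_bias(1)))
  list(gen = gen, tex = tex, disc = disc, cfg = cfg)
}

#' Texture embedding from fish-local patches
#'
#' Small convolutional encoder with global pooling; multiple patches are
#' averaged, so the embedding is invariant to patch order.
#'
#' @param patches list of \code{patch_size} x \code{patch_size} matrices
#'   (IR crops centered on fish boxes).
#' @param models from \code{\link{make_gan_models}}.
#' @return autodiff node holding the 1 x 128 embedding; an empty patch set
#'   yields the zero vector with a warning.
#' @export
extract_texture_embedding <- function(patches, models) {
  ed <- models$cfg$embed_dim
  if (length(patches) == 0L) {
    warning("no fish patches; texture embedding is the zero vector")
    return(ag_const(matrix(0, 1, ed)))
  }
  tex <- models$tex
  embs <- lapply(patches, function(p) {
    x <- ag_const(array(p, c(dim(p), 1L)))
    h <- ag_relu(ag_conv2d(x, tex$c1$w, tex$c1$b))
    h <- ag_avgpool2(h)
    h <- ag_relu(ag_conv2d(h, tex$c2$w, tex$c2$b))
    h <- ag_avgpool2(h)
    h <- ag_relu(ag_conv2d(h, tex$c3$w, tex$c3$b))
    ag_add_bias_cols(ag_matmul(ag_global_meanpool(h), tex$fc$w), tex$fc$b)
  })
  e <- embs[[1]]
  if (length(embs) > 1L) {
    for (k in 2L:length(embs)) e <- ag_add(e, embs[[k]])
    e <- ag_scale(e, 1 / length(embs))
  }
  e
}

#' Inject a texture embedding into generator features
#'
#' \code{Z = concat(G, tile(E))} channelwise; \code{U =
#' conv3x3(LeakyReLU(Z))}; output is the batch-normalized \code{U}
#' (per-channel normalization with learned gain/shift). Spatial size is
#' preserved.
#'
#' @param features feature-map node (H x W x C).
#' @param E embedding node (1 x 128).
#' @param inj injection parameter set (a generator's \code{inj} block).
#' @return feature-map node, same H x W.
#' @export
inject_texture <- function(features, E, inj) {
  d <- dim(features$value)
  if (d[1] < 1 || d[2] < 1) stop("feature map has zero spatial extent")
  z <- ag_concat_chan(features, ag_tile_vec(E, d[1], d[2]))
  u <- ag_conv2d(ag_leaky_relu(z), inj$w, inj$b)
  ag_chan_norm(u, inj$gamma, inj$beta)
}

generator_forward <- function(ir, models, E = NULL) {
  gen <- models$gen
  x <- ag_const(array(ir, c(dim(ir), 1L)))
  e1 <- ag_relu(ag_conv2d(x, gen$e1$w, gen$e1$b))
  e2 <- ag_relu(ag_conv2d(ag_avgpool2(e1), gen$e2$w, gen$e2$b))
  bt <- ag_relu(ag_conv2d(ag_avgpool2(e2), gen$bott$w, gen$bott$b))
  d2 <- ag_relu(ag_conv2d(ag_concat_chan(ag_upsample2(bt), e2),
                          gen$d2$w, gen$d2$b))
  if (!is.null(E)) d2 <- inject_texture(d2, E, gen$inj)
  d1 <- ag_relu(ag_conv2d(ag_concat_chan(ag_upsample2(d2), e1),
                          gen$d1$w, gen$d1$b))
  ag_sigmoid(ag_conv2d(d1, gen$out$w, gen$out$b))
}

# conditional patch discriminator on (ir, rgb): spatial logit map with a
# 70 x 70 receptive field
disc_forward <- function(ir, rgb, models) {
  disc <- models$disc
  irn <- if (is_ag(ir)) ir else ag_const(array(ir, c(dim(ir), 1L)))
  rn <- if (is_ag(rgb)) rgb else ag_const(rgb)
  x <- ag_concat_chan(irn, rn)
  h <- ag_leaky_relu(ag_conv2d(x, disc$l1$w, disc$l1$b, k = 4, stride = 2, pad = 1))
  h <- ag_leaky_relu(ag_conv2d(h, disc$l2$w, disc$l2$b, k = 4, stride = 2, pad = 1))
  h <- ag_leaky_relu(ag_conv2d(h, disc$l3$w, disc$l3$b, k = 4, stride = 2, pad = 1))
  h <- ag_leaky_relu(ag_conv2d(h, disc$l4$w, disc$l4$b, k = 4, stride = 1, pad = 1))
  ag_conv2d(h, disc$l5$w, disc$l5$b, k = 4, stride = 1, pad = 1)   # logits
}

bce_logits <- function(logits, target) {
  # mean binary cross-entropy on a logit map against constant target 0/1
  p <- ag_sigmoid(logits)
  p <- ag_clamp(p, 1e-7, 1 - 1e-7)
  if (target >= 0.5) ag_scale(ag_mean(ag_log(p)), -1)
  else ag_scale(ag_mean(ag_log(ag_sub(ag_const(array(1, dim(p$value))), p))), -1)
}

#' Water-adaptive generator loss
#'
#' \code{total = L_GAN + beta * L_L1 + gamma * mean |R - ir *
#' exp(-kappa D)|}; the single-channel IR target is broadcast across the
#' three output channels. Components are returned separately.
#'
#' @param R generated H x W x 3 frame (node or array).
#' @param ir IR frame matrix.
#' @param D depth matrix, meters (non-negative).
#' @param rgb_gt ground-truth RGB array for the L1 term (NULL drops it).
#' @param disc_fake discriminator logit map on the generated pair (NULL
#'   drops the GAN term).
#' @param cfg a \code{\link{gen_config}}.
#' @return list with numeric \code{total}, \code{gan}, \code{l1},
#'   \code{water} and the autodiff \code{node}.
#' @export
water_adaptive_loss <- function(R, ir, D, rgb_gt = NULL, disc_fake = NULL,
                                cfg = gen_config()) {
  if (any(D < 0)) stop("negative depth")
  Rn <- if (is_ag(R)) R else ag_const(R)
  if (!all(dim(Rn$value)[1:2] == dim(ir)) || !all(dim(ir) == dim(D)))
    stop("R, ir and D must share spatial size")
  kap <- if (length(cfg$kappa) == 3L) cfg$kappa else rep(cfg$kappa, 3L)
  tgt <- array(0, dim(Rn$value))
  for (ch in 1:3) tgt[, , ch] <- ir * exp(-kap[ch] * D)
  water_t <- ag_scale(ag_mean(ag_abs(ag_sub(Rn, ag_const(tgt)))), cfg$gamma)
  l1_t <- if (is.null(rgb_gt)) ag_const(0)
  else ag_scale(ag_mean(ag_abs(ag_sub(Rn, ag_const(rgb_gt)))), cfg$beta)
  gan_t <- if (is.null(disc_fake)) ag_const(0) else bce_logits(disc_fake, 1)
  total <- ag_add(ag_add(gan_t, l1_t), water_t)
  list(total = total$value, gan = gan_t$value, l1 = l1_t$value,
       water = water_t$value, node = total)
}

fish_patches <- function(ir, boxes, patch_size = 32L) {
  if (is.null(boxes) || nrow(boxes) == 0L) return(list())
  ok <- apply(boxes, 1L, function(b) all(is.finite(b)) && b[3] > 0 && b[4] > 0)
  boxes <- boxes[ok, , drop = FALSE]
  if (nrow(boxes) == 0L) return(list())
  H <- nrow(ir); W <- ncol(ir)
  lapply(seq_len(nrow(boxes)), function(k) {
    b <- boxes[k, ]
    cx <- b[1] + b[3] / 2; cy <- b[2] + b[4] / 2
    half <- patch_size / 2
    g <- roi_grid(c(cx - half, cy - half, patch_size, patch_size),
                  H, W, patch_size, patch_size)
    v <- as.vector(ir)
    matrix(v[g$idx[, 1]] * g$w[, 1] + v[g$idx[, 2]] * g$w[, 2] +
             v[g$idx[, 3]] * g$w[, 3] + v[g$idx[, 4]] * g$w[, 4],
           patch_size, patch_size)
  })
}

#' Translate one IR frame to pseudo-RGB
#'
#' @param ir H x W matrix in [0, 1].
#' @param models from \code{\link{make_gan_models}}.
#' @param boxes optional fish boxes for texture conditioning.
#' @return H x W x 3 array in [0, 1].
#' @export
translate_ir <- function(ir, models, boxes = NULL) {
  ag_tape_reset()
  E <- if (!is.null(boxes) && nrow(boxes) > 0L)
    extract_texture_embedding(fish_patches(ir, boxes, models$cfg$patch_size),
                              models)
  else NULL
  out <- generator_forward(ir, models, E)$value
  ag_tape_reset()
  out
}

#' One adversarial training step
#'
#' Discriminator update on the (real, generated) pair at patch level, then
#' a generator update on the full water-adaptive objective.
#'
#' @param models from \code{\link{make_gan_models}}.
#' @param ir,rgb_gt,D one paired sample (IR matrix, RGB array, depth
#'   matrix).
#' @param boxes optional fish boxes for texture conditioning.
#' @param opt optimizer state (NULL on the first call).
#' @param lr learning rate.
#' @return list with \code{opt} state and the loss \code{record}
#'   (disc, total, gan, l1, water).
#' @export
train_gan_step <- function(models, ir, rgb_gt, D, boxes = NULL, opt = NULL,
                           lr = 2e-3) {
  if (is.null(rgb_gt) || !all(dim(rgb_gt)[1:2] == dim(ir)))
    stop("unpaired batch: matching rgb_gt required")
  gp <- ag_collect_params(list(models$gen, models$tex))
  dp <- ag_collect_params(models$disc)
  if (is.null(opt)) opt <- list(g = adam_init(gp), d = adam_init(dp))
  patches <- fish_patches(ir, boxes, models$cfg$patch_size)
  # --- discriminator step (generator output detached) ---
  ag_tape_reset()
  E <- if (length(patches)) extract_texture_embedding(patches, models) else NULL
  fake <- generator_forward(ir, models, E)$value
  ag_tape_reset()
  ag_zero_grad(dp)
  dl <- ag_add(bce_logits(disc_forward(ir, rgb_gt, models), 1),
               bce_logits(disc_forward(ir, fake, models), 0))
  ag_backward(dl)
  opt$d <- adam_step(dp, opt$d, lr = lr)
  disc_loss <- dl$value
  # --- generator step ---
  ag_tape_reset()
  ag_zero_grad(gp)
  E <- if (length(patches)) extract_texture_embedding(patches, models) else NULL
  R <- generator_forward(ir, models, E)
  lg <- water_adaptive_loss(R, ir, D, rgb_gt,
                            disc_forward(ir, R, models), models$cfg)
  ag_backward(lg$node)
  opt$g <- adam_step(gp, opt$g, lr = lr)
  ag_tape_reset()
  list(opt = opt, record = c(disc = disc_loss, total = lg$total,
                             gan = lg$gan, l1 = lg$l1, water = lg$water))
}

#' Train the generator adversarially over paired frames
#'
#' @param frames list of IR matrices.
#' @param rgbs list of RGB arrays.
#' @param depths list of depth matrices.
#' @param models from \code{\link{make_gan_models}}.
#' @param boxes_list optional per-frame boxes.
#' @param steps training steps (one frame per step, cycling).
#' @param lr learning rate.
#' @return list with updated \code{models} and the loss \code{trace}.
#' @export
train_gan <- function(frames, rgbs, depths, models, boxes_list = NULL,
                      steps = 300, lr = 2e-3) {
  opt <- NULL
  trace <- matrix(0, steps, 5,
                  dimnames = list(NULL, c("disc", "total", "gan", "l1", "water")))
  n <- length(frames)
  for (k in seq_len(steps)) {
    i <- (k - 1L) %% n + 1L
    res <- train_gan_step(models, frames[[i]], rgbs[[i]], depths[[i]],
                          if (is.null(boxes_list)) NULL else boxes_list[[i]],
                          opt, lr)
    opt <- res$opt
    trace[k, ] <- res$record
  }
  list(models = models, trace = trace)
}
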