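# End-to-end orchestration: IR clip -> depth -> pseudo-RGB -> tracks ->
# masks/DR -> volumes, plus the evaluation harness (volume, mask and
# identity metrics) and stratified dataset splitting.

#' Pipeline configuration
#'
#' @param depth_mode "model" (trained depth network) or "oracle"
#'   (simulator truth).
#' @param gen_mode "model" or "oracle".
#' @param detector "oracle" (simulator truth with jitter) or "csv".
#' @param seg_mode "model" or "oracle".
#' @param depth_model,gen_models,seg_model,tdt_model stage checkpoints
#'   (NULL in oracle modes; fresh seeded tiny models are built when a
#'   model-mode stage has no checkpoint).
#' @param jitter_sd oracle-detector jitter, pixels.
#' @param occl_drop oracle-detector occlusion drop threshold.
#' @param seed master seed propagated to every stochastic component.
#' @param out_dir artifact directory (NULL disables writing).
#' @param lr,batch_size,plateau_patience,plateau_factor training policy
#'   defaults (AdamW-style step size 1e-4 at paper scale, halve on
#'   plateau) recorded for the training verbs.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(depth_mode = "oracle", gen_mode = "oracle",
                            detector = "oracle", seg_mode = "model",
                            depth_model = NULL, gen_models = NULL,
                            seg_model = NULL, tdt_model = NULL,
                            jitter_sd = 2, occl_drop = 0.3, seed = 1,
                            out_dir = NULL, lr = 1e-4, batch_size = 16,
                            plateau_patience = 5, plateau_factor = 0.5) {
  structure(list(depth_mode = depth_mode, gen_mode = gen_mode,
                 detector = detector, seg_mode = seg_mode,
                 depth_model = depth_model, gen_models = gen_models,
                 seg_model = seg_model, tdt_model = tdt_model,
                 jitter_sd = jitter_sd, occl_drop = occl_drop, seed = seed,
                 out_dir = out_dir, lr = lr, batch_size = batch_size,
                 plateau_patience = plateau_patience,
                 plateau_factor = plateau_factor),
            class = "pipeline_config")
}

#' Run the full pipeline on one clip
#'
#' Stage order follows the dataflow: depth from IR, pseudo-RGB from IR,
#' tracking on IR + pseudo-RGB features, segmentation on IR + depth,
#' volume from trajectories + masked depth regions. Every intermediate is
#' returned and, when \code{out_dir} is set, persisted (16-bit depth PNGs,
#' 8-bit RGB PNGs, MOT CSV, COCO mask JSON, volume CSV). Deterministic
#' given the config seed and checkpoints.
#'
#' @param clip a simulated clip (or a compatible list with \code{ir} and,
#'   for oracle modes, \code{truth} and \code{config}).
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{depth}, \code{rgb}, \code{tracks},
#'   \code{masks} (per frame), \code{volumes} and the effective config.
#' @export
run_pipeline <- function(clip, config = pipeline_config()) {
  T_ <- length(clip$ir)
  if (!is.null(clip$config) && T_ < clip$config$clip_len)
    stop("clip shorter than clip_len")
  H <- nrow(clip$ir[[1]]); W <- ncol(clip$ir[[1]])
  set.seed(config$seed)
  # ---- depth ----
  depth <- switch(config$depth_mode,
    oracle = clip$depth,
    model = {
      dm <- config$depth_model
      if (is.null(dm)) dm <- make_depth_model(depth_net_config())
      lapply(clip$ir, predict_depth, model = dm)
    },
    stop("depth stage: unknown mode ", config$depth_mode))
  # ---- pseudo-RGB ----
  rgb <- switch(config$gen_mode,
    oracle = clip$rgb,
    model = {
      gm <- config$gen_models
      if (is.null(gm)) gm <- make_gan_models(gen_config())
      lapply(clip$ir, translate_ir, models = gm)
    },
    stop("generator stage: unknown mode ", config$gen_mode))
  # ---- detection + tracking ----
  if (config$detector == "oracle") {
    if (is.null(clip$truth)) stop("tracking stage: oracle detector needs truth")
    det <- oracle_detections(clip, config$jitter_sd, config$occl_drop,
                             rgb_frames = rgb)
  } else stop("tracking stage: unknown detector ", config$detector)
  fw <- make_fusion_weights()
  tank <- clip$config
  m_per_px <- if (!is.null(tank))
    (tank$camera_height + 0.5 * tank$tank_size[3]) / tank$focal_px
  else 1 / 560
  kcfg <- kf_config(dt = if (!is.null(tank)) 1 / tank$fps else 1 / 30,
                    m_per_px = m_per_px)
  tracks <- track_clip(det, kcfg, fw)
  # ---- segmentation ----
  seg_model <- config$seg_model
  if (config$seg_mode == "model" && is.null(seg_model))
    seg_model <- make_seg_model(seg_config())
  masks <- vector("list", T_)
  for (t in seq_len(T_)) {
    tf <- tracks[tracks$frame == t, ]
    bx <- as.matrix(tf[, c("x", "y", "w", "h")])
    masks[[t]] <- if (config$seg_mode == "oracle") {
      oracle_masks_for_boxes(clip, t, bx, tf$id, depth[[t]])
    } else {
      segment_frame(clip$ir[[t]], depth[[t]], seg_model, bx, tf$id)
    }
  }
  # ---- volume ----
  tdt <- config$tdt_model
  if (is.null(tdt)) tdt <- make_tdt_model(tdt_config_tiny())
  focal <- if (!is.null(tank)) tank$focal_px else stop("missing calibration")
  vol_rows <- list()
  for (id in sort(unique(tracks$id))) {
    tt <- tracks[tracks$id == id, ]
    if (nrow(tt) < 2L) next
    cx <- tt$x + tt$w / 2; cy <- tt$y + tt$h / 2
    vx <- c(diff(cx), 0); vx[length(vx)] <- vx[max(1, length(vx) - 1)]
    vy <- c(diff(cy), 0); vy[length(vy)] <- vy[max(1, length(vy) - 1)]
    traj <- cbind(cx, cy, vx, vy)
    # reference frame: mask area closest to the track's median area — the
    # typical unoccluded appearance, robust against frames where the mask
    # leaked onto a neighboring fish
    areas <- vapply(seq_len(nrow(tt)), function(r) {
      ms <- masks[[tt$frame[r]]]
      k <- match(id, ms$ids)
      if (is.na(k) || length(ms$masks) < k) 0 else sum(ms$masks[[k]] >= 0.5)
    }, numeric(1))
    if (all(areas == 0)) next
    med <- stats::median(areas[areas > 0])
    rbest <- which.min(abs(areas - med))
    ms <- masks[[tt$frame[rbest]]]
    k <- match(id, ms$ids)
    if (is.na(k) || areas[rbest] == 0) next
    dr_crop <- extract_dr_crop(ms$DR[[k]], cx[rbest], cy[rbest], tdt$cfg)
    theta <- estimate_incidence(traj, c(H, W), focal)
    series <- tdt_predict_series(traj, dr_crop, theta, tdt)
    series$frame <- tt$frame
    series$id <- id
    vol_rows[[length(vol_rows) + 1L]] <- series
  }
  volumes <- if (length(vol_rows)) do.call(rbind, vol_rows) else
    data.frame(frame = integer(), theta_deg = numeric(),
               v_pre_cm3 = numeric(), v_cm3 = numeric(), id = integer())
  volumes <- volumes[, c("frame", "id", "theta_deg", "v_pre_cm3", "v_cm3")]
  out <- list(depth = depth, rgb = rgb, tracks = tracks, masks = masks,
              volumes = volumes, config = config)
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, clip, config$out_dir)
  out
}

oracle_masks_for_boxes <- function(clip, t, boxes, ids, D) {
  H <- nrow(clip$ir[[1]]); W <- ncol(clip$ir[[1]])
  out <- list(masks = list(), boxes = boxes, ids = ids, DR = list())
  class(out) <- "instance_mask_set"
  gtb <- clip$truth$boxes[[t]]
  for (k in seq_along(ids)) {
    b <- boxes[k, ]
    # best-overlap GT instance (IoU, falling back to center distance)
    ious <- vapply(seq_len(nrow(gtb)), function(i) box_iou(gtb[i, ], b),
                   numeric(1))
    if (any(is.finite(ious) & ious > 0)) {
      g <- which.max(ifelse(is.finite(ious), ious, -1))
    } else {
      d <- sqrt((gtb[, 1] + gtb[, 3] / 2 - b[1] - b[3] / 2)^2 +
                  (gtb[, 2] + gtb[, 4] / 2 - b[2] - b[4] / 2)^2)
      g <- which.min(ifelse(is.finite(d), d, Inf))
    }
    m <- truth_mask(clip$truth, t, g, c(H, W)) * 1
    out$masks[[k]] <- m
    out$DR[[k]] <- ifelse(m >= 0.5, m * D, 0)
  }
  out
}

write_pipeline_artifacts <- function(res, clip, dir) {
  for (d in file.path(dir, c("depth", "rgb"))) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  T_ <- length(res$depth)
  for (t in seq_len(T_)) {
    fn <- sprintf("frame_%05d.png", t - 1L)
    write_png16(pmin(round(res$depth[[t]] * 1000), 65535),
                file.path(dir, "depth", fn))
    write_png8(res$rgb[[t]], file.path(dir, "rgb", fn))
  }
  write_mot_csv(res$tracks, file.path(dir, "tracks.csv"))
  sz <- dim(res$depth[[1]])
  masks_by_frame <- lapply(seq_len(T_), function(t) {
    ms <- res$masks[[t]]
    out <- lapply(seq_along(ms$masks), function(k) ms$masks[[k]] >= 0.5)
    stats::setNames(out, as.character(ms$ids))
  })
  write_coco_masks(masks_by_frame, sz, file.path(dir, "masks.json"))
  write_volume_csv(res$volumes, file.path(dir, "volumes.csv"))
  invisible(dir)
}

# ---- evaluation ----

box_iou <- function(a, b) {
  x1 <- pmax(a[1], b[1]); y1 <- pmax(a[2], b[2])
  x2 <- pmin(a[1] + a[3], b[1] + b[3]); y2 <- pmin(a[2] + a[4], b[2] + b[4])
  inter <- pmax(0, x2 - x1) * pmax(0, y2 - y1)
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

#' Evaluate pipeline output against simulator truth
#'
#' Identity matching per frame follows the CLEAR-MOT convention: a
#' ground-truth fish keeps its previous hypothesis while that hypothesis
#' stays within one body length; remaining pairs match greedily by center
#' distance. ID switches count changes of the matched hypothesis.
#' Volume metrics (MAE, RMSE, MAPE, R^2, Pearson) are computed over
#' matched (fish, frame) volume pairs; mask IoU / precision / recall / F1
#' over binarized masks of matched identities.
#'
#' @param res output of \code{\link{run_pipeline}} (or a compatible list
#'   with \code{tracks}, \code{volumes}, \code{masks}).
#' @param truth a simulated clip's \code{truth}.
#' @return list of class \code{eval_report}.
#' @export
evaluate <- function(res, truth) {
  n <- length(truth$ids)
  frames <- sort(unique(res$tracks$frame))
  if (length(frames) == 0L) stop("no overlapping frames between prediction and truth")
  lastmatch <- rep(NA_integer_, n)
  switches <- 0L
  match_log <- list()
  for (t in frames) {
    pf <- res$tracks[res$tracks$frame == t, ]
    if (nrow(pf) == 0L) next
    pcx <- pf$x + pf$w / 2; pcy <- pf$y + pf$h / 2
    gb <- truth$boxes[[t]]
    gcx <- gb[, 1] + gb[, 3] / 2; gcy <- gb[, 2] + gb[, 4] / 2
    thr <- pmax(gb[, 3], gb[, 4])
    D <- sqrt(outer(gcx, pcx, "-")^2 + outer(gcy, pcy, "-")^2)
    used <- rep(FALSE, nrow(pf)); match_t <- rep(NA_integer_, n)
    for (g in seq_len(n)) {
      if (!is.na(lastmatch[g])) {
        j <- which(pf$id == lastmatch[g])
        if (length(j) == 1L && is.finite(D[g, j]) && D[g, j] <= thr[g]) {
          match_t[g] <- lastmatch[g]; used[j] <- TRUE
        }
      }
    }
    repeat {
      cand <- which(is.na(match_t))
      if (!length(cand) || all(used)) break
      Dm <- D[cand, !used, drop = FALSE]
      if (!any(is.finite(Dm))) break
      k <- which(Dm == min(Dm, na.rm = TRUE), arr.ind = TRUE)[1, ]
      g <- cand[k[1]]; j <- which(!used)[k[2]]
      if (is.finite(D[g, j]) && D[g, j] <= thr[g]) {
        match_t[g] <- pf$id[j]; used[j] <- TRUE
      } else break
    }
    for (g in seq_len(n)) {
      if (!is.na(match_t[g])) {
        if (!is.na(lastmatch[g]) && match_t[g] != lastmatch[g])
          switches <- switches + 1L
        lastmatch[g] <- match_t[g]
      }
    }
    match_log[[as.character(t)]] <- match_t
  }
  # volume metrics over matched (fish, frame) pairs
  vp <- c(); vg <- c()
  if (nrow(res$volumes) > 0) {
    for (t in names(match_log)) {
      mt <- match_log[[t]]
      vt <- res$volumes[res$volumes$frame == as.integer(t), ]
      for (g in seq_len(n)) {
        if (is.na(mt[g])) next
        row <- vt[vt$id == mt[g], ]
        if (nrow(row) == 1L) { vp <- c(vp, row$v_cm3); vg <- c(vg, truth$volumes[g]) }
      }
    }
  }
  vol <- if (length(vp) >= 2L) {
    list(mae = mean(abs(vp - vg)), rmse = sqrt(mean((vp - vg)^2)),
         mape = mean(abs(vp - vg) / vg) * 100,
         r2 = 1 - sum((vp - vg)^2) / sum((vg - mean(vg))^2),
         pearson = if (stats::sd(vp) > 0 && stats::sd(vg) > 0)
           stats::cor(vp, vg) else NA_real_,
         n = length(vp))
  } else list(mae = NA_real_, rmse = NA_real_, mape = NA_real_,
              r2 = NA_real_, pearson = NA_real_, n = 0L)
  # mask metrics over matched identities
  tp <- fp <- fn_ <- 0; ious <- c()
  if (!is.null(res$masks)) {
    sz <- dim(if (!is.null(truth$depth)) truth$depth[[1]] else res$masks[[1]]$masks[[1]])
    for (t in names(match_log)) {
      ti <- as.integer(t)
      mt <- match_log[[t]]
      ms <- res$masks[[ti]]
      if (is.null(ms) || length(ms$masks) == 0L) next
      for (g in seq_len(n)) {
        if (is.na(mt[g])) next
        k <- match(mt[g], ms$ids)
        if (is.na(k) || length(ms$masks) < k) next
        pr <- ms$masks[[k]] >= 0.5
        gt <- truth_mask(truth, ti, g, sz)
        i_ <- sum(pr & gt); u_ <- sum(pr | gt)
        if (u_ > 0) ious <- c(ious, i_ / u_)
        tp <- tp + i_; fp <- fp + sum(pr & !gt); fn_ <- fn_ + sum(!pr & gt)
      }
    }
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn_ > 0) tp / (tp + fn_) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  structure(list(mae = vol$mae, rmse = vol$rmse, mape = vol$mape,
                 r2 = vol$r2, pearson = vol$pearson,
                 iou = if (length(ious)) mean(ious) else NA_real_,
                 precision = prec, recall = rec, f1 = f1,
                 id_switches = switches,
                 n_volume_pairs = vol$n, n_mask_pairs = length(ious)),
            class = "eval_report")
}

#' Stratified train/validation/test split of clips
#'
#' Floor-then-distribute rounding inside each stratum: each split first
#' receives \code{floor(n * fraction)} clips, the remainder goes to the
#' splits with the largest fractional parts (ties broken by split order).
#' Deterministic per seed; no clip appears in two splits.
#'
#' @param clips list (or vector) of clip identifiers.
#' @param fractions length-3 non-negative vector summing to 1.
#' @param strata optional factor of the same length (e.g. density bucket).
#' @param seed shuffle seed.
#' @return list with \code{train}, \code{validation}, \code{test}.
#' @export
split_dataset <- function(clips, fractions = c(0.7, 0.15, 0.15),
                          strata = NULL, seed = 1) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-9)
  n <- length(clips)
  if (is.null(strata)) strata <- rep(1L, n)
  strata <- as.factor(strata)
  out <- list(train = list(), validation = list(), test = list())
  set.seed(seed)
  for (lv in levels(strata)) {
    idx <- which(strata == lv)
    idx <- idx[sample.int(length(idx))]
    m <- length(idx)
    base <- floor(m * fractions)
    rem <- m - sum(base)
    if (rem > 0) {
      fracpart <- m * fractions - base
      add <- order(-fracpart, seq_along(fracpart))[seq_len(rem)]
      base[add] <- base[add] + 1L
    }
    splits <- rep(1:3, times = base)
    out$train <- c(out$train, clips[idx[splits == 1]])
    out$validation <- c(out$validation, clips[idx[splits == 2]])
    out$test <- c(out$test, clips[idx[splits == 3]])
  }
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Volume:  MAE", signif(x$mae, 4), "cm^3  RMSE", signif(x$rmse, 4),
      "cm^3  MAPE", signif(x$mape, 4), "%\n")
  cat("         R2", signif(x$r2, 4), "  Pearson", signif(x$pearson, 4),
      " (", x$n_volume_pairs, "pairs )\n")
  cat("Masks:   IoU", signif(x$iou, 4), "  P", signif(x$precision, 4),
      "  R", signif(x$recall, 4), "  F1", signif(x$f1, 4), "\n")
  cat("Tracking: ID switches", x$id_switches, "\n")
  invisible(x)
}
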