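# Multi-fish tracking: cross-modal attention feature fusion, a
# behavior-constrained Kalman filter with covariance clipping, Mahalanobis
# gating, and gated Hungarian association (DeepSORT-style track management).

# ---- cross-modal attention fusion ----

#' Build cross-modal fusion weights
#'
#' Random projection weights for \code{\link{fuse_crossmodal}}: per-head
#' query/key/value maps of width \code{d_k} and an output projection from
#' the concatenated heads back to \code{d}. Drawn from the current RNG
#' stream; seed outside for reproducibility.
#'
#' @param d feature dimension (default 128).
#' @param d_k per-head attention width (default 128).
#' @param heads number of heads concatenated (default 4).
#' @return list of matrices \code{W_Q}, \code{W_K}, \code{W_V}
#'   (\code{d x heads*d_k}) and \code{W_O} (\code{heads*d_k x d}), with the
#'   head count attached.
#' @export
make_fusion_weights <- function(d = 128, d_k = 128, heads = 4) {
  sd <- 1 / sqrt(d)
  w <- function(r, c) matrix(stats::rnorm(r * c, sd = sd), r, c)
  list(W_Q = w(d, heads * d_k), W_K = w(d, heads * d_k),
       W_V = w(d, heads * d_k), W_O = w(heads * d_k, d), heads = heads,
       d_k = d_k)
}

#' Fuse IR and pseudo-RGB appearance features by multi-head attention
#'
#' Queries come from the IR features, keys and values from the RGB
#' features: \code{Q = F_IR W_Q}, \code{K = F_RGB W_K}, \code{V = F_RGB
#' W_V}; each head applies scaled dot-product softmax attention with width
#' \code{d_k}, the heads are concatenated and projected by \code{W_O}.
#'
#' @param feat_ir n x d matrix of IR appearance vectors.
#' @param feat_rgb n x d matrix of RGB appearance vectors (same n, d).
#' @param weights from \code{\link{make_fusion_weights}}.
#' @return n x d matrix of fused features.
#' @export
fuse_crossmodal <- function(feat_ir, feat_rgb, weights) {
  stopifnot(nrow(feat_ir) == nrow(feat_rgb), ncol(feat_ir) == ncol(feat_rgb))
  h <- weights$heads
  if (ncol(weights$W_Q) %% h != 0)
    stop("projection width not divisible by head count")
  d_k <- ncol(weights$W_Q) %/% h
  Q <- feat_ir %*% weights$W_Q
  K <- feat_rgb %*% weights$W_K
  V <- feat_rgb %*% weights$W_V
  heads_out <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- (i - 1L) * d_k + seq_len(d_k)
    s <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(d_k)
    s <- s - apply(s, 1L, max)
    e <- exp(s)
    a <- e / rowSums(e)
    heads_out[[i]] <- a %*% V[, cols, drop = FALSE]
  }
  do.call(cbind, heads_out) %*% weights$W_O
}

# ---- Kalman filter ----

#' Kalman tracker configuration
#'
#' State is \code{[p_x, p_y, a, v_x, v_y, omega]}: planar position (m),
#' box aspect ratio, planar velocity (m/s) and angular velocity (rad/s).
#' Behavior constraints clamp speed to \code{[0, max_speed]} m/s and the
#' turn rate so the turn radius speed/|omega| stays above
#' \code{min_turn_radius} whenever the fish is moving. The covariance is
#' regularized as \code{P <- clip(P + Q_kal, P_min, P_max)} (eigenvalue
#' clipping by default, elementwise diagonal clipping behind
#' \code{clip_mode = "diag"}).
#'
#' @param dt frame interval, seconds.
#' @param q_accel white-acceleration process-noise density (m^2/s^3) for
#'   each planar axis; builds the standard discretized block
#'   \code{[[dt^3/3, dt^2/2], [dt^2/2, dt]] * q_accel} coupling position
#'   and velocity. The coupling is what makes velocity observable under
#'   the \code{P + Q_kal} covariance propagation.
#' @param q_aspect,q_omega process-noise rates (per second) for the aspect
#'   ratio and angular velocity; aspect drifts quickly when a fish turns
#'   (its box aspect sweeps its full range within about a second).
#' @param r_meas measurement-noise diagonal for \code{[p_x, p_y, a]}.
#' @param p0 initial covariance diagonal.
#' @param P_min,P_max covariance eigenvalue bounds.
#' @param max_speed speed bound, m/s.
#' @param min_turn_radius minimum turn radius, m.
#' @param gate_quantile chi-square quantile for Mahalanobis gating (3 dof).
#' @param clip_mode "eigen" or "diag".
#' @param lambda_match cost mix: lambda * Mahalanobis + (1 - lambda) *
#'   cosine appearance distance.
#' @param max_age frames a track survives unmatched.
#' @param n_init hits before a track is confirmed.
#' @param m_per_px pixel-to-metric conversion (meters per pixel at nominal
#'   fish depth).
#' @return list of class \code{kf_config}.
#' @export
kf_config <- function(dt = 1 / 30,
                      q_accel = 0.5, q_aspect = 2, q_omega = 1,
                      r_meas = c(4e-4, 4e-4, 1),
                      p0 = c(0.01, 0.01, 0.25, 0.25, 0.25, 1),
                      P_min = 1e-4, P_max = 10,
                      max_speed = 1, min_turn_radius = 0.05,
                      gate_quantile = 0.95, clip_mode = "eigen",
                      lambda_match = 0.5, max_age = 30L, n_init = 3L,
                      m_per_px = 1 / 560) {
  Q <- matrix(0, 6, 6)
  for (ax in 1:2) {
    p <- ax; v <- ax + 3L
    Q[p, p] <- q_accel * dt^3 / 3
    Q[p, v] <- Q[v, p] <- q_accel * dt^2 / 2
    Q[v, v] <- q_accel * dt
  }
  Q[3, 3] <- q_aspect * dt
  Q[6, 6] <- q_omega * dt
  structure(list(dt = dt, Q = Q, R = diag(r_meas),
                 p0 = diag(p0), P_min = P_min, P_max = P_max,
                 max_speed = max_speed, min_turn_radius = min_turn_radius,
                 gate = stats::qchisq(gate_quantile, df = 3),
                 clip_mode = clip_mode, lambda_match = lambda_match,
                 max_age = as.integer(max_age), n_init = as.integer(n_init),
                 m_per_px = m_per_px),
            class = "kf_config")
}

symmpart <- function(P) (P + t(P)) / 2

clip_cov <- function(P, cfg) {
  P <- symmpart(P)
  if (cfg$clip_mode == "diag") {
    diag(P) <- pmin(pmax(diag(P), cfg$P_min), cfg$P_max)
    return(P)
  }
  e <- eigen(P, symmetric = TRUE)
  lam <- pmin(pmax(e$values, cfg$P_min), cfg$P_max)
  symmpart(e$vectors %*% (lam * t(e$vectors)))
}

check_psd <- function(P) {
  ev <- eigen(symmpart(P), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("covariance is not positive semidefinite")
  invisible(TRUE)
}

apply_behavior_constraints <- function(x, cfg) {
  sp <- sqrt(x[4]^2 + x[5]^2)
  if (sp > cfg$max_speed) {
    x[4:5] <- x[4:5] * cfg$max_speed / sp
    sp <- cfg$max_speed
  }
  if (sp > 0) {
    wmax <- sp / cfg$min_turn_radius
    x[6] <- max(min(x[6], wmax), -wmax)
  }
  x
}

#' Initialize a Kalman state from a first measurement
#'
#' @param z measurement \code{c(p_x, p_y, a)} in metric units.
#' @param cfg a \code{\link{kf_config}}.
#' @return list with state mean \code{x} and covariance \code{P}.
#' @export
kf_init <- function(z, cfg) {
  list(x = c(z[1], z[2], z[3], 0, 0, 0), P = cfg$p0)
}

#' Kalman predict with behavior constraints
#'
#' Constant-velocity plus angular-rate motion: the velocity vector rotates
#' by \code{omega * dt}, position advances by the velocity. Speed and turn
#' rate are then clamped to biologically plausible bounds and the
#' covariance regularized by \code{clip(P + Q_kal, P_min, P_max)}.
#'
#' @param state list with \code{x} (length 6) and \code{P} (6 x 6 PSD).
#' @param dt time step, seconds (> 0); defaults to the config interval.
#' @param cfg a \code{\link{kf_config}}.
#' @return updated state.
#' @export
kf_predict <- function(state, dt = cfg$dt, cfg = kf_config()) {
  stopifnot(dt > 0)
  check_psd(state$P)
  x <- state$x
  x[1] <- x[1] + x[4] * dt
  x[2] <- x[2] + x[5] * dt
  ang <- x[6] * dt
  R2 <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  x[4:5] <- as.vector(R2 %*% x[4:5])
  x <- apply_behavior_constraints(x, cfg)
  P <- clip_cov(state$P + cfg$Q * (dt / cfg$dt), cfg)
  list(x = x, P = P)
}

kf_H <- function() {
  H <- matrix(0, 3, 6)
  H[1, 1] <- H[2, 2] <- H[3, 3] <- 1
  H
}

#' Kalman measurement update
#'
#' Linear observation of \code{[p_x, p_y, a]} with standard gain-based
#' correction, followed by covariance clipping and the behavior
#' constraints.
#'
#' @param state predicted state.
#' @param z measurement \code{c(p_x, p_y, a)}.
#' @param cfg a \code{\link{kf_config}}.
#' @return corrected state.
#' @export
kf_update <- function(state, z, cfg = kf_config()) {
  H <- kf_H()
  S <- H %*% state$P %*% t(H) + cfg$R
  if (rcond(S) < 1e-12)
    stop("singular innovation covariance (S condition ",
         format(rcond(S)), "); check R_meas and P bounds")
  K <- state$P %*% t(H) %*% solve(S)
  nu <- z - as.vector(H %*% state$x)
  x <- state$x + as.vector(K %*% nu)
  P <- (diag(6) - K %*% H) %*% state$P
  x <- apply_behavior_constraints(x, cfg)
  list(x = x, P = clip_cov(P, cfg))
}

#' Mahalanobis gate
#'
#' Squared Mahalanobis distance of a measurement under the predicted
#' innovation distribution; accepted iff it falls inside the chi-square
#' 0.95 region for 3 degrees of freedom (7.815).
#'
#' @param state predicted state.
#' @param z measurement \code{c(p_x, p_y, a)}.
#' @param cfg a \code{\link{kf_config}}.
#' @return list with \code{accept} and \code{distance} (squared).
#' @export
mahalanobis_gate <- function(state, z, cfg = kf_config()) {
  H <- kf_H()
  S <- H %*% state$P %*% t(H) + cfg$R
  nu <- z - as.vector(H %*% state$x)
  d2 <- as.numeric(t(nu) %*% solve(S, nu))
  list(accept = d2 <= cfg$gate, distance = d2)
}

# ---- Hungarian assignment (shortest augmenting path with potentials) ----

#' Solve the linear assignment problem
#'
#' Minimum-cost row-to-column assignment (Jonker-Volgenant style, O(n^3)).
#' Rectangular matrices are padded internally; entries of \code{Inf} are
#' treated as forbidden.
#'
#' @param cost numeric cost matrix.
#' @return integer vector: for each row, the assigned column (NA if the row
#'   ends up on a forbidden or padded entry).
#' @export
hungarian_assign <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L) return(rep(NA_integer_, nr))
  n <- max(nr, nc)
  big <- 1e9
  a <- matrix(big, n, n)
  finite <- is.finite(cost)
  if (any(finite)) {
    mx <- max(abs(cost[finite]))
    big <- max(1e9, 1e6 * (mx + 1))
    a <- matrix(big, n, n)
    a[seq_len(nr), seq_len(nc)][finite] <- cost[finite]
  }
  # e-maxx potentials algorithm, 1-based with virtual 0 handled via index 0
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- a[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_col <- rep(NA_integer_, nr)
  for (j in seq_len(n)) {
    i <- p[j + 1L]
    if (i >= 1L && i <= nr && j <= nc && is.finite(cost[i, j]))
      assign_col[i] <- j
  }
  assign_col
}

# ---- association ----

cosine_dist <- function(A, B) {
  # rows of A vs rows of B
  An <- A / pmax(sqrt(rowSums(A^2)), 1e-12)
  Bn <- B / pmax(sqrt(rowSums(B^2)), 1e-12)
  1 - An %*% t(Bn)
}

#' Associate tracks with detections
#'
#' Cost is \code{lambda * Mahalanobis^2 + (1 - lambda) * cosine appearance
#' distance} on fused features, with Mahalanobis-gated entries forbidden;
#' assignment by the Hungarian algorithm.
#'
#' @param tracks list of track records (with predicted \code{state} and
#'   running \code{feat}).
#' @param det_z matrix of metric measurements (n x 3).
#' @param det_feat matrix of fused detection features (n x d).
#' @param cfg a \code{\link{kf_config}}.
#' @return list with \code{matches} (2-column matrix track/detection),
#'   \code{unmatched_tracks}, \code{unmatched_dets}.
#' @export
associate <- function(tracks, det_z, det_feat, cfg = kf_config()) {
  nt <- length(tracks); nd <- nrow(det_z)
  if (nt == 0L || is.null(nd) || nd == 0L)
    return(list(matches = matrix(integer(), 0, 2),
                unmatched_tracks = seq_len(nt),
                unmatched_dets = seq_len(if (is.null(nd)) 0L else nd)))
  cost <- matrix(Inf, nt, nd)
  for (i in seq_len(nt)) {
    tf <- matrix(tracks[[i]]$feat, 1)
    ad <- as.vector(cosine_dist(tf, det_feat))
    # the printed covariance propagation P + Q_kal does not inflate the
    # position block while a track coasts, so the gate is widened with the
    # number of consecutive misses (position error grows ~ (misses dt)^2)
    age <- if (is.null(tracks[[i]]$misses)) 0L else tracks[[i]]$misses
    infl <- 1 + age
    for (j in seq_len(nd)) {
      g <- mahalanobis_gate(tracks[[i]]$state, det_z[j, ], cfg)
      if (g$distance <= cfg$gate * infl)
        cost[i, j] <- cfg$lambda_match * g$distance / infl +
          (1 - cfg$lambda_match) * ad[j]
    }
  }
  asg <- hungarian_assign(cost)
  matches <- cbind(which(!is.na(asg)), asg[!is.na(asg)])
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(nt), matches[, 1]),
       unmatched_dets = setdiff(seq_len(nd), matches[, 2]))
}

# ---- detector interface ----

#' Oracle detector from simulator ground truth
#'
#' A pluggable detector stand-in that reads the simulator's truth: tight
#' ground-truth boxes with Gaussian center jitter, dropped when the fish is
#' occluded beyond a threshold. Appearance features are bilinear 16 x 8
#' resamples of the IR and RGB crops (length 128, L2-normalized).
#'
#' @param clip simulated clip.
#' @param jitter_sd box-center jitter, pixels.
#' @param occl_drop drop a detection when the occluded fraction exceeds
#'   this value.
#' @param rgb_frames optional frame list to use for RGB features (e.g.
#'   pseudo-RGB from the generator); defaults to the clip's RGB stack.
#' @return list per frame: \code{boxes} (n x 4), \code{conf}, \code{feat_ir},
#'   \code{feat_rgb} (n x 128 each).
#' @export
oracle_detections <- function(clip, jitter_sd = 2, occl_drop = 0.5,
                              rgb_frames = NULL) {
  T_ <- length(clip$ir)
  H <- dim(clip$ir[[1]])[1]; W <- dim(clip$ir[[1]])[2]
  out <- vector("list", T_)
  if (is.null(rgb_frames)) rgb_frames <- clip$rgb
  for (t in seq_len(T_)) {
    keep <- which(clip$truth$occluded[t, ] <= occl_drop &
                    clip$truth$boxes[[t]][, 3] > 0)
    b <- clip$truth$boxes[[t]][keep, , drop = FALSE]
    if (nrow(b) > 0) {
      b[, 1] <- b[, 1] + stats::rnorm(nrow(b), sd = jitter_sd)
      b[, 2] <- b[, 2] + stats::rnorm(nrow(b), sd = jitter_sd)
    }
    gray <- if (length(dim(rgb_frames[[t]])) == 3)
      (rgb_frames[[t]][, , 1] + rgb_frames[[t]][, , 2] + rgb_frames[[t]][, , 3]) / 3
    else rgb_frames[[t]]
    fi <- matrix(0, nrow(b), 128); fr <- matrix(0, nrow(b), 128)
    for (k in seq_len(nrow(b))) {
      fi[k, ] <- appearance_feature(clip$ir[[t]], b[k, ])
      fr[k, ] <- appearance_feature(gray, b[k, ])
    }
    out[[t]] <- list(boxes = b, conf = rep(1, nrow(b)), feat_ir = fi,
                     feat_rgb = fr, truth_idx = keep)
  }
  out
}

# 16 x 8 bilinear resample of the crop, flattened and L2-normalized
appearance_feature <- function(img, box) {
  H <- nrow(img); W <- ncol(img)
  g <- roi_grid(box, H, W, 16L, 8L)
  v <- as.vector(img)[g$idx[, 1]] * g$w[, 1] +
    as.vector(img)[g$idx[, 2]] * g$w[, 2] +
    as.vector(img)[g$idx[, 3]] * g$w[, 3] +
    as.vector(img)[g$idx[, 4]] * g$w[, 4]
  v / max(sqrt(sum(v^2)), 1e-12)
}

# ---- full tracker ----

#' Track a clip of detections
#'
#' DeepSORT-style management over the behavior-constrained Kalman filter:
#' fused appearance via cross-modal attention, gated Hungarian association,
#' tracks confirmed after \code{n_init} hits and deleted after
#' \code{max_age} misses. Coasting (unmatched) confirmed tracks report the
#' predicted box.
#'
#' @param detections per-frame detection list (see
#'   \code{\link{oracle_detections}}).
#' @param cfg a \code{\link{kf_config}}.
#' @param fusion_weights from \code{\link{make_fusion_weights}}; NULL
#'   disables fusion (raw IR features used).
#' @return data frame \code{frame, id, x, y, w, h, conf} (a TrackSet).
#' @export
track_clip <- function(detections, cfg = kf_config(), fusion_weights = NULL) {
  tracks <- list()
  next_id <- 1L
  rows <- list()
  for (t in seq_along(detections)) {
    det <- detections[[t]]
    nd <- nrow(det$boxes)
    for (i in seq_along(tracks))
      tracks[[i]]$state <- kf_predict(tracks[[i]]$state, cfg$dt, cfg)
    if (nd > 0) {
      feat <- if (!is.null(fusion_weights))
        fuse_crossmodal(det$feat_ir, det$feat_rgb, fusion_weights)
      else det$feat_ir
      z <- cbind((det$boxes[, 1] + det$boxes[, 3] / 2) * cfg$m_per_px,
                 (det$boxes[, 2] + det$boxes[, 4] / 2) * cfg$m_per_px,
                 det$boxes[, 3] / pmax(det$boxes[, 4], 1))
    } else {
      feat <- matrix(0, 0, 128); z <- matrix(0, 0, 3)
    }
    # cascade: confirmed tracks claim detections first, tentative tracks
    # compete only for the remainder (prevents one-frame gate blips from
    # seeding rivals that steal the measurement stream)
    conf_idx <- which(vapply(tracks, `[[`, logical(1), "confirmed"))
    tent_idx <- setdiff(seq_along(tracks), conf_idx)
    res1 <- associate(tracks[conf_idx], z, feat, cfg)
    rem <- res1$unmatched_dets
    res2 <- associate(tracks[tent_idx], z[rem, , drop = FALSE],
                      feat[rem, , drop = FALSE], cfg)
    m1 <- cbind(conf_idx[res1$matches[, 1]], res1$matches[, 2])
    m2 <- cbind(tent_idx[res2$matches[, 1]], rem[res2$matches[, 2]])
    res <- list(
      matches = rbind(m1, m2),
      unmatched_tracks = c(conf_idx[res1$unmatched_tracks],
                           tent_idx[res2$unmatched_tracks]),
      unmatched_dets = rem[res2$unmatched_dets])
    if (nrow(res$matches) > 0) {
      for (r in seq_len(nrow(res$matches))) {
        i <- res$matches[r, 1]; j <- res$matches[r, 2]
        tracks[[i]]$state <- kf_update(tracks[[i]]$state, z[j, ], cfg)
        tracks[[i]]$feat <- 0.9 * tracks[[i]]$feat + 0.1 * feat[j, ]
        tracks[[i]]$hits <- tracks[[i]]$hits + 1L
        tracks[[i]]$misses <- 0L
        tracks[[i]]$box <- det$boxes[j, ]
        row <- data.frame(
          frame = t, id = tracks[[i]]$id, x = det$boxes[j, 1],
          y = det$boxes[j, 2], w = det$boxes[j, 3], h = det$boxes[j, 4],
          conf = det$conf[j])
        if (tracks[[i]]$confirmed) {
          rows[[length(rows) + 1L]] <- row
        } else if (tracks[[i]]$hits >= cfg$n_init) {
          # confirmation: backfill the rows buffered while tentative
          tracks[[i]]$confirmed <- TRUE
          for (pr in tracks[[i]]$pending) rows[[length(rows) + 1L]] <- pr
          tracks[[i]]$pending <- NULL
          rows[[length(rows) + 1L]] <- row
        } else {
          tracks[[i]]$pending <- c(tracks[[i]]$pending, list(row))
        }
      }
    }
    if (length(res$unmatched_tracks) > 0) {
      for (i in res$unmatched_tracks) {
        tracks[[i]]$misses <- tracks[[i]]$misses + 1L
        # damp coasting velocity: the constant-velocity model is the least
        # trustworthy part of the state while unobserved
        tracks[[i]]$state$x[4:5] <- tracks[[i]]$state$x[4:5] * 0.8
        if (tracks[[i]]$confirmed && tracks[[i]]$misses <= cfg$max_age) {
          st <- tracks[[i]]$state
          cx <- st$x[1] / cfg$m_per_px; cy <- st$x[2] / cfg$m_per_px
          b <- tracks[[i]]$box
          rows[[length(rows) + 1L]] <- data.frame(
            frame = t, id = tracks[[i]]$id, x = cx - b[3] / 2,
            y = cy - b[4] / 2, w = b[3], h = b[4], conf = 0.5)
        }
      }
    }
    keep <- vapply(tracks, function(tr) {
      tr$misses <= cfg$max_age && (tr$confirmed || tr$misses == 0L)
    }, logical(1))
    tracks <- tracks[keep]
    for (j in res$unmatched_dets) {
      row <- data.frame(frame = t, id = next_id, x = det$boxes[j, 1],
                        y = det$boxes[j, 2], w = det$boxes[j, 3],
                        h = det$boxes[j, 4], conf = det$conf[j])
      confirmed0 <- cfg$n_init <= 1L
      if (confirmed0) rows[[length(rows) + 1L]] <- row
      tracks[[length(tracks) + 1L]] <- list(
        id = next_id, state = kf_init(z[j, ], cfg), feat = feat[j, ],
        hits = 1L, misses = 0L, confirmed = confirmed0,
        box = det$boxes[j, ],
        pending = if (confirmed0) NULL else list(row))
      next_id <- next_id + 1L
    }
  }
  if (length(rows) == 0)
    return(data.frame(frame = integer(), id = integer(), x = numeric(),
                      y = numeric(), w = numeric(), h = numeric(),
                      conf = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$frame, out$id), ]
}
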