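# Shared fixtures: small simulated clips (memoised per session) and
# brute-force oracles used by several test files.

small_clip <- local({
  cache <- new.env(parent = emptyenv())
  function(n_fish = 6, image_size = c(48, 48), focal_px = 45, clip_len = 60,
           seed = 42, scenario = "free") {
    key <- paste(n_fish, paste(image_size, collapse = "x"), focal_px,
                 clip_len, seed, scenario, sep = "_")
    if (is.null(cache[[key]])) {
      cfg <- tank_config(n_fish = n_fish, image_size = image_size,
                         focal_px = focal_px, clip_len = clip_len,
                         seed = seed, scenario = scenario)
      cache[[key]] <- simulate_clip(cfg)
    }
    cache[[key]]
  }
})

# explicit double-loop scaled-dot-product attention (per-head), the oracle
# for both fusion (queries from IR, keys/values from RGB) and the TDT
brute_attention <- function(feat_q, feat_kv, W_Q, W_K, W_V, W_O, heads) {
  d_k <- ncol(W_Q) / heads
  n <- nrow(feat_q); m <- nrow(feat_kv)
  Q <- feat_q %*% W_Q; K <- feat_kv %*% W_K; V <- feat_kv %*% W_V
  out <- NULL
  for (h in seq_len(heads)) {
    cols <- (h - 1) * d_k + seq_len(d_k)
    O <- matrix(0, n, d_k)
    for (i in seq_len(n)) {
      sc <- vapply(seq_len(m), function(j)
        sum(Q[i, cols] * K[j, cols]) / sqrt(d_k), numeric(1))
      a <- exp(sc - max(sc)); a <- a / sum(a)
      for (j in seq_len(m)) O[i, ] <- O[i, ] + a[j] * V[j, cols]
    }
    out <- cbind(out, O)
  }
  out %*% W_O
}

# brute-force minimum-cost assignment by enumeration (small instances)
brute_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  k <- min(n, m)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- Inf
  rows <- utils::combn(n, k)
  for (ri in seq_len(ncol(rows))) {
    for (cs in perms(seq_len(m))) {
      tot <- sum(cost[cbind(rows[, ri], cs[seq_len(k)])])
      best <- min(best, tot)
    }
  }
  best
}

clear_mot_switches <- function(tracks, truth, T_) {
  n <- length(truth$ids)
  lastmatch <- rep(NA_integer_, n)
  switches <- 0L
  for (t in seq_len(T_)) {
    pf <- tracks[tracks$frame == t, ]
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
  }
  switches
}
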