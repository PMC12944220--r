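# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Values are plain numeric vectors, matrices or 3-D arrays (H x W x C).
# Each forward op appends a node to a global tape; ag_backward() walks the
# tape in reverse, calling each node's backfn with the accumulated upstream
# gradient. Parameters (ag_param) live off-tape and keep their gradients
# until ag_zero_grad(). One tape per training step: call ag_tape_reset()
# before every forward pass.

.ag <- new.env(parent = emptyenv())
.ag$tape <- vector("list", 256L)
.ag$n <- 0L

ag_tape_reset <- function() {
  if (.ag$n > 0L) .ag$tape[seq_len(.ag$n)] <- list(NULL)
  .ag$n <- 0L
  invisible(NULL)
}

ag_node <- function(value, track = TRUE, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$track <- track
  nd$backfn <- backfn
  class(nd) <- "ag_node"
  if (track && !is.null(backfn)) {
    n <- .ag$n + 1L
    if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
    .ag$tape[[n]] <- nd
    .ag$n <- n
  }
  nd
}

#' @keywords internal
ag_param <- function(value) {
  nd <- ag_node(value, track = TRUE, backfn = NULL)
  class(nd) <- c("ag_param", "ag_node")
  nd
}

ag_const <- function(value) ag_node(value, track = FALSE, backfn = NULL)

is_ag <- function(x) inherits(x, "ag_node")
as_node <- function(x) if (is_ag(x)) x else ag_const(x)

ag_accum <- function(nd, g) {
  if (!nd$track) return(invisible(NULL))
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$value) == 1L)
  loss$grad <- 1
  if (!is.null(loss$backfn)) loss$backfn(loss)
  # loss is the last tape node; walk the rest in reverse
  if (.ag$n >= 1L) {
    for (i in rev(seq_len(.ag$n))) {
      nd <- .ag$tape[[i]]
      if (identical(nd, loss)) next
      if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd)
    }
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise ----

ag_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$value + b$value, backfn = function(nd) {
    ag_accum(a, nd$grad); ag_accum(b, nd$grad)
  })
}

ag_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$value - b$value, backfn = function(nd) {
    ag_accum(a, nd$grad); ag_accum(b, -nd$grad)
  })
}

ag_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$value * b$value, backfn = function(nd) {
    ag_accum(a, nd$grad * b$value); ag_accum(b, nd$grad * a$value)
  })
}

# multiply / shift by plain constants (cheaper, no node for the constant)
ag_scale <- function(a, k) {
  ag_node(a$value * k, backfn = function(nd) ag_accum(a, nd$grad * k))
}

ag_square <- function(a) ag_mul(a, a)

ag_abs <- function(a) {
  s <- sign(a$value)
  ag_node(abs(a$value), backfn = function(nd) ag_accum(a, nd$grad * s))
}

ag_exp <- function(a) {
  v <- exp(a$value)
  ag_node(v, backfn = function(nd) ag_accum(a, nd$grad * v))
}

ag_log <- function(a) {
  ag_node(log(a$value), backfn = function(nd) ag_accum(a, nd$grad / a$value))
}

ag_clamp <- function(a, lo, hi) {
  v <- pmin(pmax(a$value, lo), hi)
  pass <- (a$value >= lo) & (a$value <= hi)
  ag_node(v, backfn = function(nd) ag_accum(a, nd$grad * pass))
}

ag_relu <- function(a) {
  pos <- a$value > 0
  ag_node(a$value * pos, backfn = function(nd) ag_accum(a, nd$grad * pos))
}

ag_leaky_relu <- function(a, slope = 0.2) {
  m <- ifelse(a$value > 0, 1, slope)
  ag_node(a$value * m, backfn = function(nd) ag_accum(a, nd$grad * m))
}

ag_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$value))
  ag_node(v, backfn = function(nd) ag_accum(a, nd$grad * v * (1 - v)))
}

ag_tanh <- function(a) {
  v <- tanh(a$value)
  ag_node(v, backfn = function(nd) ag_accum(a, nd$grad * (1 - v * v)))
}

ag_softplus <- function(a) {
  x <- a$value
  v <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  s <- 1 / (1 + exp(-x))
  ag_node(v, backfn = function(nd) ag_accum(a, nd$grad * s))
}

# ---- reductions ----

ag_sum <- function(a) {
  n_el <- length(a$value)
  ag_node(sum(a$value), backfn = function(nd) {
    g <- a$value; g[] <- nd$grad
    ag_accum(a, g)
  })
}

ag_mean <- function(a) {
  n_el <- length(a$value)
  ag_node(mean(a$value), backfn = function(nd) {
    g <- a$value; g[] <- nd$grad / n_el
    ag_accum(a, g)
  })
}

# ---- matrix ops ----

ag_matmul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$value %*% b$value, backfn = function(nd) {
    ag_accum(a, nd$grad %*% t(b$value))
    ag_accum(b, t(a$value) %*% nd$grad)
  })
}

# A %*% t(B)
ag_matmul_t <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$value %*% t(b$value), backfn = function(nd) {
    ag_accum(a, nd$grad %*% b$value)
    ag_accum(b, t(nd$grad) %*% a$value)
  })
}

# add a length-ncol bias vector to every row of a matrix
ag_add_bias_cols <- function(m, b) {
  ag_node(sweep(m$value, 2L, b$value, "+"), backfn = function(nd) {
    ag_accum(m, nd$grad)
    ag_accum(b, colSums(nd$grad))
  })
}

ag_concat_cols <- function(a, b) {
  ca <- ncol(a$value)
  ag_node(cbind(a$value, b$value), backfn = function(nd) {
    ag_accum(a, nd$grad[, seq_len(ca), drop = FALSE])
    ag_accum(b, nd$grad[, -seq_len(ca), drop = FALSE])
  })
}

ag_rows <- function(m, idx) {
  ag_node(m$value[idx, , drop = FALSE], backfn = function(nd) {
    g <- matrix(0, nrow(m$value), ncol(m$value))
    g[idx, ] <- nd$grad
    ag_accum(m, g)
  })
}

ag_mean_rows <- function(m) {
  n <- nrow(m$value)
  ag_node(matrix(colMeans(m$value), 1L), backfn = function(nd) {
    ag_accum(m, matrix(rep(nd$grad / n, each = n), n))
  })
}

ag_softmax_rows <- function(m) {
  x <- m$value
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  s <- e / rowSums(e)
  ag_node(s, backfn = function(nd) {
    dot <- rowSums(nd$grad * s)
    ag_accum(m, (nd$grad - dot) * s)
  })
}

ag_layernorm_rows <- function(m, gamma, beta, eps = 1e-5) {
  x <- m$value
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  ag_node(y, backfn = function(nd) {
    dxhat <- sweep(nd$grad, 2L, gamma$value, "*")
    ag_accum(gamma, colSums(nd$grad * xhat))
    ag_accum(beta, colSums(nd$grad))
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    ag_accum(m, dx)
  })
}

# ---- 2-D slicing (single-channel maps as matrices) ----

ag_mat_slice <- function(m, ri, ci) {
  ag_node(m$value[ri, ci, drop = FALSE], backfn = function(nd) {
    g <- matrix(0, nrow(m$value), ncol(m$value))
    g[ri, ci] <- nd$grad
    ag_accum(m, g)
  })
}

# ---- H x W x C array ops ----

ag_concat_chan <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(da[1] == db[1], da[2] == db[2])
  v <- array(c(a$value, b$value), c(da[1], da[2], da[3] + db[3]))
  ag_node(v, backfn = function(nd) {
    ag_accum(a, nd$grad[, , seq_len(da[3]), drop = FALSE])
    ag_accum(b, nd$grad[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

ag_avgpool2 <- function(a) {
  d <- dim(a$value)
  H <- d[1]; W <- d[2]
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  x <- a$value
  v <- (x[io, jo, , drop = FALSE] + x[io + 1L, jo, , drop = FALSE] +
        x[io, jo + 1L, , drop = FALSE] + x[io + 1L, jo + 1L, , drop = FALSE]) / 4
  ag_node(v, backfn = function(nd) {
    g <- array(0, d)
    q <- nd$grad / 4
    g[io, jo, ] <- q; g[io + 1L, jo, ] <- q
    g[io, jo + 1L, ] <- q; g[io + 1L, jo + 1L, ] <- q
    ag_accum(a, g)
  })
}

ag_upsample2 <- function(a) {
  d <- dim(a$value)
  ri <- rep(seq_len(d[1]), each = 2L); ci <- rep(seq_len(d[2]), each = 2L)
  ag_node(a$value[ri, ci, , drop = FALSE], backfn = function(nd) {
    io <- seq(1L, 2L * d[1], 2L); jo <- seq(1L, 2L * d[2], 2L)
    g <- nd$grad[io, jo, , drop = FALSE] + nd$grad[io + 1L, jo, , drop = FALSE] +
      nd$grad[io, jo + 1L, , drop = FALSE] + nd$grad[io + 1L, jo + 1L, , drop = FALSE]
    ag_accum(a, g)
  })
}

ag_global_meanpool <- function(a) {
  d <- dim(a$value)
  n <- d[1] * d[2]
  m <- a$value; dim(m) <- c(n, d[3])
  ag_node(matrix(colMeans(m), 1L), backfn = function(nd) {
    g <- array(rep(as.vector(nd$grad) / n, each = n), d)
    ag_accum(a, g)
  })
}

# tile a 1 x C row vector to an H x W x C array
ag_tile_vec <- function(e, H, W) {
  C <- length(e$value)
  ag_node(array(rep(as.vector(e$value), each = H * W), c(H, W, C)),
          backfn = function(nd) {
    g <- nd$grad; dim(g) <- c(H * W, C)
    ag_accum(e, matrix(colSums(g), 1L))
  })
}

# per-channel normalization over the spatial extent (batch-norm over a
# single-image batch), learnable gain/shift
ag_chan_norm <- function(a, gamma, beta, eps = 1e-5) {
  d <- dim(a$value)
  n <- d[1] * d[2]
  x <- a$value; dim(x) <- c(n, d[3])
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  dim(y) <- d
  ag_node(y, backfn = function(nd) {
    g <- nd$grad; dim(g) <- c(n, d[3])
    dxhat <- sweep(g, 2L, gamma$value, "*")
    ag_accum(gamma, colSums(g * xhat))
    ag_accum(beta, colSums(g))
    dx <- sweep(dxhat - rep(colMeans(dxhat), each = n) -
                  xhat * rep(colMeans(dxhat * xhat), each = n), 2L, inv, "*")
    dim(dx) <- d
    ag_accum(a, dx)
  })
}

# ---- convolution ----

# weight layout: matrix (kh*kw*cin, cout); row index = (b-1)*cin + c where
# block b = (q-1)*kh + p over kernel positions (p = row, q = col)
conv_weight_from_array <- function(w4) {
  d <- dim(w4)  # kh, kw, cin, cout
  kh <- d[1]; kw <- d[2]; cin <- d[3]; cout <- d[4]
  wm <- matrix(0, kh * kw * cin, cout)
  for (b in seq_len(kh * kw)) {
    p <- (b - 1L) %% kh + 1L
    q <- (b - 1L) %/% kh + 1L
    wm[(b - 1L) * cin + seq_len(cin), ] <- w4[p, q, , ]
  }
  wm
}

pad_hwc <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  xp
}

ag_conv2d <- function(x, w, b, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  xv <- x$value
  d <- dim(xv)
  stopifnot(length(d) == 3L)
  H <- d[1]; W <- d[2]; cin <- d[3]
  cout <- ncol(w$value)
  stopifnot(nrow(w$value) == k * k * cin)
  xp <- pad_hwc(xv, pad)
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  if (Ho < 1L || Wo < 1L) stop("convolution input too small for kernel")
  nb <- k * k
  P <- matrix(0, Ho * Wo, nb * cin)
  for (blk in seq_len(nb)) {
    p <- (blk - 1L) %% k + 1L
    q <- (blk - 1L) %/% k + 1L
    ri <- seq(p, by = stride, length.out = Ho)
    ci <- seq(q, by = stride, length.out = Wo)
    s <- xp[ri, ci, , drop = FALSE]
    dim(s) <- c(Ho * Wo, cin)
    P[, (blk - 1L) * cin + seq_len(cin)] <- s
  }
  Y <- P %*% w$value
  Y <- sweep(Y, 2L, b$value, "+")
  dim(Y) <- c(Ho, Wo, cout)
  ag_node(Y, backfn = function(nd) {
    G <- nd$grad; dim(G) <- c(Ho * Wo, cout)
    ag_accum(w, crossprod(P, G))
    ag_accum(b, colSums(G))
    if (x$track) {
      dP <- tcrossprod(G, w$value)
      dxp <- array(0, dim(xp))
      for (blk in seq_len(nb)) {
        p <- (blk - 1L) %% k + 1L
        q <- (blk - 1L) %/% k + 1L
        ri <- seq(p, by = stride, length.out = Ho)
        ci <- seq(q, by = stride, length.out = Wo)
        s <- dP[, (blk - 1L) * cin + seq_len(cin)]
        dim(s) <- c(Ho, Wo, cin)
        dxp[ri, ci, ] <- dxp[ri, ci, , drop = FALSE] + s
      }
      if (pad > 0L) dxp <- dxp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
      ag_accum(x, dxp)
    }
  })
}

# ---- bilinear ROI crop-resize (differentiable w.r.t. the feature map) ----

scatter_add <- function(vec, idx, vals) {
  s <- rowsum(vals, idx)
  at <- as.integer(rownames(s))
  vec[at] <- vec[at] + as.vector(s)
  vec
}

roi_grid <- function(box, H, W, oh, ow) {
  # box = [x, y, w, h], 0-based pixel coords; sample at output-cell centers
  u <- box[1] + (seq_len(ow) - 0.5) / ow * box[3]
  v <- box[2] + (seq_len(oh) - 0.5) / oh * box[4]
  cu <- pmin(pmax(u, 0), W - 1)
  cv <- pmin(pmax(v, 0), H - 1)
  j0 <- pmin(floor(cu), W - 2); j1 <- j0 + 1; wx <- cu - j0
  i0 <- pmin(floor(cv), H - 2); i1 <- i0 + 1; wy <- cv - i0
  if (H == 1L) { i0 <- i1 <- rep(0, oh); wy <- rep(0, oh) }
  if (W == 1L) { j0 <- j1 <- rep(0, ow); wx <- rep(0, ow) }
  # expand to oh*ow grid, row-fast (column-major in the output matrix)
  I0 <- rep(i0, times = ow); I1 <- rep(i1, times = ow)
  J0 <- rep(j0, each = oh); J1 <- rep(j1, each = oh)
  WY <- rep(wy, times = ow); WX <- rep(wx, each = oh)
  list(
    idx = cbind(I0 + 1 + H * J0, I1 + 1 + H * J0, I0 + 1 + H * J1, I1 + 1 + H * J1),
    w = cbind((1 - WY) * (1 - WX), WY * (1 - WX), (1 - WY) * WX, WY * WX)
  )
}

ag_roi_resize <- function(x, box, oh = 14L, ow = 14L) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]
  g <- roi_grid(box, H, W, oh, ow)
  plane <- H * W
  xf <- as.vector(x$value)
  out <- array(0, c(oh, ow, C))
  for (cc in seq_len(C)) {
    off <- (cc - 1L) * plane
    out[, , cc] <- matrix(
      g$w[, 1] * xf[g$idx[, 1] + off] + g$w[, 2] * xf[g$idx[, 2] + off] +
      g$w[, 3] * xf[g$idx[, 3] + off] + g$w[, 4] * xf[g$idx[, 4] + off], oh, ow)
  }
  ag_node(out, backfn = function(nd) {
    if (!x$track) return(invisible(NULL))
    dx <- numeric(plane * C)
    for (cc in seq_len(C)) {
      off <- (cc - 1L) * plane
      gv <- as.vector(nd$grad[, , cc])
      for (corner in 1:4)
        dx <- scatter_add(dx, g$idx[, corner] + off, gv * g$w[, corner])
    }
    dim(dx) <- d
    ag_accum(x, dx)
  })
}

# ---- parameter utilities ----

ag_collect_params <- function(x) {
  out <- list()
  rec <- function(e) {
    if (inherits(e, "ag_param")) out[[length(out) + 1L]] <<- e
    else if (is.list(e)) for (el in e) rec(el)
  }
  rec(x)
  out
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p$value * 0, v = p$value * 0, t = 0L))
}

adam_step <- function(params, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    st <- state[[i]]
    st$t <- st$t + 1L
    st$m <- beta1 * st$m + (1 - beta1) * p$grad
    st$v <- beta2 * st$v + (1 - beta2) * p$grad^2
    mh <- st$m / (1 - beta1^st$t)
    vh <- st$v / (1 - beta2^st$t)
    p$value <- p$value - lr * mh / (sqrt(vh) + eps)
    state[[i]] <- st
  }
  state
}

# He-normal initializers (draw from the caller's RNG stream)
init_conv_w <- function(k, cin, cout) {
  ag_param(matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                  k * k * cin, cout))
}
init_dense_w <- function(cin, cout) {
  ag_param(matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout))
}
init_bias <- function(n, value = 0) ag_param(rep(value, n))
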