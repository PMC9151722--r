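# Minimal neural-network layer library with explicit backpropagation.
#
# There is no deep-learning runtime in the supported environment, so the
# layers the three networks need are implemented directly in vectorized R:
# dilated 3x3 convolution, 2x2 max pooling, 2x2 stride-2 transposed
# convolution, dense layers, global average pooling, LSTM, and fused
# softmax losses. Every op is a pair fwd(...) -> list(out, cache) /
# bwd(cache, grad_out) -> gradients, and all are covered by
# finite-difference gradient checks in the test suite.
#
# Data layout for spatial tensors: a matrix of dim (C, H*W*N) where the
# column index runs over spatial position hw = h + H*(w-1) fastest, then
# batch element n. Dense activations are (features, N) matrices. LSTM
# sequences are (features, N, T) arrays.

.geom_cache <- new.env(parent = emptyenv())

geom_memo <- function(key, fn) {
  if (is.null(.geom_cache[[key]])) assign(key, fn(), envir = .geom_cache)
  .geom_cache[[key]]
}

# Column indices of the un-padded H x W grid inside the (H+2p) x (W+2p) grid.
pad_cols <- function(H, W, p) {
  geom_memo(sprintf("pad_%d_%d_%d", H, W, p), function() {
    h <- rep(seq_len(H), W); w <- rep(seq_len(W), each = H)
    (h + p) + (H + 2L * p) * (w + p - 1L)
  })
}

# For each output position (h, w), the padded-grid column of (h+dy, w+dx)
# relative to the padded origin (offsets include the +p shift).
shift_cols <- function(H, W, p, dy, dx) {
  geom_memo(sprintf("shift_%d_%d_%d_%d_%d", H, W, p, dy, dx), function() {
    h <- rep(seq_len(H), W); w <- rep(seq_len(W), each = H)
    (h + p + dy) + (H + 2L * p) * (w + p + dx - 1L)
  })
}

# Expand per-position indices across a batch of N blocks of stride `blk`.
# `key` must uniquely identify `idx` (callers pass their own memo key).
expand_cols <- function(key, idx, blk, N) {
  geom_memo(sprintf("exp_%s_%d_%d", key, blk, N),
            function() rep(idx, N) + rep((seq_len(N) - 1L) * blk,
                                         each = length(idx)))
}

conv_offsets <- function(d) {
  o <- expand.grid(dy = c(-d, 0L, d), dx = c(-d, 0L, d))
  o[order(o$dx, o$dy), ]
}

# 3x3 convolution, stride 1, dilation d, "same" zero padding.
# W: array (Cin, Cout, 9); b: length Cout. The im2col + GEMM kernel lives
# in src/conv_ops.cpp; offset ordering matches conv_offsets().
conv2d_fwd <- function(X, W, b, H, Wd, N, d = 1L) {
  if (length(dim(W)) == 3L) {
    Cin <- dim(W)[1]; Cout <- dim(W)[2]
    Wmat <- matrix(aperm(W, c(1, 3, 2)), 9L * Cin, Cout)
  } else {
    Cin <- nrow(W) %/% 9L; Cout <- ncol(W); Wmat <- W
  }
  Y <- .cpp_conv2d_fwd(X, Wmat, b, H, Wd, N, d)
  list(out = Y, cache = list(X = X, Wmat = Wmat, Cin = Cin, Cout = Cout,
                             H = H, Wd = Wd, N = N, d = d))
}

conv2d_bwd <- function(cache, dY, array_form = TRUE) {
  r <- .cpp_conv2d_bwd(cache$X, cache$Wmat, dY, cache$H, cache$Wd, cache$N,
                       cache$d)
  dW <- if (array_form)
    aperm(array(r$dW, c(cache$Cin, 9L, cache$Cout)), c(1, 3, 2))
  else r$dW
  list(dX = r$dX, dW = dW, db = as.numeric(r$db))
}

# 2x2 max pooling, stride 2; odd sizes are padded (with -Inf) to even first.
maxpool_fwd <- function(X, H, Wd, N) {
  C <- nrow(X)
  He <- H + H %% 2L; We <- Wd + Wd %% 2L
  Ho <- He %/% 2L; Wo <- We %/% 2L
  Xp <- matrix(-Inf, C, He * We * N)
  pc <- geom_memo(sprintf("mpad_%d_%d", H, Wd), function() {
    h <- rep(seq_len(H), Wd); w <- rep(seq_len(Wd), each = H)
    h + He * (w - 1L)
  })
  pce <- expand_cols(sprintf("mpad_%d_%d", H, Wd), pc, He * We, N)
  Xp[, pce] <- X
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  gexp <- lapply(offs, function(o) {
    key <- sprintf("mg_%d_%d_%d_%d", H, Wd, o[1], o[2])
    g <- geom_memo(key, function() {
      i <- rep(seq_len(Ho), Wo); j <- rep(seq_len(Wo), each = Ho)
      (2L * i - 1L + o[1]) + He * (2L * j - 2L + o[2])
    })
    expand_cols(key, g, He * We, N)
  })
  cur <- Xp[, gexp[[1]], drop = FALSE]
  sel <- matrix(1L, nrow(cur), ncol(cur))
  for (k in 2:4) {
    Mk <- Xp[, gexp[[k]], drop = FALSE]
    upd <- Mk > cur
    sel[upd] <- k
    cur[upd] <- Mk[upd]
  }
  list(out = cur,
       cache = list(sel = sel, N = N, He = He, We = We, C = C,
                    gexp = gexp, pce = pce))
}

maxpool_bwd <- function(cache, dY) {
  dXp <- matrix(0, cache$C, cache$He * cache$We * cache$N)
  for (k in 1:4) {
    contrib <- dY * (cache$sel == k)
    g <- cache$gexp[[k]]
    dXp[, g] <- dXp[, g, drop = FALSE] + contrib
  }
  list(dX = dXp[, cache$pce, drop = FALSE])
}

# 2x2 transposed convolution, stride 2 (exact 2x upsampling).
# W: array (Cin, Cout, 4), offsets ordered (0,0),(1,0),(0,1),(1,1).
deconv_fwd <- function(X, W, b, H, Wd, N) {
  Cout <- dim(W)[2]
  Ho <- 2L * H; Wo <- 2L * Wd
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  Y <- matrix(0, Cout, Ho * Wo * N)
  oidx <- vector("list", 4)
  for (k in 1:4) {
    key <- sprintf("dcg_%d_%d_%d_%d", H, Wd, offs[[k]][1], offs[[k]][2])
    dy <- offs[[k]][1]; dx <- offs[[k]][2]
    o <- geom_memo(key, function() {
      h <- rep(seq_len(H), Wd); w <- rep(seq_len(Wd), each = H)
      (2L * h - 1L + dy) + Ho * (2L * w - 2L + dx)
    })
    oidx[[k]] <- expand_cols(key, o, Ho * Wo, N)
    Y[, oidx[[k]]] <- crossprod(array(W[, , k], dim(W)[1:2]), X)
  }
  Y <- Y + b
  list(out = Y, cache = list(X = X, W = W, oidx = oidx, H = H, Wd = Wd,
                             N = N))
}

deconv_bwd <- function(cache, dY) {
  W <- cache$W; X <- cache$X
  dW <- array(0, dim(W))
  dX <- matrix(0, nrow(X), ncol(X))
  for (k in 1:4) {
    dYk <- dY[, cache$oidx[[k]], drop = FALSE]
    dW[, , k] <- tcrossprod(X, dYk)
    dX <- dX + array(W[, , k], dim(W)[1:2]) %*% dYk
  }
  list(dX = dX, dW = dW, db = rowSums(dY))
}

# Crop a (H, W) spatial grid down to its top-left (Ho, Wo) corner.
crop_fwd <- function(X, H, Wd, N, Ho, Wo) {
  key <- sprintf("crop_%d_%d_%d_%d", H, Wd, Ho, Wo)
  sel <- geom_memo(key, function() {
    h <- rep(seq_len(Ho), Wo); w <- rep(seq_len(Wo), each = Ho)
    h + H * (w - 1L)
  })
  sele <- expand_cols(key, sel, H * Wd, N)
  list(out = X[, sele, drop = FALSE],
       cache = list(sele = sele, C = nrow(X), ncol = ncol(X)))
}

crop_bwd <- function(cache, dY) {
  dX <- matrix(0, cache$C, cache$ncol)
  dX[, cache$sele] <- dY
  list(dX = dX)
}

relu_fwd <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_bwd <- function(cache, dY) list(dX = dY * cache)

dense_fwd <- function(X, W, b) {
  list(out = W %*% X + b, cache = list(X = X, W = W))
}
dense_bwd <- function(cache, dY) {
  list(dX = crossprod(cache$W, dY), dW = tcrossprod(dY, cache$X),
       db = rowSums(dY))
}

sigmoid_fwd <- function(X) {
  Y <- 1 / (1 + exp(-X))
  list(out = Y, cache = Y)
}
sigmoid_bwd <- function(cache, dY) list(dX = dY * cache * (1 - cache))

# Global average pooling over the spatial grid: (C, HW*N) -> (C, N).
gap_fwd <- function(X, HW, N) {
  a <- array(X, c(nrow(X), HW, N))
  Y <- colMeans(aperm(a, c(2, 1, 3)))       # (C, N)
  list(out = Y, cache = list(HW = HW, N = N))
}
gap_bwd <- function(cache, dY) {
  list(dX = dY[, rep(seq_len(cache$N), each = cache$HW),
               drop = FALSE] / cache$HW)
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

# Fused softmax + focal loss head. logits: (K, N); targets: 0-based classes.
# Returns the batch-mean loss and the gradient w.r.t. the logits.
focal_head <- function(logits, targets, gamma, eps = 1e-7) {
  N <- ncol(logits)
  P <- softmax_cols(logits)
  ti <- cbind(as.integer(targets) + 1L, seq_len(N))
  pt <- pmin(pmax(P[ti], eps), 1)
  loss <- mean(-(1 - pt)^gamma * log(pt))
  fp <- gamma * (1 - pt)^(pmax(gamma - 1, 0)) * log(pt) - (1 - pt)^gamma / pt
  if (gamma == 0) fp <- -1 / pt
  G <- -P * rep(fp * pt, each = nrow(P))
  G[ti] <- G[ti] + fp * pt
  list(loss = loss, dlogits = G / N, probs = P)
}

# Single-direction LSTM over a (F, N, T) sequence. Gate row blocks: i,f,g,o.
lstm_fwd <- function(Xseq, Wx, Wh, b, reverse = FALSE) {
  Fdim <- dim(Xseq)[1]; N <- dim(Xseq)[2]; Tn <- dim(Xseq)[3]
  H <- ncol(Wh)
  h <- matrix(0, H, N); cst <- matrix(0, H, N)
  steps <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  Hseq <- array(0, c(H, N, Tn))
  cache <- vector("list", Tn)
  for (s in seq_along(steps)) {
    t <- steps[s]
    xt <- Xseq[, , t, drop = FALSE]; dim(xt) <- c(Fdim, N)
    z <- Wx %*% xt + Wh %*% h + b
    i <- 1 / (1 + exp(-z[1:H, , drop = FALSE]))
    f <- 1 / (1 + exp(-z[(H + 1):(2 * H), , drop = FALSE]))
    g <- tanh(z[(2 * H + 1):(3 * H), , drop = FALSE])
    o <- 1 / (1 + exp(-z[(3 * H + 1):(4 * H), , drop = FALSE]))
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    hp <- h
    h <- o * tc
    Hseq[, , t] <- h
    cache[[s]] <- list(t = t, xt = xt, h_prev = hp, c_prev = c_prev,
                       i = i, f = f, g = g, o = o, tc = tc)
  }
  list(out = Hseq, h_final = h,
       cache = list(steps = cache, Wx = Wx, Wh = Wh, Fdim = Fdim, N = N,
                    Tn = Tn, H = H))
}

# dHseq: (H, N, T) gradient on the full hidden sequence (or NULL);
# dh_final: gradient on the final hidden state (or NULL).
lstm_bwd <- function(cache, dHseq = NULL, dh_final = NULL) {
  Wx <- cache$Wx; Wh <- cache$Wh
  H <- cache$H; N <- cache$N; Tn <- cache$Tn; Fdim <- cache$Fdim
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4L * H)
  dX <- array(0, c(Fdim, N, Tn))
  dh <- matrix(0, H, N); dc <- matrix(0, H, N)
  for (s in rev(seq_len(Tn))) {
    st <- cache$steps[[s]]
    if (s == Tn && !is.null(dh_final)) dh <- dh + dh_final
    if (!is.null(dHseq)) dh <- dh + dHseq[, , st$t]
    do <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dz <- rbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    dWx <- dWx + tcrossprod(dz, st$xt)
    dWh <- dWh + tcrossprod(dz, st$h_prev)
    db <- db + rowSums(dz)
    dX[, , st$t] <- crossprod(Wx, dz)
    dh <- crossprod(Wh, dz)
    dc <- dc * st$f
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# Seeded uniform fan-in initialization for each parameter shape.
init_mat <- function(nr, nc, fan_in) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}
init_conv <- function(cin, cout, k = 9L) {
  lim <- 1 / sqrt(cin * k)
  matrix(stats::runif(cin * cout * k, -lim, lim), k * cin, cout)
}
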