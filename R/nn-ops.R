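# Tensor operations for the autodiff tape.
#
# Feature maps are (H, W, B, C) arrays, so that `dim(x) <- c(H*W*B, C)`
# exposes a (pixels*batch) x channels matrix view feeding BLAS directly.

# k x k same-padding convolution with optional dilation (stride 1).
# Evaluated as one im2col unfold (C++) plus one BLAS product; the input
# gradient is the convolution of the output gradient with the spatially
# flipped, channel-transposed kernel, so no scatter pass is needed.
nn_conv <- function(tp, x, w, b, dilation = 1L) {
  X <- tp_val(tp, x); W <- tp_val(tp, w); bias <- tp_val(tp, b)
  d <- dim(X)
  H <- d[1]; Wd <- d[2]; B <- d[3]; Cin <- d[4]
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cout <- dim(W)[4]
  HWB <- H * Wd * B
  Xcol <- cpp_im2col(X, H, Wd, B, Cin, kh, kw, as.integer(dilation))
  Wm <- W
  dim(Wm) <- c(kh * kw * Cin, Cout)
  val <- Xcol %*% Wm
  cpp_add_bias(val, bias)   # in place; val is freshly allocated
  dim(val) <- c(H, Wd, B, Cout)
  backward <- function(g) {
    gm <- g
    dim(gm) <- c(HWB, Cout)
    dW <- crossprod(Xcol, gm)
    dim(dW) <- dim(W)
    Wr <- aperm(W[kh:1, kw:1, , , drop = FALSE], c(1, 2, 4, 3))
    dim(Wr) <- c(kh * kw * Cout, Cin)
    dX <- cpp_im2col(g, H, Wd, B, Cout, kh, kw, as.integer(dilation)) %*% Wr
    dim(dX) <- d
    list(dX, dW, colSums(gm))
  }
  tp_push(tp, val, c(x, w, b), backward)
}

# 2x2 stride-2 transposed convolution (doubles H and W; kernel tiles do not
# overlap, so each output pixel receives exactly one contribution)
nn_convT2 <- function(tp, x, w, b) {
  X <- tp_val(tp, x); W <- tp_val(tp, w); bias <- tp_val(tp, b)
  d <- dim(X)
  H <- d[1]; Wd <- d[2]; B <- d[3]; Cin <- d[4]; Cout <- dim(W)[4]
  Ho <- 2L * H; Wo <- 2L * Wd
  Xm <- matrix(X, H * Wd * B, Cin)
  out <- array(rep(bias, each = Ho * Wo * B), c(Ho, Wo, B, Cout))
  for (a in 1:2) {
    for (bb in 1:2) {
      Wk <- matrix(W[a, bb, , ], Cin, Cout)
      prod <- array(Xm %*% Wk, c(H, Wd, B, Cout))
      ri <- seq.int(a, Ho, 2L); ci <- seq.int(bb, Wo, 2L)
      out[ri, ci, , ] <- out[ri, ci, , , drop = FALSE] + prod
    }
  }
  backward <- function(g) {
    dX <- matrix(0, H * Wd * B, Cin)
    dW <- array(0, dim(W))
    db <- numeric(Cout)
    for (a in 1:2) {
      for (bb in 1:2) {
        ri <- seq.int(a, Ho, 2L); ci <- seq.int(bb, Wo, 2L)
        gs <- matrix(g[ri, ci, , , drop = FALSE], H * Wd * B, Cout)
        Wk <- matrix(W[a, bb, , ], Cin, Cout)
        dX <- dX + gs %*% t(Wk)
        dW[a, bb, , ] <- crossprod(Xm, gs)
        db <- db + colSums(gs)
      }
    }
    list(array(dX, d), dW, db)
  }
  tp_push(tp, out, c(x, w, b), backward)
}

# 1x1 convolution (pure channel mixing)
nn_conv1 <- function(tp, x, w, b) {
  X <- tp_val(tp, x); W <- tp_val(tp, w); bias <- tp_val(tp, b)
  d <- dim(X)
  Cin <- d[4]; Cout <- ncol(W)
  m <- prod(d[1:3])
  val <- matrix(X, m, Cin) %*% W
  val <- val + matrix(bias, m, Cout, byrow = TRUE)
  backward <- function(g) {
    gm <- matrix(g, m, Cout)
    list(array(gm %*% t(W), d),
         crossprod(matrix(X, m, Cin), gm),
         colSums(gm))
  }
  tp_push(tp, array(val, c(d[1:3], Cout)), c(x, w, b), backward)
}

nn_maxpool2 <- function(tp, x) {
  X <- tp_val(tp, x)
  d <- dim(X)
  H <- d[1]; W <- d[2]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  ri <- list(seq.int(1L, H, 2L), seq.int(2L, H, 2L))
  ci <- list(seq.int(1L, W, 2L), seq.int(2L, W, 2L))
  s <- list(X[ri[[1]], ci[[1]], , , drop = FALSE], X[ri[[2]], ci[[1]], , , drop = FALSE],
            X[ri[[1]], ci[[2]], , , drop = FALSE], X[ri[[2]], ci[[2]], , , drop = FALSE])
  val <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  backward <- function(g) {
    dX <- array(0, d)
    taken <- array(FALSE, dim(val))
    pos <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
    for (k in 1:4) {
      m <- (s[[k]] == val) & !taken
      taken <- taken | m
      dX[ri[[pos[[k]][1]]], ci[[pos[[k]][2]]], , ] <- g * m
    }
    dX
  }
  tp_push(tp, val, x, function(g) list(backward(g)))
}

# batch normalization over (H, W, B) per channel; running statistics are
# stored in `state` (an environment) and are not trainable
nn_bn <- function(tp, x, gamma, beta, state, name, training,
                  momentum = 0.1, eps = 1e-5) {
  X <- tp_val(tp, x); gam <- tp_val(tp, gamma); bet <- tp_val(tp, beta)
  d <- dim(X)
  C <- d[4]; m <- prod(d[1:3])
  Xm <- X
  dim(Xm) <- c(m, C)
  if (training) {
    mu <- .colMeans(Xm, m, C)
    v <- .colMeans(Xm * Xm, m, C) - mu^2
    v[v < 0] <- 0
    inv <- 1 / sqrt(v + eps)
    fw <- cpp_bn_fwd(Xm, mu, inv, gam, bet)
    xhat <- fw$xhat
    st <- state[[name]]
    if (is.null(st)) st <- list(mean = numeric(C), var = rep(1, C))
    state[[name]] <- list(mean = (1 - momentum) * st$mean + momentum * mu,
                          var = (1 - momentum) * st$var + momentum * v)
    backward <- function(g) {
      gm <- g
      dim(gm) <- c(m, C)
      bwd <- cpp_bn_bwd(gm, xhat, gam, inv)
      dX <- bwd$dX
      dim(dX) <- d
      list(dX, bwd$dgam, bwd$dbet)
    }
  } else {
    st <- state[[name]]
    if (is.null(st)) st <- list(mean = numeric(C), var = rep(1, C))
    inv <- 1 / sqrt(st$var + eps)
    fw <- cpp_bn_fwd(Xm, st$mean, inv, gam, bet)
    xhat <- fw$xhat
    backward <- function(g) {
      gm <- g
      dim(gm) <- c(m, C)
      dX <- gm * matrix(gam * inv, m, C, byrow = TRUE)
      dim(dX) <- d
      list(dX, colSums(gm * xhat), colSums(gm))
    }
  }
  y <- fw$y
  dim(y) <- d
  tp_push(tp, y, c(x, gamma, beta), backward)
}

nn_relu <- function(tp, x) {
  X <- tp_val(tp, x)
  val <- cpp_relu(X)
  tp_push(tp, val, x, function(g) list(cpp_relu_bwd(g, val)))
}

nn_leaky_relu <- function(tp, x, slope = 0.2) {
  X <- tp_val(tp, x)
  pos <- X > 0
  val <- X * ifelse(pos, 1, slope)
  tp_push(tp, val, x, function(g) list(g * ifelse(pos, 1, slope)))
}

nn_elu <- function(tp, x) {
  X <- tp_val(tp, x)
  pos <- X > 0
  ex <- exp(pmin(X, 0)) - 1
  val <- ifelse(pos, X, ex)
  tp_push(tp, val, x, function(g) list(g * ifelse(pos, 1, ex + 1)))
}

nn_sigmoid <- function(tp, x) {
  X <- tp_val(tp, x)
  val <- 1 / (1 + exp(-X))
  tp_push(tp, val, x, function(g) list(g * val * (1 - val)))
}

nn_add <- function(tp, a, b) {
  tp_push(tp, tp_val(tp, a) + tp_val(tp, b), c(a, b), function(g) list(g, g))
}

# channel concatenation of two (H, W, B, C) maps
nn_concat_c <- function(tp, a, b) {
  A <- tp_val(tp, a); B_ <- tp_val(tp, b)
  da <- dim(A); db_ <- dim(B_)
  m <- prod(da[1:3])
  val <- array(cbind(matrix(A, m, da[4]), matrix(B_, m, db_[4])),
               c(da[1:3], da[4] + db_[4]))
  backward <- function(g) {
    gm <- matrix(g, m, da[4] + db_[4])
    list(array(gm[, seq_len(da[4]), drop = FALSE], da),
         array(gm[, da[4] + seq_len(db_[4]), drop = FALSE], db_))
  }
  tp_push(tp, val, c(a, b), backward)
}

# global average pool (H, W, B, C) -> (B, C)
nn_gap <- function(tp, x) {
  X <- tp_val(tp, x)
  d <- dim(X)
  hw <- d[1] * d[2]
  val <- matrix(.colMeans(matrix(X, hw, d[3] * d[4]), hw, d[3] * d[4]),
                d[3], d[4])
  backward <- function(g) {
    list(array(rep(as.vector(g) / hw, each = hw), d))
  }
  tp_push(tp, val, x, backward)
}

# dense layer on a (B, Cin) matrix
nn_dense <- function(tp, x, w, b) {
  X <- tp_val(tp, x); W <- tp_val(tp, w); bias <- tp_val(tp, b)
  val <- X %*% W + matrix(bias, nrow(X), ncol(W), byrow = TRUE)
  backward <- function(g) {
    list(g %*% t(W), crossprod(X, g), colSums(g))
  }
  tp_push(tp, val, c(x, w, b), backward)
}

# multiply a (H, W, B, C) map by a per-sample per-channel gate (B, C)
nn_channel_gate <- function(tp, x, gate) {
  X <- tp_val(tp, x); G <- tp_val(tp, gate)
  d <- dim(X)
  hw <- d[1] * d[2]
  G4 <- array(rep(as.vector(G), each = hw), d)
  backward <- function(g) {
    dG <- matrix(.colSums(matrix(g * X, hw, d[3] * d[4]), hw, d[3] * d[4]),
                 d[3], d[4])
    list(g * G4, dG)
  }
  tp_push(tp, X * G4, c(x, gate), backward)
}

# (H, W, B, C) <-> node-matrix views; rows are (y, x, b) with b slowest, so
# each sample occupies a contiguous block of H*W rows
nn_grid_to_nodes <- function(tp, x) {
  X <- tp_val(tp, x)
  d <- dim(X)
  m <- prod(d[1:3])
  tp_push(tp, matrix(X, m, d[4]), x, function(g) list(array(g, d)))
}

nn_nodes_to_grid <- function(tp, x, hwbc) {
  X <- tp_val(tp, x)
  tp_push(tp, array(X, hwbc), x, function(g) list(matrix(g, nrow(X), ncol(X))))
}

# ---- graph / attention primitives on node matrices -------------------------

nn_matmul <- function(tp, x, w) {
  X <- tp_val(tp, x); W <- tp_val(tp, w)
  tp_push(tp, X %*% W, c(x, w),
          function(g) list(g %*% t(W), crossprod(X, g)))
}

nn_gather_rows <- function(tp, x, idx) {
  X <- tp_val(tp, x)
  backward <- function(g) {
    dX <- matrix(0, nrow(X), ncol(X))
    rs <- rowsum(g, idx)
    dX[as.integer(rownames(rs)), ] <- rs
    list(dX)
  }
  tp_push(tp, X[idx, , drop = FALSE], x, backward)
}

nn_colcat <- function(tp, a, b) {
  A <- tp_val(tp, a); B_ <- tp_val(tp, b)
  ca <- ncol(A)
  backward <- function(g) {
    list(g[, seq_len(ca), drop = FALSE],
         g[, ca + seq_len(ncol(B_)), drop = FALSE])
  }
  tp_push(tp, cbind(A, B_), c(a, b), backward)
}

# matrix-vector product returning a plain vector (attention scores per edge)
nn_matvec <- function(tp, x, a) {
  X <- tp_val(tp, x); av <- tp_val(tp, a)
  val <- drop(X %*% av)
  backward <- function(g) {
    list(outer(g, av), drop(crossprod(X, g)))
  }
  tp_push(tp, val, c(x, a), backward)
}

# softmax over contiguous segments; `seg` must be sorted non-decreasing and
# cover 1..nseg.  When every segment has the same number of entries
# (`n_per_seg`), the max/sum reductions use a reshape instead of split().
nn_segment_softmax <- function(tp, e, seg, nseg, n_per_seg = NULL) {
  ev <- tp_val(tp, e)
  if (!is.null(n_per_seg)) {
    M <- matrix(ev, nrow = n_per_seg)
    mx <- do.call(pmax, lapply(seq_len(n_per_seg), function(r) M[r, ]))
    a <- exp(ev - rep(mx, each = n_per_seg))
    den <- .colSums(matrix(a, nrow = n_per_seg), n_per_seg, nseg)
    val <- a / rep(den, each = n_per_seg)
  } else {
    mx <- vapply(split(ev, seg), max, numeric(1))
    a <- exp(ev - mx[seg])
    den <- as.vector(rowsum(a, seg))
    val <- a / den[seg]
  }
  backward <- function(g) {
    if (!is.null(n_per_seg)) {
      s <- .colSums(matrix(g * val, nrow = n_per_seg), n_per_seg, nseg)
      list(val * (g - rep(s, each = n_per_seg)))
    } else {
      s <- as.vector(rowsum(g * val, seg))
      list(val * (g - s[seg]))
    }
  }
  tp_push(tp, val, e, backward)
}

# scale each row of an edge-feature matrix by an edge scalar
nn_rowscale <- function(tp, x, s) {
  X <- tp_val(tp, x); sv <- tp_val(tp, s)
  backward <- function(g) {
    list(g * sv, rowSums(g * X))
  }
  tp_push(tp, X * sv, c(x, s), backward)
}

# sum edge rows into their target segment (rows must be sorted by seg; every
# segment 1..nseg must be present)
nn_segment_sum <- function(tp, x, seg, nseg) {
  X <- tp_val(tp, x)
  val <- rowsum(X, seg)
  backward <- function(g) list(g[seg, , drop = FALSE])
  tp_push(tp, val, x, backward)
}

# ---- losses ----------------------------------------------------------------

# batch-aggregated smoothed soft Dice loss; `truth` is a constant array
nn_soft_dice_loss <- function(tp, pred, truth, smooth = 1) {
  P <- tp_val(tp, pred)
  I <- sum(P * truth)
  U <- sum(P) + sum(truth)
  val <- 1 - (2 * I + smooth) / (U + smooth)
  backward <- function(g) {
    den <- (U + smooth)
    list(g * (-(2 * truth * den - (2 * I + smooth)) / den^2))
  }
  tp_push(tp, val, pred, backward)
}
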