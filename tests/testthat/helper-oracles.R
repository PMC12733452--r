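# Independent reference implementations used as oracles, written against the
# definitions rather than the package internals.

# set-counting Dice / IoU on pixel index sets
set_dice <- function(pred, truth) {
  a <- which(pred > 0)
  b <- which(truth > 0)
  if (length(a) == 0 && length(b) == 0) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

set_iou <- function(pred, truth) {
  a <- which(pred > 0)
  b <- which(truth > 0)
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# double-loop multi-head graph attention: logits LeakyReLU(a^T [Wh_i||Wh_j]),
# softmax over N(i), weighted sum of Wh_j, per-head activation, concat heads
loop_gat <- function(h, neighbors, Wl, al, slope = 0.2, act = identity) {
  N <- nrow(h)
  K <- length(Wl)
  out <- NULL
  for (k in seq_len(K)) {
    W <- Wl[[k]]
    a <- al[[k]]
    Fp <- nrow(W)
    hk <- matrix(0, N, Fp)
    for (i in seq_len(N)) {
      nb <- neighbors[[i]]
      e <- numeric(length(nb))
      for (m in seq_along(nb)) {
        j <- nb[m]
        z <- sum(a * c(W %*% h[i, ], W %*% h[j, ]))
        e[m] <- if (z > 0) z else slope * z
      }
      alpha <- exp(e - max(e))
      alpha <- alpha / sum(alpha)
      acc <- numeric(Fp)
      for (m in seq_along(nb)) {
        acc <- acc + alpha[m] * as.vector(W %*% h[nb[m], ])
      }
      hk[i, ] <- act(acc)
    }
    out <- cbind(out, hk)
  }
  out
}

# brute-force cosine similarity matrix
brute_cosine <- function(Fm) {
  N <- nrow(Fm)
  S <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      ni <- sqrt(sum(Fm[i, ]^2))
      nj <- sqrt(sum(Fm[j, ]^2))
      S[i, j] <- if (ni < 1e-12 || nj < 1e-12) 0 else
        sum(Fm[i, ] * Fm[j, ]) / (ni * nj)
    }
  }
  S
}

# mask with given true-positive / false-positive / false-negative counts
confusion_masks <- function(tp, fp, fn, len = NULL) {
  len <- len %||% (tp + fp + fn + 10)
  truth <- numeric(len)
  pred <- numeric(len)
  truth[seq_len(tp + fn)] <- 1
  pred[seq_len(tp)] <- 1
  if (fp > 0) pred[tp + fn + seq_len(fp)] <- 1
  list(pred = pred, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_report <- function(image_size = 64, tumor_radius = 8, jitter = 0,
                        seed = 1, min_size = 5) {
  ph <- generate_phantom(phantom_params(image_size = image_size,
                                        tumor_radius = tumor_radius,
                                        boundary_jitter = jitter,
                                        seed = seed))
  anomaly_report(ph$image, ph$mask, min_size = min_size)
}
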