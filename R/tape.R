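# Reverse-mode autodiff tape.
#
# The segmentation networks are small enough to train on a CPU, so instead of
# binding to an external deep-learning framework the package records every
# tensor operation on a dynamic tape and replays it backwards.  Values are
# plain R arrays; feature maps use the (H, W, B, C) layout so that
# `matrix(x, ncol = C)` exposes a (pixels*batch) x channels view that feeds
# BLAS matrix products directly.

tp_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", 64L)
  tp$bw <- vector("list", 64L)
  tp$parents <- vector("list", 64L)
  tp$pname <- rep(NA_character_, 64L)
  tp$n <- 0L
  tp
}

tp_push <- function(tp, value, parents = integer(0), backward = NULL,
                    pname = NA_character_) {
  n <- tp$n + 1L
  if (n > length(tp$vals)) {
    len <- 2L * length(tp$vals)
    length(tp$vals) <- len
    length(tp$bw) <- len
    length(tp$parents) <- len
    tp$pname <- c(tp$pname, rep(NA_character_, len - length(tp$pname)))
  }
  tp$vals[[n]] <- value
  if (!is.null(backward)) tp$bw[[n]] <- backward
  tp$parents[[n]] <- parents
  tp$pname[n] <- pname
  tp$n <- n
  n
}

tp_val <- function(tp, id) {
  # force the id before touching tp$vals: nested op calls push nodes onto the
  # tape while their result id is still a lazy promise
  id <- as.integer(id)
  tp$vals[[id]]
}

# leaf holding an input or constant (no gradient tracked)
tp_const <- function(tp, value) tp_push(tp, value)

# leaf holding a named trainable parameter; gradients are collected under
# `name` by tp_backward()
tp_param <- function(tp, value, name) tp_push(tp, value, pname = name)

# Backpropagate from the (scalar) node `loss_id`; returns a named list of
# gradients for every parameter leaf that the loss depends on.
tp_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  grads[[loss_id]] <- 1
  pg <- list()
  for (i in seq.int(tp$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nm <- tp$pname[i]
    if (!is.na(nm)) {
      pg[[nm]] <- if (is.null(pg[[nm]])) g else pg[[nm]] + g
    }
    f <- tp$bw[[i]]
    if (!is.null(f)) {
      pgr <- f(g)
      ps <- tp$parents[[i]]
      for (k in seq_along(ps)) {
        gk <- pgr[[k]]
        if (is.null(gk)) next
        p <- ps[k]
        grads[[p]] <- if (is.null(grads[[p]])) gk else grads[[p]] + gk
      }
    }
    grads[i] <- list(NULL)
  }
  pg
}
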