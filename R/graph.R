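#' Build a feature-similarity graph from a spatial feature grid
#'
#' Nodes are the spatial locations of an `h x w x F` feature grid in
#' row-major order (node `(r, c)` has index `(r - 1) * w + c`).  Edge
#' weights are cosine similarities between node feature vectors; zero-norm
#' vectors are guarded (similarity 0).  In `"dense_cosine"` mode every node
#' pair is connected; in `"topk_cosine"` mode each node keeps its `k` most
#' similar non-self neighbors plus a self-loop.  Ties are broken by node
#' index, lowest first.
#'
#' @param feature_grid numeric array `h x w x F` (a plain `N x F` matrix is
#'   also accepted, treated as `N x 1 x F`).
#' @param mode `"dense_cosine"` or `"topk_cosine"`.
#' @param k neighbor budget for `"topk_cosine"`; `1 <= k <= N - 1`.
#' @return an object of class `sonoseg_graph` with `node_features` (`N x F`),
#'   `neighbors` (list of integer vectors, self included), `similarity`
#'   (`N x N`), `mode`, `k`, and the grid size.
#' @seealso [gat_attention()]
#' @export
build_graph_from_features <- function(feature_grid,
                                      mode = c("dense_cosine", "topk_cosine"),
                                      k = NULL) {
  mode <- match.arg(mode)
  d <- dim(feature_grid)
  if (is.matrix(feature_grid)) {
    gh <- nrow(feature_grid); gw <- 1L
    Fm <- feature_grid
  } else {
    stopifnot(length(d) == 3L)
    gh <- d[1]; gw <- d[2]
    # row-major node order: row index varies slowest
    Fm <- matrix(aperm(feature_grid, c(2, 1, 3)), gh * gw, d[3])
  }
  N <- gh * gw
  if (N < 2L) abort_sonoseg("need at least 2 nodes", class = "sonoseg_graph_error")
  if (all(Fm == 0)) {
    abort_sonoseg("degenerate features: all node feature vectors are zero",
                  class = "sonoseg_graph_error")
  }
  nr <- sqrt(rowSums(Fm^2))
  safe <- ifelse(nr < 1e-12, 1, nr)
  S <- tcrossprod(Fm / safe)
  S[nr < 1e-12, ] <- 0
  S[, nr < 1e-12] <- 0
  if (mode == "dense_cosine") {
    neighbors <- lapply(seq_len(N), function(i) seq_len(N))
  } else {
    if (is.null(k) || k < 1L || k > N - 1L) {
      abort_sonoseg("k must satisfy 1 <= k <= N - 1 for topk_cosine",
                    class = "sonoseg_graph_error")
    }
    neighbors <- lapply(seq_len(N), function(i) {
      s <- S[i, ]
      s[i] <- -Inf
      ord <- order(-s, seq_len(N))
      sort(c(i, ord[seq_len(k)]))
    })
  }
  structure(list(node_features = Fm, neighbors = neighbors, similarity = S,
                 mode = mode, k = if (mode == "topk_cosine") as.integer(k),
                 grid = c(gh, gw)),
            class = "sonoseg_graph")
}

#' Parameters for a multi-head graph attention layer
#'
#' @param W a single `F' x F` matrix or a list of them (one per head).
#' @param a a length-`2 F'` attention scoring vector or a list (one per head).
#' @param negative_slope LeakyReLU slope used in the attention logits.
#' @param activation nonlinearity applied to each head's aggregated output:
#'   `"elu"`, `"identity"`, or a function.
#' @return an object of class `sonoseg_gat_params`.
#' @export
gat_params <- function(W, a, negative_slope = 0.2, activation = "elu") {
  if (!is.list(W)) W <- list(W)
  if (!is.list(a)) a <- list(a)
  stopifnot(length(W) == length(a))
  Fp <- nrow(W[[1]])
  for (k in seq_along(W)) {
    stopifnot(nrow(W[[k]]) == Fp, length(a[[k]]) == 2L * Fp)
  }
  structure(list(W = W, a = a, negative_slope = negative_slope,
                 activation = activation),
            class = "sonoseg_gat_params")
}

#' Multi-head graph attention
#'
#' For each head, attention logits between node `i` and neighbor `j` are
#' `LeakyReLU(a^T [W h_i || W h_j])`, normalized with a softmax over the
#' neighbors of `i`; the updated feature of `i` is the attention-weighted sum
#' of transformed neighbor features, passed through the head activation.
#' Head outputs are concatenated, so the result has `K * F'` columns.
#'
#' @param graph a [sonoseg_graph][build_graph_from_features()].
#' @param params a [gat_params()] object.
#' @return `N x (K * F')` matrix of updated node features, with attention
#'   rows summing to one per head (returned as attribute `"alpha"`, a list of
#'   per-head lists of neighbor weights).
#' @export
gat_attention <- function(graph, params) {
  stopifnot(inherits(graph, "sonoseg_graph"), inherits(params, "sonoseg_gat_params"))
  h <- graph$node_features
  N <- nrow(h)
  cnt <- lengths(graph$neighbors)
  if (any(cnt == 0L)) {
    abort_sonoseg("node with empty neighbor set: attention cannot be normalized",
                  class = "sonoseg_graph_error")
  }
  edge_i <- rep.int(seq_len(N), cnt)
  edge_j <- unlist(graph$neighbors, use.names = FALSE)
  K <- length(params$W)
  act <- params$activation
  actf <- if (is.function(act)) act
  else switch(act,
              elu = function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
              identity = identity,
              abort_sonoseg("unknown activation"))
  outs <- vector("list", K)
  alphas <- vector("list", K)
  for (k in seq_len(K)) {
    Wh <- h %*% t(params$W[[k]])                       # N x F'
    z <- cbind(Wh[edge_i, , drop = FALSE], Wh[edge_j, , drop = FALSE])
    e <- drop(z %*% params$a[[k]])
    e <- ifelse(e > 0, e, params$negative_slope * e)
    mx <- vapply(split(e, edge_i), max, numeric(1))
    ex <- exp(e - mx[edge_i])
    den <- as.vector(rowsum(ex, edge_i))
    alpha <- ex / den[edge_i]
    agg <- rowsum(Wh[edge_j, , drop = FALSE] * alpha, edge_i)
    outs[[k]] <- actf(agg)
    alphas[[k]] <- split(alpha, edge_i)
  }
  res <- do.call(cbind, outs)
  attr(res, "alpha") <- alphas
  res
}
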