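#' Declare a segmentation network
#'
#' A model spec is a declarative description of one of the four segmentation
#' architectures; [build_model()] turns it into a trainable network.  All
#' architectures map an `H x W x C` slice to a per-pixel tumor probability in
#' `(0, 1)` (sigmoid head), with the output spatial size equal to the input.
#'
#' @param architecture one of `"unet"`, `"deeplab"`, `"gat"`, `"sgnn"`.
#' @param input_size integer `(H, W, C)`; `H` and `W` must be divisible by
#'   `2^depth` (and by the graph grid for the graph models). Default
#'   `c(256, 256, 3)`.
#' @param base_width channel count of the first U-Net/DeepLab stage
#'   (doubles per stage). Default 64.
#' @param depth number of encoder stages for `"unet"` / residual blocks for
#'   `"deeplab"`. Default 4.
#' @param aspp_rates dilation rates of the atrous spatial pyramid pooling
#'   branches of the DeepLab variant. Default `c(6, 12, 18)`.
#' @param heads number of attention heads of the graph models. Default 8.
#' @param head_dim per-head output width F' (head outputs are concatenated,
#'   so node embeddings have width `heads * head_dim`). Default 8.
#' @param top_k neighbor budget per node for the sparse graph model
#'   (`"sgnn"` only). Default 8.
#' @param graph_grid integer `(h, w)` node-grid size the conv stem
#'   downsamples to before graph construction. Default `c(16, 16)`.
#' @param attention_layers number of stacked attention layers. Default 2.
#' @param stem_width first stem channel count for the graph models
#'   (doubles per downsampling step, capped at 128). Default 32.
#' @param seed integer seed for weight initialization.
#'
#' @return an object of class `sonoseg_model_spec`.
#' @seealso [build_model()], [count_trainable_parameters()]
#' @export
model_spec <- function(architecture = c("unet", "deeplab", "gat", "sgnn"),
                       input_size = c(256L, 256L, 3L),
                       base_width = 64L,
                       depth = 4L,
                       aspp_rates = c(6L, 12L, 18L),
                       heads = 8L,
                       head_dim = 8L,
                       top_k = 8L,
                       graph_grid = c(16L, 16L),
                       attention_layers = 2L,
                       stem_width = 32L,
                       seed = 42L) {
  architecture <- match.arg(architecture)
  stopifnot(length(input_size) == 3L, all(input_size >= 1))
  input_size <- as.integer(input_size)
  H <- input_size[1]; W <- input_size[2]
  if (architecture %in% c("unet", "deeplab")) {
    if (H %% 2L^depth != 0L || W %% 2L^depth != 0L) {
      abort_sonoseg(sprintf(
        "input size %dx%d is not divisible by 2^depth = %d",
        H, W, 2L^depth), class = "sonoseg_spec_error")
    }
  }
  if (architecture %in% c("gat", "sgnn")) {
    gh <- graph_grid[1]; gw <- graph_grid[2]
    if (H %% gh != 0L || W %% gw != 0L) {
      abort_sonoseg(sprintf("graph grid %dx%d does not divide input %dx%d",
                            gh, gw, H, W), class = "sonoseg_spec_error")
    }
    rh <- H %/% gh; rw <- W %/% gw
    if (rh != rw || bitwAnd(rh, rh - 1L) != 0L) {
      abort_sonoseg("input/graph_grid ratio must be a power of two and equal in both axes",
                    class = "sonoseg_spec_error")
    }
    if (heads < 1L) abort_sonoseg("heads must be >= 1")
    if (architecture == "sgnn") {
      if (is.null(top_k) || is.na(top_k)) {
        abort_sonoseg("top_k must be set for the sgnn architecture",
                      class = "sonoseg_spec_error")
      }
      if (top_k >= gh * gw) {
        abort_sonoseg("top_k must be smaller than the number of graph nodes",
                      class = "sonoseg_spec_error")
      }
    }
  }
  if (architecture == "deeplab" && length(aspp_rates) == 0L) {
    abort_sonoseg("aspp_rates must contain at least one dilation rate",
                  class = "sonoseg_spec_error")
  }
  structure(list(architecture = architecture, input_size = input_size,
                 base_width = as.integer(base_width), depth = as.integer(depth),
                 aspp_rates = as.integer(aspp_rates), heads = as.integer(heads),
                 head_dim = as.integer(head_dim),
                 top_k = if (is.null(top_k)) NULL else as.integer(top_k),
                 graph_grid = as.integer(graph_grid),
                 attention_layers = as.integer(attention_layers),
                 stem_width = as.integer(stem_width),
                 seed = as.integer(seed)),
            class = "sonoseg_model_spec")
}

# ---- initializers ----------------------------------------------------------

# He truncated normal for convolution kernels (clipped at 2 sd)
init_he <- function(dims, fan_in) {
  sd <- sqrt(2 / fan_in)
  v <- stats::rnorm(prod(dims), sd = sd)
  array(pmin(pmax(v, -2 * sd), 2 * sd), dims)
}

# Glorot uniform for attention / dense parameters
init_glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  if (length(dims) == 1L) stats::runif(dims, -lim, lim)
  else array(stats::runif(prod(dims), -lim, lim), dims)
}

# ---- parameter store -------------------------------------------------------

param_store <- function() {
  ps <- new.env(parent = emptyenv())
  ps$params <- new.env(parent = emptyenv())
  ps$order <- character(0)
  ps
}

ps_add <- function(ps, name, value) {
  ps$params[[name]] <- value
  ps$order <- c(ps$order, name)
  invisible(name)
}

ps_add_conv <- function(ps, name, kh, kw, cin, cout) {
  ps_add(ps, paste0(name, "_w"), init_he(c(kh, kw, cin, cout), kh * kw * cin))
  ps_add(ps, paste0(name, "_b"), numeric(cout))
}

ps_add_bn <- function(ps, name, c) {
  ps_add(ps, paste0(name, "_g"), rep(1, c))
  ps_add(ps, paste0(name, "_s"), numeric(c))
}

new_seg_model <- function(spec, ps, forward, subclass) {
  trainable <- new.env(parent = emptyenv())
  for (nm in ps$order) trainable[[nm]] <- TRUE
  structure(list(spec = spec, params = ps$params, param_order = ps$order,
                 trainable = trainable, state = new.env(parent = emptyenv()),
                 forward = forward),
            class = c(subclass, "sonoseg_model"))
}

# ---- shared forward building blocks ----------------------------------------

# conv + BN + ReLU; `pget` maps a parameter name to a tape node
conv_bn_relu <- function(tp, x, name, pget, state, training, dilation = 1L) {
  y <- nn_conv(tp, x, pget(paste0(name, "_w")), pget(paste0(name, "_b")),
               dilation = dilation)
  y <- nn_bn(tp, y, pget(paste0(name, "_bn_g")), pget(paste0(name, "_bn_s")),
             state, paste0(name, "_bn"), training)
  nn_relu(tp, y)
}

#' Build a segmentation network from its spec
#'
#' Dispatches on `spec$architecture`.  Weights are initialized
#' deterministically from `spec$seed` (He truncated normal for convolutions,
#' Glorot uniform for attention and dense parameters).
#'
#' @param spec a [model_spec()].
#' @return an object of class `sonoseg_model` holding the parameter store and
#'   a forward closure.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "sonoseg_model_spec"))
  switch(spec$architecture,
         unet = build_unet(spec),
         deeplab = build_deeplab(spec),
         gat = build_gat_segmenter(spec),
         sgnn = build_sgnn_segmenter(spec))
}

#' @rdname build_model
#' @export
build_unet <- function(spec) {
  stopifnot(spec$architecture == "unet")
  base <- spec$base_width; depth <- spec$depth; cin <- spec$input_size[3]
  with_seed(spec$seed, {
    ps <- param_store()
    enc_w <- base * 2L^(seq_len(depth) - 1L)
    prev <- cin
    for (i in seq_len(depth)) {
      ps_add_conv(ps, sprintf("enc%d_1", i), 3, 3, prev, enc_w[i])
      ps_add_bn(ps, sprintf("enc%d_1_bn", i), enc_w[i])
      ps_add_conv(ps, sprintf("enc%d_2", i), 3, 3, enc_w[i], enc_w[i])
      ps_add_bn(ps, sprintf("enc%d_2_bn", i), enc_w[i])
      prev <- enc_w[i]
    }
    bot <- base * 2L^depth
    ps_add_conv(ps, "bot_1", 3, 3, prev, bot); ps_add_bn(ps, "bot_1_bn", bot)
    ps_add_conv(ps, "bot_2", 3, 3, bot, bot); ps_add_bn(ps, "bot_2_bn", bot)
    prev <- bot
    for (i in rev(seq_len(depth))) {
      ps_add_conv(ps, sprintf("up%d", i), 2, 2, prev, enc_w[i])  # transposed
      ps_add_conv(ps, sprintf("dec%d_1", i), 3, 3, 2L * enc_w[i], enc_w[i])
      ps_add_bn(ps, sprintf("dec%d_1_bn", i), enc_w[i])
      ps_add_conv(ps, sprintf("dec%d_2", i), 3, 3, enc_w[i], enc_w[i])
      ps_add_bn(ps, sprintf("dec%d_2_bn", i), enc_w[i])
      prev <- enc_w[i]
    }
    ps_add(ps, "head_w", init_glorot(c(prev, 1L), prev, 1L))
    ps_add(ps, "head_b", numeric(1))
  })
  model <- NULL
  forward <- function(tp, x, training = FALSE) {
    pget <- function(nm) tp_param(tp, model$params[[nm]], nm)
    st <- model$state
    skips <- vector("list", depth)
    h <- x
    for (i in seq_len(depth)) {
      h <- conv_bn_relu(tp, h, sprintf("enc%d_1", i), pget, st, training)
      h <- conv_bn_relu(tp, h, sprintf("enc%d_2", i), pget, st, training)
      skips[[i]] <- h
      h <- nn_maxpool2(tp, h)
    }
    h <- conv_bn_relu(tp, h, "bot_1", pget, st, training)
    h <- conv_bn_relu(tp, h, "bot_2", pget, st, training)
    for (i in rev(seq_len(depth))) {
      h <- nn_convT2(tp, h, pget(sprintf("up%d_w", i)), pget(sprintf("up%d_b", i)))
      h <- nn_concat_c(tp, h, skips[[i]])
      h <- conv_bn_relu(tp, h, sprintf("dec%d_1", i), pget, st, training)
      h <- conv_bn_relu(tp, h, sprintf("dec%d_2", i), pget, st, training)
    }
    h <- nn_conv1(tp, h, pget("head_w"), pget("head_b"))
    nn_sigmoid(tp, h)
  }
  model <- new_seg_model(spec, ps, forward, "sonoseg_unet")
  model
}

#' @rdname build_model
#' @export
build_deeplab <- function(spec) {
  stopifnot(spec$architecture == "deeplab")
  if (length(spec$aspp_rates) == 0L) {
    abort_sonoseg("aspp_rates must not be empty", class = "sonoseg_spec_error")
  }
  base <- spec$base_width; cin <- spec$input_size[3]
  widths <- base * 2L^pmin(seq_len(4L) - 1L, 3L)          # 64 128 256 512
  aspp_c <- 256L
  attn_bottleneck <- max(1L, widths[4] %/% 8L)
  dec_w <- c(aspp_c %/% 2L, aspp_c %/% 4L, aspp_c %/% 8L, aspp_c %/% 16L)
  with_seed(spec$seed, {
    ps <- param_store()
    ps_add_conv(ps, "stem", 3, 3, cin, widths[1]); ps_add_bn(ps, "stem_bn", widths[1])
    prev <- widths[1]
    for (i in 1:4) {
      ps_add_conv(ps, sprintf("res%d_1", i), 3, 3, prev, widths[i])
      ps_add_bn(ps, sprintf("res%d_1_bn", i), widths[i])
      ps_add_conv(ps, sprintf("res%d_2", i), 3, 3, widths[i], widths[i])
      ps_add_bn(ps, sprintf("res%d_2_bn", i), widths[i])
      if (prev != widths[i]) {
        ps_add(ps, sprintf("res%d_proj_w", i),
               init_glorot(c(prev, widths[i]), prev, widths[i]))
        ps_add(ps, sprintf("res%d_proj_b", i), numeric(widths[i]))
      }
      prev <- widths[i]
    }
    ps_add(ps, "ca_w1", init_glorot(c(prev, attn_bottleneck), prev, attn_bottleneck))
    ps_add(ps, "ca_b1", numeric(attn_bottleneck))
    ps_add(ps, "ca_w2", init_glorot(c(attn_bottleneck, prev), attn_bottleneck, prev))
    ps_add(ps, "ca_b2", numeric(prev))
    ps_add(ps, "aspp0_w", init_glorot(c(prev, aspp_c), prev, aspp_c))
    ps_add(ps, "aspp0_b", numeric(aspp_c))
    ps_add_bn(ps, "aspp0_bn", aspp_c)
    for (r in seq_along(spec$aspp_rates)) {
      ps_add_conv(ps, sprintf("aspp%d", r), 3, 3, prev, aspp_c)
      ps_add_bn(ps, sprintf("aspp%d_bn", r), aspp_c)
    }
    nb <- length(spec$aspp_rates) + 1L
    ps_add(ps, "fuse_w", init_glorot(c(nb * aspp_c, aspp_c), nb * aspp_c, aspp_c))
    ps_add(ps, "fuse_b", numeric(aspp_c))
    ps_add_bn(ps, "fuse_bn", aspp_c)
    prev <- aspp_c
    for (i in 1:4) {
      ps_add_conv(ps, sprintf("dec%d", i), 2, 2, prev, dec_w[i])  # transposed
      ps_add_bn(ps, sprintf("dec%d_bn", i), dec_w[i])
      prev <- dec_w[i]
    }
    ps_add(ps, "head_w", init_glorot(c(prev, 1L), prev, 1L))
    ps_add(ps, "head_b", numeric(1))
  })
  model <- NULL
  forward <- function(tp, x, training = FALSE) {
    pget <- function(nm) tp_param(tp, model$params[[nm]], nm)
    st <- model$state
    h <- conv_bn_relu(tp, x, "stem", pget, st, training)
    for (i in 1:4) {
      y <- conv_bn_relu(tp, h, sprintf("res%d_1", i), pget, st, training)
      y <- nn_conv(tp, y, pget(sprintf("res%d_2_w", i)), pget(sprintf("res%d_2_b", i)))
      y <- nn_bn(tp, y, pget(sprintf("res%d_2_bn_g", i)), pget(sprintf("res%d_2_bn_s", i)),
                 st, sprintf("res%d_2_bn", i), training)
      skip <- h
      if (!is.null(model$params[[sprintf("res%d_proj_w", i)]])) {
        skip <- nn_conv1(tp, h, pget(sprintf("res%d_proj_w", i)),
                         pget(sprintf("res%d_proj_b", i)))
      }
      h <- nn_relu(tp, nn_add(tp, y, skip))
      h <- nn_maxpool2(tp, h)
    }
    # global channel attention: squeeze -> two dense layers -> sigmoid gate
    p <- nn_gap(tp, h)
    p <- nn_relu(tp, nn_dense(tp, p, pget("ca_w1"), pget("ca_b1")))
    gate <- nn_sigmoid(tp, nn_dense(tp, p, pget("ca_w2"), pget("ca_b2")))
    h <- nn_channel_gate(tp, h, gate)
    # ASPP: one 1x1 branch plus one dilated 3x3 branch per rate
    branches <- list(conv1_bn_relu_branch(tp, h, "aspp0", pget, st, training))
    for (r in seq_along(spec$aspp_rates)) {
      branches[[r + 1L]] <- conv_bn_relu(tp, h, sprintf("aspp%d", r), pget, st,
                                         training, dilation = spec$aspp_rates[r])
    }
    h <- Reduce(function(a, b) nn_concat_c(tp, a, b), branches)
    h <- conv1_bn_relu_branch(tp, h, "fuse", pget, st, training)
    for (i in 1:4) {
      h <- nn_convT2(tp, h, pget(sprintf("dec%d_w", i)), pget(sprintf("dec%d_b", i)))
      h <- nn_bn(tp, h, pget(sprintf("dec%d_bn_g", i)), pget(sprintf("dec%d_bn_s", i)),
                 st, sprintf("dec%d_bn", i), training)
      h <- nn_relu(tp, h)
    }
    h <- nn_conv1(tp, h, pget("head_w"), pget("head_b"))
    nn_sigmoid(tp, h)
  }
  model <- new_seg_model(spec, ps, forward, "sonoseg_deeplab")
  model
}

conv1_bn_relu_branch <- function(tp, x, name, pget, state, training) {
  y <- nn_conv1(tp, x, pget(paste0(name, "_w")), pget(paste0(name, "_b")))
  y <- nn_bn(tp, y, pget(paste0(name, "_bn_g")), pget(paste0(name, "_bn_s")),
             state, paste0(name, "_bn"), training)
  nn_relu(tp, y)
}

# shared graph-segmenter builder; gat and sgnn differ only in how the
# adjacency is constructed from the stem features
build_graph_segmenter <- function(spec, subclass) {
  cin <- spec$input_size[3]
  gh <- spec$graph_grid[1]; gw <- spec$graph_grid[2]
  n_down <- as.integer(round(log2(spec$input_size[1] / gh)))
  stem_w <- pmin(spec$stem_width * 2L^(seq_len(max(n_down, 1L)) - 1L), 128L)
  Fstem <- stem_w[length(stem_w)]
  K <- spec$heads; Fp <- spec$head_dim; L <- spec$attention_layers
  emb <- K * Fp
  dec_w <- pmax(emb %/% 2L^seq_len(n_down), 4L)
  with_seed(spec$seed, {
    ps <- param_store()
    prev <- cin
    for (j in seq_len(n_down)) {
      ps_add_conv(ps, sprintf("stem%d", j), 3, 3, prev, stem_w[j])
      ps_add_bn(ps, sprintf("stem%d_bn", j), stem_w[j])
      prev <- stem_w[j]
    }
    fin <- Fstem
    for (l in seq_len(L)) {
      for (k in seq_len(K)) {
        ps_add(ps, sprintf("att%d_h%d_W", l, k), init_glorot(c(fin, Fp), fin, Fp))
        ps_add(ps, sprintf("att%d_h%d_a", l, k), init_glorot(2L * Fp, 2L * Fp, 1L))
      }
      fin <- emb
    }
    prev <- emb
    for (j in seq_len(n_down)) {
      ps_add_conv(ps, sprintf("dec%d", j), 2, 2, prev, dec_w[j])  # transposed
      ps_add_bn(ps, sprintf("dec%d_bn", j), dec_w[j])
      prev <- dec_w[j]
    }
    ps_add(ps, "head_w", init_glorot(c(prev, 1L), prev, 1L))
    ps_add(ps, "head_b", numeric(1))
  })
  mode <- if (subclass == "sonoseg_sgnn") "topk_cosine" else "dense_cosine"
  model <- NULL
  forward <- function(tp, x, training = FALSE) {
    pget <- function(nm) tp_param(tp, model$params[[nm]], nm)
    st <- model$state
    h <- x
    for (j in seq_len(n_down)) {
      h <- conv_bn_relu(tp, h, sprintf("stem%d", j), pget, st, training)
      h <- nn_maxpool2(tp, h)
    }
    dims <- dim(tp_val(tp, h))                     # (gh, gw, B, Fstem)
    B <- dims[3]
    N <- gh * gw
    nodes <- nn_grid_to_nodes(tp, h)               # (N*B, Fstem), sample-major
    # adjacency from the (detached) stem features; selection is not
    # differentiated through, gradients flow via the attention weights
    feats <- tp_val(tp, nodes)
    ed <- batched_cosine_edges(feats, N, B, mode, spec$top_k)
    hcur <- nodes
    for (l in seq_len(L)) {
      heads_out <- vector("list", K)
      for (k in seq_len(K)) {
        Wk <- pget(sprintf("att%d_h%d_W", l, k))
        ak <- pget(sprintf("att%d_h%d_a", l, k))
        Wh <- nn_matmul(tp, hcur, Wk)
        src <- nn_gather_rows(tp, Wh, ed$i)
        dst <- nn_gather_rows(tp, Wh, ed$j)
        e <- nn_leaky_relu(tp, nn_matvec(tp, nn_colcat(tp, src, dst), ak), 0.2)
        al <- nn_segment_softmax(tp, e, ed$i, N * B, n_per_seg = ed$n_per_seg)
        agg <- nn_segment_sum(tp, nn_rowscale(tp, dst, al), ed$i, N * B)
        heads_out[[k]] <- if (l < L) nn_elu(tp, agg) else agg
      }
      hcur <- Reduce(function(a, b) nn_colcat(tp, a, b), heads_out)
    }
    h <- nn_nodes_to_grid(tp, hcur, c(gh, gw, B, emb))
    for (j in seq_len(n_down)) {
      h <- nn_convT2(tp, h, pget(sprintf("dec%d_w", j)), pget(sprintf("dec%d_b", j)))
      h <- nn_bn(tp, h, pget(sprintf("dec%d_bn_g", j)), pget(sprintf("dec%d_bn_s", j)),
                 st, sprintf("dec%d_bn", j), training)
      h <- nn_relu(tp, h)
    }
    h <- nn_conv1(tp, h, pget("head_w"), pget("head_b"))
    nn_sigmoid(tp, h)
  }
  model <- new_seg_model(spec, ps, forward, subclass)
  model
}

#' @rdname build_model
#' @export
build_gat_segmenter <- function(spec) {
  stopifnot(spec$architecture == "gat")
  build_graph_segmenter(spec, "sonoseg_gat")
}

#' @rdname build_model
#' @export
build_sgnn_segmenter <- function(spec) {
  stopifnot(spec$architecture == "sgnn")
  if (is.null(spec$top_k)) {
    abort_sonoseg("top_k must be set for the sgnn architecture",
                  class = "sonoseg_spec_error")
  }
  build_graph_segmenter(spec, "sonoseg_sgnn")
}

# cosine-similarity edge lists for a batch of node blocks (each sample
# occupies N consecutive rows).  Returns i/j index vectors sorted by i and a
# constant per-node neighbor count.
batched_cosine_edges <- function(feats, N, B, mode, k) {
  if (mode == "dense_cosine") {
    i <- rep(seq_len(N * B), each = N)
    off <- rep((seq_len(B) - 1L) * N, each = N * N)
    j <- rep.int(rep(seq_len(N), times = N), B) + off
    return(list(i = i, j = j, n_per_seg = N))
  }
  kk <- min(k, N - 1L)
  jl <- vector("list", B)
  for (b in seq_len(B)) {
    off <- (b - 1L) * N
    Fb <- feats[off + seq_len(N), , drop = FALSE]
    nr <- sqrt(rowSums(Fb * Fb))
    nr[nr < 1e-12] <- 1e-12
    S <- tcrossprod(Fb / nr)
    diag(S) <- -Inf                       # exclude self from the top-k pick
    jm <- matrix(0L, kk + 1L, N)
    for (i in seq_len(N)) {
      ord <- order(-S[, i], seq_len(N))   # stable tie-break by node index
      jm[, i] <- c(i, ord[seq_len(kk)])   # self-loop first
    }
    jl[[b]] <- as.integer(jm) + off
  }
  list(i = rep(seq_len(N * B), each = kk + 1L),
       j = unlist(jl, use.names = FALSE),
       n_per_seg = kk + 1L)
}

# ---- prediction ------------------------------------------------------------

#' Predict tumor probability maps
#'
#' Runs the network in inference mode (batch-norm uses running statistics).
#'
#' @param model a built [sonoseg model][build_model()].
#' @param images a single `H x W x C` array or an `H x W x C x N` stack with
#'   values in `[0, 1]`.
#' @param batch_size number of slices evaluated per forward pass.
#' @return probabilities with the same spatial layout (`H x W` or
#'   `H x W x N`), values strictly in `(0, 1)`.
#' @export
predict_probs <- function(model, images, batch_size = 8L) {
  stopifnot(inherits(model, "sonoseg_model"))
  d <- dim(images)
  single <- length(d) == 3L
  if (single) dim(images) <- c(d, 1L)
  d <- dim(images)
  n <- d[4]
  out <- array(NA_real_, c(d[1], d[2], n))
  for (s in seq.int(1L, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1L)
    xb <- aperm(images[, , , idx, drop = FALSE], c(1, 2, 4, 3))
    tp <- tp_new()
    pid <- model$forward(tp, tp_const(tp, xb), training = FALSE)
    out[, , idx] <- tp_val(tp, pid)[, , , 1]
  }
  if (single) out[, , 1] else out
}

#' @rdname predict_probs
#' @param threshold probability cut for binarization; a pixel at exactly the
#'   threshold counts as positive.
#' @return `predict_masks()`: binary masks of the same layout.
#' @export
predict_masks <- function(model, images, threshold = 0.5, batch_size = 8L) {
  p <- predict_probs(model, images, batch_size = batch_size)
  (p >= threshold) * 1
}

# ---- parameter accounting --------------------------------------------------

#' Count trainable parameters
#'
#' Sums element counts over all trainable tensors.  Batch-norm scale and
#' shift are trainable and counted; running statistics are state, not
#' parameters, and are excluded.
#'
#' @param model a built model (or any object with `params` and `trainable`
#'   stores).
#' @return integer total.
#' @export
count_trainable_parameters <- function(model) {
  nms <- model$param_order %||% ls(model$params)
  total <- 0
  for (nm in nms) {
    tr <- model$trainable[[nm]] %||% TRUE
    if (isTRUE(tr)) total <- total + length(model$params[[nm]])
  }
  as.integer(total)
}

#' Freeze parameters
#'
#' Marks parameters as non-trainable: they are skipped by the optimizer and
#' by [count_trainable_parameters()].
#'
#' @param model a built model.
#' @param names parameter names to freeze; default all.
#' @return the model, invisibly (stores are environments, updated in place).
#' @export
freeze_parameters <- function(model, names = NULL) {
  names <- names %||% model$param_order
  for (nm in names) model$trainable[[nm]] <- FALSE
  invisible(model)
}

#' Parameter shape manifest
#'
#' @param model a built model.
#' @return a tibble with one row per trainable tensor: `name`, `shape`
#'   (`"x"`-separated), `n` elements, `trainable`.
#' @export
parameter_manifest <- function(model) {
  nms <- model$param_order
  tibble::tibble(
    name = nms,
    shape = vapply(nms, function(nm) {
      v <- model$params[[nm]]
      paste(dim(v) %||% length(v), collapse = "x")
    }, character(1), USE.NAMES = FALSE),
    n = vapply(nms, function(nm) length(model$params[[nm]]), numeric(1),
               USE.NAMES = FALSE),
    trainable = vapply(nms, function(nm) isTRUE(model$trainable[[nm]]),
                       logical(1), USE.NAMES = FALSE))
}

#' Write the parameter manifest as JSON
#'
#' @param model a built model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_parameter_manifest <- function(model, path) {
  jsonlite::write_json(parameter_manifest(model), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.sonoseg_model <- function(x, ...) {
  cat(sprintf("<sonoseg_model:%s> input %s, %s trainable parameters\n",
              x$spec$architecture,
              paste(x$spec$input_size, collapse = "x"),
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load model checkpoints
#'
#' Checkpoints hold the spec, all parameter tensors, batch-norm running
#' statistics and trainability flags; [load_checkpoint()] rebuilds the model
#' from its spec and restores them.
#'
#' @param model a built model.
#' @param path checkpoint file (RDS).
#' @return `save_checkpoint()`: `path` invisibly; `load_checkpoint()`: the
#'   restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(spec = model$spec,
               params = as.list(model$params),
               state = as.list(model$state),
               trainable = as.list(model$trainable)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$spec)
  for (nm in names(ck$params)) model$params[[nm]] <- ck$params[[nm]]
  for (nm in names(ck$state)) model$state[[nm]] <- ck$state[[nm]]
  for (nm in names(ck$trainable)) model$trainable[[nm]] <- ck$trainable[[nm]]
  model
}

#' Read / write model specs as YAML
#'
#' Human-readable serialization of a [model_spec()].
#'
#' @param spec a model spec.
#' @param path YAML file.
#' @return `write_model_spec()`: `path` invisibly; `read_model_spec()`: the
#'   spec.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "sonoseg_model_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  do.call(model_spec, yaml::read_yaml(path))
}
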