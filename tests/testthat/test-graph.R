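test_that("cosine graph construction matches brute-force similarities", {
  set.seed(5)
  fg <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  g <- build_graph_from_features(fg, "dense_cosine")
  Fm <- g$node_features
  expect_equal(g$similarity, brute_cosine(Fm), tolerance = 1e-12)
  # row-major node order: node 2 is grid position (row 1, col 2)
  expect_equal(Fm[2, ], fg[1, 2, ])
  expect_true(all(lengths(g$neighbors) == 16))
})

test_that("degenerate and identical feature grids behave per the cosine identities", {
  f1 <- array(rep(c(1, 2, 3), each = 4), c(2, 2, 3))
  g <- build_graph_from_features(f1, "dense_cosine")
  expect_true(all(abs(g$similarity - 1) < 1e-12))

  f2 <- array(0, c(1, 2, 2))
  f2[1, 1, ] <- c(1, 0)
  f2[1, 2, ] <- c(0, 1)
  g2 <- build_graph_from_features(f2, "dense_cosine")
  expect_equal(g2$similarity[1, 2], 0)

  expect_error(build_graph_from_features(array(0, c(2, 2, 3))),
               "degenerate", class = "sonoseg_graph_error")
})

test_that("top-k neighborhoods match a brute-force sort and keep self-loops", {
  set.seed(8)
  for (rep in 1:10) {
    fg <- array(rnorm(2 * 2 * 5), c(2, 2, 5))
    g <- build_graph_from_features(fg, "topk_cosine", k = 2)
    S <- brute_cosine(g$node_features)
    for (i in 1:4) {
      nb <- g$neighbors[[i]]
      expect_true(i %in% nb)
      others <- setdiff(nb, i)
      expect_length(others, 2)
      s <- S[i, ]
      s[i] <- -Inf
      expect_setequal(others, order(-s, seq_along(s))[1:2])
    }
  }
  expect_error(build_graph_from_features(array(rnorm(12), c(2, 2, 3)),
                                         "topk_cosine", k = 4),
               class = "sonoseg_graph_error")
})

test_that("gat_attention reduces to softmax identities in degenerate graphs", {
  set.seed(2)
  h <- matrix(rnorm(6), 3, 2)
  W <- matrix(rnorm(4), 2, 2)
  a <- rnorm(4)
  g <- build_graph_from_features(array(h, c(3, 1, 2)), "dense_cosine")

  # single neighbor -> weight exactly 1
  g1 <- g
  g1$neighbors <- list(2L, 1L, 3L)
  out <- gat_attention(g1, gat_params(W, a))
  al <- attr(out, "alpha")[[1]]
  expect_equal(unname(unlist(al)), c(1, 1, 1))

  # all-equal logits (a = 0) -> uniform weights 1/m
  out2 <- gat_attention(g, gat_params(W, numeric(4)))
  al2 <- attr(out2, "alpha")[[1]]
  for (w in al2) expect_equal(unname(w), rep(1 / 3, 3))

  g0 <- g
  g0$neighbors[[2]] <- integer(0)
  expect_error(gat_attention(g0, gat_params(W, a)),
               class = "sonoseg_graph_error")
})

test_that("gat_attention equals the hand-rolled double-loop evaluation", {
  elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
  for (seed in 1:20) {
    set.seed(seed)
    N <- sample(3:6, 1)
    F_ <- sample(2:4, 1)
    Fp <- sample(2:3, 1)
    K <- sample(1:3, 1)
    h <- matrix(sample(-3:3, N * F_, replace = TRUE), N, F_)
    Wl <- replicate(K, matrix(sample(-2:2, Fp * F_, replace = TRUE), Fp, F_),
                    simplify = FALSE)
    al <- replicate(K, sample(-2:2, 2 * Fp, replace = TRUE), simplify = FALSE)
    g <- build_graph_from_features(array(h + 0.1, c(N, 1, F_)),
                                   "dense_cosine")
    out <- gat_attention(g, gat_params(Wl, al, activation = "elu"))
    ref <- loop_gat(h + 0.1, g$neighbors, Wl, al, act = elu)
    expect_equal(unclass(out), ref, tolerance = 1e-5,
                 ignore_attr = TRUE)
    # attention rows normalize to 1 for every node and head
    for (k in seq_len(K)) {
      sums <- vapply(attr(out, "alpha")[[k]], sum, numeric(1))
      expect_equal(unname(sums), rep(1, N), tolerance = 1e-10)
    }
  }
})

test_that("gat_attention is permutation-consistent", {
  set.seed(33)
  N <- 5
  h <- matrix(rnorm(N * 3), N, 3)
  Wl <- list(matrix(rnorm(6), 2, 3))
  al <- list(rnorm(4))
  g <- build_graph_from_features(array(h, c(N, 1, 3)), "dense_cosine")
  out <- gat_attention(g, gat_params(Wl, al))
  perm <- sample(N)
  gp <- build_graph_from_features(array(h[perm, ], c(N, 1, 3)),
                                  "dense_cosine")
  outp <- gat_attention(gp, gat_params(Wl, al))
  expect_equal(unclass(outp), unclass(out)[perm, ], tolerance = 1e-10,
               ignore_attr = TRUE)
})
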