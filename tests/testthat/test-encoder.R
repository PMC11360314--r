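# Graph-attention encoder: attention math, representations, loss, training.

tiny_graph <- function(seq = "GALS", conf = "alpha", center = 1L) {
  p <- make_peptide(seq, conf)
  ann <- annotate_structure(p)
  build_graph(p, center, ann)
}

test_that("attention coefficients normalize and isolated nodes self-attend", {
  cfg <- encoder_config(head_dim = 4L, seed = 2)
  st <- init_encoder(cfg)
  g <- tiny_graph()
  ed <- gatddg:::directed_edges(g$edges, g$n)
  # recompute alpha for head 1 and check normalization per node
  W <- st$params[["L1.W.1"]]; as_ <- st$params[["L1.as.1"]]; ad_ <- st$params[["L1.ad.1"]]
  Z <- g$X %*% t(W)
  pre <- as.numeric(Z %*% as_)[ed$i] + as.numeric(Z %*% ad_)[ed$j]
  lre <- ifelse(pre > 0, pre, 0.2 * pre)
  alpha <- exp(lre) / as.numeric(rowsum(exp(lre), ed$i))[ed$i]
  sums <- as.numeric(rowsum(alpha, ed$i))
  expect_equal(sums, rep(1, g$n), tolerance = 1e-12)
  # isolated node: softmax over the self-loop only -> ELU(W f)
  one <- list(X = g$X[1, , drop = FALSE], edges = matrix(integer(0), 0, 2),
              n = 1L)
  ed1 <- gatddg:::directed_edges(one$edges, 1L)
  out <- attention_layer(one$X, ed1, st$params, 1, cfg)$out
  z <- as.numeric(one$X %*% t(W))
  expect_equal(out[1, 1:4], ifelse(z > 0, z, exp(pmin(z, 0)) - 1),
               tolerance = 1e-12)
})

test_that("sparse attention equals dense masked attention on small graphs", {
  cfg <- encoder_config(head_dim = 4L, seed = 6)
  st <- init_encoder(cfg)
  dense_layer <- function(X, edges, layer) {
    n <- nrow(X)
    A <- diag(n) > 0
    if (nrow(edges)) {
      A[edges] <- TRUE
      A[edges[, c(2, 1), drop = FALSE]] <- TRUE
    }
    out <- NULL
    for (h in seq_len(cfg$n_heads)) {
      W <- st$params[[sprintf("L%d.W.%d", layer, h)]]
      as_ <- st$params[[sprintf("L%d.as.%d", layer, h)]]
      ad_ <- st$params[[sprintf("L%d.ad.%d", layer, h)]]
      Z <- X %*% t(W)
      E <- outer(as.numeric(Z %*% as_), rep(1, n)) +
        outer(rep(1, n), as.numeric(Z %*% ad_))
      E <- ifelse(E > 0, E, 0.2 * E)
      E[!A] <- -Inf
      al <- exp(E - apply(E, 1, max))
      al <- al / rowSums(al)
      M <- al %*% Z
      out <- cbind(out, ifelse(M > 0, M, exp(pmin(M, 0)) - 1))
    }
    out
  }
  set.seed(10)
  for (trial in 1:4) {
    n <- sample(3:12, 1)
    X <- matrix(stats::rnorm(n * 36), n, 36)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    take <- sample(nrow(pairs), min(nrow(pairs), n))
    edges <- pairs[take, , drop = FALSE]
    ed <- gatddg:::directed_edges(edges, n)
    sparse <- attention_layer(X, ed, st$params, 1, cfg)$out
    expect_equal(sparse, dense_layer(X, edges, 1), tolerance = 1e-5)
  }
})

test_that("representations have the advertised width and permutation equivariance", {
  cfg <- encoder_config(head_dim = 4L, seed = 3)
  st <- init_encoder(cfg)
  g <- tiny_graph("GALSK", center = 2L)
  rep_ <- encode(g, st)
  expect_identical(dim(rep_), c(g$n, 2L * 8L * 4L))
  # permute nodes: outputs permute identically
  set.seed(5)
  perm <- sample(g$n)
  inv <- order(perm)
  g2 <- g
  g2$X <- g$X[perm, , drop = FALSE]
  if (nrow(g$edges)) {
    e <- matrix(inv[g$edges], ncol = 2)
    g2$edges <- e
  }
  rep2 <- encode(g2, st)
  expect_equal(rep2[inv, ], rep_, tolerance = 1e-10)
})

test_that("encoder output is invariant under rigid-body transforms", {
  p <- make_peptide("GALSKY", "alpha")
  pr <- random_rotate_structure(p, seed = 44)
  st <- init_encoder(encoder_config(head_dim = 4L, seed = 8))
  g1 <- build_graph(p, 2, annotate_structure(p))
  g2 <- build_graph(pr, 2, annotate_structure(pr))
  expect_identical(g1$X, g2$X)
  expect_identical(g1$edges, g2$edges)
  expect_identical(encode(g1, st), encode(g2, st))
})

test_that("displacement head and loss follow their definitions", {
  cfg <- encoder_config(head_dim = 4L, mlp_hidden = c(3L, 2L), seed = 4)
  st <- init_encoder(cfg)
  g <- tiny_graph("GSLS", center = 1L)
  rep_ <- encode(g, st)
  pred <- predict_displacement(rep_, st, g$perturbed_nodes)
  expect_length(pred, length(g$perturbed_nodes))
  # zero-weight MLP: all outputs equal the final bias
  st0 <- st
  st0$params$mlp.W1 <- st0$params$mlp.W1 * 0
  st0$params$mlp.W2 <- st0$params$mlp.W2 * 0
  st0$params$mlp.W3 <- st0$params$mlp.W3 * 0
  st0$params$mlp.b3 <- 1.25
  expect_identical(unique(predict_displacement(rep_, st0, g$perturbed_nodes)), 1.25)
  # hand-computed two-matrix-multiply on a toy representation
  toy <- st
  toy$params$mlp.W1 <- matrix(1:(ncol(rep_) * 3) / 100, ncol(rep_), 3)
  toy$params$mlp.b1 <- c(0.1, -0.2, 0.3)
  toy$params$mlp.W2 <- matrix(seq(-0.3, 0.2, length.out = 6), 3, 2)
  toy$params$mlp.b2 <- c(0, 0.1)
  toy$params$mlp.W3 <- matrix(c(0.5, -0.5), 2, 1)
  toy$params$mlp.b3 <- 0.05
  G <- rep_[g$perturbed_nodes, , drop = FALSE]
  h1 <- pmax(sweep(G %*% toy$params$mlp.W1, 2, toy$params$mlp.b1, `+`), 0)
  h2 <- pmax(sweep(h1 %*% toy$params$mlp.W2, 2, toy$params$mlp.b2, `+`), 0)
  expect_equal(predict_displacement(rep_, toy, g$perturbed_nodes),
               as.numeric(h2 %*% toy$params$mlp.W3 + 0.05), tolerance = 1e-12)
  # loss arithmetic
  expect_identical(encoder_loss(c(1, 3), c(0, 0)), 5)
  expect_identical(encoder_loss(c(2, 2), c(2, 2)), 0)
  set.seed(6)
  a <- stats::rnorm(40); b <- stats::rnorm(40)
  acc <- 0
  for (k in seq_along(a)) acc <- acc + (a[k] - b[k])^2
  expect_equal(encoder_loss(a, b), acc / 40, tolerance = 1e-12)
  expect_error(encoder_loss(numeric(0), numeric(0)), "empty")
})

test_that("training reduces the loss deterministically and rejects degenerate data", {
  p <- make_peptide("GSLSK", "alpha")
  set.seed(14)
  samples <- make_perturbation_dataset(list(p), 12)
  prep <- prepare_encoder_samples(samples)
  cfg <- encoder_config(head_dim = 3L, mlp_hidden = c(8L, 4L), epochs = 4L,
                        seed = 5, batch_size = 8L)
  st1 <- train_encoder(prep, cfg)
  st2 <- train_encoder(prep, cfg)
  expect_identical(st1$history, st2$history)  # same seed, same trajectory
  expect_lt(utils::tail(st1$history$train_loss, 1), st1$history$train_loss[1])
  # all-zero targets (GLY/ALA only) are rejected
  pz <- make_peptide("GAGA", "alpha")
  expect_warning(z <- make_perturbation_dataset(list(pz), 2), "no perturbable")
  expect_error(train_encoder(list(), cfg), "no training samples")
  zprep <- prep[1:3]
  for (i in seq_along(zprep)) zprep[[i]]$target <- zprep[[i]]$target * 0
  expect_error(train_encoder(zprep, cfg), "degenerate")
})
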