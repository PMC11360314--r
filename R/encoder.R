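# Multi-head graph-attention encoder with a displacement-prediction MLP
# head, trained by Adam on the self-supervised rotamer-perturbation task.
# Forward and backward passes are written directly in matrix code: per head
# k, e_ij = LeakyReLU(a_src . W f_i + a_dst . W f_j) over the closed
# neighborhood (self-loops mandatory), alpha = softmax_j(e_ij), and the head
# output is ELU(sum_j alpha_ij W f_j); the eight heads are concatenated.
# Per-atom geometric representations are the concatenation of layer-3 and
# layer-4 outputs; the MLP maps them to a scalar displacement and the loss
# is the mean squared error over the perturbed residue's atoms.

#' Encoder configuration
#'
#' @param n_layers Number of stacked attention layers (>= 4 when layer-3/4
#'   concatenation is used).
#' @param n_heads Attention heads per layer.
#' @param head_dim Per-head output width.
#' @param leaky_slope LeakyReLU slope in the attention logits.
#' @param mlp_hidden Two hidden widths of the displacement MLP.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size (graphs per step).
#' @param epochs Training epochs.
#' @param seed RNG seed for initialization and batching.
#' @param in_dim Node-attribute dimension.
#' @return An `EncoderConfig` list.
#' @export
encoder_config <- function(n_layers = 4L, n_heads = 8L, head_dim = 16L,
                           leaky_slope = 0.2, mlp_hidden = c(128L, 64L),
                           learning_rate = 0.001, batch_size = 128L,
                           epochs = 30L, seed = 1L, in_dim = 36L) {
  stopifnot(n_layers >= 4, n_heads >= 1, head_dim >= 1,
            length(mlp_hidden) == 2, all(mlp_hidden >= 1))
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 head_dim = as.integer(head_dim), leaky_slope = leaky_slope,
                 mlp_hidden = as.integer(mlp_hidden),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 in_dim = as.integer(in_dim)),
            class = "EncoderConfig")
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Initialize encoder weights
#' @param config An `EncoderConfig`.
#' @return An `EncoderState` with Glorot-uniform weights.
#' @export
init_encoder <- function(config) {
  set.seed(config$seed)
  H <- config$n_heads
  d <- config$head_dim
  params <- list()
  for (l in seq_len(config$n_layers)) {
    din <- if (l == 1) config$in_dim else H * d
    for (h in seq_len(H)) {
      params[[sprintf("L%d.W.%d", l, h)]] <- glorot(d, din)
      params[[sprintf("L%d.as.%d", l, h)]] <- as.numeric(glorot(d, 1))
      params[[sprintf("L%d.ad.%d", l, h)]] <- as.numeric(glorot(d, 1))
    }
  }
  gdim <- 2L * H * d
  m1 <- config$mlp_hidden[1]
  m2 <- config$mlp_hidden[2]
  params$mlp.W1 <- glorot(gdim, m1); params$mlp.b1 <- numeric(m1)
  params$mlp.W2 <- glorot(m1, m2); params$mlp.b2 <- numeric(m2)
  params$mlp.W3 <- glorot(m2, 1); params$mlp.b3 <- 0
  structure(list(config = config, params = params,
                 history = data.frame(epoch = integer(0),
                                      train_loss = numeric(0),
                                      val_loss = numeric(0))),
            class = "EncoderState")
}

# Directed edge arrays with mandatory self-loops: row pairs (i attends to j).
directed_edges <- function(edges, n) {
  if (nrow(edges)) {
    i_idx <- c(edges[, 1], edges[, 2], seq_len(n))
    j_idx <- c(edges[, 2], edges[, 1], seq_len(n))
  } else {
    i_idx <- j_idx <- seq_len(n)
  }
  list(i = as.integer(i_idx), j = as.integer(j_idx))
}

group_max <- function(x, g, n) {
  as.numeric(tapply(x, factor(g, levels = seq_len(n)), max))
}

group_sum <- function(X, g) {
  rowsum(X, g)  # groups 1..n all present via self-loops; sorted numerically
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

#' One multi-head attention layer (forward)
#'
#' @param F_in Node feature matrix (n x din).
#' @param ed Directed edge arrays from `directed_edges()`.
#' @param params Encoder parameter list.
#' @param layer Layer number.
#' @param config An `EncoderConfig`.
#' @param keep_cache Keep intermediates for backprop.
#' @return List with `out` (n x n_heads*head_dim) and `cache`.
#' @export
attention_layer <- function(F_in, ed, params, layer, config, keep_cache = FALSE) {
  n <- nrow(F_in)
  H <- config$n_heads
  d <- config$head_dim
  slope <- config$leaky_slope
  out <- matrix(0, n, H * d)
  cache <- if (keep_cache) vector("list", H) else NULL
  for (h in seq_len(H)) {
    W <- params[[sprintf("L%d.W.%d", layer, h)]]
    as_ <- params[[sprintf("L%d.as.%d", layer, h)]]
    ad_ <- params[[sprintf("L%d.ad.%d", layer, h)]]
    Z <- F_in %*% t(W)                       # n x d
    s <- as.numeric(Z %*% as_)
    t_ <- as.numeric(Z %*% ad_)
    pre <- s[ed$i] + t_[ed$j]
    lre <- ifelse(pre > 0, pre, slope * pre)
    mx <- group_max(lre, ed$i, n)
    w <- exp(lre - mx[ed$i])
    denom <- as.numeric(group_sum(matrix(w), ed$i))
    alpha <- w / denom[ed$i]
    M <- group_sum(Z[ed$j, , drop = FALSE] * alpha, ed$i)  # n x d
    out[, (h - 1) * d + seq_len(d)] <- elu(M)
    if (keep_cache) cache[[h]] <- list(Z = Z, pre = pre, alpha = alpha, M = M)
  }
  list(out = out, cache = cache)
}

# Backward through one attention layer. dOut is n x H*d; returns dF plus
# parameter gradients for this layer.
attention_layer_backward <- function(dOut, F_in, ed, params, layer, config, cache) {
  n <- nrow(F_in)
  H <- config$n_heads
  d <- config$head_dim
  slope <- config$leaky_slope
  dF <- matrix(0, n, ncol(F_in))
  grads <- list()
  for (h in seq_len(H)) {
    W <- params[[sprintf("L%d.W.%d", layer, h)]]
    as_ <- params[[sprintf("L%d.as.%d", layer, h)]]
    ad_ <- params[[sprintf("L%d.ad.%d", layer, h)]]
    ch <- cache[[h]]
    dM <- dOut[, (h - 1) * d + seq_len(d), drop = FALSE] * elu_grad(ch$M)
    # d alpha_e = dM_i . z_j
    dalpha <- rowSums(dM[ed$i, , drop = FALSE] * ch$Z[ed$j, , drop = FALSE])
    dZ <- group_sum(dM[ed$i, , drop = FALSE] * ch$alpha, ed$j)
    # softmax backward per attending node
    Ssum <- as.numeric(group_sum(matrix(ch$alpha * dalpha), ed$i))
    de <- ch$alpha * (dalpha - Ssum[ed$i])
    dpre <- de * ifelse(ch$pre > 0, 1, slope)
    ds <- as.numeric(group_sum(matrix(dpre), ed$i))
    dt <- as.numeric(group_sum(matrix(dpre), ed$j))
    dZ <- dZ + outer(ds, as_) + outer(dt, ad_)
    grads[[sprintf("L%d.as.%d", layer, h)]] <- as.numeric(t(ch$Z) %*% ds)
    grads[[sprintf("L%d.ad.%d", layer, h)]] <- as.numeric(t(ch$Z) %*% dt)
    grads[[sprintf("L%d.W.%d", layer, h)]] <- t(dZ) %*% F_in
    dF <- dF + dZ %*% W
  }
  list(dF = dF, grads = grads)
}

gat_forward <- function(X, ed, state, keep_cache = FALSE) {
  cfg <- state$config
  feats <- vector("list", cfg$n_layers + 1)
  caches <- vector("list", cfg$n_layers)
  feats[[1]] <- X
  for (l in seq_len(cfg$n_layers)) {
    r <- attention_layer(feats[[l]], ed, state$params, l, cfg, keep_cache)
    feats[[l + 1]] <- r$out
    caches[[l]] <- r$cache
  }
  list(feats = feats, caches = caches)
}

#' Per-atom geometric representations
#'
#' Runs the four stacked attention layers over a protein graph and returns,
#' per node, the concatenation of the layer-3 and layer-4 outputs.
#'
#' @param graph A `ProteinGraph`.
#' @param state An `EncoderState`.
#' @return Numeric matrix (n x 2*n_heads*head_dim).
#' @export
encode <- function(graph, state) {
  if (ncol(graph$X) != state$config$in_dim) {
    stop("graph attributes are ", ncol(graph$X), "-dim; encoder expects ",
         state$config$in_dim)
  }
  ed <- directed_edges(graph$edges, graph$n)
  fw <- gat_forward(graph$X, ed, state)
  nl <- state$config$n_layers
  cbind(fw$feats[[nl]], fw$feats[[nl + 1]])  # layer 3 and layer 4 outputs
}

mlp_forward <- function(G, params, keep_cache = FALSE) {
  a1 <- sweep(G %*% params$mlp.W1, 2, params$mlp.b1, `+`)
  h1 <- pmax(a1, 0)
  a2 <- sweep(h1 %*% params$mlp.W2, 2, params$mlp.b2, `+`)
  h2 <- pmax(a2, 0)
  y <- as.numeric(h2 %*% params$mlp.W3 + params$mlp.b3)
  if (keep_cache) list(y = y, a1 = a1, h1 = h1, a2 = a2, h2 = h2) else y
}

mlp_backward <- function(dy, G, params, cache) {
  dy <- matrix(dy, ncol = 1)
  g <- list()
  g$mlp.W3 <- t(cache$h2) %*% dy
  g$mlp.b3 <- sum(dy)
  dh2 <- dy %*% t(params$mlp.W3)
  da2 <- dh2 * (cache$a2 > 0)
  g$mlp.W2 <- t(cache$h1) %*% da2
  g$mlp.b2 <- colSums(da2)
  dh1 <- da2 %*% t(params$mlp.W2)
  da1 <- dh1 * (cache$a1 > 0)
  g$mlp.W1 <- t(G) %*% da1
  g$mlp.b1 <- colSums(da1)
  dG <- da1 %*% t(params$mlp.W1)
  list(grads = g, dG = dG)
}

#' Predict per-atom displacements from representations
#'
#' @param rep Geometric representation matrix (n x 2*n_heads*head_dim).
#' @param state An `EncoderState`.
#' @param node_set Node indices (the perturbed residue's atoms).
#' @return Numeric vector of predicted displacements (A), one per node in
#'   `node_set`.
#' @export
predict_displacement <- function(rep, state, node_set = seq_len(nrow(rep))) {
  mlp_forward(rep[node_set, , drop = FALSE], state$params)
}

#' Self-supervision loss
#'
#' Mean squared error between predicted and true displacements over the
#' perturbed residue's atoms.
#'
#' @param predicted,real Equal-length numeric vectors.
#' @return Scalar loss.
#' @export
encoder_loss <- function(predicted, real) {
  if (length(predicted) == 0) stop("loss undefined for an empty node set")
  if (length(predicted) != length(real)) stop("length mismatch")
  mean((predicted - real)^2)
}

# Full forward + backward for one prepared sample; returns loss and grads.
sample_grad <- function(sm, state) {
  cfg <- state$config
  fw <- gat_forward(sm$X, sm$ed, state, keep_cache = TRUE)
  nl <- cfg$n_layers
  G <- cbind(fw$feats[[nl]], fw$feats[[nl + 1]])[sm$np, , drop = FALSE]
  mc <- mlp_forward(G, state$params, keep_cache = TRUE)
  loss <- mean((mc$y - sm$target)^2)
  dy <- 2 * (mc$y - sm$target) / length(sm$target)
  mb <- mlp_backward(dy, G, state$params, mc)
  grads <- mb$grads
  w <- cfg$n_heads * cfg$head_dim
  # route dG back to layer-3 / layer-4 outputs at the N_p rows
  n <- nrow(sm$X)
  dOut4 <- matrix(0, n, w)
  dOut3 <- matrix(0, n, w)
  dOut3[sm$np, ] <- mb$dG[, seq_len(w), drop = FALSE]
  dOut4[sm$np, ] <- mb$dG[, w + seq_len(w), drop = FALSE]
  bk <- attention_layer_backward(dOut4, fw$feats[[nl]], sm$ed, state$params,
                                 nl, cfg, fw$caches[[nl]])
  for (nm in names(bk$grads)) grads[[nm]] <- bk$grads[[nm]]
  dOut <- dOut3 + bk$dF
  for (l in seq(nl - 1, 1)) {
    bk <- attention_layer_backward(dOut, fw$feats[[l]], sm$ed, state$params,
                                   l, cfg, fw$caches[[l]])
    for (nm in names(bk$grads)) grads[[nm]] <- bk$grads[[nm]]
    dOut <- bk$dF
  }
  list(loss = loss, grads = grads)
}

sample_loss <- function(sm, state) {
  fw <- gat_forward(sm$X, sm$ed, state)
  nl <- state$config$n_layers
  G <- cbind(fw$feats[[nl]], fw$feats[[nl + 1]])[sm$np, , drop = FALSE]
  mean((mlp_forward(G, state$params) - sm$target)^2)
}

#' Prepare perturbation samples for encoder training
#'
#' Annotates each perturbed structure, builds the atom graph around the
#' perturbed residue, and aligns the displacement targets with the graph's
#' perturbed-node order.
#'
#' @param samples Output of [make_perturbation_dataset()].
#' @param radius,cutoff Graph construction parameters (A).
#' @param n_points SASA quadrature points.
#' @return List of prepared samples (attribute matrix, directed edges,
#'   perturbed node indices, displacement targets).
#' @export
prepare_encoder_samples <- function(samples, radius = 12.0, cutoff = 3.0,
                                    n_points = 100L) {
  lapply(samples, function(s) {
    ann <- annotate_structure(s$structure, n_points = n_points)
    gr <- build_graph(s$structure, s$record$residue_index, ann,
                      radius = radius, cutoff = cutoff)
    target <- as.numeric(s$record$displacement[gr$atoms$atom[gr$perturbed_nodes]])
    list(X = gr$X, ed = directed_edges(gr$edges, gr$n),
         np = gr$perturbed_nodes, target = target)
  })
}

#' Train the encoder on the self-supervised task
#'
#' Adam over minibatches of graphs (disjoint graphs are processed per
#' sample and gradients averaged, equivalent to block-diagonal batching).
#' Records per-epoch training and validation loss; the returned weights are
#' the best-validation-loss checkpoint. Deterministic given `config$seed`.
#'
#' @param samples Output of [make_perturbation_dataset()] or
#'   [prepare_encoder_samples()].
#' @param config An `EncoderConfig`.
#' @param val_fraction Fraction of samples held out for validation.
#' @return A trained `EncoderState` with `history`.
#' @export
train_encoder <- function(samples, config = encoder_config(),
                          val_fraction = 0.1) {
  if (length(samples) && !is.null(samples[[1]]$record)) {
    samples <- prepare_encoder_samples(samples)
  }
  if (length(samples) == 0) stop("no training samples")
  if (all(vapply(samples, function(s) all(s$target == 0), logical(1)))) {
    stop("degenerate dataset: all displacement targets are zero")
  }
  state <- init_encoder(config)  # seeds the RNG
  n <- length(samples)
  n_val <- floor(n * val_fraction)
  idx <- sample.int(n)
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(idx, val_idx)
  adam_m <- lapply(state$params, function(p) p * 0)
  adam_v <- lapply(state$params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0
  eval_mean <- function(ii) mean(vapply(samples[ii], sample_loss, 0, state = state))
  hist <- data.frame(epoch = 0L, train_loss = eval_mean(tr_idx),
                     val_loss = if (length(val_idx)) eval_mean(val_idx) else NA_real_)
  best_val <- hist$val_loss[1]
  best_params <- state$params
  for (ep in seq_len(config$epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    ep_losses <- numeric(0)
    for (start in seq(1, length(ord), by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1, length(ord))]
      acc <- NULL
      bl <- 0
      for (si in batch) {
        sg <- sample_grad(samples[[si]], state)
        bl <- bl + sg$loss
        if (is.null(acc)) {
          acc <- sg$grads
        } else {
          for (nm in names(sg$grads)) acc[[nm]] <- acc[[nm]] + sg$grads[[nm]]
        }
      }
      B <- length(batch)
      ep_losses <- c(ep_losses, bl / B)
      t_step <- t_step + 1
      for (nm in names(acc)) {
        g <- acc[[nm]] / B
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
        mh <- adam_m[[nm]] / (1 - b1^t_step)
        vh <- adam_v[[nm]] / (1 - b2^t_step)
        state$params[[nm]] <- state$params[[nm]] -
          config$learning_rate * mh / (sqrt(vh) + eps)
      }
    }
    vl <- if (length(val_idx)) eval_mean(val_idx) else NA_real_
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(ep_losses),
                                   val_loss = vl))
    if (length(val_idx) && (is.na(best_val) || vl < best_val)) {
      best_val <- vl
      best_params <- state$params
    }
  }
  if (length(val_idx)) state$params <- best_params
  state$history <- hist
  state
}

#' Save / load an encoder checkpoint
#' @param state An `EncoderState`.
#' @param path File path.
#' @return `load_encoder` returns the `EncoderState`.
#' @export
save_encoder <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) readRDS(path)
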