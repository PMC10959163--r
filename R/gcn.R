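#' Symmetrically normalized adjacency operator
#'
#' Adds self-connections to the (binary) adjacency and normalizes by the
#' resulting degrees: `S = D^{-1/2} (A + I) D^{-1/2}`. One application of
#' `S` is a Laplacian-smoothing step: each node's new feature is a
#' degree-weighted mean of its own and its neighbours' features, and on a
#' k-regular graph every row of `S` sums to 1 with equal off-diagonal
#' weights.
#'
#' @param graph a `pair_graph`, or a symmetric 0/1 adjacency matrix
#'   (dense or sparse) without self-loops.
#' @return a symmetric sparse `Matrix`.
#' @export
normalized_adjacency <- function(graph) {
  A <- if (inherits(graph, "pair_graph")) graph_adjacency(graph) else {
    if (nrow(graph) != ncol(graph)) abort_input("adjacency must be square")
    methods::as(Matrix::Matrix(graph, sparse = TRUE), "generalMatrix")
  }
  At <- A + Matrix::Diagonal(nrow(A))
  d <- Matrix::rowSums(At)
  Dinv <- Matrix::Diagonal(x = 1 / sqrt(d))
  Dinv %*% At %*% Dinv
}

#' One graph-convolution layer
#'
#' Computes `sigma(A_norm %*% H %*% W (+ bias))`. With identity operator,
#' identity weights and identity activation the input passes through
#' unchanged.
#'
#' @param H node feature matrix (nodes x channels).
#' @param A_norm normalized adjacency operator ([normalized_adjacency()]).
#' @param W weight matrix (channels x out-channels).
#' @param activation activation function (default identity).
#' @param bias optional length-`ncol(W)` bias vector.
#' @return the new node feature matrix.
#' @export
gcn_layer <- function(H, A_norm, W, activation = identity, bias = NULL) {
  if (ncol(A_norm) != nrow(H)) abort_input("A_norm and H shapes do not conform")
  if (nrow(W) != ncol(H)) abort_input("H and W shapes do not conform")
  Z <- as.matrix(A_norm %*% (H %*% W))
  if (!is.null(bias)) Z <- sweep(Z, 2, bias, "+")
  activation(Z)
}

#' Hyperparameter bundle for the pair-node GCN classifier
#'
#' Defaults are the package's own working configuration, all tunable: two
#' graph-convolution layers with ReLU and dropout, a dense layer to a single
#' logit, Adam updates with weight decay. `lambda_cap` bounds both the
#' per-node loss weight `1/lambda_v` and the per-edge aggregation rescale
#' `1/alpha_uv` so rarely-sampled nodes cannot dominate a minibatch.
#'
#' @param hidden sizes of the graph-convolution layers.
#' @param activation `"relu"`, `"tanh"`, `"sigmoid"` or `"identity"`.
#' @param dropout dropout rate on hidden activations during training.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to weight gradients (not biases).
#' @param epochs training epochs.
#' @param batches_per_epoch subgraph minibatches per epoch when the edge
#'   sampler is on; also sets the default draw count
#'   `M = |E| / batches_per_epoch`.
#' @param lambda_cap cap on `1/lambda_v` loss weights and `1/alpha_uv`
#'   aggregation rescales.
#' @return an object of class `gcn_config`.
#' @export
gcn_config <- function(hidden = c(64, 32), activation = "relu", dropout = 0.3,
                       learning_rate = 5e-3, weight_decay = 5e-4, epochs = 100,
                       batches_per_epoch = 10, lambda_cap = 10) {
  if (length(hidden) < 1 || any(hidden < 1)) abort_input("need at least one hidden layer")
  if (dropout < 0 || dropout >= 1) abort_input("dropout must lie in [0, 1)")
  if (epochs < 1) abort_input("epochs must be at least 1")
  structure(list(hidden = as.integer(hidden), activation = activation,
                 dropout = dropout, learning_rate = learning_rate,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 lambda_cap = lambda_cap),
            class = "gcn_config")
}

glorot_init <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

init_params <- function(input_dim, config) {
  dims <- c(input_dim, config$hidden)
  W <- lapply(seq_len(length(dims) - 1),
              function(l) glorot_init(dims[l], dims[l + 1]))
  b <- lapply(config$hidden, function(h) numeric(h))
  list(W = W, b = b,
       W_out = glorot_init(dims[length(dims)], 1L),
       b_out = 0)
}

# Forward pass; keeps intermediates for backprop when train = TRUE.
gcn_forward <- function(X, S, params, config, train = FALSE) {
  act <- act_fun(config$activation)
  L <- length(params$W)
  inputs <- vector("list", L)   # layer input after previous dropout
  Zs <- vector("list", L)
  Hs <- vector("list", L)
  masks <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    inputs[[l]] <- H
    Z <- as.matrix(S %*% (H %*% params$W[[l]]))
    Z <- sweep(Z, 2, params$b[[l]], "+")
    Zs[[l]] <- Z
    H <- act(Z)
    Hs[[l]] <- H
    if (train && config$dropout > 0) {
      keep <- 1 - config$dropout
      m <- matrix(stats::rbinom(length(H), 1, keep) / keep, nrow(H), ncol(H))
      masks[[l]] <- m
      H <- H * m
    }
  }
  logits <- as.vector(H %*% params$W_out) + params$b_out
  list(inputs = inputs, Zs = Zs, Hs = Hs, masks = masks,
       last_hidden = H, logits = logits)
}

# Gradient of the weighted BCE loss w.r.t. every parameter.
gcn_backward <- function(fw, S, params, config, dlogit) {
  agrad <- act_grad(config$activation)
  L <- length(params$W)
  g <- list(W = vector("list", L), b = vector("list", L))
  dcol <- matrix(dlogit, ncol = 1)
  g$W_out <- crossprod(fw$last_hidden, dcol)
  g$b_out <- sum(dlogit)
  dH <- dcol %*% t(params$W_out)
  for (l in rev(seq_len(L))) {
    if (!is.null(fw$masks[[l]])) dH <- dH * fw$masks[[l]]
    dZ <- dH * agrad(fw$Zs[[l]], fw$Hs[[l]])
    SdZ <- as.matrix(Matrix::crossprod(S, dZ))  # t(S) %*% dZ; S may be alpha-rescaled
    g$W[[l]] <- crossprod(fw$inputs[[l]], SdZ)
    g$b[[l]] <- colSums(dZ)
    if (l > 1) dH <- SdZ %*% t(params$W[[l]])
  }
  g
}

adam_state <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  upd <- function(path) {
    res <- walk(params[[path]], grads[[path]], state$m[[path]], state$v[[path]])
    params[[path]] <<- res$p; state$m[[path]] <<- res$m; state$v[[path]] <<- res$v
  }
  for (l in seq_along(params$W)) {
    res <- walk(params$W[[l]], grads$W[[l]], state$m$W[[l]], state$v$W[[l]])
    params$W[[l]] <- res$p; state$m$W[[l]] <- res$m; state$v$W[[l]] <- res$v
    res <- walk(params$b[[l]], grads$b[[l]], state$m$b[[l]], state$v$b[[l]])
    params$b[[l]] <- res$p; state$m$b[[l]] <- res$m; state$v$b[[l]] <- res$v
  }
  upd("W_out"); upd("b_out")
  list(params = params, state = state)
}

# Normalized operator of the subgraph induced by `sub_nodes`, optionally
# rescaling each directed aggregation term by 1/alpha (capped).
subgraph_operator <- function(graph, sub_nodes, induced, norm = NULL, cap = 10) {
  local <- integer(graph$n_nodes)
  local[sub_nodes] <- seq_along(sub_nodes)
  ns <- length(sub_nodes)
  ef <- local[graph$edges$from[induced]]
  et <- local[graph$edges$to[induced]]
  At <- Matrix::sparseMatrix(i = c(ef, et, seq_len(ns)),
                             j = c(et, ef, seq_len(ns)),
                             x = 1, dims = c(ns, ns))
  d <- Matrix::rowSums(At)
  Dinv <- Matrix::Diagonal(x = 1 / sqrt(d))
  S <- Dinv %*% At %*% Dinv
  if (!is.null(norm) && length(induced)) {
    af <- norm$alpha$alpha_from[induced]
    at <- norm$alpha$alpha_to[induced]
    rf <- ifelse(is.finite(af) & af > 0, pmin(1 / af, cap), 1)
    rt <- ifelse(is.finite(at) & at > 0, pmin(1 / at, cap), 1)
    S <- methods::as(S, "TsparseMatrix")
    key <- paste(c(ef, et), c(et, ef))
    scale <- stats::setNames(c(rf, rt), key)
    ek <- paste(S@i + 1L, S@j + 1L)
    hit <- match(ek, names(scale))
    S@x <- S@x * ifelse(is.na(hit), 1, scale[hit])
    S <- methods::as(S, "CsparseMatrix")
  }
  S
}

#' Train the pair-node GCN, optionally with edge-sampled minibatches
#'
#' Trains a graph convolutional classifier over miRNA-disease pair nodes.
#' With the edge sampler on, each minibatch is the subgraph induced by `M`
#' degree-weighted edge draws; per-node losses are reweighted by
#' `1/lambda_v` and per-edge aggregation terms rescaled by `1/alpha_uv`
#' (both estimated by [estimate_normalization()] and capped) to de-bias the
#' subgraph estimates. Without the sampler the full graph is used for every
#' update. Only nodes with `role == "train"` contribute to the loss
#' (binary cross-entropy on a single sigmoid logit); masked test nodes
#' still participate in message passing, keeping the setting transductive.
#'
#' @param nodes an [build_mdp_nodes()] result.
#' @param graph the `pair_graph` over those nodes.
#' @param config a [gcn_config()].
#' @param sampler use the random edge sampler (`TRUE`) or full-graph
#'   updates (`FALSE`).
#' @param M edge draws per subgraph; default `|E| / batches_per_epoch`.
#' @param norm_N pre-sampling subgraphs for the normalization coefficients.
#' @param seed RNG seed; training is deterministic given it.
#' @return an object of class `gcn_model` with the fitted weights, the
#'   config, a per-epoch loss `history` tibble and the seed.
#' @export
gcn_train <- function(nodes, graph, config = gcn_config(), sampler = TRUE,
                      M = NULL, norm_N = 50, seed = 1) {
  stopifnot(inherits(nodes, "mdp_nodes"), inherits(graph, "pair_graph"))
  X <- nodes$features
  if (nrow(X) != graph$n_nodes) abort_input("nodes and graph disagree on size")
  is_train <- nodes$table$role == "train"
  y <- nodes$table$label
  if (length(unique(y[is_train])) < 2) {
    abort_input("training nodes must contain both classes")
  }

  probs <- NULL; norm <- NULL; loss_w <- rep(1, nrow(X))
  if (sampler) {
    probs <- edge_probabilities(graph)
    M <- M %||% max(1L, round(nrow(probs) / config$batches_per_epoch))
    norm <- estimate_normalization(graph, probs, M, norm_N,
                                   seed = derive_seed(seed, 1))
    lam <- norm$lambda$lambda
    loss_w <- ifelse(lam > 0, pmin(1 / lam, config$lambda_cap), 0)
  }

  history <- numeric(config$epochs)
  with_seed(derive_seed(seed, 2), {
    params <- init_params(ncol(X), config)
    state <- adam_state(params)
    S_full <- if (!sampler) normalized_adjacency(graph)

    step <- function(Xb, Sb, train_idx, wb, yb) {
      fw <- gcn_forward(Xb, Sb, params, config, train = TRUE)
      p <- sigmoid(fw$logits[train_idx])
      eps <- 1e-12
      loss <- sum(wb * -(yb * log(p + eps) + (1 - yb) * log(1 - p + eps))) / sum(wb)
      dlogit <- numeric(nrow(Xb))
      dlogit[train_idx] <- wb * (p - yb) / sum(wb)
      g <- gcn_backward(fw, Sb, params, config, dlogit)
      wd <- config$weight_decay
      if (wd > 0) {
        for (l in seq_along(g$W)) g$W[[l]] <- g$W[[l]] + wd * params$W[[l]]
        g$W_out <- g$W_out + wd * params$W_out
      }
      res <- adam_update(params, g, state, config$learning_rate)
      params <<- res$params; state <<- res$state
      loss
    }

    for (epoch in seq_len(config$epochs)) {
      if (sampler) {
        losses <- rep(NA_real_, config$batches_per_epoch)
        for (bb in seq_len(config$batches_per_epoch)) {
          draws <- sample.int(nrow(probs), M, replace = TRUE, prob = probs$prob)
          in_set <- logical(graph$n_nodes)
          in_set[c(probs$from[draws], probs$to[draws])] <- TRUE
          sub <- which(in_set)
          induced <- which(in_set[graph$edges$from] & in_set[graph$edges$to])
          tr <- which(is_train[sub] & loss_w[sub] > 0)
          if (length(tr) == 0 || length(unique(y[sub][tr])) < 2) next
          Sb <- subgraph_operator(graph, sub, induced, norm, config$lambda_cap)
          losses[bb] <- step(X[sub, , drop = FALSE], Sb, tr,
                             loss_w[sub][tr], y[sub][tr])
        }
        history[epoch] <- mean(losses, na.rm = TRUE)
      } else {
        tr <- which(is_train)
        history[epoch] <- step(X, S_full, tr, loss_w[tr], y[tr])
      }
      if (!is.finite(history[epoch])) {
        rlang::abort(sprintf("non-finite training loss at epoch %d", epoch),
                     class = "mdpgcn_train_error")
      }
    }
  })

  structure(list(params = params, config = config,
                 history = tibble::tibble(epoch = seq_len(config$epochs),
                                          loss = history),
                 sampler = sampler, M = M, norm = norm, seed = seed,
                 input_dim = ncol(X)),
            class = "gcn_model")
}

#' Predict association scores for pair nodes
#'
#' Full-graph forward pass of a trained model (no sampling, no dropout);
#' scores are sigmoid-mapped logits in \[0, 1\] and do not depend on which
#' subset of nodes is requested.
#'
#' @param model a [gcn_train()] result.
#' @param graph the `pair_graph` used at prediction time.
#' @param nodes the matching [build_mdp_nodes()] result.
#' @param node_ids nodes to score; default all.
#' @return tibble with columns `node_id`, `mirna`, `disease`, `score`.
#' @export
predict_scores <- function(model, graph, nodes, node_ids = NULL) {
  stopifnot(inherits(model, "gcn_model"))
  node_ids <- node_ids %||% nodes$table$node_id
  unknown <- setdiff(node_ids, nodes$table$node_id)
  if (length(unknown)) abort_input("unknown node id %s", unknown[1])
  S <- normalized_adjacency(graph)
  fw <- gcn_forward(nodes$features, S, model$params, model$config, train = FALSE)
  dplyr::mutate(nodes$table[match(node_ids, nodes$table$node_id),
                            c("node_id", "mirna", "disease")],
                score = sigmoid(fw$logits)[node_ids])
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf("gcn_model: %d -> %s -> 1 logit, %d epochs, final loss %.4f (%s)\n",
              x$input_dim, paste(x$config$hidden, collapse = " -> "),
              x$config$epochs, x$history$loss[nrow(x$history)],
              if (x$sampler) "edge-sampled minibatches" else "full graph"))
  invisible(x)
}

#' @method tidy gcn_model
#' @export
tidy.gcn_model <- function(x, ...) x$history

#' @method glance gcn_model
#' @export
glance.gcn_model <- function(x, ...) {
  n_par <- sum(vapply(x$params$W, length, 0)) + sum(vapply(x$params$b, length, 0)) +
    length(x$params$W_out) + 1
  tibble::tibble(epochs = x$config$epochs,
                 initial_loss = x$history$loss[1],
                 final_loss = x$history$loss[nrow(x$history)],
                 n_parameters = n_par,
                 edge_sampler = x$sampler)
}

#' @method autoplot gcn_model
#' @export
autoplot.gcn_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "weighted cross-entropy",
                  title = "GCN training loss") +
    ggplot2::theme_minimal()
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a self-describing serialized archive of the weight
#' arrays, config, history and seed; loading restores the model bit-exactly.
#'
#' @param model a `gcn_model`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `gcn_model` (load).
#' @export
save_gcn_model <- function(model, path) {
  stopifnot(inherits(model, "gcn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_gcn_model
#' @export
load_gcn_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gcn_model")) abort_input("'%s' is not a model checkpoint", path)
  model
}
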