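test_that("normalized adjacency matches hand computations", {
  # single node: self-loop only
  g1 <- graph_from_edges(1, integer(0), integer(0))
  expect_equal(as.matrix(normalized_adjacency(g1)), matrix(1, 1, 1))

  # two nodes, one edge: D = diag(2, 2) -> all entries 1/2
  g2 <- graph_from_edges(2, 1, 2)
  expect_equal(as.matrix(normalized_adjacency(g2)), matrix(0.5, 2, 2))

  # symmetric for arbitrary undirected input; k-regular rows sum to 1
  ring <- graph_from_edges(6, 1:6, c(2:6, 1))
  S <- as.matrix(normalized_adjacency(ring))
  expect_equal(S, t(S))
  expect_equal(unname(Matrix::rowSums(S)), rep(1, 6))
})

test_that("a single layer reduces to sigma(S H W) with the expected special cases", {
  H <- diag(2)
  S2 <- normalized_adjacency(graph_from_edges(2, 1, 2))
  expect_equal(gcn_layer(H, S2, diag(2)), matrix(0.5, 2, 2))
  expect_equal(gcn_layer(H, diag(2), diag(2)), H)           # identity everywhere
  expect_equal(gcn_layer(H, S2, matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_error(gcn_layer(H, S2, matrix(0, 3, 2)), "conform")
})

test_that("layer output equals the dense brute-force evaluation on random graphs", {
  set.seed(61)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    g <- random_small_graph(n, 0.5, seed = rep + 100)
    d_in <- sample(2:5, 1); d_out <- sample(2:4, 1)
    H <- matrix(rnorm(n * d_in), n)
    W <- matrix(rnorm(d_in * d_out), d_in)
    A <- as.matrix(graph_adjacency(g))
    want <- pmax(dense_norm_adj(A) %*% H %*% W, 0)
    got <- gcn_layer(H, normalized_adjacency(g), W, activation = function(z) pmax(z, 0))
    expect_lte(max(abs(got - want)), 1e-10)
  }
})

test_that("repeated smoothing on a regular cycle contracts feature variance", {
  ring <- graph_from_edges(6, 1:6, c(2:6, 1))
  S <- normalized_adjacency(ring)
  set.seed(3)
  H <- matrix(rnorm(6), ncol = 1)
  v <- var(as.vector(H))
  for (l in 1:4) {
    H <- as.matrix(S %*% H)  # W = I, linear layer
    v_new <- var(as.vector(H))
    expect_lt(v_new, v)
    v <- v_new
  }
})

test_that("training is seed-deterministic and sensitive to the learning rate", {
  data <- small_synthetic(seed = 12, new_fraction_mirna = 0, new_fraction_disease = 0)
  neg <- sample_negatives(data$assoc, 1, seed = 1)
  pairs <- dplyr::bind_rows(
    dplyr::mutate(mdpgcn:::assoc_to_pairs(data$assoc), label = 1),
    dplyr::mutate(neg, label = 0))
  nodes <- build_mdp_nodes(pairs, data$mirna_sim, data$disease_sim)
  g <- knn_regular_graph(nodes, k = 4)
  cfg <- gcn_config(hidden = c(16, 8), epochs = 8, batches_per_epoch = 3)

  m1 <- gcn_train(nodes, g, cfg, seed = 6)
  m2 <- gcn_train(nodes, g, cfg, seed = 6)
  expect_identical(m1$history$loss, m2$history$loss)  # bitwise determinism
  expect_identical(m1$params, m2$params)

  # learning rate 0, no dropout, full graph: weights frozen, loss constant
  cfg0 <- gcn_config(hidden = c(16, 8), epochs = 4, learning_rate = 0, dropout = 0)
  m0 <- gcn_train(nodes, g, cfg0, sampler = FALSE, seed = 6)
  expect_equal(stats::sd(m0$history$loss), 0)
  init <- mdpgcn:::with_seed(mdpgcn:::derive_seed(6, 2),
                             mdpgcn:::init_params(ncol(nodes$features), cfg0))
  expect_equal(m0$params$W, init$W)

  # loss decreases under real training
  expect_lt(m1$history$loss[8], m1$history$loss[1])

  # single-class training labels are rejected
  pos_only <- dplyr::mutate(pairs[pairs$label == 1, ], label = 1)
  nodes_pos <- build_mdp_nodes(pos_only, data$mirna_sim, data$disease_sim)
  g_pos <- knn_regular_graph(nodes_pos, k = 4)
  expect_error(gcn_train(nodes_pos, g_pos, cfg, seed = 1), "both classes")
})

test_that("prediction is a full-graph forward pass with subset consistency", {
  fit <- cached_small_fit()
  all_scores <- predict_scores(fit$model, fit$graph, fit$nodes)
  expect_true(all(all_scores$score >= 0 & all_scores$score <= 1))
  sub <- predict_scores(fit$model, fit$graph, fit$nodes, node_ids = c(3, 7, 11))
  expect_equal(sub$score, all_scores$score[match(c(3, 7, 11), all_scores$node_id)])
  expect_error(predict_scores(fit$model, fit$graph, fit$nodes, node_ids = 10^6),
               "unknown node id")

  # zeroed output head gives sigmoid(0) = 0.5 everywhere
  m <- fit$model
  m$params$W_out <- m$params$W_out * 0
  m$params$b_out <- 0
  flat <- predict_scores(m, fit$graph, fit$nodes)
  expect_equal(flat$score, rep(0.5, nrow(flat)))
})

test_that("predictions are equivariant under node relabeling", {
  fit <- cached_small_fit()
  n <- fit$graph$n_nodes
  set.seed(44); perm <- sample(n)
  # permuted graph and node table; same trained weights
  g2 <- graph_from_edges(n, perm[fit$graph$edges$from], perm[fit$graph$edges$to])
  nodes2 <- fit$nodes
  inv <- order(perm)
  nodes2$features <- fit$nodes$features[inv, , drop = FALSE]
  nodes2$table <- fit$nodes$table[inv, ]
  nodes2$table$node_id <- seq_len(n)
  s1 <- predict_scores(fit$model, fit$graph, fit$nodes)
  s2 <- predict_scores(fit$model, g2, nodes2)
  expect_equal(s2$score, s1$score[inv], tolerance = 1e-10)
})

test_that("minibatch forward on an induced subgraph equals the dense restriction", {
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    g <- random_small_graph(n, 0.6, seed = rep + 300)
    probs <- edge_probabilities(g)
    s <- sample_subgraph(g, probs, M = 3, seed = rep)
    Ssub <- mdpgcn:::subgraph_operator(g, s$nodes, s$induced)
    A <- as.matrix(graph_adjacency(g))[s$nodes, s$nodes, drop = FALSE]
    expect_lte(max(abs(as.matrix(Ssub) - dense_norm_adj(A))), 1e-10)
  }
})

test_that("model checkpoints round-trip bit-exactly", {
  fit <- cached_small_fit()
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path), add = TRUE)
  save_gcn_model(fit$model, path)
  back <- load_gcn_model(path)
  expect_identical(back$params, fit$model$params)
  expect_identical(back$history, fit$model$history)
  s1 <- predict_scores(fit$model, fit$graph, fit$nodes, 1:5)
  s2 <- predict_scores(back, fit$graph, fit$nodes, 1:5)
  expect_identical(s1$score, s2$score)
})
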