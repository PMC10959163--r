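# Shared fixtures, all generated in code.

# tiny weighted gene network: g1-g2 (0.7 after normalization), g2-g3, g1-g4
tiny_gene_network <- function() {
  gene_network(tibble::tibble(
    gene1 = c("g1", "g2", "g1", "g5"),
    gene2 = c("g2", "g3", "g4", "g6"),
    # min-max over raw scores: 0 -> 0, 10 -> 1; 7 -> 0.7, 4 -> 0.4
    score = c(7, 4, 0, 10)
  ))
}

# small labeled association matrix
tiny_assoc <- function() {
  A <- matrix(c(1, 0, 0, 1, 1, 0), nrow = 3,
              dimnames = list(c("m1", "m2", "m3"), c("d1", "d2")))
  A
}

# deterministic small synthetic dataset used across modules
small_synthetic <- function(seed = 42, ...) {
  generate_synthetic(synthetic_spec(n_mirna = 40, n_disease = 30, n_blocks = 3,
                                    seed = seed, ...))
}

# direct triple-loop evaluation of the best-match-average similarity,
# independent of the package implementation
brute_force_mfsm <- function(S, sets) {
  n <- length(sets)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      gi <- sets[[i]]; gj <- sets[[j]]
      best_in <- function(g, G) max(vapply(G, function(h) S[g, h], 0))
      num <- sum(vapply(gi, best_in, 0, G = gj)) +
        sum(vapply(gj, best_in, 0, G = gi))
      M[i, j] <- num / (length(gi) + length(gj))
    }
  }
  M
}

# brute-force concordant-pair AUC (ties count half)
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# random connected-ish small graph as a pair_graph (Erdos-Renyi, no isolates)
random_small_graph <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
    A <- A + t(A)
    if (all(rowSums(A) > 0)) break
  }
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  mdpgcn:::new_pair_graph(n, tibble::tibble(from = idx[, 1], to = idx[, 2],
                                            weight = 1),
                          method = "fixture")
}

# pair_graph from an explicit undirected edge list
graph_from_edges <- function(n, from, to) {
  mdpgcn:::new_pair_graph(n, tibble::tibble(from = from, to = to,
                                            weight = rep(1, length(from))),
                          method = "fixture")
}

# dense reference computation of the normalized operator
dense_norm_adj <- function(A) {
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  diag(1 / sqrt(d)) %*% At %*% diag(1 / sqrt(d))
}

# one small trained fit reused by evaluation tests (memoized per session)
cached_small_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      fit <<- run_mda_experiment(
        small_synthetic(seed = 31, new_fraction_mirna = 0, new_fraction_disease = 0),
        tasks = "tp",
        config = gcn_config(hidden = c(32, 16), epochs = 40, batches_per_epoch = 5),
        seed = 17)
    }
    fit
  }
})
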