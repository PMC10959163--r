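#' Degree-weighted edge sampling probabilities
#'
#' Minibatch subgraphs are drawn edge by edge with probability
#' `p(e_uv) = (1/deg(u) + 1/deg(v)) / sum_{(u',v') in E} (1/deg(u') + 1/deg(v'))`,
#' favouring edges incident to low-degree nodes so every edge keeps a
#' non-negligible chance of appearing. On a regular graph all degrees cancel
#' and the law is uniform over edges.
#'
#' @param graph a `pair_graph` with at least one edge.
#' @return an object of class `edge_prob`: tibble with columns `from`, `to`,
#'   `prob`, row-aligned with `graph$edges` and summing to 1.
#' @export
edge_probabilities <- function(graph) {
  stopifnot(inherits(graph, "pair_graph"))
  if (nrow(graph$edges) == 0) abort_input("graph has no edges to sample")
  deg <- graph$degree
  raw <- 1 / deg[graph$edges$from] + 1 / deg[graph$edges$to]
  out <- tibble::tibble(from = graph$edges$from, to = graph$edges$to,
                        prob = raw / sum(raw))
  class(out) <- c("edge_prob", class(out))
  out
}

#' Draw one edge-sampled subgraph
#'
#' `M` edges are drawn independently with replacement according to the
#' degree-weighted law; the subgraph's node set is the union of sampled
#' endpoints and its edge set is induced (every full-graph edge with both
#' endpoints in the node set), which is what the in-subgraph propagation
#' step sees during training.
#'
#' @param graph a `pair_graph`.
#' @param probs matching [edge_probabilities()].
#' @param M number of edge draws (with replacement).
#' @param seed RNG seed; the draw is deterministic given it.
#' @return an object of class `subgraph_sample`: list with `edge_draws`
#'   (length-`M` indices into `graph$edges`), `nodes` (sorted node ids) and
#'   `induced` (indices of the induced edges in `graph$edges`).
#' @export
sample_subgraph <- function(graph, probs, M, seed = 1) {
  stopifnot(inherits(graph, "pair_graph"), inherits(probs, "edge_prob"))
  if (M < 1) abort_input("M must be at least 1")
  draws <- with_seed(seed,
    sample.int(nrow(probs), M, replace = TRUE, prob = probs$prob))
  in_set <- logical(graph$n_nodes)
  in_set[c(probs$from[draws], probs$to[draws])] <- TRUE
  induced <- which(in_set[graph$edges$from] & in_set[graph$edges$to])
  structure(list(edge_draws = draws, nodes = which(in_set), induced = induced),
            class = "subgraph_sample")
}

#' Estimate the bias-correcting normalization coefficients
#'
#' Edge-sampled subgraphs over-represent some nodes and edges. Running `N`
#' independent pre-sampling subgraphs, the node frequency `C_v` and induced
#' edge frequency `C_uv` define `lambda_v = C_v / N` (used to reweight the
#' per-node training loss by `1 / lambda_v`) and `alpha_uv = C_uv / C_v`
#' (used to rescale the `(u, v)` aggregation term inside a subgraph).
#' Nodes never seen get `lambda_v = 0` and undefined alpha entries (`NA`).
#'
#' @param graph a `pair_graph`.
#' @param probs matching [edge_probabilities()].
#' @param M edge draws per subgraph.
#' @param N number of pre-sampling subgraphs.
#' @param seed RNG seed.
#' @return an object of class `norm_coef`: list with `lambda` (tibble
#'   `node`, `C`, `lambda`), `alpha` (tibble `from`, `to`, `C_uv`,
#'   `alpha_from`, `alpha_to`, row-aligned with `graph$edges`; `alpha_to` is
#'   `C_uv / C_v` of the receiving endpoint `to`), and `N`, `M`.
#' @export
estimate_normalization <- function(graph, probs, M, N = 50, seed = 1) {
  stopifnot(inherits(graph, "pair_graph"), inherits(probs, "edge_prob"))
  if (N < 1) abort_input("N must be at least 1")
  if (M < 1) abort_input("M must be at least 1")
  n <- graph$n_nodes
  draws <- with_seed(seed,
    matrix(sample.int(nrow(probs), M * N, replace = TRUE, prob = probs$prob), M, N))
  # covered[v, j]: node v appears in subgraph j
  covered <- matrix(FALSE, n, N)
  for (j in seq_len(N)) {
    covered[c(probs$from[draws[, j]], probs$to[draws[, j]]), j] <- TRUE
  }
  C_v <- rowSums(covered)
  C_uv <- rowSums(covered[graph$edges$from, , drop = FALSE] &
                  covered[graph$edges$to, , drop = FALSE])
  alpha_from <- ifelse(C_v[graph$edges$from] > 0, C_uv / C_v[graph$edges$from], NA_real_)
  alpha_to <- ifelse(C_v[graph$edges$to] > 0, C_uv / C_v[graph$edges$to], NA_real_)
  structure(list(
    lambda = tibble::tibble(node = seq_len(n), C = C_v, lambda = C_v / N),
    alpha = tibble::tibble(from = graph$edges$from, to = graph$edges$to,
                           C_uv = C_uv, alpha_from = alpha_from,
                           alpha_to = alpha_to),
    N = N, M = M
  ), class = "norm_coef")
}

#' @export
print.norm_coef <- function(x, ...) {
  cat(sprintf("norm_coef: %d nodes (%d never sampled), %d edges, N = %d, M = %d\n",
              nrow(x$lambda), sum(x$lambda$C == 0), nrow(x$alpha), x$N, x$M))
  invisible(x)
}

#' Export sampler probabilities or coefficients as delimited text
#'
#' @param x an `edge_prob` or `norm_coef` object.
#' @param path output file; tab-delimited.
#' @return `path`, invisibly.
#' @export
write_sampler_table <- function(x, path) {
  if (inherits(x, "norm_coef")) {
    utils::write.table(dplyr::left_join(x$alpha, x$lambda,
                                        by = c(from = "node")),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
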