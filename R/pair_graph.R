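#' Sample negative miRNA-disease pairs from the unlabeled zeros
#'
#' Known associations are the positives; all zero cells of the association
#' matrix are unlabeled, and a balanced negative set is drawn from them
#' uniformly without replacement.
#'
#' @param assoc binary association matrix with dimnames.
#' @param ratio negatives per positive; the count is `round(ratio * positives)`.
#' @param seed RNG seed; the draw is deterministic given it.
#' @return tibble with columns `mirna`, `disease`.
#' @export
sample_negatives <- function(assoc, ratio = 1, seed = 1) {
  check_association(assoc)
  if (ratio <= 0) abort_input("ratio must be positive")
  n_pos <- sum(assoc)
  n_neg <- round(ratio * n_pos)
  zeros <- which(assoc == 0)
  if (length(zeros) < n_neg) {
    abort_input("only %d unknown pairs available, %d negatives requested",
                length(zeros), n_neg)
  }
  picked <- with_seed(seed, sort(sample(zeros, n_neg)))
  tibble::tibble(
    mirna = rownames(assoc)[(picked - 1) %% nrow(assoc) + 1],
    disease = colnames(assoc)[(picked - 1) %/% nrow(assoc) + 1]
  )
}

#' Assemble miRNA-disease pair nodes with concatenated similarity features
#'
#' Every (miRNA, disease) pair becomes one node of the homogeneous graph.
#' Its feature vector concatenates the miRNA's row of the integrated miRNA
#' similarity matrix with the disease's row of the integrated disease
#' similarity matrix, so feature length is `n_mirna + n_disease`.
#'
#' @param pairs data frame with columns `mirna`, `disease`, `label` (0/1)
#'   and optionally `role` (defaults to `"train"`) and `truth` (the held-out
#'   true label for masked test nodes). In the graph-construction view
#'   masked test nodes carry observed label 0.
#' @param mirna_sim,disease_sim integrated [similarity_matrix()]s.
#' @return an object of class `mdp_nodes`: list with `table` (tibble:
#'   `node_id`, `mirna`, `disease`, `label`, `role`, `truth`) and `features`
#'   (numeric matrix, one row per node).
#' @export
build_mdp_nodes <- function(pairs, mirna_sim, disease_sim) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("mirna", "disease", "label") %in% names(pairs))) {
    abort_input("pairs need columns mirna, disease, label")
  }
  if (!all(pairs$label %in% c(0, 1))) abort_input("pair labels must be 0/1")
  key <- paste(pairs$mirna, pairs$disease, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- pairs[duplicated(key), ][1, ]
    abort_input("duplicate pair (%s, %s)", dup$mirna, dup$disease)
  }
  mi <- match(pairs$mirna, rownames(mirna_sim))
  di <- match(pairs$disease, rownames(disease_sim))
  if (anyNA(mi)) abort_input("unknown miRNA '%s'", pairs$mirna[which(is.na(mi))[1]])
  if (anyNA(di)) abort_input("unknown disease '%s'", pairs$disease[which(is.na(di))[1]])

  features <- cbind(mirna_sim[mi, , drop = FALSE], disease_sim[di, , drop = FALSE])
  dimnames(features) <- NULL
  table <- tibble::tibble(
    node_id = seq_len(nrow(pairs)),
    mirna = as.character(pairs$mirna),
    disease = as.character(pairs$disease),
    label = as.numeric(pairs$label),
    role = if ("role" %in% names(pairs)) as.character(pairs$role) else "train",
    truth = if ("truth" %in% names(pairs)) as.numeric(pairs$truth) else as.numeric(pairs$label)
  )
  structure(list(table = table, features = features), class = "mdp_nodes")
}

#' @export
print.mdp_nodes <- function(x, ...) {
  cat(sprintf("mdp_nodes: %d pair nodes, feature length %d (%d train / %d masked)\n",
              nrow(x$table), ncol(x$features),
              sum(x$table$role == "train"), sum(x$table$role != "train")))
  invisible(x)
}

#' @method tidy mdp_nodes
#' @export
tidy.mdp_nodes <- function(x, ...) x$table

node_features <- function(nodes) {
  if (inherits(nodes, "mdp_nodes")) nodes$features
  else if (is.matrix(nodes)) nodes
  else abort_input("expected an mdp_nodes object or a feature matrix")
}

new_pair_graph <- function(n_nodes, edges, method, params = list(),
                           node_type = NULL, entity = NULL, features = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  if (any(edges$from == edges$to)) abort_input("self-edges are not stored")
  deg <- tabulate(c(edges$from, edges$to), nbins = n_nodes)
  structure(list(n_nodes = n_nodes, edges = edges, degree = deg,
                 method = method, params = params,
                 node_type = node_type, entity = entity, features = features),
            class = "pair_graph")
}

#' @export
print.pair_graph <- function(x, ...) {
  cat(sprintf("pair_graph (%s): %d nodes, %d edges, degree range [%d, %d]\n",
              x$method, x$n_nodes, nrow(x$edges),
              if (x$n_nodes) min(x$degree) else 0L,
              if (x$n_nodes) max(x$degree) else 0L))
  invisible(x)
}

#' Sparse adjacency matrix of a pair graph
#'
#' @param graph a `pair_graph`.
#' @param weighted use stored edge weights instead of 0/1.
#' @return a symmetric sparse `Matrix`.
#' @export
graph_adjacency <- function(graph, weighted = FALSE) {
  stopifnot(inherits(graph, "pair_graph"))
  w <- if (weighted) graph$edges$weight else rep(1, nrow(graph$edges))
  Matrix::sparseMatrix(i = c(graph$edges$from, graph$edges$to),
                       j = c(graph$edges$to, graph$edges$from),
                       x = c(w, w), dims = c(graph$n_nodes, graph$n_nodes))
}

#' Exactly k-regular pair graph by mutual k-nearest neighbours with repair
#'
#' Builds the regular homogeneous graph over miRNA-disease pair nodes:
#' (i) pairwise distances between node features; (ii) each node selects its
#' `k` nearest neighbours (ties broken by lowest node index); (iii) only
#' mutual selections are kept as edges, weighted by the mean of the two
#' directed distances; (iv) a deterministic repair pass then raises every
#' deficient node back to degree exactly `k`: nodes are visited in ascending
#' degree order and connected to their nearest non-adjacent node that is
#' also deficient; if pairing stalls, the lowest-degree deficient node is
#' connected to its nearest non-neighbour and, when that partner exceeds
#' `k`, the partner's farthest surplus edge is dropped. The result is
#' exactly k-regular, which an undirected graph admits whenever `n * k` is
#' even.
#'
#' @param nodes an [build_mdp_nodes()] result or a raw feature matrix.
#' @param k target degree; `1 <= k < n` and `n * k` even.
#' @param metric `"euclidean"` on raw features or `"cosine"` (distance
#'   `1 - cosine similarity`).
#' @return a `pair_graph` with every degree equal to `k`.
#' @export
knn_regular_graph <- function(nodes, k = 5, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  X <- node_features(nodes)
  n <- nrow(X)
  if (k < 1) abort_input("k must be at least 1")
  if (k >= n) abort_input("k (%d) must be below the number of nodes (%d)", k, n)
  if ((n * k) %% 2 == 1) {
    abort_input("no k-regular graph on %d nodes exists for odd k = %d", n, k)
  }
  X <- prepare_metric(X, metric)
  mutual <- mutual_knn_edges(X, k)
  reg <- repair_regularity(mutual$adj, mutual$wadj, X, k)
  edges_from_adj(reg$adj, reg$wadj, n, method = "regular",
                 params = list(k = k, metric = metric))
}

prepare_metric <- function(X, metric) {
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    nrm[nrm == 0] <- 1
    X <- X / nrm  # euclidean on unit vectors is monotone in cosine distance
  }
  X
}

# Directed k-NN then mutual symmetrization. Returns neighbour lists:
# adj[[i]] = sorted neighbour indices, wadj[[i]] = matching distances.
mutual_knn_edges <- function(X, k, block = 1024L) {
  n <- nrow(X)
  row_norms <- rowSums(X^2)
  nn <- matrix(0L, n, k)
  nd <- matrix(0, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d <- rowwise_sqdist(X, rows, row_norms)
    d[cbind(seq_along(rows), rows)] <- Inf
    for (r in seq_along(rows)) {
      ord <- order(d[r, ], seq_len(n))[seq_len(k)]
      nn[rows[r], ] <- ord
      nd[rows[r], ] <- sqrt(d[r, ord])
    }
  }
  # mutual: i selected j and j selected i
  from <- rep(seq_len(n), each = k)
  sel <- Matrix::sparseMatrix(i = from, j = as.vector(t(nn)), x = 1, dims = c(n, n))
  mut <- methods::as(sel * Matrix::t(sel), "TsparseMatrix")
  idx <- cbind(mut@i + 1L, mut@j + 1L)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  adj <- vector("list", n)
  wadj <- vector("list", n)
  dist_lookup <- stats::setNames(as.vector(t(nd)), paste(from, as.vector(t(nn))))
  if (nrow(idx)) {
    w <- unname(dist_lookup[paste(idx[, 1], idx[, 2])] +
                dist_lookup[paste(idx[, 2], idx[, 1])]) / 2
    for (e in seq_len(nrow(idx))) {
      i <- idx[e, 1]; j <- idx[e, 2]
      adj[[i]] <- c(adj[[i]], j); wadj[[i]] <- c(wadj[[i]], w[e])
      adj[[j]] <- c(adj[[j]], i); wadj[[j]] <- c(wadj[[j]], w[e])
    }
  }
  list(adj = adj, wadj = wadj)
}

# Deterministic regularity repair; see knn_regular_graph() docs.
repair_regularity <- function(adj, wadj, X, k) {
  n <- nrow(X)
  deg <- vapply(adj, length, 0L)
  row_norms <- rowSums(X^2)
  add_edge <- function(i, j, w) {
    adj[[i]] <<- c(adj[[i]], j); wadj[[i]] <<- c(wadj[[i]], w)
    adj[[j]] <<- c(adj[[j]], i); wadj[[j]] <<- c(wadj[[j]], w)
    deg[i] <<- deg[i] + 1L; deg[j] <<- deg[j] + 1L
  }
  drop_edge <- function(i, j) {
    pi <- match(j, adj[[i]]); pj <- match(i, adj[[j]])
    adj[[i]] <<- adj[[i]][-pi]; wadj[[i]] <<- wadj[[i]][-pi]
    adj[[j]] <<- adj[[j]][-pj]; wadj[[j]] <<- wadj[[j]][-pj]
    deg[i] <<- deg[i] - 1L; deg[j] <<- deg[j] - 1L
  }
  guard <- 0L
  repeat {
    defic <- which(deg < k)
    if (!length(defic)) break
    guard <- guard + 1L
    if (guard > 4L * n) abort_input("regularity repair failed to converge")
    added <- 0L
    if (length(defic) >= 2L) {
      # nearest-deficient candidate lists, computed in blocks
      cand <- deficient_candidates(X, defic, row_norms)
      order_u <- defic[order(deg[defic], defic)]
      for (u in order_u) {
        while (deg[u] < k) {
          pool <- cand[[as.character(u)]]
          pick <- NA_integer_
          for (v in pool) {
            if (deg[v] < k && v != u && !(v %in% adj[[u]])) { pick <- v; break }
          }
          if (is.na(pick)) break
          add_edge(u, pick, sqrt(max(sum((X[u, ] - X[pick, ])^2), 0)))
          added <- added + 1L
        }
      }
    }
    if (added == 0L) {
      # pairing stalled: connect the worst-off node to its nearest
      # non-neighbour, then shed that partner's farthest surplus edge
      u <- defic[order(deg[defic], defic)][1]
      d <- as.vector(rowwise_sqdist(X, u, row_norms))
      d[c(u, adj[[u]])] <- Inf
      w <- order(d, seq_len(n))[1]
      if (!is.finite(d[w])) abort_input("regularity repair exhausted candidates")
      add_edge(u, w, sqrt(d[w]))
      if (deg[w] > k) {
        others <- setdiff(adj[[w]], u)
        far <- others[order(-wadj[[w]][match(others, adj[[w]])], others)][1]
        drop_edge(w, far)
      }
    }
  }
  list(adj = adj, wadj = wadj)
}

# For each deficient node, its deficient peers ordered by distance
# (ties by index), truncated to a candidate budget.
deficient_candidates <- function(X, defic, row_norms, budget = 64L, block = 512L) {
  m <- length(defic)
  keep <- min(budget, m - 1L)
  out <- vector("list", m)
  names(out) <- as.character(defic)
  for (start in seq(1L, m, by = block)) {
    rows <- defic[start:min(start + block - 1L, m)]
    d <- rowwise_sqdist(X, rows, row_norms)[, defic, drop = FALSE]
    for (r in seq_along(rows)) {
      dr <- d[r, ]
      dr[defic == rows[r]] <- Inf
      ord <- order(dr, defic)[seq_len(keep)]
      out[[as.character(rows[r])]] <- defic[ord]
    }
  }
  out
}

edges_from_adj <- function(adj, wadj, n, method, params) {
  from <- integer(0); to <- integer(0); weight <- numeric(0)
  for (i in seq_len(n)) {
    sel <- adj[[i]] > i
    if (any(sel)) {
      from <- c(from, rep(i, sum(sel)))
      to <- c(to, adj[[i]][sel])
      weight <- c(weight, wadj[[i]][sel])
    }
  }
  new_pair_graph(n, tibble::tibble(from = from, to = to, weight = weight),
                 method = method, params = params)
}

#' Non-regular pair graph from k-means cliques
#'
#' Contrast builder for the non-regular homogeneous architecture: node
#' features are partitioned by k-means and each cluster becomes an
#' unweighted clique, so degrees vary with cluster sizes.
#'
#' @param nodes an [build_mdp_nodes()] result or feature matrix.
#' @param n_clusters number of clusters (tuned value in the source study: 300).
#' @param seed RNG seed for the k-means restarts.
#' @return a `pair_graph` with method `"kmeans"`.
#' @export
kmeans_graph <- function(nodes, n_clusters = 300, seed = 1) {
  X <- node_features(nodes)
  n <- nrow(X)
  if (n_clusters < 1) abort_input("n_clusters must be at least 1")
  if (n_clusters > n) abort_input("n_clusters (%d) exceeds node count (%d)", n_clusters, n)
  cl <- if (n_clusters == n) seq_len(n) else if (n_clusters == 1) rep(1L, n) else {
    with_seed(seed,
      stats::kmeans(X, centers = n_clusters, nstart = 10, iter.max = 100)$cluster)
  }
  members <- split(seq_len(n), cl)
  from <- integer(0); to <- integer(0)
  for (grp in members) {
    if (length(grp) > 1) {
      pairs <- utils::combn(sort(grp), 2)
      from <- c(from, pairs[1, ]); to <- c(to, pairs[2, ])
    }
  }
  new_pair_graph(n, tibble::tibble(from = from, to = to, weight = rep(1, length(from))),
                 method = "kmeans",
                 params = list(n_clusters = n_clusters, seed = seed))
}

#' Heterogeneous entity graph over miRNAs and diseases
#'
#' Contrast builder for the heterogeneous architecture: one node per entity,
#' a fully connected miRNA-miRNA block weighted by the integrated miRNA
#' similarity, a fully connected disease-disease block weighted by the
#' integrated disease similarity, and a bipartite block holding the binary
#' training associations. Per-type node features are the similarity rows.
#'
#' @param mirna_sim,disease_sim integrated [similarity_matrix()]s.
#' @param assoc binary association matrix whose labels match the similarity
#'   matrices.
#' @return a `pair_graph` with method `"hetero"`, `node_type` in
#'   `{"mirna", "disease"}` and entity labels attached.
#' @export
hetero_graph <- function(mirna_sim, disease_sim, assoc) {
  check_association(assoc)
  if (!identical(rownames(assoc), rownames(mirna_sim)) ||
      !identical(colnames(assoc), rownames(disease_sim))) {
    abort_input("association labels must match the similarity matrices")
  }
  nm <- nrow(mirna_sim); nd <- nrow(disease_sim)
  block_pairs <- function(n, offset, W) {
    if (n < 2) return(NULL)
    pairs <- which(upper.tri(W), arr.ind = TRUE)
    tibble::tibble(from = pairs[, 1] + offset, to = pairs[, 2] + offset,
                   weight = W[pairs])
  }
  links <- which(assoc == 1, arr.ind = TRUE)
  edges <- dplyr::bind_rows(
    block_pairs(nm, 0L, mirna_sim),
    block_pairs(nd, nm, disease_sim),
    if (nrow(links)) tibble::tibble(from = links[, 1], to = nm + links[, 2],
                                    weight = 1)
  )
  new_pair_graph(nm + nd, edges, method = "hetero",
                 params = list(n_mirna = nm, n_disease = nd),
                 node_type = c(rep("mirna", nm), rep("disease", nd)),
                 entity = c(rownames(mirna_sim), rownames(disease_sim)),
                 features = list(mirna = mirna_sim, disease = disease_sim))
}
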