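#' Construct and validate a labeled similarity matrix
#'
#' Similarity matrices are plain numeric matrices with identical row and
#' column labels, entries in \[0, 1\] and symmetry up to a small tolerance.
#' All similarity producers in the package return matrices that satisfy this
#' validator.
#'
#' @param values square numeric matrix.
#' @param labels character vector of entity labels; defaults to the existing
#'   dimnames of `values`.
#' @param tol absolute tolerance for the symmetry check.
#' @return the validated matrix with dimnames set to `labels`.
#' @export
similarity_matrix <- function(values, labels = rownames(values), tol = 1e-12) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_input("similarity values must be a numeric matrix")
  }
  if (nrow(values) != ncol(values)) {
    abort_input("similarity matrix must be square (got %d x %d)",
                nrow(values), ncol(values))
  }
  if (is.null(labels) || length(labels) != nrow(values)) {
    abort_input("similarity matrix needs one label per row")
  }
  dimnames(values) <- list(labels, labels)
  if (anyNA(values)) abort_input("similarity matrix contains NA")
  if (min(values) < -tol || max(values) > 1 + tol) {
    bad <- which(values < -tol | values > 1 + tol, arr.ind = TRUE)[1, ]
    abort_input("similarity value out of [0, 1] at (%s, %s): %g",
                labels[bad[1]], labels[bad[2]], values[bad[1], bad[2]])
  }
  asym <- max(abs(values - t(values)))
  if (asym > max(tol, 1e-8)) {
    abort_input("similarity matrix asymmetric (max |M - t(M)| = %g)", asym)
  }
  values
}

#' Build a gene-gene interaction network from weighted edges
#'
#' Edge scores (e.g. log-likelihood scores of functional linkage) are min-max
#' normalized to \[0, 1\]: the observed minimum maps to 0 and the maximum to 1.
#' A constant-score network maps every weight to 1. Self-edges are dropped;
#' gene identity is handled by [gene_similarity()] directly.
#'
#' @param edges data frame with columns `gene1`, `gene2`, `score`.
#' @return an object of class `gene_network` with elements `genes` (ordered
#'   identifiers) and `weights` (named lookup of normalized edge weights).
#' @export
gene_network <- function(edges) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("gene1", "gene2", "score") %in% names(edges))) {
    abort_input("gene network edges need columns gene1, gene2, score")
  }
  edges <- dplyr::filter(edges, .data$gene1 != .data$gene2)
  genes <- unique(c(rbind(as.character(edges$gene1), as.character(edges$gene2))))
  score <- as.numeric(edges$score)
  rng <- range(score)
  w <- if (diff(rng) == 0) rep(1, length(score)) else (score - rng[1]) / diff(rng)
  key <- edge_key(as.character(edges$gene1), as.character(edges$gene2))
  weights <- stats::setNames(w, key)
  # duplicate edges keep the last normalized weight
  weights <- weights[!duplicated(names(weights), fromLast = TRUE)]
  structure(list(genes = genes, weights = weights), class = "gene_network")
}

edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Functional similarity between two genes
#'
#' Identity scores 1; a network edge scores its min-max-normalized weight;
#' any other pair scores 0.
#'
#' @param network a [gene_network()].
#' @param g_i,g_j gene identifiers known to the network.
#' @return a score in \[0, 1\].
#' @export
gene_similarity <- function(network, g_i, g_j) {
  stopifnot(inherits(network, "gene_network"))
  for (g in c(g_i, g_j)) {
    if (!g %in% network$genes) abort_input("unknown gene id '%s'", g)
  }
  if (g_i == g_j) return(1)
  w <- network$weights[edge_key(g_i, g_j)]
  if (is.na(w)) 0 else unname(w)
}

# Dense gene-gene similarity matrix over the listed genes.
gene_similarity_matrix <- function(network, genes) {
  n <- length(genes)
  S <- matrix(0, n, n, dimnames = list(genes, genes))
  diag(S) <- 1
  if (length(network$weights)) {
    parts <- strsplit(names(network$weights), "\r", fixed = TRUE)
    a <- vapply(parts, `[`, "", 1L)
    b <- vapply(parts, `[`, "", 2L)
    keep <- a %in% genes & b %in% genes
    if (any(keep)) {
      ia <- match(a[keep], genes)
      ib <- match(b[keep], genes)
      w <- unname(network$weights[keep])
      S[cbind(ia, ib)] <- w
      S[cbind(ib, ia)] <- w
    }
  }
  S
}

#' miRNA functional similarity from shared target-gene neighbourhoods
#'
#' Two miRNAs are similar when each gene associated with one has a close
#' functional partner among the genes associated with the other. For miRNAs
#' with gene sets `G_i`, `G_j` the score is the best-match average
#' `(sum_{g in G_i} S(g, G_j) + sum_{g in G_j} S(g, G_i)) / (|G_i| + |G_j|)`
#' where `S(g, G) = max_{g_t in G} S(g, g_t)` and `S(., .)` is
#' [gene_similarity()].
#'
#' @param network a [gene_network()].
#' @param gene_sets data frame with columns `mirna`, `gene`, one association
#'   per row; every miRNA needs a nonempty set and every gene must be known
#'   to the network.
#' @return a [similarity_matrix()] over the miRNAs (first-appearance order).
#' @export
mirna_functional_similarity <- function(network, gene_sets) {
  gene_sets <- tibble::as_tibble(gene_sets)
  if (!all(c("mirna", "gene") %in% names(gene_sets))) {
    abort_input("gene sets need columns mirna, gene")
  }
  mirnas <- unique(as.character(gene_sets$mirna))
  sets <- split(as.character(gene_sets$gene), factor(as.character(gene_sets$mirna), levels = mirnas))
  for (m in mirnas) {
    if (length(sets[[m]]) == 0) abort_input("empty gene set for miRNA '%s'", m)
    missing <- setdiff(sets[[m]], network$genes)
    if (length(missing)) abort_input("unknown gene id '%s'", missing[1])
  }
  genes <- unique(unlist(sets, use.names = FALSE))
  S <- gene_similarity_matrix(network, genes)
  n <- length(mirnas)
  M <- matrix(1, n, n, dimnames = list(mirnas, mirnas))
  idx <- lapply(sets, match, genes)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        sub <- S[idx[[i]], idx[[j]], drop = FALSE]
        val <- (sum(apply(sub, 1, max)) + sum(apply(sub, 2, max))) /
          (length(idx[[i]]) + length(idx[[j]]))
        M[i, j] <- M[j, i] <- val
      }
    }
  }
  similarity_matrix(M)
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Each entity's binary association profile (its row or column of the
#' association matrix) is compared with a Gaussian kernel:
#' `K(i, j) = exp(-gamma * ||P_i - P_j||^2)` with bandwidth
#' `gamma = gamma_prime / mean_i(||P_i||^2)`, the mean running over the
#' profiles being compared. With every profile zero the bandwidth is
#' undefined and an error of class `mdpgcn_zero_profile` is raised so the
#' caller can fall back to the semantic/functional matrix alone.
#'
#' @param assoc binary association matrix, miRNAs in rows, diseases in
#'   columns, with dimnames.
#' @param axis `"mirna"` compares row profiles, `"disease"` column profiles.
#' @param gamma_prime initial bandwidth, by convention 1.
#' @return a [similarity_matrix()] over the entities on the chosen axis.
#' @export
gip_kernel_similarity <- function(assoc, axis = c("mirna", "disease"), gamma_prime = 1) {
  axis <- match.arg(axis)
  check_association(assoc)
  P <- if (axis == "mirna") assoc else t(assoc)
  labels <- rownames(P)
  if (gamma_prime < 0) abort_input("gamma_prime must be nonnegative")
  norms <- rowSums(P^2)
  if (all(norms == 0)) {
    rlang::abort("all association profiles are zero; GIP bandwidth undefined",
                 class = c("mdpgcn_zero_profile", "mdpgcn_input_error"))
  }
  gamma <- if (gamma_prime == 0) 0 else gamma_prime / mean(norms)
  sq <- outer(norms, norms, "+") - 2 * tcrossprod(P)
  sq[sq < 0] <- 0
  K <- exp(-gamma * sq)
  diag(K) <- 1
  similarity_matrix((K + t(K)) / 2, labels)
}

#' Average two disease semantic similarity matrices element-wise
#'
#' Combines two semantic similarity readings of the same disease set (e.g.
#' one built from shared ontology ancestry, one from term specificity) into
#' their entrywise mean.
#'
#' @param dssm1,dssm2 similarity matrices with identical labels in identical
#'   order.
#' @return the entrywise mean, a [similarity_matrix()].
#' @export
average_semantic_similarity <- function(dssm1, dssm2) {
  if (!identical(rownames(dssm1), rownames(dssm2))) {
    abort_input("semantic similarity matrices have mismatched labels")
  }
  similarity_matrix((dssm1 + dssm2) / 2, rownames(dssm1))
}

#' Fill zero entries of a similarity matrix from a kernel matrix
#'
#' Functional/semantic similarity matrices are typically sparse; wherever the
#' primary matrix is exactly zero the GIP kernel value is substituted,
#' otherwise the primary value is kept. This yields the integrated miRNA
#' (IMSM) and disease (IDSM) similarity matrices used as node features.
#'
#' @param primary the functional (miRNA) or semantic (disease) matrix.
#' @param gip the matching GIP kernel matrix, same labels and order.
#' @return a [similarity_matrix()] with unit diagonal.
#' @export
integrate_similarity <- function(primary, gip) {
  if (!identical(dim(primary), dim(gip)) ||
      !identical(rownames(primary), rownames(gip))) {
    abort_input("primary and GIP matrices must share shape and labels")
  }
  out <- ifelse(primary != 0, primary, gip)
  diag(out) <- 1
  similarity_matrix(out, rownames(primary))
}

check_association <- function(assoc) {
  if (!is.matrix(assoc) || !is.numeric(assoc)) {
    abort_input("association matrix must be a numeric matrix")
  }
  if (length(assoc) == 0) abort_input("association matrix is empty")
  if (!all(assoc %in% c(0, 1))) abort_input("association matrix entries must be 0/1")
  if (is.null(rownames(assoc)) || is.null(colnames(assoc))) {
    abort_input("association matrix needs miRNA row names and disease column names")
  }
  invisible(assoc)
}
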