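#' Integrated similarity features from training associations
#'
#' Computes the GIP kernel on the training association matrix and integrates
#' it with the functional (miRNA) and semantic (disease) matrices. Entities
#' with an all-zero training profile (new entities, or entities whose links
#' are all held out) have no kernel information: their kernel rows/columns
#' are left at zero so integration falls back to the functional/semantic
#' similarity alone, avoiding test-association leakage into features.
#'
#' @param assoc_train binary training association matrix (miRNAs x
#'   diseases); zero rows/columns are allowed.
#' @param mirna_sim,disease_sim functional / semantic similarity matrices
#'   covering all entities of `assoc_train`.
#' @param gamma_prime GIP bandwidth parameter.
#' @return list with `imsm` and `idsm`, both [similarity_matrix()]s.
#' @export
integrated_features <- function(assoc_train, mirna_sim, disease_sim,
                                gamma_prime = 1) {
  if (!identical(rownames(assoc_train), rownames(mirna_sim)) ||
      !identical(colnames(assoc_train), rownames(disease_sim))) {
    abort_input("association labels must match the similarity matrices")
  }
  embed_gip <- function(axis) {
    labels <- if (axis == "mirna") rownames(assoc_train) else colnames(assoc_train)
    profiles <- if (axis == "mirna") rowSums(assoc_train) else colSums(assoc_train)
    full <- matrix(0, length(labels), length(labels),
                   dimnames = list(labels, labels))
    live <- which(profiles > 0)
    if (length(live) >= 1) {
      sub <- if (axis == "mirna") assoc_train[live, , drop = FALSE]
             else assoc_train[, live, drop = FALSE]
      K <- gip_kernel_similarity(sub, axis, gamma_prime)
      full[live, live] <- K
    }
    diag(full) <- 1
    full
  }
  list(imsm = integrate_similarity(mirna_sim, embed_gip("mirna")),
       idsm = integrate_similarity(disease_sim, embed_gip("disease")))
}

assoc_to_pairs <- function(assoc) {
  idx <- which(assoc == 1, arr.ind = TRUE)
  tibble::tibble(mirna = rownames(assoc)[idx[, 1]],
                 disease = colnames(assoc)[idx[, 2]])
}

pairs_to_assoc <- function(pairs, mirnas, diseases) {
  A <- matrix(0, length(mirnas), length(diseases),
              dimnames = list(mirnas, diseases))
  A[cbind(match(pairs$mirna, mirnas), match(pairs$disease, diseases))] <- 1
  A
}

#' Run one full association-prediction experiment
#'
#' End-to-end run on one dataset and one seed: hold out a fraction of the
#' old-old positives as the `tp` test set and route associations of held-out
#' new entities to `td`/`tm`/`tn`; sample balanced negatives per set;
#' compute integrated features from the training associations only; insert
#' every test pair as a label-masked node; build the pair graph; train the
#' GCN (edge-sampled minibatches by default); score the masked nodes and
#' report the five metrics per requested task.
#'
#' @param data a [generate_synthetic()] result, or any list with `assoc`,
#'   `mirna_sim`, `disease_sim` and optionally `registries` naming
#'   old/new entities.
#' @param tasks subset of `c("tp", "td", "tm", "tn")` to evaluate.
#' @param graph_method `"regular"` (mutual k-NN, exactly k-regular) or
#'   `"kmeans"` (clique contrast builder).
#' @param k degree of the regular graph.
#' @param n_clusters clusters for the k-means builder.
#' @param use_sampler train with edge-sampled minibatches (`TRUE`) or the
#'   full graph (`FALSE`).
#' @param config a [gcn_config()].
#' @param neg_ratio negatives per positive in train and test sets.
#' @param holdout_fraction fraction of old-old positives held out as `tp`.
#' @param gamma_prime GIP bandwidth parameter.
#' @param seed seed driving holdout, negative sampling, graph and training.
#' @return an object of class `mda_fit`: list with `model`, `graph`,
#'   `nodes`, `split`, `scores` (tibble for all masked test nodes) and
#'   `metrics` (tibble, one row per evaluated task).
#' @export
run_mda_experiment <- function(data, tasks = "tp",
                               graph_method = c("regular", "kmeans"),
                               k = 5, n_clusters = 300, use_sampler = TRUE,
                               config = gcn_config(), neg_ratio = 1,
                               holdout_fraction = 0.2, gamma_prime = 1,
                               seed = 1) {
  graph_method <- match.arg(graph_method)
  tasks <- match.arg(tasks, c("tp", "td", "tm", "tn"), several.ok = TRUE)
  assoc <- data$assoc
  check_association(assoc)
  reg <- data$registries %||% list(old_mirnas = rownames(assoc),
                                   new_mirnas = character(0),
                                   old_diseases = colnames(assoc),
                                   new_diseases = character(0))

  pos <- assoc_to_pairs(assoc)
  is_old <- pos$mirna %in% reg$old_mirnas & pos$disease %in% reg$old_diseases
  old_pos <- pos[is_old, ]
  new_entity_pos <- pos[!is_old, ]

  n_hold <- round(holdout_fraction * nrow(old_pos))
  hold_idx <- with_seed(derive_seed(seed, 3),
                        sort(sample.int(nrow(old_pos), n_hold)))
  train_pos <- old_pos[setdiff(seq_len(nrow(old_pos)), hold_idx), ]
  new_assoc <- dplyr::bind_rows(old_pos[hold_idx, ], new_entity_pos)

  split <- make_task_splits(train_pos, new_assoc,
                            old_mirnas = reg$old_mirnas,
                            old_diseases = reg$old_diseases,
                            neg_ratio = neg_ratio,
                            seed = derive_seed(seed, 4))

  A_train <- pairs_to_assoc(split$train[split$train$label == 1, ],
                            rownames(assoc), colnames(assoc))
  feats <- integrated_features(A_train, data$mirna_sim, data$disease_sim,
                               gamma_prime)

  pair_tbl <- dplyr::bind_rows(
    dplyr::mutate(split$train, role = "train", truth = .data$label),
    dplyr::bind_rows(lapply(tasks, function(tk) {
      dplyr::mutate(split$tasks[[tk]], role = paste0("test_", tk),
                    truth = .data$label, label = 0)
    }))
  )
  nodes <- build_mdp_nodes(pair_tbl, feats$imsm, feats$idsm)

  graph <- switch(graph_method,
    regular = knn_regular_graph(nodes, k = k),
    kmeans = kmeans_graph(nodes, n_clusters = min(n_clusters, nrow(nodes$table)),
                          seed = derive_seed(seed, 6)))

  model <- gcn_train(nodes, graph, config, sampler = use_sampler,
                     seed = derive_seed(seed, 5))

  test_tbl <- dplyr::filter(nodes$table, .data$role != "train")
  scores <- dplyr::left_join(
    predict_scores(model, graph, nodes, test_tbl$node_id),
    test_tbl[c("node_id", "role", "truth")], by = "node_id")

  metrics <- dplyr::bind_rows(lapply(tasks, function(tk) {
    sub <- dplyr::filter(scores, .data$role == paste0("test_", tk))
    if (nrow(sub) == 0 || length(unique(sub$truth)) < 2) {
      rlang::warn(sprintf("task %s has no scorable test pairs; skipped", tk))
      return(NULL)
    }
    dplyr::mutate(compute_metrics(sub$score, sub$truth), task = tk, .before = 1)
  }))

  structure(list(model = model, graph = graph, nodes = nodes, split = split,
                 scores = scores, metrics = metrics, seed = seed,
                 graph_method = graph_method),
            class = "mda_fit")
}

#' @export
print.mda_fit <- function(x, ...) {
  cat(sprintf("mda_fit (%s graph, seed %d)\n", x$graph_method, x$seed))
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' @method tidy mda_fit
#' @export
tidy.mda_fit <- function(x, ...) x$scores

#' @method glance mda_fit
#' @export
glance.mda_fit <- function(x, ...) x$metrics

#' @method autoplot mda_fit
#' @export
autoplot.mda_fit <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$score, fill = factor(.data$truth))) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.7, position = "identity") +
    ggplot2::facet_wrap(~role) +
    ggplot2::labs(x = "predicted score", fill = "true label",
                  title = "Score separation on masked test pairs") +
    ggplot2::theme_minimal()
}
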