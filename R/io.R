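# Interchange formats are tab-delimited UTF-8 text with '.' decimals and no
# index columns, so fixtures stay bit-comparable across platforms.

#' Read / write a binary association list
#'
#' Two tab-separated columns (miRNA, disease), one known association per
#' line. Duplicate pairs collapse to a single entry with a warning; entity
#' order is first-appearance order.
#'
#' @param path file path.
#' @return the binary association matrix (miRNAs x diseases).
#' @export
read_association_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort_input("association list '%s' is empty", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2)) {
    abort_input("malformed association line %d in '%s' (expected 2 fields, got %d)",
                which(nfield != 2)[1], path, nfield[which(nfield != 2)[1]])
  }
  mirna <- vapply(parts, `[`, "", 1L)
  disease <- vapply(parts, `[`, "", 2L)
  key <- paste(mirna, disease, sep = "\r")
  if (anyDuplicated(key)) {
    rlang::warn(sprintf("%d duplicate association line(s) collapsed",
                        sum(duplicated(key))))
    keep <- !duplicated(key)
    mirna <- mirna[keep]; disease <- disease[keep]
  }
  pairs_to_assoc(tibble::tibble(mirna = mirna, disease = disease),
                 unique(mirna), unique(disease))
}

#' @rdname read_association_list
#' @param assoc binary association matrix.
#' @export
write_association_list <- function(assoc, path) {
  check_association(assoc)
  pairs <- assoc_to_pairs(assoc)
  writeLines(paste(pairs$mirna, pairs$disease, sep = "\t"), path)
  invisible(path)
}

#' Read / write a labeled pair list
#'
#' Three tab-separated columns: miRNA, disease, label in {0, 1}.
#'
#' @param path file path.
#' @return tibble with columns `mirna`, `disease`, `label`.
#' @export
read_pair_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"))
  if (!all(c("mirna", "disease", "label") %in% names(df))) {
    abort_input("pair list '%s' needs columns mirna, disease, label", path)
  }
  if (!all(df$label %in% c(0, 1))) abort_input("pair labels must be 0/1")
  tibble::as_tibble(df)
}

#' @rdname read_pair_list
#' @param pairs data frame with columns `mirna`, `disease`, `label`.
#' @export
write_pair_list <- function(pairs, path) {
  utils::write.table(pairs[c("mirna", "disease", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a labeled similarity matrix
#'
#' Tab-delimited square matrix; first row and first column carry identical
#' entity labels. The reader validates squareness, label agreement, the
#' \[0, 1\] range and symmetry to 1e-8.
#'
#' @param path file path.
#' @return a validated [similarity_matrix()].
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    abort_input("similarity matrix '%s' is not square (%d x %d)",
                path, nrow(m), ncol(m))
  }
  if (!identical(rownames(m), colnames(m))) {
    abort_input("row and column labels disagree in '%s'", path)
  }
  similarity_matrix(m, tol = 1e-8)
}

#' @rdname read_similarity_matrix
#' @param m similarity matrix with dimnames.
#' @export
write_similarity_matrix <- function(m, path) {
  df <- cbind(label = rownames(m),
              as.data.frame(format(m, digits = 17, trim = TRUE, scientific = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weighted gene-gene interaction edge list
#'
#' Three tab-separated columns: gene, gene, raw log-likelihood score; scores
#' are min-max normalized by [gene_network()].
#'
#' @param path file path.
#' @return a [gene_network()].
#' @export
read_gene_network <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("gene1", "gene2", "score"),
                          colClasses = c("character", "character", "numeric"))
  gene_network(df)
}

#' Read a miRNA-to-gene membership list
#'
#' Two tab-separated columns (miRNA, gene), one pair per line.
#'
#' @param path file path.
#' @return tibble with columns `mirna`, `gene`.
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("mirna", "gene"),
                          colClasses = "character")
  tibble::as_tibble(df)
}

#' Export / import a pair graph as edge-list plus node-table text
#'
#' Writes `<path>.edges.tsv` (node_id, node_id, weight) and
#' `<path>.nodes.tsv` (node_id, mirna, disease, label, role).
#'
#' @param graph a `pair_graph`.
#' @param nodes the matching `mdp_nodes` (edge-only export if `NULL`).
#' @param path stem for the two output files.
#' @return the stem, invisibly.
#' @export
write_pair_graph <- function(graph, path, nodes = NULL) {
  utils::write.table(graph$edges, paste0(path, ".edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(nodes)) {
    utils::write.table(nodes$table, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_pair_graph
#' @param n_nodes node count of the stored graph (inferred from the node
#'   table when present).
#' @export
read_pair_graph <- function(path, n_nodes = NULL) {
  edges <- tibble::as_tibble(utils::read.delim(paste0(path, ".edges.tsv"), sep = "\t"))
  node_file <- paste0(path, ".nodes.tsv")
  if (is.null(n_nodes)) {
    if (!file.exists(node_file)) abort_input("need n_nodes or '%s'", node_file)
    n_nodes <- nrow(utils::read.delim(node_file, sep = "\t"))
  }
  new_pair_graph(n_nodes, edges, method = "imported", params = list(path = path))
}

#' Write a metrics report as key-value text plus a per-run table
#'
#' Writes `<path>.summary.txt` (mean and sd per task and metric) and
#' `<path>.runs.tsv` (one row per repetition).
#'
#' @param report a `metrics_report` from [repeat_experiment()] or a metrics
#'   tibble.
#' @param path output stem.
#' @return the stem, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  utils::write.table(tibble::as_tibble(report), paste0(path, ".runs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (inherits(report, "metrics_report")) {
    summ <- glance(report)
    lines <- unlist(lapply(seq_len(nrow(summ)), function(i) {
      row <- summ[i, ]
      vapply(setdiff(names(summ), "task"), function(nm) {
        sprintf("%s.%s = %s", row$task, nm, format(row[[nm]], digits = 10))
      }, "")
    }))
    writeLines(lines, paste0(path, ".summary.txt"))
  }
  invisible(path)
}

#' Write a ranked candidate list
#'
#' Tab-delimited columns: rank, miRNA, disease, score.
#'
#' @param ranked a [rank_candidates()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sidecar provenance record for a written artifact
#'
#' Every pipeline artifact gets a `<file>.meta.json` sidecar holding the
#' seed and an md5 hash of the generating parameters, so runs can be
#' matched to their configuration after the fact.
#'
#' @param path the artifact the sidecar describes.
#' @param seed the seed used.
#' @param params named list of generating parameters.
#' @return the sidecar path, invisibly.
#' @export
write_sidecar <- function(path, seed = NULL, params = list()) {
  cfg_json <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  meta <- list(seed = seed, config_md5 = hash, params = params)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paste0(path, ".meta.json"))
}

#' Read a flat run configuration
#'
#' YAML key-value document mirroring the arguments of
#' [run_mda_experiment()] and [gcn_config()]; missing keys fall back to the
#' package defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return named list with `run` (experiment arguments), `gcn`
#'   (a [gcn_config()]) and `synthetic` (a [synthetic_spec()]).
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  take <- function(section, fn) {
    args <- raw[[section]] %||% list()
    known <- intersect(names(args), names(formals(fn)))
    do.call(fn, args[known])
  }
  run_defaults <- list(tasks = "tp", graph_method = "regular", k = 5,
                       n_clusters = 300, use_sampler = TRUE, neg_ratio = 1,
                       holdout_fraction = 0.2, gamma_prime = 1, n_repeats = 1)
  run <- utils::modifyList(run_defaults, raw$run %||% list())
  list(run = run, gcn = take("gcn", gcn_config),
       synthetic = take("synthetic", synthetic_spec), raw = raw)
}
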