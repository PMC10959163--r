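#' Reference disease semantic similarity from an ontology DAG
#'
#' Optional builder for the two disease semantic similarity readings when no
#' precomputed matrices are available. Diseases live in a directed acyclic
#' graph (child -> parent, as in MeSH descriptor trees). Two variants are
#' provided:
#'
#' * `"wang"` (DSSM_1-style): each ancestor term `t` of disease `d`
#'   contributes `D_d(t) = decay^depth`, i.e. `D_d(d) = 1` and
#'   `D_d(t) = decay * max(D_d(c))` over `t`'s children `c` inside `d`'s
#'   ancestor closure. Diseases sharing a larger portion of their DAGs score
#'   higher.
#' * `"ic"` (DSSM_2-style): the contribution of term `t` is an
#'   information-content weight `-log(n_t / N)` where `n_t` counts the
#'   diseases whose ancestor closure contains `t`, so terms appearing in many
#'   DAGs (common diseases) contribute less.
#'
#' In both variants
#' `sim(a, b) = sum_{t in T_a ∩ T_b} (D_a(t) + D_b(t)) / (DV(a) + DV(b))`
#' with `DV(d) = sum_{t in T_d} D_d(t)`.
#'
#' @param dag data frame with columns `child`, `parent`; acyclic.
#' @param diseases diseases to score; defaults to every term in the DAG.
#' @param method `"wang"` or `"ic"`.
#' @param decay semantic contribution decay per edge for `"wang"`, in (0, 1).
#' @return a [similarity_matrix()] over `diseases`.
#' @export
disease_semantic_similarity <- function(dag, diseases = NULL,
                                        method = c("wang", "ic"), decay = 0.5) {
  method <- match.arg(method)
  dag <- tibble::as_tibble(dag)
  if (!all(c("child", "parent") %in% names(dag))) {
    abort_input("DAG needs columns child, parent")
  }
  parents <- split(as.character(dag$parent), as.character(dag$child))
  terms <- unique(c(as.character(dag$child), as.character(dag$parent)))
  diseases <- diseases %||% terms
  missing <- setdiff(diseases, terms)
  if (length(missing)) abort_input("disease '%s' absent from the DAG", missing[1])

  closures <- lapply(diseases, dag_contributions, parents = parents, decay = decay)
  names(closures) <- diseases

  if (method == "ic") {
    all_terms <- unique(unlist(lapply(closures, names), use.names = FALSE))
    counts <- table(factor(unlist(lapply(closures, names), use.names = FALSE),
                           levels = all_terms))
    ic <- -log(as.numeric(counts) / length(diseases))
    names(ic) <- all_terms
    # strictly positive floor so the root (present in every DAG) still counts
    ic[ic <= 0] <- min(c(ic[ic > 0], 1)) * 1e-3
    closures <- lapply(closures, function(d) ic[names(d)])
  }

  n <- length(diseases)
  out <- matrix(1, n, n, dimnames = list(diseases, diseases))
  dv <- vapply(closures, sum, 0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        shared <- intersect(names(closures[[i]]), names(closures[[j]]))
        val <- if (length(shared)) {
          sum(closures[[i]][shared] + closures[[j]][shared]) / (dv[i] + dv[j])
        } else 0
        out[i, j] <- out[j, i] <- val
      }
    }
  }
  similarity_matrix(out)
}

# Ancestor closure of `d` with decayed contributions; named numeric vector.
dag_contributions <- function(d, parents, decay) {
  contrib <- stats::setNames(1, d)
  frontier <- stats::setNames(1, d)
  guard <- 0L
  while (length(frontier)) {
    guard <- guard + 1L
    if (guard > 10000L) abort_input("cycle detected in disease DAG near '%s'", d)
    nxt <- numeric(0)
    for (i in seq_along(frontier)) {
      for (p in parents[[names(frontier)[i]]] %||% character(0)) {
        val <- decay * frontier[[i]]
        if (is.na(contrib[p]) || contrib[p] < val) {
          contrib[p] <- val
          nxt[p] <- max(nxt[p], val, na.rm = TRUE)
        }
      }
    }
    frontier <- nxt
  }
  contrib
}
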