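#' Route associations into the four novelty evaluation regimes
#'
#' Training uses the old (previously known) associations. Each newly
#' discovered association lands in exactly one test task by the novelty of
#' its two entities: `tp` (old miRNA, old disease), `td` (old miRNA, new
#' disease), `tm` (new miRNA, old disease), `tn` (new miRNA, new disease).
#' Each task gets count-matched negatives sampled from unknown pairs of the
#' same entity regime; training negatives are drawn first from the old-old
#' regime, and test negatives never collide with training negatives or any
#' positive, so no pair appears in more than one set.
#'
#' @param old_assoc data frame (`mirna`, `disease`) of training-time
#'   positives; entities must appear in the old registries.
#' @param new_assoc data frame of newly discovered positives.
#' @param old_mirnas,old_diseases character registries of old entities.
#' @param neg_ratio negatives per positive in every set.
#' @param seed RNG seed for all negative draws.
#' @return an object of class `task_split`: list with `train` (tibble
#'   `mirna`, `disease`, `label`), `tasks` (named list of test tibbles) and
#'   `registries`.
#' @export
make_task_splits <- function(old_assoc, new_assoc, old_mirnas, old_diseases,
                             neg_ratio = 1, seed = 1) {
  old_assoc <- tibble::as_tibble(old_assoc)
  new_assoc <- tibble::as_tibble(new_assoc)
  bad_m <- setdiff(old_assoc$mirna, old_mirnas)
  bad_d <- setdiff(old_assoc$disease, old_diseases)
  if (length(bad_m)) abort_input("training miRNA '%s' missing from old registry", bad_m[1])
  if (length(bad_d)) abort_input("training disease '%s' missing from old registry", bad_d[1])

  new_mirnas <- sort(setdiff(unique(new_assoc$mirna), old_mirnas))
  new_diseases <- sort(setdiff(unique(new_assoc$disease), old_diseases))

  task_of <- function(m, d) {
    om <- m %in% old_mirnas; od <- d %in% old_diseases
    dplyr::case_when(om & od ~ "tp", om & !od ~ "td", !om & od ~ "tm",
                     .default = "tn")
  }
  new_assoc <- dplyr::mutate(new_assoc, task = task_of(.data$mirna, .data$disease))

  pos_key <- unique(c(paste(old_assoc$mirna, old_assoc$disease, sep = "\r"),
                      paste(new_assoc$mirna, new_assoc$disease, sep = "\r")))
  taken <- character(0)

  regimes <- list(tp = list(old_mirnas, old_diseases),
                  td = list(old_mirnas, new_diseases),
                  tm = list(new_mirnas, old_diseases),
                  tn = list(new_mirnas, new_diseases))

  draw_negatives <- function(task, n_needed, seed_offset) {
    if (n_needed == 0) return(tibble::tibble(mirna = character(0), disease = character(0)))
    ms <- regimes[[task]][[1]]; ds <- regimes[[task]][[2]]
    universe <- tidyr::expand_grid(mirna = ms, disease = ds)
    key <- paste(universe$mirna, universe$disease, sep = "\r")
    universe <- universe[!(key %in% pos_key) & !(key %in% taken), ]
    if (nrow(universe) < n_needed) {
      # tiny entity regimes can run out of unknown pairs; use what exists
      rlang::warn(sprintf("only %d unknown %s pairs available for %d negatives",
                          nrow(universe), task, n_needed))
      n_needed <- nrow(universe)
      if (n_needed == 0) return(tibble::tibble(mirna = character(0),
                                               disease = character(0)))
    }
    picked <- with_seed(derive_seed(seed, seed_offset),
                        universe[sort(sample.int(nrow(universe), n_needed)), ])
    taken <<- c(taken, paste(picked$mirna, picked$disease, sep = "\r"))
    picked
  }

  train_neg <- draw_negatives("tp", round(neg_ratio * nrow(old_assoc)), 0L)
  train <- dplyr::bind_rows(
    dplyr::mutate(old_assoc[c("mirna", "disease")], label = 1),
    dplyr::mutate(train_neg, label = 0)
  )

  tasks <- list()
  for (i in seq_along(regimes)) {
    tk <- names(regimes)[i]
    pos <- dplyr::filter(new_assoc, .data$task == tk)[c("mirna", "disease")]
    neg <- draw_negatives(tk, round(neg_ratio * nrow(pos)), i)
    tasks[[tk]] <- dplyr::bind_rows(dplyr::mutate(pos, label = 1),
                                    dplyr::mutate(neg, label = 0))
  }

  structure(list(train = train, tasks = tasks,
                 registries = list(old_mirnas = old_mirnas,
                                   new_mirnas = new_mirnas,
                                   old_diseases = old_diseases,
                                   new_diseases = new_diseases)),
            class = "task_split")
}

#' @export
print.task_split <- function(x, ...) {
  cat(sprintf("task_split: %d training pairs (%d positive)\n",
              nrow(x$train), sum(x$train$label)))
  for (tk in names(x$tasks)) {
    cat(sprintf("  %s: %d pairs (%d positive)\n", tk, nrow(x$tasks[[tk]]),
                sum(x$tasks[[tk]]$label)))
  }
  invisible(x)
}

#' Area under the ROC curve by the rank statistic
#'
#' Computed from the Wilcoxon rank-sum identity with ties counted half:
#' `AUC = (sum of positive ranks - n_pos (n_pos + 1) / 2) / (n_pos n_neg)`.
#'
#' @param scores numeric scores, higher meaning more likely positive.
#' @param labels 0/1 labels; both classes must be present.
#' @return the AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) abort_input("scores and labels differ in length")
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort_input("AUC undefined: both classes must be present")
  }
  r <- rank(scores)  # average ranks handle ties as half-concordant
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Threshold and ranking metrics for a scored test set
#'
#' Accuracy, precision, recall and F1 come from the confusion matrix at the
#' given score cutoff (precision defined as 0 when nothing is called
#' positive); AUC comes from [auc_score()].
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels 0/1 labels.
#' @param threshold score cutoff for calling a pair positive.
#' @return a one-row tibble: `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `n`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) abort_input("scores and labels differ in length")
  labels <- as.numeric(labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble::tibble(accuracy = (tp + tn) / length(labels),
                 precision = precision, recall = recall, f1 = f1,
                 auc = auc_score(scores, labels), n = length(labels))
}

#' Two-tailed paired t-test on per-repetition metric values
#'
#' Closed-form paired t statistic for comparing two configurations run on
#' identical seeds: `t = mean(d) / (sd(d) / sqrt(n))` on the per-run
#' differences `d`, with `2 * P(T_{n-1} <= -|t|)` as the p-value.
#'
#' @param a,b numeric vectors of per-run values (e.g. AUCs), same length and
#'   seed order.
#' @return tibble with `mean_diff`, `t`, `df`, `p_value`.
#' @export
paired_metric_test <- function(a, b) {
  if (length(a) != length(b)) abort_input("paired vectors differ in length")
  if (length(a) < 2) abort_input("need at least two repetitions for a paired test")
  d <- a - b
  t_stat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  tibble::tibble(mean_diff = mean(d), t = t_stat, df = length(d) - 1,
                 p_value = 2 * stats::pt(-abs(t_stat), length(d) - 1))
}

#' Repeat a full experiment over independent seeds
#'
#' Runs [run_mda_experiment()] `n_repeats` times with seeds
#' `base_seed, base_seed + 1, ...` (fresh negative sampling, graph and model
#' initialization each run) and collects per-run metrics so configurations
#' can be compared with paired tests on identical seed sequences.
#'
#' @param data a `synthetic_mda` or equivalently shaped list.
#' @param n_repeats number of repetitions.
#' @param base_seed first seed.
#' @param ... passed to [run_mda_experiment()].
#' @return an object of class `metrics_report`: tibble of per-run metrics
#'   with columns `run`, `seed`, `task` and the five metrics.
#' @export
repeat_experiment <- function(data, n_repeats = 10, base_seed = 1, ...) {
  if (n_repeats < 1) abort_input("n_repeats must be at least 1")
  runs <- purrr::map(seq_len(n_repeats), function(r) {
    fit <- run_mda_experiment(data, seed = base_seed + r - 1, ...)
    dplyr::mutate(fit$metrics, run = r, seed = base_seed + r - 1,
                  .before = 1)
  })
  out <- dplyr::bind_rows(runs)
  class(out) <- c("metrics_report", class(out))
  out
}

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$task),
    dplyr::across(c("accuracy", "precision", "recall", "f1", "auc"),
                  list(mean = mean, sd = ~ ifelse(dplyr::n() > 1, stats::sd(.x), 0))),
    n_runs = dplyr::n(), .groups = "drop")
}

#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("accuracy", "precision", "recall", "f1", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$task, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "task", y = NULL, title = "Metrics across repetitions") +
    ggplot2::theme_minimal()
}

#' Rank candidate miRNAs for a disease of interest
#'
#' Scores every pair node of the given disease that is not a known training
#' positive and returns the strongest candidates, descending by score with
#' ties broken alphabetically by miRNA label. Candidate pairs must already
#' be present as (masked) nodes of the transductive graph.
#'
#' @param model a trained [gcn_train()] model.
#' @param graph,nodes the graph and node table the model scores.
#' @param disease disease label to rank candidates for.
#' @param candidate_mirnas restrict to these miRNAs; default all present.
#' @param top_k number of candidates to return (fewer if fewer exist).
#' @return tibble with `rank`, `mirna`, `disease`, `score`.
#' @export
rank_candidates <- function(model, graph, nodes, disease,
                            candidate_mirnas = NULL, top_k = 30) {
  tbl <- nodes$table
  if (!disease %in% tbl$disease) abort_input("unknown disease '%s'", disease)
  cand <- dplyr::filter(tbl, .data$disease == !!disease,
                        !(.data$role == "train" & .data$label == 1))
  if (!is.null(candidate_mirnas)) {
    cand <- dplyr::filter(cand, .data$mirna %in% candidate_mirnas)
  }
  scored <- predict_scores(model, graph, nodes, cand$node_id)
  scored <- dplyr::arrange(scored, dplyr::desc(.data$score), .data$mirna)
  out <- utils::head(scored, top_k)
  dplyr::mutate(out[c("mirna", "disease", "score")],
                rank = dplyr::row_number(), .before = 1)
}
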