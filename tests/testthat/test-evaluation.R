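test_that("new associations are routed into exactly one novelty task", {
  split <- suppressWarnings(make_task_splits(
    old_assoc = tibble::tibble(mirna = "m1", disease = "d1"),
    new_assoc = tibble::tibble(mirna = c("m1", "m1", "m2", "m2"),
                               disease = c("d1", "d2", "d1", "d2")),
    old_mirnas = c("m1", "m9"), old_diseases = c("d1", "d9"),
    seed = 3))
  got <- lapply(split$tasks, function(t) paste(t$mirna[t$label == 1],
                                               t$disease[t$label == 1]))
  expect_equal(got$tp, "m1 d1")
  expect_equal(got$td, "m1 d2")
  expect_equal(got$tm, "m2 d1")
  expect_equal(got$tn, "m2 d2")
  # partition: each new association appears once across tasks
  expect_equal(sort(unname(unlist(got))), c("m1 d1", "m1 d2", "m2 d1", "m2 d2"))

  # without new entities the novelty tasks are empty
  s2 <- make_task_splits(tibble::tibble(mirna = "m1", disease = "d1"),
                         tibble::tibble(mirna = "m9", disease = "d9"),
                         old_mirnas = c("m1", "m9"),
                         old_diseases = c("d1", "d9"), seed = 1)
  expect_equal(nrow(s2$tasks$td), 0)
  expect_equal(nrow(s2$tasks$tm), 0)
  expect_equal(nrow(s2$tasks$tn), 0)

  expect_error(make_task_splits(tibble::tibble(mirna = "mX", disease = "d1"),
                                tibble::tibble(mirna = "m1", disease = "d1"),
                                "m1", "d1"),
               "mX")
})

test_that("train and test sets never share a pair, in any task", {
  data <- small_synthetic(seed = 8)
  fit_split <- run_mda_experiment(
    data, tasks = c("tp", "td", "tm", "tn"),
    config = gcn_config(hidden = c(8), epochs = 2, batches_per_epoch = 2),
    seed = 5)$split
  train_keys <- paste(fit_split$train$mirna, fit_split$train$disease)
  for (tk in names(fit_split$tasks)) {
    test_keys <- paste(fit_split$tasks[[tk]]$mirna, fit_split$tasks[[tk]]$disease)
    expect_length(intersect(train_keys, test_keys), 0)
    expect_equal(anyDuplicated(test_keys), 0L)
  }
})

test_that("metrics reproduce the worked four-point example", {
  scores <- c(0.9, 0.8, 0.3, 0.1)
  labels <- c(1, 0, 1, 0)
  m <- compute_metrics(scores, labels, threshold = 0.5)
  # pairs: 3 of 4 positive-negative comparisons concordant
  expect_equal(m$auc, 0.75)
  # confusion at 0.5: TP = 1, FP = 1, FN = 1, TN = 1
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)

  perfect <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1", "auc")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, auc = 1))

  expect_error(auc_score(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("rank-statistic AUC equals brute-force pair counting (incl. ties)", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    scores <- round(runif(n), 1)              # coarse grid forces ties
    expect_equal(auc_score(scores, labels), brute_force_auc(scores, labels))
    # permutation invariance
    perm <- sample(n)
    expect_equal(auc_score(scores[perm], labels[perm]),
                 auc_score(scores, labels))
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- runif(50); labels <- rbinom(50, 1, 0.5); labels[1:2] <- c(0, 1)
  expect_equal(auc_score(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))))
})

test_that("repeated experiments report per-run values consistently", {
  data <- small_synthetic(seed = 3, new_fraction_mirna = 0,
                          new_fraction_disease = 0)
  rep1 <- repeat_experiment(data, n_repeats = 1, base_seed = 2, tasks = "tp",
                            config = gcn_config(hidden = c(8), epochs = 3,
                                                batches_per_epoch = 2))
  expect_equal(nrow(rep1), 1)
  g1 <- glance(rep1)
  expect_equal(g1$auc_mean, rep1$auc)
  expect_equal(g1$auc_sd, 0)

  rep2 <- repeat_experiment(data, n_repeats = 3, base_seed = 2, tasks = "tp",
                            config = gcn_config(hidden = c(8), epochs = 3,
                                                batches_per_epoch = 2))
  expect_equal(rep2$seed, 2:4)
  expect_equal(glance(rep2)$auc_mean, mean(rep2$auc))
  # paired comparison vectors line up by construction
  expect_length(rep2$auc - rev(rep2$auc), 3)
})

test_that("closed-form paired t-test matches stats::t.test", {
  set.seed(9)
  a <- runif(10, 0.8, 1); b <- a - runif(10, 0, 0.05)
  got <- paired_metric_test(a, b)
  want <- stats::t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(want$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  expect_error(paired_metric_test(a, b[1:3]), "length")
})

test_that("candidate ranking excludes training positives and orders by score", {
  fit <- cached_small_fit()
  tbl <- fit$nodes$table
  disease <- names(sort(table(tbl$disease), decreasing = TRUE))[1]
  ranked <- rank_candidates(fit$model, fit$graph, fit$nodes, disease, top_k = 5)
  expect_lte(nrow(ranked), 5)
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  expect_true(all(diff(ranked$score) <= 0))
  train_pos <- tbl[tbl$role == "train" & tbl$label == 1 & tbl$disease == disease, ]
  expect_length(intersect(ranked$mirna, train_pos$mirna), 0)
  # top_k beyond the candidate count returns the full sorted list
  all_ranked <- rank_candidates(fit$model, fit$graph, fit$nodes, disease,
                                top_k = 10^6)
  expect_equal(nrow(all_ranked),
               sum(tbl$disease == disease) - nrow(train_pos))
  expect_error(rank_candidates(fit$model, fit$graph, fit$nodes, "no-such"),
               "unknown disease")
})

test_that("ranking recovers planted associations for a well-linked disease", {
  # strong-signal fixture: block structure fully determines similarities
  data <- generate_synthetic(synthetic_spec(
    n_mirna = 60, n_disease = 40, n_blocks = 2, p_in = 0.45, p_out = 0.01,
    similarity_signal = 0.9, noise_sd = 0.02, zero_fraction = 0.1,
    new_fraction_mirna = 0, new_fraction_disease = 0, seed = 19))
  fit <- run_mda_experiment(
    data, tasks = "tp", holdout_fraction = 0.3,
    config = gcn_config(hidden = c(32, 16), epochs = 50, batches_per_epoch = 5),
    seed = 23)
  # pick the disease with most held-out positives
  test_nodes <- fit$nodes$table[fit$nodes$table$role == "test_tp", ]
  disease <- names(sort(table(test_nodes$disease[test_nodes$truth == 1]),
                        decreasing = TRUE))[1]
  ranked <- rank_candidates(fit$model, fit$graph, fit$nodes, disease, top_k = 10)
  truth <- data$blocks$mirna[ranked$mirna] == data$blocks$disease[disease]
  # most top candidates should come from the disease's own block
  expect_gte(mean(truth), 0.8)
})
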