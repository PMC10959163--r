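test_that("gene similarity follows the identity / edge / absent branches", {
  net <- tiny_gene_network()
  expect_equal(gene_similarity(net, "g1", "g1"), 1)
  expect_equal(gene_similarity(net, "g1", "g3"), 0)   # no edge
  expect_equal(gene_similarity(net, "g1", "g2"), 0.7) # normalized weight
  expect_equal(gene_similarity(net, "g2", "g1"), 0.7) # orientation-free
  expect_equal(gene_similarity(net, "g1", "g4"), 0)   # min score maps to 0
  expect_error(gene_similarity(net, "g1", "gX"), "gX")
})

test_that("constant-score networks normalize every weight to 1", {
  net <- gene_network(tibble::tibble(gene1 = c("a", "b"), gene2 = c("b", "c"),
                                     score = c(3, 3)))
  expect_equal(gene_similarity(net, "a", "b"), 1)
  expect_equal(gene_similarity(net, "b", "c"), 1)
})

test_that("miRNA functional similarity reproduces hand-worked cases", {
  net <- gene_network(tibble::tibble(gene1 = c("g1", "g1"), gene2 = c("g2", "g3"),
                                     score = c(0.5, 0.1)))
  # identical singleton sets: both sums are S(g1, g1) = 1, denominator 2
  m <- mirna_functional_similarity(net, tibble::tibble(mirna = c("a", "b"),
                                                       gene = c("g1", "g1")))
  expect_equal(m["a", "b"], 1)

  # singleton sets joined by one edge of weight 0.5: direct evaluation gives
  # (0.5 + 0.5) / 2 = 0.5; raw scores 0.5 / 1 / 0 keep 0.5 after min-max
  net2b <- gene_network(tibble::tibble(gene1 = c("g1", "g3", "g5"),
                                       gene2 = c("g2", "g4", "g6"),
                                       score = c(0.5, 1, 0)))
  m2 <- mirna_functional_similarity(net2b, tibble::tibble(mirna = c("a", "b"),
                                                          gene = c("g1", "g2")))
  expect_equal(m2["a", "b"], 0.5)

  # G_a = {g1, g2}, G_b = {g2}, S(g1, g2) = 0.4 -> (0.4 + 1 + 1) / 3 = 0.8
  net3 <- gene_network(tibble::tibble(gene1 = c("g1", "g5", "g7"),
                                      gene2 = c("g2", "g6", "g8"),
                                      score = c(0.4, 1, 0)))
  m3 <- mirna_functional_similarity(net3, tibble::tibble(
    mirna = c("a", "a", "b"), gene = c("g1", "g2", "g2")))
  expect_equal(m3["a", "b"], 0.8)

  expect_error(
    mirna_functional_similarity(net, tibble::tibble(mirna = "a", gene = "gZ")),
    "gZ")
})

test_that("functional similarity matches brute-force enumeration on random sets", {
  set.seed(202)
  for (rep in 1:10) {
    genes <- paste0("g", 1:8)
    edges <- t(combn(genes, 2))
    keep <- runif(nrow(edges)) < 0.5
    net <- gene_network(tibble::tibble(gene1 = edges[keep, 1],
                                       gene2 = edges[keep, 2],
                                       score = runif(sum(keep))))
    avail <- net$genes  # only genes the network knows can be in a set
    sets <- lapply(1:4, function(i) sample(avail, min(length(avail), sample(1:5, 1))))
    names(sets) <- paste0("m", 1:4)
    gs <- tibble::tibble(mirna = rep(names(sets), lengths(sets)),
                         gene = unlist(sets))
    got <- mirna_functional_similarity(net, gs)
    S <- mdpgcn:::gene_similarity_matrix(net, genes)
    want <- brute_force_mfsm(S, sets)
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("GIP kernel reproduces the hand-derived toy values", {
  A <- diag(2); dimnames(A) <- list(c("m1", "m2"), c("d1", "d2"))
  K <- gip_kernel_similarity(A, "disease")
  # profiles (1,0) and (0,1): mean squared norm 1 -> gamma 1 -> exp(-2)
  expect_equal(K["d1", "d2"], exp(-2), tolerance = 1e-12)
  expect_equal(diag(K), c(d1 = 1, d2 = 1))

  # identical profiles score exactly 1
  A2 <- matrix(c(1, 1, 0, 0), 2, dimnames = list(c("m1", "m2"), c("d1", "d2")))
  A2[, 2] <- A2[, 1]
  expect_equal(gip_kernel_similarity(A2, "disease")["d1", "d2"], 1)

  # zero bandwidth flattens the kernel to 1 everywhere
  expect_true(all(gip_kernel_similarity(A, "disease", gamma_prime = 0) == 1))

  # all-zero profiles leave the bandwidth undefined
  A0 <- matrix(0, 2, 2, dimnames = list(c("m1", "m2"), c("d1", "d2")))
  expect_error(gip_kernel_similarity(A0, "mirna"), class = "mdpgcn_zero_profile")
})

test_that("GIP kernel is permutation-equivariant and monotone in the bandwidth", {
  set.seed(7)
  A <- matrix(rbinom(60, 1, 0.4), 10, 6,
              dimnames = list(paste0("m", 1:10), paste0("d", 1:6)))
  A[1, ] <- 1  # no all-zero profile
  K <- gip_kernel_similarity(A, "mirna")
  perm <- sample(10)
  Kp <- gip_kernel_similarity(A[perm, ], "mirna")
  expect_equal(unname(Kp), unname(K[perm, perm]), tolerance = 1e-12)

  K2 <- gip_kernel_similarity(A, "mirna", gamma_prime = 2)
  distinct <- outer(seq_len(10), seq_len(10),
                    Vectorize(function(i, j) any(A[i, ] != A[j, ])))
  off <- distinct & upper.tri(K)
  expect_true(all(K2[off] < K[off]))
})

test_that("semantic averaging is the entrywise mean and keeps symmetry", {
  d1 <- similarity_matrix(matrix(c(1, 0.2, 0.2, 1), 2), c("a", "b"))
  d2 <- similarity_matrix(matrix(c(1, 0.4, 0.4, 1), 2), c("a", "b"))
  avg <- average_semantic_similarity(d1, d2)
  expect_equal(avg["a", "b"], 0.3)
  expect_equal(avg, t(avg))
  expect_equal(average_semantic_similarity(d1, d1), d1)
  d3 <- similarity_matrix(matrix(c(1, 0.4, 0.4, 1), 2), c("a", "c"))
  expect_error(average_semantic_similarity(d1, d3), "mismatch")
})

test_that("integration keeps nonzero primary entries and fills zeros from the kernel", {
  labs <- c("x", "y", "z")
  primary <- similarity_matrix(matrix(c(1, 0.6, 0, 0.6, 1, 0, 0, 0, 1), 3), labs)
  gip <- similarity_matrix(matrix(c(1, 0.2, 0.4, 0.2, 1, 0.3, 0.4, 0.3, 1), 3), labs)
  out <- integrate_similarity(primary, gip)
  expect_equal(out["x", "y"], 0.6)  # primary wins where nonzero
  expect_equal(out["x", "z"], 0.4)  # kernel fills the zero
  expect_equal(out["y", "z"], 0.3)
  # no zeros in primary -> passthrough
  dense <- similarity_matrix(matrix(c(1, .5, .5, 1), 2), c("x", "y"))
  expect_equal(integrate_similarity(dense, dense * 0.5 + diag(2) * 0.5), dense)
  expect_error(integrate_similarity(primary, dense), "shape")
  # integration never increases the zero count
  expect_lte(sum(out == 0), sum(primary == 0))
})

test_that("produced similarity matrices are symmetric with unit diagonal", {
  data <- small_synthetic()
  feats <- integrated_features(data$assoc, data$mirna_sim, data$disease_sim)
  for (M in list(data$mirna_sim, data$disease_sim, feats$imsm, feats$idsm)) {
    expect_lte(max(abs(M - t(M))), 1e-12)
    expect_equal(unname(diag(M)), rep(1, nrow(M)))
    expect_true(all(M >= 0 & M <= 1))
  }
})

test_that("DAG semantic similarity behaves like a shared-ancestry score", {
  dag <- tibble::tibble(child = c("b", "c", "d", "e"),
                        parent = c("a", "a", "b", "b"))
  # wang-style, decay 0.5: sim(d, e) shares {b, a}
  W <- disease_semantic_similarity(dag, method = "wang", decay = 0.5)
  # D_d = {d:1, b:.5, a:.25}, DV = 1.75; same for e
  # shared contributions: b (.5 + .5) + a (.25 + .25) = 1.5; 1.5 / 3.5
  expect_equal(W["d", "e"], 1.5 / 3.5, tolerance = 1e-12)
  expect_equal(W, t(W))
  expect_equal(unname(diag(W)), rep(1, nrow(W)))
  # siblings share more than unrelated terms
  expect_gt(W["d", "e"], W["d", "c"])
  # information-content variant downweights common ancestors but stays valid
  IC <- disease_semantic_similarity(dag, method = "ic")
  expect_equal(IC, t(IC))
  expect_true(all(IC >= 0 & IC <= 1))
  expect_gt(IC["d", "e"], IC["c", "e"])
  expect_error(disease_semantic_similarity(dag, diseases = "zz"), "zz")
})
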