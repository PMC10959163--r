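#' Specification for the planted-block synthetic benchmark
#'
#' The generator emulates the inputs a real run would read: a binary
#' miRNA-disease association matrix plus a miRNA and a disease similarity
#' matrix. Entities are assigned to latent blocks; associations are dense
#' inside matched blocks (`p_in`) and sparse elsewhere (`p_out`), and
#' similarities carry a noisy block indicator so the association signal is
#' recoverable from the features. A configurable fraction of off-diagonal
#' similarity entries is zero-masked to exercise the GIP-kernel fallback of
#' [integrate_similarity()], and designated fractions of entities are held
#' out as "new" for the association-novelty evaluation regimes.
#'
#' @param n_mirna,n_disease entity counts.
#' @param n_blocks number of latent blocks shared by both entity types.
#' @param p_in,p_out association probability when the miRNA and disease
#'   blocks match / differ; `p_in >= p_out` required (equality gives a
#'   block-free null model, useful for calibration checks).
#' @param similarity_signal weight in \[0, 1\] of the same-block indicator in
#'   the similarity value.
#' @param noise_sd standard deviation of symmetric Gaussian noise added to
#'   similarities before clipping to \[0, 1\].
#' @param base_level background similarity mixed in with weight
#'   `1 - similarity_signal` so integration has nonzero entries to prefer.
#' @param zero_fraction fraction of off-diagonal similarity entries set to
#'   exactly zero (symmetrically) to force the kernel fallback.
#' @param new_fraction_mirna,new_fraction_disease fractions in \[0, 1) of
#'   entities held out as "new": their associations are withheld from
#'   training.
#' @param seed RNG seed; the whole draw is deterministic given it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_mirna = 200, n_disease = 150, n_blocks = 5,
                           p_in = 0.3, p_out = 0.02,
                           similarity_signal = 0.8, noise_sd = 0.05,
                           base_level = 0.1, zero_fraction = 0.2,
                           new_fraction_mirna = 0.1, new_fraction_disease = 0.1,
                           seed = 1) {
  spec <- list(n_mirna = n_mirna, n_disease = n_disease, n_blocks = n_blocks,
               p_in = p_in, p_out = p_out,
               similarity_signal = similarity_signal, noise_sd = noise_sd,
               base_level = base_level, zero_fraction = zero_fraction,
               new_fraction_mirna = new_fraction_mirna,
               new_fraction_disease = new_fraction_disease, seed = seed)
  with(spec, {
    if (n_mirna < 2 || n_disease < 2) abort_input("need at least 2 of each entity")
    if (n_blocks < 1 || n_blocks > min(n_mirna, n_disease)) {
      abort_input("n_blocks must be between 1 and min(n_mirna, n_disease)")
    }
    if (p_in < p_out) abort_input("p_in must be at least p_out")
    for (p in c(p_in, p_out, similarity_signal, base_level, zero_fraction)) {
      if (p < 0 || p > 1) abort_input("probabilities must lie in [0, 1]")
    }
    if (noise_sd < 0) abort_input("noise_sd must be nonnegative")
    if (new_fraction_mirna < 0 || new_fraction_mirna >= 1 ||
        new_fraction_disease < 0 || new_fraction_disease >= 1) {
      abort_input("new-entity fractions must lie in [0, 1)")
    }
  })
  structure(spec, class = "synthetic_spec")
}

#' Draw a synthetic miRNA-disease dataset with planted block structure
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `synthetic_mda`: a list with `assoc` (binary
#'   matrix, miRNAs x diseases), `mirna_sim` and `disease_sim`
#'   ([similarity_matrix()]s), `blocks` (ground-truth block assignment per
#'   entity), `registries` (old/new entity labels) and the spec.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) abort_input("spec must be a synthetic_spec")
  with_seed(spec$seed, {
    mirnas <- sprintf("mir%03d", seq_len(spec$n_mirna))
    diseases <- sprintf("dis%03d", seq_len(spec$n_disease))
    mb <- sample.int(spec$n_blocks, spec$n_mirna, replace = TRUE)
    db <- sample.int(spec$n_blocks, spec$n_disease, replace = TRUE)

    same <- outer(mb, db, "==")
    prob <- ifelse(same, spec$p_in, spec$p_out)
    assoc <- matrix(stats::rbinom(length(prob), 1, prob),
                    spec$n_mirna, spec$n_disease,
                    dimnames = list(mirnas, diseases))

    mirna_sim <- planted_similarity(mb, mirnas, spec)
    disease_sim <- planted_similarity(db, diseases, spec)

    n_new_m <- floor(spec$new_fraction_mirna * spec$n_mirna)
    n_new_d <- floor(spec$new_fraction_disease * spec$n_disease)
    new_m <- if (n_new_m > 0) sort(sample(mirnas, n_new_m)) else character(0)
    new_d <- if (n_new_d > 0) sort(sample(diseases, n_new_d)) else character(0)

    structure(list(
      assoc = assoc,
      mirna_sim = mirna_sim,
      disease_sim = disease_sim,
      blocks = list(mirna = stats::setNames(mb, mirnas),
                    disease = stats::setNames(db, diseases)),
      registries = list(old_mirnas = setdiff(mirnas, new_m),
                        new_mirnas = new_m,
                        old_diseases = setdiff(diseases, new_d),
                        new_diseases = new_d),
      spec = spec
    ), class = "synthetic_mda")
  })
}

planted_similarity <- function(blocks, labels, spec) {
  n <- length(blocks)
  ind <- outer(blocks, blocks, "==") * 1
  vals <- spec$similarity_signal * ind + (1 - spec$similarity_signal) * spec$base_level
  if (spec$noise_sd > 0) {
    noise <- matrix(0, n, n)
    up <- upper.tri(noise)
    noise[up] <- stats::rnorm(sum(up), 0, spec$noise_sd)
    noise <- noise + t(noise)
    vals <- vals + noise
  }
  vals <- pmin(pmax(vals, 0), 1)
  if (spec$zero_fraction > 0 && n > 1) {
    up_idx <- which(upper.tri(vals))
    masked <- sample(up_idx, floor(spec$zero_fraction * length(up_idx)))
    vals[masked] <- 0
    vals <- pmin(vals, t(vals))  # mirror the zeros symmetrically
  }
  diag(vals) <- 1
  similarity_matrix(vals, labels)
}

#' @export
print.synthetic_mda <- function(x, ...) {
  cat(sprintf(
    "synthetic miRNA-disease dataset: %d miRNAs x %d diseases, %d positives, %d blocks\n",
    nrow(x$assoc), ncol(x$assoc), sum(x$assoc), x$spec$n_blocks))
  cat(sprintf("new entities held out: %d miRNAs, %d diseases\n",
              length(x$registries$new_mirnas), length(x$registries$new_diseases)))
  invisible(x)
}
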