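# Shared fixtures: a small synthetic target used across test files.
# Deliberately modest sizes so the whole suite stays fast.

tiny_model <- function(seed = 42, ...) {
  make_chemotypes(k = 3, d = 64, template_density = 0.3, seed = seed, ...)
}

tiny_populations <- function(seed = 42, n_act = 120, n_dcy = 4000, ...) {
  m <- tiny_model(seed = seed, ...)
  list(model = m,
       actives = sample_actives(m, n_act, seed = seed + 1),
       decoys = sample_decoys(m, n_dcy, seed = seed + 2))
}

# plain-R Tanimoto oracle over all pairs (brute force, no shortcuts)
brute_max_tanimoto <- function(query, reference) {
  q <- if (inherits(query, "fingerprint_matrix")) query$bits else query
  r <- if (inherits(reference, "fingerprint_matrix")) reference$bits else reference
  apply(q, 1, function(a) {
    max(apply(r, 1, function(b) {
      u <- sum(a | b)
      if (u == 0) 1 else sum(a & b) / u
    }))
  })
}

# plain-R 1-NN oracle: exhaustive scan, squared Euclidean, first-minimum tie
brute_nn1 <- function(train_bits, train_labels, test_bits) {
  apply(test_bits, 1, function(x) {
    d2 <- rowSums(sweep(train_bits, 2, x)^2)
    train_labels[which.min(d2)]
  })
}
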