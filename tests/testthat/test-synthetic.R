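test_that("chemotype models validate their parameters", {
  m <- make_chemotypes(k = 1, d = 64, template_density = 0.25, seed = 1)
  expect_equal(dim(m$templates), c(1, 64))
  # expected set bits 16, allow binomial 4-sigma
  expect_lt(abs(sum(m$templates) - 16), 4 * sqrt(64 * 0.25 * 0.75) + 1)
  expect_error(make_chemotypes(k = 0, d = 64), "k >= 1")
  expect_error(make_chemotypes(k = 2, d = 64, template_density = 0),
               "strictly between")
  expect_error(make_chemotypes(k = 2, d = 64, active_flip_prob = 0.5),
               "0, 0.5")
  expect_error(make_chemotypes(k = 2, d = 64, active_flip_prob = 0.3,
                               near_active_flip_prob = 0.2),
               "active_flip_prob")
})

test_that("generation is bit-identical under a fixed seed", {
  m1 <- make_chemotypes(k = 3, d = 64, seed = 9)
  m2 <- make_chemotypes(k = 3, d = 64, seed = 9)
  expect_identical(m1$templates, m2$templates)
  expect_identical(sample_actives(m1, 50, seed = 4)$bits,
                   sample_actives(m2, 50, seed = 4)$bits)
  expect_identical(sample_decoys(m1, 200, seed = 6)$bits,
                   sample_decoys(m2, 200, seed = 6)$bits)
  # a different seed gives different draws
  expect_false(identical(sample_actives(m1, 50, seed = 4)$bits,
                         sample_actives(m1, 50, seed = 5)$bits))
})

test_that("actives follow their templates", {
  m <- tiny_model(active_flip_prob = 0)
  act <- sample_actives(m, 30, seed = 2)
  chem <- as.integer(sub(".*_c", "", act$ids))
  # zero flip probability: every active equals its template exactly
  expect_identical(unname(act$bits), unname(m$templates[chem, ]))

  # chemotype assignment is uniform: counts within 4 sigma of n/k
  m2 <- make_chemotypes(k = 2, d = 32, seed = 3)
  act2 <- sample_actives(m2, 1000, seed = 5)
  counts <- table(sub(".*_c", "", act2$ids))
  expect_lt(abs(counts[["1"]] - 500), 4 * sqrt(1000 * 0.25))
})

test_that("active-template Tanimoto matches its closed-form expectation", {
  m <- make_chemotypes(k = 1, d = 1024, template_density = 0.3, seed = 11,
                       active_flip_prob = 0.15)
  act <- sample_actives(m, 400, seed = 12, kind = "hashed-path")
  sims <- vapply(seq_len(400), function(i) {
    tanimoto(act$bits[i, ], m$templates[1, ])
  }, numeric(1))
  expected <- expected_template_tanimoto(0.3, 0.15)
  # Monte-Carlo error of the mean over 400 draws is well under 0.01
  expect_lt(abs(mean(sims) - expected), 0.02)
})

test_that("decoy composition respects the near-active fraction", {
  m <- tiny_model(near_active_fraction = 0.1)
  dcy <- sample_decoys(m, 10000, seed = 8)
  n_near <- sum(grepl("_near$", dcy$ids))
  expect_lt(abs(n_near - 1000), 4 * sqrt(10000 * 0.1 * 0.9))
  # limiting case: no contamination
  m0 <- tiny_model(near_active_fraction = 0)
  expect_false(any(grepl("_near$", sample_decoys(m0, 500, seed = 8)$ids)))
})

test_that("similarity_density agrees with brute-force enumeration", {
  act <- fingerprint_matrix(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)),
                            c("a1", "a2"), "hashed-path")
  scr <- fingerprint_matrix(rbind(c(1, 1, 0, 0), c(1, 0, 0, 0),
                                  c(0, 1, 1, 0), c(0, 0, 0, 1)),
                            paste0("d", 1:4), "hashed-path")
  best <- brute_max_tanimoto(scr, act)
  for (s in c(0, 0.4, 0.5, 0.9, 1)) {
    expect_equal(similarity_density(act, scr, s), mean(best >= s))
  }
  # trivial anchors
  expect_equal(similarity_density(act, act, 1), 1)
  expect_equal(similarity_density(act, scr, 0), 1)
})

test_that("similarity_density is monotone in threshold and contamination", {
  pop <- tiny_populations(seed = 31, n_act = 60, n_dcy = 800)
  s_grid <- seq(0, 1, by = 0.1)
  dens <- vapply(s_grid, function(s) {
    similarity_density(pop$actives, pop$decoys, s)
  }, numeric(1))
  expect_true(all(diff(dens) <= 0))

  # expectation over replicates: more near-actives, more high-similarity mass
  lo <- hi <- numeric(20)
  for (r in 1:20) {
    m_lo <- tiny_model(seed = 500 + r, near_active_fraction = 0.02)
    m_hi <- tiny_model(seed = 500 + r, near_active_fraction = 0.3)
    act <- sample_actives(m_lo, 50, seed = 600 + r)
    lo[r] <- similarity_density(act, sample_decoys(m_lo, 400, seed = 700 + r),
                                s = 0.4)
    hi[r] <- similarity_density(act, sample_decoys(m_hi, 400, seed = 700 + r),
                                s = 0.4)
  }
  expect_gt(mean(hi), mean(lo))
})

test_that("separability responds to the active noise dial", {
  # 1-NN on actives vs background decoys: crisper chemotypes classify better
  mccs <- sapply(c(0.05, 0.4), function(flip) {
    vals <- numeric(5)
    for (r in 1:5) {
      m <- make_chemotypes(k = 3, d = 64, seed = 800 + r,
                           active_flip_prob = flip,
                           near_active_fraction = 0,
                           near_active_flip_prob = 0.45)
      tr_a <- sample_actives(m, 40, seed = 810 + r)
      tr_d <- sample_decoys(m, 40, seed = 820 + r)
      te_a <- sample_actives(m, 60, seed = 830 + r)
      te_d <- sample_decoys(m, 60, seed = 840 + r)
      pred <- knn1_predict(rbind(tr_a$bits, tr_d$bits),
                           c(rep(1, 40), rep(0, 40)),
                           rbind(te_a$bits, te_d$bits))
      vals[r] <- mcc(confusion(pred, c(rep(1, 60), rep(0, 60))))
    }
    mean(vals)
  })
  expect_gt(mccs[[1]], mccs[[2]])
})

test_that("populations write with a ground-truth sidecar", {
  pop <- tiny_populations(seed = 77, n_act = 10, n_dcy = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  sidecar <- write_population(pop$actives, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".labels.csv")))
  expect_equal(sidecar$label, rep("active", 10))
  expect_false(any(is.na(sidecar$chemotype)))
  back <- read_fingerprints(path, pop$actives$kind)
  expect_identical(unname(back$bits), unname(pop$actives$bits))
})
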