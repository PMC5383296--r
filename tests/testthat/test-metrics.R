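test_that("confusion counts partition the test set", {
  pred <- c(1, 1, 0, 0, 1, 0, 1, 0, 0, 1)
  truth <- c(1, 0, 0, 1, 1, 0, 0, 0, 1, 1)
  cc <- confusion(pred, truth)
  # manual tally
  expect_equal(cc$tp, 3)
  expect_equal(cc$fp, 2)
  expect_equal(cc$tn, 3)
  expect_equal(cc$fn, 2)
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 10)

  perfect <- confusion(truth, truth)
  expect_equal(perfect$fp + perfect$fn, 0)
  inverted <- confusion(1 - truth, truth)
  expect_equal(inverted$tp + inverted$tn, 0)
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "different lengths")
})

test_that("recall, precision and MCC match their definitions", {
  expect_equal(recall(c(tp = 8, fp = 0, tn = 0, fn = 2)), 0.8)
  expect_equal(recall(c(tp = 5, fp = 9, tn = 1, fn = 0)), 1)
  expect_equal(precision(c(tp = 8, fp = 8, tn = 0, fn = 0)), 0.5)
  expect_equal(precision(c(tp = 3, fp = 0, tn = 5, fn = 2)), 1)
  expect_equal(precision(c(tp = 0, fp = 0, tn = 5, fn = 2)), 0)
  expect_equal(mcc(c(tp = 7, fp = 0, tn = 13, fn = 0)), 1)
  expect_equal(mcc(c(tp = 0, fp = 10, tn = 0, fn = 5)), -1)
  expect_equal(mcc(c(tp = 25, fp = 25, tn = 25, fn = 25)), 0)
  # degenerate denominator falls back to 0
  expect_equal(mcc(c(tp = 0, fp = 0, tn = 9, fn = 1)), 0)
})

test_that("metrics agree with the phi-coefficient oracle on random tables", {
  # MCC is the Pearson correlation of the expanded 0/1 vectors; recall and
  # precision are conditional means. An independent route through stats::cor.
  set.seed(101)
  for (i in 1:200) {
    counts <- rmultinom(1, size = sample(20:200, 1), prob = runif(4, 0.05, 1))
    cc <- c(tp = counts[1], fp = counts[2], tn = counts[3], fn = counts[4])
    truth <- rep(c(1, 0, 0, 1), counts)
    pred <- rep(c(1, 1, 0, 0), counts)
    if (cc["tp"] + cc["fn"] > 0) {
      expect_equal(recall(cc), mean(pred[truth == 1]))
    }
    if (cc["tp"] + cc["fp"] > 0) {
      expect_equal(precision(cc), mean(truth[pred == 1]))
    }
    phi <- suppressWarnings(stats::cor(pred, truth))
    if (is.na(phi)) phi <- 0 # zero-variance margin: the 0 convention
    expect_equal(mcc(cc), phi, tolerance = 1e-12)
  }
})

test_that("MCC is overflow-safe at screening-scale counts", {
  big <- c(tp = 9e6, fp = 3e6, tn = 8e6, fn = 1e6)
  # direct high-precision evaluation of the formula, factored to stay small
  direct <- (9e6 * 8e6 - 3e6 * 1e6) /
    (sqrt(12e6) * sqrt(10e6) * sqrt(11e6) * sqrt(9e6))
  expect_equal(mcc(big), direct)
  expect_true(abs(mcc(big)) <= 1)
})

test_that("MCC is invariant under the class-swap symmetry", {
  set.seed(5)
  for (i in 1:50) {
    cc <- c(tp = sample(0:50, 1), fp = sample(0:50, 1),
            tn = sample(0:50, 1), fn = sample(0:50, 1))
    swapped <- c(tp = cc[["tn"]], fp = cc[["fn"]], tn = cc[["tp"]],
                 fn = cc[["fp"]])
    expect_equal(mcc(cc), mcc(swapped))
    expect_true(mcc(cc) >= -1 && mcc(cc) <= 1)
  }
})

test_that("score_predictions flags degenerate cells", {
  s <- score_predictions(c(0, 0, 0), c(1, 0, 1))
  expect_equal(s$precision, 0)
  expect_true(s$degenerate)
  s2 <- score_predictions(c(1, 0, 1), c(1, 0, 1))
  expect_false(s2$degenerate)
  expect_equal(s2$mcc, 1)
})

test_that("trial aggregation averages per-trial metrics, not pooled counts", {
  records <- tibble::tibble(
    classifier = "nb", fingerprint = "keyed-166",
    ratio = 1, library_size = 1000, trial = 1:2,
    recall = c(0.4, 0.6), precision = c(1, 0.5), mcc = c(0.2, 0.6),
    tp = c(4, 6), fp = c(0, 6), tn = c(90, 84), fn = c(6, 4)
  )
  agg <- aggregate_trials(records)
  expect_equal(agg$recall, 0.5)
  expect_equal(agg$precision, 0.75)
  expect_equal(agg$mcc, 0.4)
  expect_equal(agg$n_trials, 2)
  # pooling the confusion counts gives a different precision: 10/16
  pooled <- precision(c(tp = 10, fp = 6, tn = 174, fn = 10))
  expect_false(isTRUE(all.equal(agg$precision, pooled)))
  # aggregation is invariant to trial order
  agg_rev <- aggregate_trials(records[2:1, ])
  expect_equal(agg, agg_rev)
})

test_that("aggregation rejects incomplete cells and names them", {
  records <- tibble::tibble(
    classifier = "nb", fingerprint = "keyed-166",
    ratio = c(1, 1, 2), library_size = 1000, trial = c(1, 2, 1),
    recall = 0.5, precision = 0.5, mcc = 0.5
  )
  expect_error(aggregate_trials(records), "Incomplete cells")
})

test_that("PR trajectories order by ratio and label quadrants", {
  cm <- tibble::tibble(
    ratio = c(10, 0.5, 2),
    recall = c(0.4, 0.9, 0.7),
    precision = c(0.9, 0.2, 0.6)
  )
  traj <- pr_trajectory(cm)
  expect_equal(traj$ratio, c(0.5, 2, 10))
  # low ratio: high recall / low precision = quarter IV; then the good
  # corner I; heavy negatives: low recall / high precision = III
  expect_equal(traj$quadrant, c("IV", "I", "III"))
  expect_error(pr_trajectory(cm[1, ]), "at least 2")
  expect_error(pr_trajectory(cm[c(1, 1, 2), ]), "single context")
})
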