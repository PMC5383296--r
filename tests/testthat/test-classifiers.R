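test_that("classifier specs validate parameters", {
  expect_equal(classifier_spec("rf")$params$ntree, 10)
  expect_equal(classifier_spec("svm-poly")$params$C, 1)
  expect_equal(classifier_spec("svm-poly")$params$epsilon, 1e-12)
  expect_equal(classifier_spec("svm-poly", degree = 3)$params$degree, 3)
  expect_error(classifier_spec("nb", smoothing = 2), "Unknown parameter")
  expect_error(classifier_spec("knn1", k = 5), "k must be 1")
  expect_error(classifier_spec("boost"), "should be one of")
})

test_that("fitting requires both classes and records metadata", {
  bits <- rbind(c(1, 0, 1), c(0, 1, 0), c(1, 1, 1), c(0, 0, 0))
  fit <- fit_classifier(classifier_spec("nb"), bits, c(1, 0, 1, 0))
  expect_equal(fit$meta$n_pos, 2)
  expect_equal(fit$meta$n_neg, 2)
  expect_equal(fit$meta$d, 3)
  # class priors 0.5/0.5 on balanced data
  expect_equal(fit$model$log_prior_pos, log(0.5))
  expect_error(fit_classifier(classifier_spec("nb"), bits, c(1, 1, 1, 1)),
               "each class")
  expect_error(fit_classifier(classifier_spec("nb"),
                              matrix(0L, 0, 3), integer(0)), "Empty")
  # label vocabulary: active/inactive strings accepted
  fit2 <- fit_classifier(classifier_spec("nb"), bits,
                         c("active", "inactive", "active", "inactive"))
  expect_equal(fit2$meta$n_pos, 2)
})

test_that("prediction enforces the bit-width contract", {
  bits <- rbind(c(1, 0, 1), c(0, 1, 0))
  fit <- fit_classifier(classifier_spec("knn1"), bits, c(1, 0))
  expect_error(predict(fit, matrix(0L, 1, 4)), "width")
  expect_identical(predict(fit, matrix(integer(0), 0, 3)), integer(0))
})

test_that("naive Bayes posteriors match hand computation", {
  # one example per class: pos (1,0), neg (0,1); Laplace theta = 2/3 or 1/3
  bits <- rbind(c(1, 0), c(0, 1))
  fit <- fit_classifier(classifier_spec("nb"), bits, c(1, 0))
  p <- nb_posterior(fit, c(1, 0))
  # p(x|pos) = (2/3)^2, p(x|neg) = (1/3)^2 -> posterior 4/5
  expect_equal(unname(p["p_active"]), 0.8)
  expect_equal(sum(p), 1)
  expect_equal(predict(fit, matrix(c(1, 0), 1)), 1L)

  # equidistant test vectors: posterior exactly 0.5, tie goes negative
  for (x in list(c(1, 1), c(0, 0))) {
    expect_equal(unname(nb_posterior(fit, x)["p_active"]), 0.5)
    expect_equal(predict(fit, matrix(x, 1)), 0L)
  }
  expect_error(nb_posterior(fit, c(2, 0)), "0/1")
})

test_that("imbalanced priors dominate when likelihoods cancel", {
  # 2 positives, 18 negatives, each bit set in exactly half of each class
  # *after* Laplace smoothing ((1+1)/(2+2) = (9+1)/(18+2) = 1/2): every bit
  # is uninformative, so the posterior equals the 0.9 negative prior
  bits <- rbind(c(1L, 1L), c(0L, 0L),
                matrix(1L, 9, 2), matrix(0L, 9, 2))
  fit <- fit_classifier(classifier_spec("nb"), bits, c(1, 1, rep(0, 18)))
  p <- nb_posterior(fit, c(1, 0))
  expect_equal(unname(p["p_inactive"]), 0.9)
})

test_that("posteriors normalize and priors shift monotonically with ratio", {
  set.seed(41)
  bits <- matrix(rbinom(40 * 8, 1, 0.4), 40, 8)
  labels <- rep(c(1, 0), 20)
  fit <- fit_classifier(classifier_spec("nb"), bits, labels)
  post <- nb_posterior(fit, bits)
  expect_equal(unname(rowSums(post)), rep(1, 40))
  # growing the negative class never raises the active prior log-odds
  prior_logodds <- vapply(c(1, 2, 5, 10), function(r) {
    n_neg <- 10 * r
    b <- matrix(rbinom((10 + n_neg) * 8, 1, 0.4), 10 + n_neg, 8)
    f <- fit_classifier(classifier_spec("nb"), b,
                        c(rep(1, 10), rep(0, n_neg)))
    f$model$log_prior_pos - f$model$log_prior_neg
  }, numeric(1))
  expect_true(all(diff(prior_logodds) < 0))
})

test_that("1-NN matches the exhaustive Euclidean oracle", {
  set.seed(17)
  train <- matrix(rbinom(30 * 16, 1, 0.35), 30, 16)
  labels <- rbinom(30, 1, 0.5)
  labels[1:2] <- c(1, 0) # both classes present
  test <- matrix(rbinom(100 * 16, 1, 0.35), 100, 16)
  expect_equal(knn1_predict(train, labels, test),
               unname(brute_nn1(train, labels, test)))
  # a test row equal to a training row gets that row's label
  expect_equal(knn1_predict(train, labels, train[7, ]), labels[[7]])
})

test_that("1-NN ties resolve to the earliest training row", {
  train <- rbind(c(1, 0, 0), c(0, 0, 1))
  # query (0,0,0) is Hamming-1 from both rows; earlier row wins
  expect_equal(knn1_predict(train, c(1, 0), c(0, 0, 0)), 1L)
  expect_equal(knn1_predict(train[2:1, ], c(0, 1), c(0, 0, 0)), 0L)
})

test_that("Euclidean and Hamming 1-NN orderings coincide on binary data", {
  set.seed(29)
  for (i in 1:20) {
    train <- matrix(rbinom(12 * 10, 1, 0.4), 12, 10)
    x <- rbinom(10, 1, 0.4)
    eu <- apply(train, 1, function(t) sqrt(sum((t - x)^2)))
    ham <- apply(train, 1, function(t) sum(t != x))
    expect_identical(order(eu), order(ham))
  }
})

test_that("adapter-backed classifiers honour their configuration", {
  skip_if_not_installed("kernlab")
  skip_if_not_installed("rpart")
  skip_if_not_installed("randomForest")
  pop <- tiny_populations(seed = 55, n_act = 40, n_dcy = 400)
  train <- rbind(pop$actives$bits, pop$decoys$bits[1:40, ])
  labels <- c(rep(1, 40), rep(0, 40))
  test <- rbind(sample_actives(pop$model, 30, seed = 91)$bits,
                pop$decoys$bits[41:70, ])
  truth <- c(rep(1, 30), rep(0, 30))

  for (algo in c("svm-poly", "tree-c45", "rf")) {
    fit <- fit_classifier(classifier_spec(algo), train, labels, seed = 2)
    pred <- predict(fit, test)
    expect_true(all(pred %in% c(0L, 1L)), info = algo)
    # the populations are separable enough that any of these beats chance
    expect_gt(mcc(confusion(pred, truth)), 0.2)
    # determinism under a fixed seed
    fit2 <- fit_classifier(classifier_spec(algo), train, labels, seed = 2)
    expect_identical(pred, predict(fit2, test), info = algo)
  }
  # the random forest records its 10-tree default in the fitted state
  rf <- fit_classifier(classifier_spec("rf"), train, labels, seed = 2)
  expect_equal(rf$model$ntree, 10)
  expect_equal(rf$model$fit$ntree, 10)
})
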