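#' Describe a classifier configuration
#'
#' A uniform specification for the five screening classifiers. Two are
#' implemented natively in this package -- Bernoulli naive Bayes (`"nb"`)
#' and single-nearest-neighbour (`"knn1"`) -- because they are simple,
#' fully specified and double as desk-scale oracles. The remaining three
#' are adapters over established R implementations with settings matching
#' the conventional WEKA-style defaults: `"svm-poly"` (C-SVC, complexity
#' C = 1, normalized polynomial kernel of degree 2, via kernlab),
#' `"tree-c45"` (a pruned decision tree via rpart) and `"rf"` (random
#' forest with 10 trees of unlimited depth via randomForest).
#'
#' Unknown parameter names are rejected; defaults per algorithm:
#' \describe{
#'   \item{nb}{`laplace = 1` (add-one smoothing).}
#'   \item{knn1}{`k = 1`, `distance = "euclidean"` (on binary vectors the
#'     Euclidean and Hamming orderings coincide).}
#'   \item{svm-poly}{`C = 1`, `epsilon = 1e-12`, `degree = 2`,
#'     `normalize = TRUE`.}
#'   \item{tree-c45}{`prune = TRUE`.}
#'   \item{rf}{`ntree = 10`, `seed = 1`.}
#' }
#'
#' @param algorithm one of `"nb"`, `"knn1"`, `"svm-poly"`, `"tree-c45"`,
#'   `"rf"`.
#' @param ... parameter overrides, validated against the algorithm's schema.
#' @return a `classifier_spec` object.
#' @examples
#' classifier_spec("rf")
#' classifier_spec("svm-poly", degree = 3)
#' @export
classifier_spec <- function(algorithm = c("nb", "knn1", "svm-poly",
                                          "tree-c45", "rf"), ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    "nb" = list(laplace = 1),
    "knn1" = list(k = 1, distance = "euclidean"),
    "svm-poly" = list(C = 1, epsilon = 1e-12, degree = 2, normalize = TRUE),
    "tree-c45" = list(prune = TRUE),
    "rf" = list(ntree = 10, seed = 1)
  )
  overrides <- list(...)
  if (length(overrides) > 0 && (is.null(names(overrides)) ||
                                any(!nzchar(names(overrides))))) {
    stop("Classifier parameters must be named.", call. = FALSE)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("Unknown parameter(s) for ", algorithm, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  params <- utils::modifyList(defaults, overrides)
  if (algorithm == "knn1" && params$k != 1) {
    stop("knn1 is the single-nearest-neighbour classifier; k must be 1.",
         call. = FALSE)
  }
  structure(list(algorithm = algorithm, params = params),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  p <- paste(names(x$params), unlist(lapply(x$params, format)),
             sep = "=", collapse = ", ")
  cat("<classifier_spec> ", x$algorithm, " (", p, ")\n", sep = "")
  invisible(x)
}

check_binary_matrix <- function(bits, arg = "bits") {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  if (length(bits) > 0 && !all(bits %in% c(0L, 1L))) {
    stop("`", arg, "` must be a 0/1 matrix.", call. = FALSE)
  }
  bits
}

check_binary_labels <- function(labels, n) {
  if (is.character(labels)) labels <- as.integer(labels == "active")
  if (is.logical(labels) || is.factor(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (length(labels) != n || !all(labels %in% c(0L, 1L))) {
    stop("`train_labels` must be one 0/1 label per training row.",
         call. = FALSE)
  }
  labels
}

#' Fit a classifier for virtual screening
#'
#' Trains the classifier described by `spec` on a binary fingerprint matrix
#' with 0/1 labels (1 = active). Fitting is deterministic under a fixed
#' seed, and the returned state records the class counts, bit width and
#' configuration.
#'
#' @param spec a [classifier_spec()].
#' @param train_bits 0/1 matrix, one fingerprint per row.
#' @param train_labels 0/1 vector (or `"active"`/`"inactive"` strings), one
#'   per row; both classes must be present.
#' @param seed integer seed for stochastic learners.
#' @return a `vs_fit` object with a [predict()][predict.vs_fit] method.
#' @export
fit_classifier <- function(spec, train_bits, train_labels, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  bits <- check_binary_matrix(train_bits, "train_bits")
  if (nrow(bits) == 0) {
    stop("Empty training set.", call. = FALSE)
  }
  labels <- check_binary_labels(train_labels, nrow(bits))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("Training set must contain at least one example of each class.",
         call. = FALSE)
  }
  model <- switch(spec$algorithm,
    "nb" = nb_fit(bits, labels, spec$params$laplace),
    "knn1" = list(train_bits = bits, train_labels = labels),
    "svm-poly" = svm_poly_fit(bits, labels, spec$params, seed),
    "tree-c45" = tree_fit(bits, labels, spec$params, seed),
    "rf" = rf_fit(bits, labels, spec$params, seed)
  )
  structure(
    list(spec = spec, model = model,
         meta = list(n_pos = n_pos, n_neg = n_neg, d = ncol(bits),
                     seed = as.integer(seed))),
    class = "vs_fit"
  )
}

#' @export
print.vs_fit <- function(x, ...) {
  cat("<vs_fit> ", x$spec$algorithm, ": ", x$meta$n_pos, " actives / ",
      x$meta$n_neg, " inactives, ", x$meta$d, " bits\n", sep = "")
  invisible(x)
}

#' Predict hard labels for a screening set
#'
#' Returns one hard 0/1 label per test fingerprint (1 = predicted active).
#' The evaluation pipeline scores hard classifications only.
#'
#' @param object a `vs_fit` from [fit_classifier()].
#' @param test_bits 0/1 matrix with the training bit width.
#' @param ... unused.
#' @return integer vector of 0/1 predictions.
#' @export
predict.vs_fit <- function(object, test_bits, ...) {
  bits <- check_binary_matrix(test_bits, "test_bits")
  if (ncol(bits) != object$meta$d && nrow(bits) > 0) {
    stop("Test bit width (", ncol(bits), ") differs from training width (",
         object$meta$d, ").", call. = FALSE)
  }
  if (nrow(bits) == 0) {
    return(integer(0))
  }
  switch(object$spec$algorithm,
    "nb" = nb_predict(object$model, bits),
    "knn1" = nn1_predict_cpp(object$model$train_bits,
                             object$model$train_labels, bits),
    "svm-poly" = svm_poly_predict(object$model, bits),
    "tree-c45" = tree_predict(object$model, bits),
    "rf" = rf_predict(object$model, bits)
  )
}

# --- native Bernoulli naive Bayes --------------------------------------------

nb_fit <- function(bits, labels, laplace = 1) {
  pos <- labels == 1L
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  theta_pos <- (colSums(bits[pos, , drop = FALSE]) + laplace) /
    (n_pos + 2 * laplace)
  theta_neg <- (colSums(bits[!pos, , drop = FALSE]) + laplace) /
    (n_neg + 2 * laplace)
  list(log_prior_pos = log(n_pos / (n_pos + n_neg)),
       log_prior_neg = log(n_neg / (n_pos + n_neg)),
       theta_pos = theta_pos, theta_neg = theta_neg)
}

# log-posterior margin via a linear form: log P(x|c) = sum_j x_j log(theta) +
# (1-x_j) log(1-theta); the decision is linear in x for Bernoulli NB.
nb_margin <- function(model, bits) {
  w <- (log(model$theta_pos) - log(1 - model$theta_pos)) -
    (log(model$theta_neg) - log(1 - model$theta_neg))
  b <- model$log_prior_pos - model$log_prior_neg +
    sum(log(1 - model$theta_pos) - log(1 - model$theta_neg))
  as.numeric(bits %*% w) + b
}

nb_predict <- function(model, bits) {
  # margin > 0 means p_active > 0.5; ties (margin == 0) go to the negative
  # class, the conservative call in a screening context
  as.integer(nb_margin(model, bits) > 0)
}

#' Naive Bayes class posteriors
#'
#' The Bernoulli naive Bayes posterior for a fingerprint:
#' `p(c | x) proportional to prior(c) * prod_j theta_jc^x_j (1 - theta_jc)^(1 - x_j)`,
#' with add-one (Laplace) smoothed per-bit rates. The returned pair is
#' normalized to sum to 1.
#'
#' @param state a `vs_fit` trained with the `"nb"` algorithm.
#' @param x a single binary vector, or a 0/1 matrix of fingerprints.
#' @return named vector `c(p_active, p_inactive)`, or a two-column matrix
#'   for matrix input.
#' @export
nb_posterior <- function(state, x) {
  stopifnot(inherits(state, "vs_fit"))
  if (state$spec$algorithm != "nb") {
    stop("`state` was not trained with the nb algorithm.", call. = FALSE)
  }
  single <- is.null(dim(x))
  bits <- check_binary_matrix(if (single) matrix(x, nrow = 1) else x, "x")
  if (ncol(bits) != state$meta$d) {
    stop("Fingerprint width (", ncol(bits), ") differs from training width (",
         state$meta$d, ").", call. = FALSE)
  }
  margin <- nb_margin(state$model, bits)
  p_active <- stats::plogis(margin)
  out <- cbind(p_active = p_active, p_inactive = 1 - p_active)
  if (single) {
    c(p_active = unname(out[1, 1]), p_inactive = unname(out[1, 2]))
  } else {
    out
  }
}

#' Single-nearest-neighbour prediction
#'
#' Labels each query with the label of the closest training fingerprint
#' under the Euclidean distance; on binary vectors the squared Euclidean
#' distance equals the Hamming distance, so the orderings coincide. Ties
#' resolve to the lowest training-row index.
#'
#' @param train_bits 0/1 training matrix.
#' @param train_labels 0/1 labels, one per row.
#' @param x a single binary vector or a 0/1 query matrix.
#' @return integer 0/1 label(s).
#' @export
knn1_predict <- function(train_bits, train_labels, x) {
  bits <- check_binary_matrix(train_bits, "train_bits")
  if (nrow(bits) == 0) {
    stop("Empty training set.", call. = FALSE)
  }
  labels <- check_binary_labels(train_labels, nrow(bits))
  single <- is.null(dim(x))
  q <- check_binary_matrix(if (single) matrix(x, nrow = 1) else x, "x")
  out <- nn1_predict_cpp(bits, labels, q)
  if (single) out[[1]] else out
}

# --- adapters ----------------------------------------------------------------

require_adapter <- function(pkg, algorithm) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("The ", algorithm, " adapter needs the ", pkg, " package.",
         call. = FALSE)
  }
}

# Normalized polynomial kernel: K'(x,y) = K(x,y) / sqrt(K(x,x) K(y,y)) with
# K(x,y) = (<x,y> + 1)^degree; the +1 keeps the kernel defined for all-zero
# fingerprints.
normalized_poly_kernel <- function(degree = 2) {
  force(degree)
  k <- function(x, y) {
    kxy <- (sum(x * y) + 1)^degree
    kxx <- (sum(x * x) + 1)^degree
    kyy <- (sum(y * y) + 1)^degree
    kxy / sqrt(kxx * kyy)
  }
  class(k) <- "kernel"
  k
}

svm_poly_fit <- function(bits, labels, params, seed) {
  require_adapter("kernlab", "svm-poly")
  kern <- if (isTRUE(params$normalize)) {
    normalized_poly_kernel(params$degree)
  } else {
    kernlab::polydot(degree = params$degree, offset = 1)
  }
  fit <- with_seed(seed, {
    kernlab::ksvm(x = bits, y = factor(labels, levels = c(0, 1)),
                  type = "C-svc", C = params$C, kernel = kern,
                  scaled = FALSE)
  })
  list(fit = fit, params = params)
}

svm_poly_predict <- function(model, bits) {
  as.integer(as.character(kernlab::predict(model$fit, bits)))
}

tree_fit <- function(bits, labels, params, seed) {
  require_adapter("rpart", "tree-c45")
  df <- as.data.frame(bits)
  names(df) <- paste0("b", seq_len(ncol(bits)))
  df$.label <- factor(labels, levels = c(0, 1))
  cp <- if (isTRUE(params$prune)) 0.01 else 0
  fit <- with_seed(seed, {
    rpart::rpart(.label ~ ., data = df, method = "class",
                 control = rpart::rpart.control(cp = cp, xval = 0))
  })
  list(fit = fit, d = ncol(bits))
}

tree_predict <- function(model, bits) {
  df <- as.data.frame(bits)
  names(df) <- paste0("b", seq_len(ncol(bits)))
  as.integer(as.character(stats::predict(model$fit, df, type = "class")))
}

rf_fit <- function(bits, labels, params, seed) {
  require_adapter("randomForest", "rf")
  fit <- with_seed(as.integer(params$seed) + as.integer(seed), {
    randomForest::randomForest(x = bits, y = factor(labels, levels = c(0, 1)),
                               ntree = params$ntree)
  })
  list(fit = fit, ntree = params$ntree)
}

rf_predict <- function(model, bits) {
  as.integer(as.character(stats::predict(model$fit, bits)))
}
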