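# Classifier bank for window-level behaviour recognition.  Six families are
# supported behind one interface: k-nearest neighbours, naive Bayes, a
# single-hidden-layer perceptron, an RBF support vector machine, a pruned
# binary classification tree, and a random forest.

classifier_kinds <- function() c("knn", "naive_bayes", "mlp", "svm", "bct", "rf")

default_hyperparams <- function(kind) {
  switch(kind,
    knn = list(k = 5L),
    naive_bayes = list(laplace = 0),
    mlp = list(size = 64L, maxit = 500L, decay = 1e-4),
    svm = list(kernel = "radial", cost = 10, gamma = NULL), # NULL -> 1/n_features
    bct = list(cp = 0.01, minsplit = 20L),
    rf = list(ntree = 200L),
    stopf(
      "unknown classifier kind '%s'; valid kinds: %s", kind,
      paste(classifier_kinds(), collapse = ", ")
    )
  )
}

# scale-sensitive models get per-feature z-scoring by default
standardize_by_default <- function(kind) kind %in% c("knn", "mlp", "svm")

fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(x, scaler) {
  if (is.null(scaler)) {
    return(x)
  }
  sweep(sweep(x, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

#' Train a behaviour classifier on a feature matrix
#'
#' @param features A [build_feature_matrix()] result with behaviour labels.
#' @param kind One of `"knn"`, `"naive_bayes"`, `"mlp"`, `"svm"`, `"bct"`,
#'   `"rf"`.
#' @param hyperparams Named list overriding the kind's defaults (KNN `k = 5`;
#'   SVM RBF kernel, `cost = 10`, `gamma = 1/n_features`; RF `ntree = 200`;
#'   MLP one hidden layer of 64 units, `maxit = 500`; BCT a pruned single
#'   tree via `cp = 0.01`).
#' @param seed Integer seed; training is deterministic for a fixed seed.
#' @param standardize Z-score features (fitted on the training rows only)?
#'   Defaults to on for the scale-sensitive kinds (SVM, KNN, MLP), off for
#'   trees and naive Bayes.
#' @return An object of class `behavior_model` with a [predict][stats::predict]
#'   method returning label vectors.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(), 600, seed = 1)
#' fm <- build_feature_matrix(segment_windows(ds$stream, ds$schedule))
#' if (length(unique(fm$label)) > 1) {
#'   m <- train_classifier(fm, "svm", seed = 1)
#'   mean(predict(m, fm$x) == fm$label)
#' }
train_classifier <- function(features, kind, hyperparams = list(), seed = 1L,
                             standardize = standardize_by_default(kind)) {
  if (length(kind) != 1L || !kind %in% classifier_kinds()) {
    stopf(
      "unknown classifier kind '%s'; valid kinds: %s",
      paste(kind, collapse = ","), paste(classifier_kinds(), collapse = ", ")
    )
  }
  x <- features$x
  y <- features$label
  keep <- !is.na(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  if (any(!is.finite(x))) stopf("feature matrix contains non-finite values")
  classes <- unique(y)
  if (length(classes) < 2L) stopf("training data contains a single class")
  yf <- if (all(classes %in% behavior_levels())) behavior_factor(y) else factor(y)
  hp <- utils::modifyList(default_hyperparams(kind), hyperparams)
  scaler <- if (standardize) fit_scaler(x) else NULL
  xs <- apply_scaler(x, scaler)

  fit <- with_seed(seed, switch(kind,
    knn = list(x = xs, y = yf, k = hp$k), # lazy learner: keep the training set
    naive_bayes = e1071::naiveBayes(xs, yf, laplace = hp$laplace),
    mlp = nnet::nnet(xs, nnet::class.ind(yf),
      size = hp$size, maxit = hp$maxit,
      decay = hp$decay, softmax = TRUE, trace = FALSE, MaxNWts = 100000L
    ),
    svm = e1071::svm(xs, yf,
      kernel = hp$kernel, cost = hp$cost,
      gamma = if (is.null(hp$gamma)) 1 / ncol(xs) else hp$gamma
    ),
    bct = {
      tr <- rpart::rpart(y ~ .,
        data = data.frame(y = yf, xs), method = "class",
        control = rpart::rpart.control(cp = hp$cp, minsplit = hp$minsplit)
      )
      rpart::prune(tr, cp = hp$cp)
    },
    rf = randomForest::randomForest(xs, yf, ntree = hp$ntree)
  ))
  structure(
    list(
      kind = kind, fit = fit, scaler = scaler, classes = levels(yf),
      hyperparams = hp, seed = as.integer(seed)
    ),
    class = "behavior_model"
  )
}

#' Predict behaviour labels for feature rows
#'
#' @param object A [train_classifier()] model.
#' @param newdata Numeric feature matrix (63 columns) or a `feature_matrix`.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.behavior_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else as.matrix(newdata)
  xs <- apply_scaler(x, object$scaler)
  out <- switch(object$kind,
    knn = with_seed(
      object$seed,
      class::knn(object$fit$x, xs, object$fit$y, k = object$fit$k)
    ),
    naive_bayes = stats::predict(object$fit, xs),
    mlp = {
      p <- stats::predict(object$fit, xs)
      factor(colnames(p)[max.col(p, ties.method = "first")], levels = object$classes)
    },
    svm = stats::predict(object$fit, xs),
    bct = stats::predict(object$fit, data.frame(xs), type = "class"),
    rf = stats::predict(object$fit, xs)
  )
  as.character(out)
}

#' @export
print.behavior_model <- function(x, ...) {
  cat(sprintf(
    "Behavior classifier [%s]: %d classes (%s)%s\n",
    x$kind, length(x$classes), paste(x$classes, collapse = ", "),
    if (is.null(x$scaler)) "" else ", z-scored features"
  ))
  invisible(x)
}

# deterministic assignment of groups (animals) to folds
make_group_folds <- function(groups, n_folds, seed) {
  u <- sort(unique(groups))
  if (is.null(n_folds)) n_folds <- length(u)
  if (n_folds < 2L) stopf("grouped cross-validation needs at least 2 folds")
  if (length(u) < n_folds) stopf("fewer groups (%d) than folds (%d)", length(u), n_folds)
  perm <- with_seed(seed, sample(u))
  fold_of_group <- stats::setNames(rep(seq_len(n_folds), length.out = length(u)), perm)
  unname(fold_of_group[groups])
}

#' Grouped cross-validation of a behaviour classifier
#'
#' Folds are split by animal (grouped k-fold, default leave-one-animal-out)
#' so no individual contributes windows to both training and test.  Held-out
#' predictions are pooled across folds before scoring with [evaluate()].
#'
#' @param features A [build_feature_matrix()] result spanning >= 2 animals.
#' @param kind Classifier kind, see [train_classifier()].
#' @param n_folds Number of folds; default one fold per animal.
#' @param seed Integer seed controlling fold assignment and training.
#' @param hyperparams,standardize Passed to [train_classifier()].
#' @param classes Optional class subset to report on (e.g. the five main
#'   behaviours); defaults to all classes present.
#' @param folds Optional precomputed integer fold id per row (used by
#'   [compare_classifiers()] to pair comparisons); overrides `n_folds`.
#' @return A [class_report()] with attribute `folds`.
#' @export
cross_validate <- function(features, kind, n_folds = NULL, seed = 1L,
                           hyperparams = list(),
                           standardize = standardize_by_default(kind),
                           classes = NULL, folds = NULL) {
  keep <- which(!is.na(features$label))
  if (!length(keep)) stopf("no labeled rows")
  if (is.null(folds)) {
    folds <- make_group_folds(features$animal_id[keep], n_folds, seed)
  } else {
    folds <- folds[keep]
  }
  pred <- rep(NA_character_, length(keep))
  for (f in sort(unique(folds))) {
    tr <- keep[folds != f]
    te <- keep[folds == f]
    sub <- list(
      x = features$x[tr, , drop = FALSE], label = features$label[tr],
      animal_id = features$animal_id[tr]
    )
    class(sub) <- "feature_matrix"
    model <- train_classifier(sub, kind,
      hyperparams = hyperparams, seed = seed,
      standardize = standardize
    )
    pred[folds == f] <- predict(model, features$x[te, , drop = FALSE])
  }
  rep_out <- evaluate(features$label[keep], pred,
    classes = classes, classifier = kind
  )
  attr(rep_out, "folds") <- folds
  rep_out
}

#' Compare classifier families on identical folds
#'
#' Runs [cross_validate()] for each requested kind with one shared fold
#' assignment, so the comparison is paired: every classifier sees exactly the
#' same training and test animals.
#'
#' @param features A [build_feature_matrix()] result.
#' @param kinds Classifier kinds to compare (default all six).
#' @param n_folds,seed,classes As in [cross_validate()].
#' @param hyperparams Optional named list of per-kind hyperparameter
#'   overrides, e.g. `list(mlp = list(size = 16))`.
#' @return Named list of [class_report()]s, one per kind, with attribute
#'   `folds`.
#' @export
compare_classifiers <- function(features, kinds = classifier_kinds(),
                                n_folds = NULL, seed = 1L, classes = NULL,
                                hyperparams = list()) {
  keep <- which(!is.na(features$label))
  folds_keep <- make_group_folds(features$animal_id[keep], n_folds, seed)
  folds <- rep(NA_integer_, length(features$label))
  folds[keep] <- folds_keep
  out <- lapply(kinds, function(k) {
    cross_validate(features, k,
      seed = seed, classes = classes, folds = folds,
      hyperparams = hyperparams[[k]] %||% list()
    )
  })
  names(out) <- kinds
  attr(out, "folds") <- folds_keep
  out
}
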