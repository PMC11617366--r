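# Eq.-style sensitivity/precision scoring and the classifier bank.

test_that("per-class sensitivity and precision follow their definitions", {
  # class "a": TP = 9, FN = 1, FP = 3
  truth <- c(rep("a", 10), rep("b", 13))
  pred <- c(rep("a", 9), "b", rep("a", 3), rep("b", 10))
  rep_out <- evaluate(truth, pred)
  a <- rep_out$per_class[rep_out$per_class$class == "a", ]
  expect_equal(a$sensitivity_pct, 90)
  expect_equal(a$precision_pct, 75)
  expect_equal(a$tp, 9L)
  expect_equal(a$fn, 1L)
  expect_equal(a$fp, 3L)
})

test_that("perfect predictions score 100/100 everywhere", {
  truth <- sample(behavior_levels(), 60, replace = TRUE)
  rep_out <- evaluate(truth, truth)
  expect_true(all(rep_out$per_class$sensitivity_pct == 100))
  expect_true(all(rep_out$per_class$precision_pct == 100))
  expect_equal(rep_out$macro_sensitivity_pct, 100)
  expect_error(evaluate(truth, truth[-1]), "length")
})

test_that("counts agree with a confusion-matrix oracle on random labels", {
  set.seed(3)
  classes <- c("feeding", "grazing", "walking", "lying_resting")
  for (rep_i in 1:25) {
    n <- sample(10:200, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    rep_out <- evaluate(truth, pred, classes = classes)
    cm <- table(
      factor(truth, levels = classes),
      factor(pred, levels = classes)
    )
    for (i in seq_along(classes)) {
      tp <- cm[i, i]
      fn <- sum(cm[i, ]) - tp
      fp <- sum(cm[, i]) - tp
      row <- rep_out$per_class[i, ]
      expect_equal(row$tp, unname(tp))
      if (tp + fn > 0) expect_equal(row$sensitivity_pct, unname(100 * tp / (tp + fn)))
      if (tp + fp > 0) expect_equal(row$precision_pct, unname(100 * tp / (tp + fp)))
    }
    # every misclassification is one FN and one FP
    expect_equal(sum(rep_out$per_class$fp), sum(rep_out$per_class$fn))
    # micro-averaged sensitivity equals overall accuracy
    expect_equal(
      sum(rep_out$per_class$tp) / sum(rep_out$per_class$support),
      mean(truth == pred)
    )
  }
})

test_that("a never-predicted class drops out of the macro precision", {
  truth <- c("a", "a", "b", "b")
  pred <- c("a", "a", "a", "a")
  rep_out <- evaluate(truth, pred)
  b <- rep_out$per_class[rep_out$per_class$class == "b", ]
  expect_true(is.na(b$precision_pct))
  expect_equal(rep_out$macro_precision_pct, 50) # only class "a" contributes
  expect_equal(rep_out$macro_sensitivity_pct, 50)
})

test_that("macro averages are unweighted means of per-class values", {
  r <- class_report(
    paste0("c", 1:5),
    sensitivity_pct = c(92.53, 93.85, 95.73, 94.38, 92.64),
    precision_pct = c(90.12, 88.54, 91.27, 89.17, 90.43)
  )
  expect_equal(r$macro_sensitivity_pct, mean(c(92.53, 93.85, 95.73, 94.38, 92.64)))
  expect_equal(r$macro_precision_pct, mean(c(90.12, 88.54, 91.27, 89.17, 90.43)))
})

test_that("every classifier kind separates an easy two-class problem", {
  fm <- separable_features()
  for (kind in classifier_kinds()) {
    hp <- if (kind == "mlp") list(size = 8, maxit = 200) else list()
    m <- train_classifier(fm, kind, hyperparams = hp, seed = 1)
    pred <- predict(m, fm$x)
    rep_out <- evaluate(fm$label, pred, classifier = kind)
    expect_true(
      all(rep_out$per_class$sensitivity_pct == 100),
      label = paste(kind, "training sensitivity 100%")
    )
  }
})

test_that("training and prediction are deterministic for a fixed seed", {
  fm <- cohort_features(2, 300, 10)
  holdout <- cohort_features(1, 300, 10, base_seed = 50)
  for (kind in c("svm", "rf", "knn", "mlp")) {
    hp <- if (kind == "mlp") list(size = 8, maxit = 100) else list()
    p1 <- predict(train_classifier(fm, kind, hp, seed = 3), holdout$x)
    p2 <- predict(train_classifier(fm, kind, hp, seed = 3), holdout$x)
    expect_identical(p1, p2, label = paste(kind, "deterministic"))
  }
})

test_that("degenerate training inputs are rejected", {
  fm <- separable_features()
  fm$label <- rep("walking", length(fm$label))
  expect_error(train_classifier(fm, "svm"), "single class")
  expect_error(train_classifier(separable_features(), "boost"), "unknown classifier")
})

test_that("grouped cross-validation holds each animal out exactly once", {
  fm <- cohort_features(3, 600, 10)
  rep_out <- cross_validate(fm, "svm", seed = 1)
  folds <- attr(rep_out, "folds")
  expect_equal(length(unique(folds)), 3L)
  # fold id is a function of the animal only
  expect_true(all(tapply(folds, fm$animal_id, function(f) length(unique(f))) == 1))
  # each fold holds exactly one animal
  expect_equal(length(unique(tapply(fm$animal_id, folds, function(a) a[1]))), 3L)
  expect_error(cross_validate(fm, "svm", n_folds = 5), "fewer groups")
})

test_that("row order does not change the cross-validation report", {
  fm <- cohort_features(3, 600, 10)
  set.seed(1)
  perm <- sample(nrow(fm$x))
  fm_shuf <- fake_feature_matrix(
    fm$x[perm, ], fm$label[perm],
    animal_id = fm$animal_id[perm], start_s = fm$start_s[perm]
  )
  r1 <- cross_validate(fm, "svm", seed = 2)
  r2 <- cross_validate(fm_shuf, "svm", seed = 2)
  expect_equal(r1$per_class, r2$per_class)
  expect_equal(r1$macro_sensitivity_pct, r2$macro_sensitivity_pct)
})

test_that("classifier comparison is paired and beats chance on synthetic data", {
  fm <- cohort_features(3, 600, 10)
  reports <- compare_classifiers(fm,
    seed = 1,
    hyperparams = list(mlp = list(size = 12, maxit = 150))
  )
  expect_named(reports, classifier_kinds())
  # identical fold assignment across kinds
  for (r in reports) expect_equal(attr(r, "folds"), attr(reports[[1]], "folds"))
  # all kinds clear the 1-in-7 chance level by a wide margin
  for (k in names(reports)) {
    expect_gt(reports[[k]]$macro_sensitivity_pct, 100 / 7)
  }
})
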