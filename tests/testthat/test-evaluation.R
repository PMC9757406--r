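test_that("confusion matrices tally true against predicted labels", {
  cm <- confusion_matrix(c("a", "b", "a"), c("a", "b", "a"),
                         class_names = c("a", "b"))
  expect_equal(unclass(cm), matrix(c(2L, 0L, 0L, 1L), 2,
                                   dimnames = list(true = c("a", "b"),
                                                   predicted = c("a", "b"))))
  # all predicted as the first class -> single nonzero column
  cm2 <- confusion_matrix(c("a", "b", "b"), rep("a", 3), c("a", "b"))
  expect_equal(colSums(unclass(cm2)), c(a = 3, b = 0))

  # random labels agree with a brute-force tally loop
  set.seed(6)
  cls <- c("x", "y", "z")
  tr <- sample(cls, 100, replace = TRUE)
  pr <- sample(cls, 100, replace = TRUE)
  cm3 <- unclass(confusion_matrix(tr, pr, cls))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cm3[i, j], sum(tr == cls[i] & pr == cls[j]))
  }

  expect_error(confusion_matrix("a", "q", class_names = c("a", "b")),
               "outside")
  expect_error(confusion_matrix(c("a", "b"), "a"), "length")
})

test_that("metrics reproduce the hand-derived binary example", {
  cm <- matrix(c(8, 1, 2, 9), 2)  # rows true: [[8,2],[1,9]]
  m <- classification_metrics(cm)
  expect_equal(round(m[["accuracy"]], 4), 0.85)
  expect_equal(round(m[["sensitivity"]], 4), 0.85)
  expect_equal(round(m[["specificity"]], 4), 0.85)
  expect_equal(round(m[["f_score"]], 4), 0.8496)
  # binary macro sensitivity/specificity agree with the direct formulas
  expect_equal(m[["sensitivity"]], (8 / 10 + 9 / 10) / 2)
  expect_equal(m[["specificity"]], (9 / 10 + 8 / 10) / 2)
})

test_that("metrics handle perfect and degenerate predictions", {
  perfect <- diag(c(5L, 3L, 7L))
  expect_equal(unname(classification_metrics(perfect)), rep(1, 4))
  # one class never predicted: its precision 0/0 -> 0, so its F is 0
  cm <- matrix(c(5, 5, 0, 0), 2)
  m <- classification_metrics(cm)
  expect_equal(m[["accuracy"]], 0.5)
  expect_true(all(m >= 0 & m <= 1))
  expect_error(classification_metrics(matrix(0, 2, 2)), "empty")
})

test_that("metrics agree with the per-class tally oracle on random matrices", {
  set.seed(9)
  for (i in 1:100) {
    C <- sample(2:5, 1)
    cm <- matrix(rpois(C * C, 4), C)
    if (sum(cm) == 0) cm[1, 1] <- 1
    expect_equal(classification_metrics(cm), oracle_metrics(cm),
                 tolerance = 1e-12)
  }
})

test_that("stratified folds balance classes to within one sample", {
  for (n in c(30, 31, 35)) {
    y <- factor(rep(c("a", "b", "c"), length.out = 3 * n)[seq_len(3 * n)])
    y <- factor(rep(c("a", "b", "c"), times = c(n, n, n)))
    folds <- dmelm:::stratified_folds(y, 10, seed = 1)
    for (cls in levels(y)) {
      sizes <- table(factor(folds[y == cls], levels = 1:10))
      expect_lte(max(sizes) - min(sizes), 1)
    }
    expect_equal(sort(unique(folds)), 1:10)
  }
  expect_error(dmelm:::stratified_folds(factor(rep(c("a", "b"), c(3, 20))), 5,
                                        seed = 1),
               "at least k")
})

test_that("cross-validation reports chance level for trivial classifiers", {
  tab <- as.data.frame(matrix(rnorm(90 * 4), 90))
  names(tab) <- paste0("f", 1:4)
  tab$label <- rep(c("a", "b", "c"), each = 30)
  class(tab) <- c("feature_table", "data.frame")
  majority_trainer <- function(x, y) {
    structure(list(lab = names(which.max(table(y))), levels = levels(y)),
              class = "majority")
  }
  assign("predict.majority",
         function(object, newdata, ...) {
           factor(rep(object$lab, nrow(newdata)), levels = object$levels)
         },
         envir = globalenv())
  on.exit(rm("predict.majority", envir = globalenv()))
  rep <- cross_validate(tab, majority_trainer, k = 5, seed = 2)
  expect_equal(rep$mean[["accuracy"]], 1 / 3, tolerance = 1e-9)
  expect_equal(dim(rep$per_fold), c(5L, 4L))
  expect_true(all(rep$sd >= 0))
  # determinism
  rep2 <- cross_validate(tab, majority_trainer, k = 5, seed = 2)
  expect_identical(rep$per_fold, rep2$per_fold)
})

test_that("the activation sweep compares all activations on frozen folds", {
  tab <- synth_table_cache()[c(1:30, 101:130, 201:230), ]
  class(tab) <- c("feature_table", "data.frame")
  sw <- activation_sweep(tab, n_hidden = 50, k = 5, seed = 0)
  expect_equal(nrow(sw), 10L)
  expect_equal(sw$activation, activation_kinds())
  expect_true(all(sw$accuracy_mean >= 0 & sw$accuracy_mean <= 1))
  # the radial multiquadric dominates the piecewise-linear activations
  acc <- setNames(sw$accuracy_mean, sw$activation)
  expect_gt(acc[["multiquadric"]], acc[["tribas"]])
  expect_gt(acc[["multiquadric"]], acc[["inv_tribas"]])
  expect_gte(acc[["multiquadric"]], acc[["hardlim"]])
})

test_that("validation curves track capacity on frozen folds deterministically", {
  tab <- synth_table_cache()[c(1:25, 101:125, 201:225), ]
  class(tab) <- c("feature_table", "data.frame")
  grid <- c(5, 20, 60)
  vc <- validation_curve(tab, grid, activation = "sine", k = 5, seed = 1)
  expect_equal(vc$n_hidden, grid)
  expect_true(all(vc$train_accuracy >= 0 & vc$train_accuracy <= 1))
  # training accuracy non-decreasing in capacity (small tolerance)
  expect_true(all(diff(vc$train_accuracy) >= -0.02))
  vc2 <- validation_curve(tab, grid, activation = "sine", k = 5, seed = 1)
  expect_identical(vc, vc2)
})
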