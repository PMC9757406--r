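#' Confusion matrix
#'
#' Cross-tabulates true against predicted labels: entry \eqn{(i, j)} counts
#' samples of true class \eqn{i} predicted as class \eqn{j}.
#'
#' @param true,predicted Label vectors of equal length.
#' @param class_names Ordered class names; defaults to the sorted union of
#'   the observed labels.
#' @return A `"confusion_matrix"`: an integer matrix with class-name
#'   dimnames.
#' @export
confusion_matrix <- function(true, predicted, class_names = NULL) {
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (length(true) != length(predicted)) {
    stop_dmelm("true and predicted labels differ in length")
  }
  if (is.null(class_names)) class_names <- sort(unique(c(true, predicted)))
  unknown <- setdiff(unique(c(true, predicted)), class_names)
  if (length(unknown) > 0) {
    stop_dmelm("labels outside class_names: %s", paste(unknown, collapse = ", "))
  }
  cm <- table(factor(true, levels = class_names),
              factor(predicted, levels = class_names))
  cm <- matrix(as.integer(cm), nrow = length(class_names),
               dimnames = list(true = class_names, predicted = class_names))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the trace over the total. Sensitivity (recall), specificity
#' and F-score are computed one-vs-rest per class and macro-averaged
#' (unweighted mean over classes): sensitivity \eqn{TP/(TP+FN)},
#' specificity \eqn{TN/(TN+FP)}, F-score
#' \eqn{2\,prec\cdot rec/(prec+rec)}. Any 0/0 ratio is defined as 0.
#'
#' @param cm A [confusion_matrix()] (any square count matrix works).
#' @return Named numeric vector: `accuracy`, `sensitivity`, `specificity`,
#'   `f_score`, all in `[0, 1]`.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop_dmelm("empty confusion matrix")
  C <- nrow(cm)
  ratio0 <- function(num, den) ifelse(den > 0, num / den, 0)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  sens <- ratio0(tp, tp + fn)
  spec <- ratio0(tn, tn + fp)
  prec <- ratio0(tp, tp + fp)
  f <- ratio0(2 * prec * sens, prec + sens)
  c(accuracy = sum(tp) / total, sensitivity = mean(sens),
    specificity = mean(spec), f_score = mean(f))
}

# Stratified k-fold assignment: within each class, shuffle then deal
# indices round-robin, so per-class fold sizes differ by at most one.
stratified_folds <- function(y, k, seed) {
  y <- factor(y)
  if (any(table(y) < k)) {
    stop_dmelm("every class needs at least k = %d samples for stratified folds", k)
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in levels(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation
#'
#' Splits the table into `k` stratified folds (seeded shuffle; per-class
#' fold sizes differ by at most one), trains on \eqn{k-1} folds, evaluates
#' [classification_metrics()] on the held-out fold, and aggregates the
#' fold-level metrics as mean and population standard deviation — the
#' "mean ± sd" presentation standard in this literature.
#'
#' @param table A `"feature_table"` (features plus `label` column).
#' @param trainer Function `(x, y) -> model` where the model has a
#'   `predict(model, x)` method returning labels. See [elm_trainer()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold shuffle.
#' @param folds Optional precomputed fold assignment (overrides `k`/`seed`
#'   shuffling; used to share folds across compared classifiers).
#' @return A `"cv_report"`: list with `mean`, `sd` (named vectors over the
#'   four metrics), `per_fold` (k x 4 matrix), `k`, `seed`.
#' @export
cross_validate <- function(table, trainer, k = 10, seed = 1, folds = NULL) {
  fm <- feature_matrix(table)
  if (is.null(folds)) {
    folds <- stratified_folds(fm$y, k, seed)
  } else {
    k <- max(folds)
  }
  per_fold <- matrix(NA_real_, k, 4,
                     dimnames = list(NULL, c("accuracy", "sensitivity",
                                             "specificity", "f_score")))
  for (f in seq_len(k)) {
    test <- folds == f
    model <- trainer(fm$x[!test, , drop = FALSE], fm$y[!test])
    pred <- predict(model, fm$x[test, , drop = FALSE])
    cm <- confusion_matrix(fm$y[test], pred, class_names = levels(fm$y))
    per_fold[f, ] <- classification_metrics(cm)
  }
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  structure(list(mean = colMeans(per_fold), sd = apply(per_fold, 2, pop_sd),
                 per_fold = per_fold, k = k, seed = seed, folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (mean %s sd over folds):\n",
              x$k, "±"))
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %.3f ± %.3f\n", m, x$mean[m], x$sd[m]))
  }
  invisible(x)
}

#' ELM trainer factory for cross-validation
#'
#' Wraps [elm()] with fixed hyperparameters into the `(x, y) -> model`
#' trainer form that [cross_validate()] expects.
#'
#' @inheritParams elm
#' @return A trainer function.
#' @export
elm_trainer <- function(n_hidden = 500, activation = "multiquadric",
                        weight_scale = 1, ridge = 0, shape = 1, seed = 1) {
  force(n_hidden); force(activation); force(weight_scale)
  force(ridge); force(shape); force(seed)
  function(x, y) {
    elm(x, y, n_hidden = n_hidden, activation = activation,
        weight_scale = weight_scale, ridge = ridge, shape = shape, seed = seed)
  }
}

#' Cross-validated accuracy per activation function
#'
#' Runs [cross_validate()] once per activation on a shared (frozen)
#' stratified fold split, so the comparison isolates the activation choice.
#'
#' @param table A `"feature_table"`.
#' @param activations Character vector of activations to compare; defaults
#'   to all ten in their conventional order.
#' @param n_hidden,weight_scale,ridge,shape,seed Passed to [elm()].
#' @param k Number of folds.
#' @return A data frame with columns `activation`, `accuracy_mean`,
#'   `accuracy_sd`, in the order of `activations`.
#' @export
activation_sweep <- function(table, activations = activation_kinds(),
                             n_hidden = 500, k = 10, seed = 1,
                             weight_scale = 1, ridge = 0, shape = 1) {
  fm <- feature_matrix(table)
  folds <- stratified_folds(fm$y, k, seed)
  rows <- lapply(activations, function(act) {
    rep <- cross_validate(table,
                          elm_trainer(n_hidden = n_hidden, activation = act,
                                      weight_scale = weight_scale,
                                      ridge = ridge, shape = shape,
                                      seed = seed),
                          folds = folds, seed = seed)
    data.frame(activation = act, accuracy_mean = unname(rep$mean["accuracy"]),
               accuracy_sd = unname(rep$sd["accuracy"]))
  })
  do.call(rbind, rows)
}

#' Validation curve over hidden-layer size
#'
#' For each hidden-unit count in `hidden_grid`, computes mean training and
#' held-out (cross-validated) accuracy on a frozen stratified fold split —
#' the standard capacity diagnostic: training accuracy rises with \eqn{H}
#' while validation accuracy flattens or dips once the model overfits.
#'
#' @param table A `"feature_table"`.
#' @param hidden_grid Ascending vector of hidden-unit counts.
#' @param activation,weight_scale,ridge,shape,seed Passed to [elm()].
#' @param k Number of folds.
#' @return A data frame with columns `n_hidden`, `train_accuracy`,
#'   `validation_accuracy`.
#' @export
validation_curve <- function(table, hidden_grid, activation = "multiquadric",
                             k = 5, seed = 1, weight_scale = 1, ridge = 0,
                             shape = 1) {
  stopifnot(all(diff(hidden_grid) > 0))
  fm <- feature_matrix(table)
  folds <- stratified_folds(fm$y, k, seed)
  rows <- lapply(hidden_grid, function(h) {
    tr_acc <- numeric(max(folds))
    va_acc <- numeric(max(folds))
    for (f in seq_len(max(folds))) {
      test <- folds == f
      model <- elm(fm$x[!test, , drop = FALSE], fm$y[!test], n_hidden = h,
                   activation = activation, weight_scale = weight_scale,
                   ridge = ridge, shape = shape, seed = seed)
      tr_acc[f] <- mean(predict(model, fm$x[!test, , drop = FALSE]) ==
                          fm$y[!test])
      va_acc[f] <- mean(predict(model, fm$x[test, , drop = FALSE]) ==
                          fm$y[test])
    }
    data.frame(n_hidden = h, train_accuracy = mean(tr_acc),
               validation_accuracy = mean(va_acc))
  })
  do.call(rbind, rows)
}
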