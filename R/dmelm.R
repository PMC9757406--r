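#' Apply an MFO parameter vector to the classifier
#'
#' The search-space encoding of the hybrid method. In `feature_scaling`
#' mode a position of length \eqn{d} multiplies the feature columns
#' (column \eqn{j} of `x` scaled by `position[j]`), so the optimizer learns
#' a per-feature weighting; the all-ones position is the identity and
#' recovers the plain ELM. In `input_weights` mode the position of length
#' \eqn{H'(d+1)} is reshaped into \eqn{H' \times d} hidden input weights
#' plus \eqn{H'} biases that replace the random initialization.
#'
#' @param position Numeric parameter vector.
#' @param x Feature matrix (`feature_scaling` mode) or `NULL`.
#' @param mode `"feature_scaling"` or `"input_weights"`.
#' @param n_features Feature count \eqn{d} (required for `input_weights`).
#' @return Scaled matrix (`feature_scaling`) or a list with `weights` and
#'   `biases` (`input_weights`).
#' @export
apply_parameters <- function(position, x = NULL,
                             mode = c("feature_scaling", "input_weights"),
                             n_features = if (!is.null(x)) ncol(x) else NULL) {
  mode <- match.arg(mode)
  if (mode == "feature_scaling") {
    if (length(position) != n_features) {
      stop_dmelm("position length %d does not match %d features",
                 length(position), n_features)
    }
    sweep(x, 2, position, `*`)
  } else {
    if (is.null(n_features)) stop_dmelm("n_features is required")
    if (length(position) %% (n_features + 1L) != 0L) {
      stop_dmelm("position length %d is not a multiple of d + 1 = %d",
                 length(position), n_features + 1L)
    }
    h <- length(position) %/% (n_features + 1L)
    list(weights = matrix(position[seq_len(h * n_features)], nrow = h),
         biases = position[h * n_features + seq_len(h)])
  }
}

# Train an ELM under a search position. feature_scaling scales the columns;
# input_weights injects the decoded hidden layer.
elm_under_position <- function(position, x, y, mode, n_hidden, activation,
                               weight_scale, ridge, shape, seed) {
  if (mode == "feature_scaling") {
    elm(apply_parameters(position, x, mode), y, n_hidden = n_hidden,
        activation = activation, weight_scale = weight_scale, ridge = ridge,
        shape = shape, seed = seed)
  } else {
    hp <- apply_parameters(position, mode = "input_weights",
                           n_features = ncol(x))
    model <- elm(x, y, n_hidden = nrow(hp$weights), activation = activation,
                 weight_scale = weight_scale, ridge = ridge, shape = shape,
                 seed = seed)
    if (model$hidden$family != "projection") {
      stop_dmelm("input_weights mode requires a projection-family activation")
    }
    model$hidden$weights <- hp$weights
    model$hidden$biases <- hp$biases
    m <- hidden_matrix(x, model$hidden, activation, shape)
    targets <- diag(length(model$class_names))[as.integer(factor(y, model$class_names)), , drop = FALSE]
    model$output_weights <- solve_output_weights(m, targets, ridge)
    model
  }
}

#' Cross-validation objective for the MFO search
#'
#' Builds the deterministic fitness function the optimizer minimizes: the
#' fold assignment and the ELM hidden-layer seeds are frozen once at
#' creation, and each call evaluates
#' \eqn{1 - } (mean stratified k-fold CV accuracy) of the ELM induced by
#' the position. Freezing makes the objective a pure function of the
#' position, and makes the all-ones position exactly the plain-ELM CV
#' objective on the same folds.
#'
#' @param table A `"feature_table"`.
#' @param mode Search encoding, see [apply_parameters()].
#' @param cv_folds Number of stratified folds (default 10).
#' @param n_hidden,activation,weight_scale,ridge,shape Passed to [elm()].
#' @param seed Seed freezing the folds and hidden layers.
#' @return Function `position -> 1 - mean CV accuracy`, with the frozen
#'   fold assignment attached as attribute `"folds"`.
#' @export
dmelm_objective <- function(table, mode = c("feature_scaling", "input_weights"),
                            cv_folds = 10, n_hidden = 500,
                            activation = "multiquadric", weight_scale = 1,
                            ridge = 0, shape = 1, seed = 1) {
  mode <- match.arg(mode)
  fm <- feature_matrix(table)
  folds <- stratified_folds(fm$y, cv_folds, seed)
  k <- max(folds)
  obj <- function(position) {
    acc <- numeric(k)
    for (f in seq_len(k)) {
      test <- folds == f
      model <- elm_under_position(position, fm$x[!test, , drop = FALSE],
                                  fm$y[!test], mode, n_hidden, activation,
                                  weight_scale, ridge, shape,
                                  seed = seed + f)
      xt <- fm$x[test, , drop = FALSE]
      if (mode == "feature_scaling") {
        xt <- apply_parameters(position, xt, mode)
      }
      acc[f] <- mean(predict(model, xt) == fm$y[test])
    }
    1 - mean(acc)
  }
  attr(obj, "folds") <- folds
  obj
}

#' Fit a moth-flame-optimized extreme learning machine (DM-ELM)
#'
#' The hybrid classifier: [mfo_optimize()] searches the parameter space of
#' the ELM ([apply_parameters()] defines the encoding), scoring each
#' candidate by the frozen-fold cross-validated objective of
#' [dmelm_objective()]; the best position then parameterizes a final ELM
#' refit on the full table. One moth of the initial population is seeded at
#' the identity (all-ones) position, so the plain ELM is always inside the
#' search and the optimized objective can never be worse than the plain
#' ELM's on the frozen folds.
#'
#' @param table A `"feature_table"` (wavelet features plus `label`), e.g.
#'   from [build_feature_table()].
#' @param mode Search encoding (default `"feature_scaling"`, whose
#'   dimension equals the feature count — 30 for the default level-4
#'   pipeline).
#' @param cv_folds Folds of the CV objective (default 10).
#' @param n_hidden,activation,weight_scale,ridge,shape Passed to [elm()].
#' @param n_agents,max_iterations,b MFO population, iteration budget and
#'   spiral constant. The defaults (10 agents, 20 iterations) are
#'   desk-scale; reference-scale runs use 50 agents and 1000 iterations.
#' @param lower,upper Search box (default \eqn{[-1, 1]} per dimension).
#' @param reduced_hidden Hidden size \eqn{H'} searched in `input_weights`
#'   mode (the full `n_hidden` would make the search space impractically
#'   large).
#' @param seed Master seed: folds, ELM layers and the MFO stream all derive
#'   from it.
#' @return An object of class `"dmelm"`: `best_parameters`, `model` (the
#'   final `"elm"` refit under them), `optimization` (the `"mfo_result"`),
#'   `objective_best` / `objective_identity` (frozen-fold objective at the
#'   optimum and at the identity), and the configuration.
#' @examples
#' \donttest{
#' ds <- synth_eeg_dataset(synth_spec(n_per_class = 20, seed = 1))
#' tab <- build_feature_table(ds)
#' fit <- dmelm(tab, n_hidden = 50, activation = "sine", cv_folds = 5,
#'              n_agents = 5, max_iterations = 5, seed = 1)
#' fit
#' }
#' @export
dmelm <- function(table, mode = c("feature_scaling", "input_weights"),
                  cv_folds = 10, n_hidden = 500, activation = "multiquadric",
                  weight_scale = 1, ridge = 0, shape = 1, n_agents = 10,
                  max_iterations = 20, b = 1, lower = -1, upper = 1,
                  reduced_hidden = 20, seed = 1) {
  mode <- match.arg(mode)
  fm <- feature_matrix(table)
  d <- ncol(fm$x)
  dimension <- if (mode == "feature_scaling") d else reduced_hidden * (d + 1L)

  objective <- dmelm_objective(table, mode = mode, cv_folds = cv_folds,
                               n_hidden = n_hidden, activation = activation,
                               weight_scale = weight_scale, ridge = ridge,
                               shape = shape, seed = seed)
  identity_pos <- if (mode == "feature_scaling") rep(1, dimension) else NULL
  init <- if (!is.null(identity_pos)) matrix(identity_pos, nrow = 1) else NULL

  opt <- mfo_optimize(objective, dimension = dimension, lower = lower,
                      upper = upper, n_agents = n_agents,
                      max_iterations = max_iterations, b = b, seed = seed,
                      init_positions = init)

  final <- elm_under_position(opt$best_position, fm$x, fm$y, mode, n_hidden,
                              activation, weight_scale, ridge, shape,
                              seed = seed)
  structure(list(best_parameters = opt$best_position, model = final,
                 optimization = opt, mode = mode, cv_folds = cv_folds,
                 objective_best = opt$best_fitness,
                 objective_identity = if (!is.null(identity_pos)) {
                   objective(identity_pos)
                 } else {
                   NA_real_
                 },
                 n_hidden = n_hidden, activation = activation,
                 weight_scale = weight_scale, ridge = ridge, shape = shape,
                 seed = seed, class_names = final$class_names,
                 folds = attr(objective, "folds")),
            class = "dmelm")
}

#' @export
print.dmelm <- function(x, ...) {
  cat(sprintf("DM-ELM (%s mode): %d hidden units, '%s' activation\n",
              x$mode, x$n_hidden, x$activation))
  cat(sprintf("  MFO: %d agents x %d iterations (%d evaluations)\n",
              x$optimization$n_agents, x$optimization$max_iterations,
              x$optimization$evaluations))
  cat(sprintf("  frozen-fold CV objective: %.4f (plain ELM identity: %s)\n",
              x$objective_best,
              if (is.na(x$objective_identity)) "n/a" else
                sprintf("%.4f", x$objective_identity)))
  invisible(x)
}

#' @export
summary.dmelm <- function(object, ...) {
  cat(sprintf("DM-ELM fit (%s mode, seed %d)\n", object$mode, object$seed))
  cat(sprintf("  classes: %s\n", paste(object$class_names, collapse = ", ")))
  cat(sprintf("  CV accuracy under optimum:  %.4f\n",
              1 - object$objective_best))
  if (!is.na(object$objective_identity)) {
    cat(sprintf("  CV accuracy under identity: %.4f\n",
                1 - object$objective_identity))
  }
  if (object$mode == "feature_scaling") {
    cat("  top feature weights (|value|):\n")
    w <- object$best_parameters
    ord <- order(abs(w), decreasing = TRUE)[seq_len(min(5, length(w)))]
    for (i in ord) cat(sprintf("    [%d] %+.3f\n", i, w[i]))
  }
  invisible(object)
}

#' Predict method for DM-ELM fits
#'
#' Applies the optimized parameters to the new data and delegates to the
#' final ELM.
#'
#' @param object A `"dmelm"` fit.
#' @param newdata Feature matrix or `"feature_table"`.
#' @param type `"class"` or `"scores"`, as in [predict.elm()].
#' @param ... Unused.
#' @export
predict.dmelm <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, setdiff(names(newdata), "label"),
                                 drop = FALSE])
  }
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (object$mode == "feature_scaling" && nrow(newdata) > 0) {
    newdata <- apply_parameters(object$best_parameters, newdata,
                                "feature_scaling")
  }
  predict(object$model, newdata, type = type)
}

#' DM-ELM trainer factory for cross-validation
#'
#' Wraps [dmelm()] into the trainer form [cross_validate()] expects, for
#' nested evaluation (the inner MFO objective uses its own folds on the
#' training portion only).
#'
#' @param ... Passed to [dmelm()].
#' @return A trainer function `(x, y) -> "dmelm"`.
#' @export
dmelm_trainer <- function(...) {
  args <- list(...)
  function(x, y) {
    tab <- as.data.frame(x)
    tab$label <- y
    class(tab) <- c("feature_table", "data.frame")
    do.call(dmelm, c(list(table = tab), args))
  }
}
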