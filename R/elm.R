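#' ELM activation functions
#'
#' The ten hidden-unit activation functions supported by [elm()]. Seven are
#' projection-type, applied to the affine pre-activation
#' \eqn{a = w_i \cdot x + \beta_i}:
#' `sine` (\eqn{\sin a}), `tanh`, `tribas` (\eqn{\max(0, 1-|a|)}),
#' `inv_tribas` (\eqn{1-\max(0, 1-|a|)}), `sigmoid` (\eqn{1/(1+e^{-a})}),
#' `hardlim` (1 if \eqn{a > 0} else 0) and `softlim` (\eqn{a} clamped to
#' \eqn{[0,1]}). Three are distance-type (radial-basis), applied to the
#' scaled sample-to-center distance \eqn{d = \|x - c_i\| / \sigma_i}:
#' `gaussian` (\eqn{e^{-d^2}}), `multiquadric` (\eqn{\sqrt{d^2+c^2}}) and
#' `inv_multiquadric` (\eqn{1/\sqrt{d^2+c^2}}) with shape constant `c`.
#'
#' @param kind Activation name.
#' @return `activation_kinds()` returns the ten names in their conventional
#'   order; `activation_family()` returns `"projection"` or `"distance"`;
#'   `activation_value()` applies the scalar activation elementwise.
#' @export
activation_kinds <- function() {
  c("sine", "tanh", "tribas", "inv_tribas", "sigmoid", "hardlim", "softlim",
    "gaussian", "multiquadric", "inv_multiquadric")
}

#' @rdname activation_kinds
#' @export
activation_family <- function(kind) {
  kind <- match.arg(kind, activation_kinds())
  if (kind %in% c("gaussian", "multiquadric", "inv_multiquadric")) {
    "distance"
  } else {
    "projection"
  }
}

#' @rdname activation_kinds
#' @param a Numeric vector: affine pre-activations (projection family) or
#'   nonnegative scaled distances (distance family).
#' @param shape Shape constant \eqn{c > 0} of the multiquadric pair.
#' @export
activation_value <- function(kind, a, shape = 1) {
  kind <- match.arg(kind, activation_kinds())
  switch(kind,
    sine = sin(a),
    tanh = tanh(a),
    tribas = pmax(0, 1 - abs(a)),
    inv_tribas = 1 - pmax(0, 1 - abs(a)),
    sigmoid = 1 / (1 + exp(-a)),
    hardlim = as.numeric(a > 0),
    softlim = pmin(pmax(a, 0), 1),
    gaussian = exp(-a^2),
    multiquadric = sqrt(a^2 + shape^2),
    inv_multiquadric = 1 / sqrt(a^2 + shape^2))
}

# Random hidden-layer parameters. Projection family: uniform weights and
# biases in [-weight_scale, weight_scale]. Distance family: centers uniform
# within the per-feature data ranges; one common width, the median pairwise
# training-sample distance (subsampled), fallback 1 when degenerate.
init_hidden <- function(n_hidden, n_features, activation, weight_scale,
                        shape, x = NULL) {
  fam <- activation_family(activation)
  if (fam == "projection") {
    w <- matrix(stats::runif(n_hidden * n_features, -weight_scale, weight_scale),
                nrow = n_hidden)
    b <- stats::runif(n_hidden, -weight_scale, weight_scale)
    list(family = fam, weights = w, biases = b)
  } else {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    centers <- matrix(stats::runif(n_hidden * n_features), nrow = n_hidden)
    centers <- sweep(sweep(centers, 2, hi - lo, `*`), 2, lo, `+`)
    sub <- x[sample.int(nrow(x), min(nrow(x), 200L)), , drop = FALSE]
    med <- stats::median(stats::dist(sub))
    if (!is.finite(med) || med <= 0) med <- 1
    list(family = fam, centers = centers, widths = rep(med, n_hidden),
         shape = shape)
  }
}

# N x H hidden-layer output matrix for data x under hidden parameters hp.
hidden_matrix <- function(x, hp, activation, shape = 1) {
  if (hp$family == "projection") {
    if (ncol(x) != ncol(hp$weights)) {
      stop_dmelm("feature count %d does not match model dimension %d",
                 ncol(x), ncol(hp$weights))
    }
    pre <- tcrossprod(x, hp$weights)   # N x H of w_i . x_j
    pre <- sweep(pre, 2, hp$biases, `+`)
    # activation_value may drop dim attributes (e.g. hardlim); restore
    matrix(activation_value(activation, pre, shape), nrow(pre), ncol(pre))
  } else {
    if (ncol(x) != ncol(hp$centers)) {
      stop_dmelm("feature count %d does not match model dimension %d",
                 ncol(x), ncol(hp$centers))
    }
    # squared distances via the expansion |x|^2 - 2 x.c + |c|^2
    d2 <- outer(rowSums(x^2), rowSums(hp$centers^2), `+`) -
      2 * tcrossprod(x, hp$centers)
    d2[d2 < 0] <- 0
    d <- sweep(sqrt(d2), 2, hp$widths, `/`)
    matrix(activation_value(activation, d, hp$shape %||% shape),
           nrow(d), ncol(d))
  }
}

# Minimum-norm least-squares solve via SVD (rank-revealing), or ridge.
solve_output_weights <- function(m, y, ridge = 0) {
  if (ridge > 0) {
    h <- crossprod(m) + diag(ridge, ncol(m))
    return(solve(h, crossprod(m, y)))
  }
  sv <- svd(m)
  tol <- max(dim(m)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(matrix(0, ncol(m), ncol(y)))
  dinv <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (dinv * crossprod(sv$u, y))
}

#' Fit an extreme learning machine classifier
#'
#' A single-hidden-layer feedforward network whose hidden-layer parameters
#' are drawn at random and whose output weights are solved in closed form.
#' The network output for a sample \eqn{x} is
#' \deqn{f_H(x) = \sum_{i=1}^{H} v_i\, h(w_i \cdot x + \beta_i),}
#' with \eqn{H} hidden units, activation \eqn{h}, random input weights
#' \eqn{w_i} and biases \eqn{\beta_i}, and output weights \eqn{v} obtained
#' as the minimum-norm least-squares solution of \eqn{M v = Y} (one-hot 0/1
#' class targets \eqn{Y}, hidden-output matrix \eqn{M}), or the ridge
#' solution \eqn{(M^\top M + \lambda I)^{-1} M^\top Y} when `ridge > 0`.
#' For distance-type activations the hidden units are radial: random
#' centers within the data ranges, pre-activation
#' \eqn{\|x - c_i\|/\sigma_i}.
#'
#' @param x Numeric feature matrix (samples in rows), or a
#'   `"feature_table"` data frame with a `label` column (then `y` is taken
#'   from it).
#' @param y Class labels (factor or character), one per row of `x`.
#' @param n_hidden Number of hidden units \eqn{H} (default 500).
#' @param activation One of [activation_kinds()]; default `"multiquadric"`.
#' @param weight_scale Half-width of the uniform law for random input
#'   weights and biases (projection family).
#' @param ridge Ridge penalty \eqn{\lambda \ge 0}; 0 gives the
#'   pseudoinverse (minimum-norm) solution.
#' @param shape Shape constant of the multiquadric activations.
#' @param seed Integer seed for the random hidden layer.
#' @return An object of class `"elm"` with components including
#'   `output_weights` (\eqn{H \times C}), `hidden` (the random layer),
#'   `class_names` and the call parameters.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' y <- rep(c("a", "b"), each = 20)
#' fit <- elm(x, y, n_hidden = 30, activation = "sine", seed = 1)
#' mean(predict(fit, x) == y)
#' @seealso [predict.elm()], [dmelm()] for the optimized variant.
#' @export
elm <- function(x, y = NULL, n_hidden = 500, activation = "multiquadric",
                weight_scale = 1, ridge = 0, shape = 1, seed = 1) {
  if (inherits(x, "feature_table") || (is.data.frame(x) && "label" %in% names(x))) {
    fm <- feature_matrix(x)
    x <- fm$x
    y <- fm$y
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(y)) stop_dmelm("class labels 'y' are required")
  if (any(!is.finite(x))) stop_dmelm("features contain non-finite values")
  if (nrow(x) < 2L) stop_dmelm("need at least 2 training samples")
  y <- factor(y)
  # drop unused levels but keep a stable sorted class order
  y <- factor(as.character(y), levels = sort(unique(as.character(y))))
  if (nlevels(y) < 2L) stop_dmelm("need at least 2 distinct classes")
  activation <- match.arg(activation, activation_kinds())
  n_hidden <- as.integer(n_hidden)
  stopifnot(n_hidden >= 1, ridge >= 0, weight_scale >= 0)

  hp <- with_seed(seed, init_hidden(n_hidden, ncol(x), activation,
                                    weight_scale, shape, x))
  m <- hidden_matrix(x, hp, activation, shape)
  targets <- diag(nlevels(y))[as.integer(y), , drop = FALSE]
  v <- solve_output_weights(m, targets, ridge)

  structure(list(output_weights = v, hidden = hp, activation = activation,
                 shape = shape, n_hidden = n_hidden, ridge = ridge,
                 weight_scale = weight_scale, seed = seed,
                 class_names = levels(y), n_features = ncol(x),
                 n_train = nrow(x)),
            class = "elm")
}

#' Predict method for ELM models
#'
#' @param object An `"elm"` fit.
#' @param newdata Feature matrix or `"feature_table"` (its label column, if
#'   present, is ignored).
#' @param type `"class"` for labels (argmax of the network output, ties
#'   going to the first class in sorted order) or `"scores"` for the raw
#'   \eqn{N \times C} output matrix.
#' @param ... Unused.
#' @return Factor of predicted labels, or a numeric score matrix.
#' @export
predict.elm <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, setdiff(names(newdata), "label"),
                                 drop = FALSE])
  }
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (nrow(newdata) == 0L) {
    if (type == "scores") {
      return(matrix(0, 0, length(object$class_names),
                    dimnames = list(NULL, object$class_names)))
    }
    return(factor(character(0), levels = object$class_names))
  }
  m <- hidden_matrix(newdata, object$hidden, object$activation, object$shape)
  scores <- m %*% object$output_weights
  colnames(scores) <- object$class_names
  if (type == "scores") return(scores)
  idx <- max.col(scores, ties.method = "first")
  factor(object$class_names[idx], levels = object$class_names)
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("Extreme learning machine: %d hidden units, '%s' activation\n",
              x$n_hidden, x$activation))
  cat(sprintf("  classes: %s\n", paste(x$class_names, collapse = ", ")))
  cat(sprintf("  trained on %d samples x %d features (ridge %.3g, seed %d)\n",
              x$n_train, x$n_features, x$ridge, x$seed))
  invisible(x)
}

#' @export
coef.elm <- function(object, ...) object$output_weights

#' Save and load ELM models
#'
#' Models are stored as a self-describing JSON archive (arrays plus
#' metadata), not a serialized R object, so saved models are portable and
#' inspectable.
#'
#' @param model An `"elm"` fit.
#' @param path File path (conventionally `.json`).
#' @return `write_elm` returns `path` invisibly; `read_elm` returns the
#'   restored `"elm"` object.
#' @export
write_elm <- function(model, path) {
  stopifnot(inherits(model, "elm"))
  hp <- model$hidden
  payload <- list(
    format = "dmelm-elm", version = 1L,
    activation = model$activation, family = hp$family,
    n_hidden = model$n_hidden, n_features = model$n_features,
    shape = model$shape, ridge = model$ridge,
    weight_scale = model$weight_scale, seed = model$seed,
    n_train = model$n_train, class_names = model$class_names,
    output_weights = model$output_weights)
  if (hp$family == "projection") {
    payload$weights <- hp$weights
    payload$biases <- hp$biases
  } else {
    payload$centers <- hp$centers
    payload$widths <- hp$widths
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "dmelm-elm")) {
    stop_dmelm("'%s' is not a dmelm ELM archive", path)
  }
  as_mat <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  }
  hp <- if (identical(p$family, "projection")) {
    list(family = "projection", weights = as_mat(p$weights),
         biases = as.numeric(p$biases))
  } else {
    list(family = "distance", centers = as_mat(p$centers),
         widths = as.numeric(p$widths), shape = p$shape)
  }
  structure(list(output_weights = as_mat(p$output_weights), hidden = hp,
                 activation = p$activation, shape = p$shape,
                 n_hidden = as.integer(p$n_hidden), ridge = p$ridge,
                 weight_scale = p$weight_scale, seed = as.integer(p$seed),
                 class_names = as.character(p$class_names),
                 n_features = as.integer(p$n_features),
                 n_train = as.integer(p$n_train)),
            class = "elm")
}
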