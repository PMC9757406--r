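test_that("activation values match their definitions at hand-picked points", {
  expect_equal(activation_value("tribas", c(0, 0.5, 2, -2)), c(1, 0.5, 0, 0))
  expect_equal(activation_value("inv_tribas", c(0, 2)), c(0, 1))
  expect_equal(activation_value("sigmoid", 0), 0.5)
  expect_equal(activation_value("hardlim", c(-1, 0, 1e-9)), c(0, 0, 1))
  expect_equal(activation_value("softlim", c(-0.5, 0.3, 2)), c(0, 0.3, 1))
  expect_equal(activation_value("sine", pi / 2), 1)
  expect_equal(activation_value("gaussian", c(0, 1)), c(1, exp(-1)))
  expect_equal(activation_value("multiquadric", 0, shape = 1), 1)
  expect_equal(activation_value("inv_multiquadric", 0, shape = 1), 1)
  expect_equal(activation_value("multiquadric", 3, shape = 4), 5)

  expect_equal(activation_family("sine"), "projection")
  expect_equal(activation_family("gaussian"), "distance")
  expect_setequal(activation_kinds()[8:10],
                  c("gaussian", "multiquadric", "inv_multiquadric"))
})

test_that("hidden matrix matches the element-by-element scalar oracle", {
  set.seed(2)
  x <- matrix(rnorm(15), 5, 3)
  for (act in c("sine", "sigmoid", "tribas", "multiquadric", "gaussian")) {
    fit <- elm(rbind(x, x + 2), rep(c("p", "q"), each = 5), n_hidden = 4,
               activation = act, seed = 9)
    m <- dmelm:::hidden_matrix(x, fit$hidden, act, fit$shape)
    expect_lt(max(abs(m - oracle_hidden_matrix(x, fit$hidden, act))), 1e-12)
  }
})

test_that("degenerate hidden layers behave as the definitions dictate", {
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(c("a", "b"), 5)
  fit <- elm(x, y, n_hidden = 6, activation = "sigmoid", weight_scale = 0,
             seed = 1)
  m <- dmelm:::hidden_matrix(x, fit$hidden, "sigmoid", 1)
  expect_true(all(m == 0.5))
  # same seed twice -> identical hidden parameters
  fit2 <- elm(x, y, n_hidden = 6, activation = "sigmoid", weight_scale = 0,
              seed = 1)
  expect_identical(fit$hidden, fit2$hidden)
})

test_that("distance-family centers stay inside the training data box", {
  set.seed(4)
  for (s in 1:20) {
    x <- matrix(runif(60, -3, 5), 20, 3)
    fit <- elm(x, rep(c("a", "b"), 10), n_hidden = 25,
               activation = "gaussian", seed = s)
    ctr <- fit$hidden$centers
    for (j in 1:3) {
      expect_true(all(ctr[, j] >= min(x[, j]) & ctr[, j] <= max(x[, j])))
    }
    expect_true(all(fit$hidden$widths > 0))
  }
})

test_that("fitted output weights satisfy the least-squares normal equations", {
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    h <- sample(3:20, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    y <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("a", "b")
    fit <- elm(x, y, n_hidden = h, activation = "tanh", seed = rep)
    m <- dmelm:::hidden_matrix(x, fit$hidden, "tanh", 1)
    yy <- factor(y, sort(unique(y)))
    targets <- diag(nlevels(yy))[as.integer(yy), , drop = FALSE]
    resid <- crossprod(m, m %*% fit$output_weights - targets)
    expect_lt(max(abs(resid)), 1e-6)
    # independent normal-equations oracle (full column rank a.s. for h < n)
    if (h < n) {
      v_ref <- solve(crossprod(m), crossprod(m, targets))
      expect_lt(max(abs(fit$output_weights - v_ref)), 1e-6)
    }
  }
})

test_that("ridge solutions converge to the minimum-norm solution", {
  set.seed(5)
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(c("a", "b"), 10)
  base <- elm(x, y, n_hidden = 8, ridge = 0, activation = "sine", seed = 2)
  err <- vapply(c(1e-2, 1e-4, 1e-6), function(lam) {
    fit <- elm(x, y, n_hidden = 8, ridge = lam, activation = "sine", seed = 2)
    max(abs(fit$output_weights - base$output_weights))
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-4)
})

test_that("interpolating regimes reach perfect training accuracy", {
  set.seed(8)
  x <- matrix(rnorm(30), 10, 3)
  y <- sample(c("a", "b"), 10, replace = TRUE)
  y[1:2] <- c("a", "b")
  for (act in c("sine", "tanh", "sigmoid", "gaussian", "multiquadric",
                "inv_multiquadric")) {
    fit <- elm(x, y, n_hidden = 40, activation = act, seed = 3)
    expect_equal(mean(predict(fit, x) == y), 1,
                 info = paste("activation", act))
  }
})

test_that("separable blobs are classified perfectly across seeds", {
  for (s in 0:4) {
    blobs <- make_blobs(n = 200, separation = 6, seed = s)
    for (act in c("sine", "sigmoid", "multiquadric")) {
      fit <- elm(blobs$x, blobs$y, n_hidden = 50, activation = act, seed = s)
      expect_equal(mean(predict(fit, blobs$x) == blobs$y), 1)
    }
  }
})

test_that("prediction follows the scores with first-class tie-breaking", {
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c("a", "b"), 10)
  fit <- elm(x, y, n_hidden = 10, activation = "sine", seed = 1)
  sc <- predict(fit, x, type = "scores")
  expect_equal(dim(sc), c(20L, 2L))
  expect_equal(colnames(sc), c("a", "b"))
  lab <- predict(fit, x)
  expect_equal(as.character(lab),
               c("a", "b")[max.col(sc, ties.method = "first")])
  # duplicated sample scores identically
  sc2 <- predict(fit, x[c(1, 1), , drop = FALSE], type = "scores")
  expect_equal(sc2[1, ], sc2[2, ])
  # forced tie: zero output weights score both classes equally -> first class
  fit0 <- fit
  fit0$output_weights[] <- 0
  expect_equal(as.character(predict(fit0, x[1:3, ])), rep("a", 3))
  # empty input
  expect_length(predict(fit, x[0, , drop = FALSE]), 0)
})

test_that("fit rejects invalid inputs", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(elm(x, rep("a", 10)), "2 distinct classes")
  x[1, 1] <- NA
  expect_error(elm(x, rep(c("a", "b"), 5)), "non-finite")
  expect_error(elm(matrix(1, 1, 2), "a"), "2 training samples")
  fit <- elm(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5), n_hidden = 5,
             seed = 1)
  expect_error(predict(fit, matrix(1, 2, 5)), "does not match")
})

test_that("models survive the JSON archive round-trip", {
  set.seed(12)
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(c("a", "b"), 10)
  for (act in c("sine", "multiquadric")) {
    fit <- elm(x, y, n_hidden = 7, activation = act, seed = 4)
    f <- withr::local_tempfile(fileext = ".json")
    write_elm(fit, f)
    back <- read_elm(f)
    expect_equal(back$class_names, fit$class_names)
    expect_equal(predict(back, x, type = "scores"),
                 predict(fit, x, type = "scores"), tolerance = 1e-12)
    expect_identical(as.character(predict(back, x)),
                     as.character(predict(fit, x)))
  }
})
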