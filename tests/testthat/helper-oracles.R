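# Independent brute-force oracles used to cross-check the implementation.

# One analysis step as an explicit circulant-downsampled matrix applied to
# the signal: row k of the low/high-pass operator holds the filter placed at
# circular offset 2(k-1).
oracle_dwt_step <- function(x, lo, hi) {
  n <- length(x)
  half <- n %/% 2L
  A <- matrix(0, half, n)
  D <- matrix(0, half, n)
  for (k in seq_len(half)) {
    for (m in seq_along(lo)) {
      col <- ((2L * (k - 1L) + m - 1L) %% n) + 1L
      A[k, col] <- A[k, col] + lo[m]
      D[k, col] <- D[k, col] + hi[m]
    }
  }
  list(a = as.numeric(A %*% x), d = as.numeric(D %*% x))
}

# Full decomposition via the matrix oracle.
oracle_dwt <- function(x, level) {
  f <- db2_filters()
  details <- list()
  a <- x
  for (l in seq_len(level)) {
    s <- oracle_dwt_step(a, f$lo_d, f$hi_d)
    details[[l]] <- s$d
    a <- s$a
  }
  list(details = details, approximation = a)
}

# Per-class one-vs-rest metric tally with explicit loops over the labels.
oracle_metrics <- function(cm) {
  cm <- unclass(cm)
  C <- nrow(cm)
  total <- sum(cm)
  sens <- spec <- fsc <- numeric(C)
  for (i in seq_len(C)) {
    tp <- cm[i, i]
    fn <- 0
    fp <- 0
    for (j in seq_len(C)) {
      if (j != i) {
        fn <- fn + cm[i, j]
        fp <- fp + cm[j, i]
      }
    }
    tn <- total - tp - fn - fp
    sens[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec[i] <- if (tn + fp > 0) tn / (tn + fp) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    fsc[i] <- if (prec + sens[i] > 0) 2 * prec * sens[i] / (prec + sens[i]) else 0
  }
  c(accuracy = sum(diag(cm)) / total, sensitivity = mean(sens),
    specificity = mean(spec), f_score = mean(fsc))
}

# Element-by-element scalar evaluation of the hidden-layer matrix.
oracle_hidden_matrix <- function(x, hp, activation, shape = 1) {
  n <- nrow(x)
  H <- if (hp$family == "projection") nrow(hp$weights) else nrow(hp$centers)
  out <- matrix(0, n, H)
  for (j in seq_len(n)) {
    for (i in seq_len(H)) {
      a <- if (hp$family == "projection") {
        sum(hp$weights[i, ] * x[j, ]) + hp$biases[i]
      } else {
        sqrt(sum((x[j, ] - hp$centers[i, ])^2)) / hp$widths[i]
      }
      out[j, i] <- activation_value(activation, a,
                                    if (hp$family == "distance") hp$shape else shape)
    }
  }
  out
}

# Two well-separated Gaussian blobs in 2-D (unit sd, mean separation in sd).
make_blobs <- function(n = 200, separation = 6, seed = 0) {
  set.seed(seed)
  half <- n %/% 2L
  x <- rbind(matrix(rnorm(half * 2), half),
             matrix(rnorm((n - half) * 2, mean = separation), n - half))
  list(x = x, y = rep(c("a", "b"), c(half, n - half)))
}

# Shared synthetic feature table (300 segments, defaults), built once.
synth_table_cache <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      ds <- synth_eeg_dataset(synth_spec(n_per_class = 100, seed = 1))
      tab <<- build_feature_table(ds)
    }
    tab
  }
})
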