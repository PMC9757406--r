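#' Daubechies-2 analysis and synthesis filters
#'
#' Returns the four-tap db2 filter bank. The analysis low-pass filter is
#' \eqn{g = (1+\sqrt3,\; 3+\sqrt3,\; 3-\sqrt3,\; 1-\sqrt3)/(4\sqrt2)}; the
#' analysis high-pass is its quadrature mirror \eqn{h_k = (-1)^k g_{L-1-k}};
#' the synthesis filters are the time-reversed analysis filters. The filters
#' are orthonormal: \eqn{\sum g = \sqrt2}, \eqn{\sum g^2 = 1},
#' \eqn{\sum h = 0}.
#'
#' @return A list with components `lo_d`, `hi_d` (analysis low/high-pass) and
#'   `lo_r`, `hi_r` (synthesis low/high-pass), each a numeric vector of
#'   length 4.
#' @examples
#' f <- db2_filters()
#' sum(f$lo_d)    # sqrt(2)
#' sum(f$hi_d)    # 0
#' @export
db2_filters <- function() {
  s3 <- sqrt(3)
  lo <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  L <- length(lo)
  hi <- (-1)^(seq_len(L) - 1) * rev(lo)
  list(lo_d = lo, hi_d = hi, lo_r = rev(lo), hi_r = rev(hi))
}

#' Wavelet decomposition settings
#'
#' Bundle of the wavelet, decomposition depth and boundary handling used by
#' [dwt_decompose()] and [extract_features()].
#'
#' @param wavelet Wavelet name; only the Daubechies-2 wavelet (`"db2"`) is
#'   supported.
#' @param level Decomposition depth \eqn{L \ge 1}. Default 4.
#' @param mode Signal extension mode: `"periodization"` (circular; the
#'   transform is orthonormal and energy-preserving when the signal length is
#'   divisible by \eqn{2^L}) or `"symmetric"` (half-point reflection at the
#'   boundaries, as common wavelet toolchains use).
#' @return An object of class `"wavelet_spec"`.
#' @export
wavelet_spec <- function(wavelet = "db2", level = 4,
                         mode = c("periodization", "symmetric")) {
  if (!identical(wavelet, "db2")) {
    stop_dmelm("unsupported wavelet '%s' (only 'db2' is available)", wavelet)
  }
  mode <- match.arg(mode)
  level <- as.integer(level)
  if (level < 1) stop_dmelm("decomposition level must be >= 1")
  structure(list(wavelet = wavelet, level = level, mode = mode),
            class = "wavelet_spec")
}

# One periodized analysis step: circular convolve with each filter and keep
# every second output. For even n this is an orthogonal map R^n -> R^n.
dwt_step_per <- function(x, lo, hi) {
  n <- length(x)
  half <- n %/% 2L
  L <- length(lo)
  a <- numeric(half)
  d <- numeric(half)
  # coefficient k (1-based): sum_m filter[m] * x[(2(k-1) + m - 1) mod n + 1]
  for (m in seq_len(L)) {
    idx <- ((2L * (seq_len(half) - 1L) + m - 1L) %% n) + 1L
    a <- a + lo[m] * x[idx]
    d <- d + hi[m] * x[idx]
  }
  list(a = a, d = d)
}

# One symmetric-extension analysis step (half-point reflection), full
# convolution downsampled; output length floor((n + L - 1) / 2).
dwt_step_sym <- function(x, lo, hi) {
  n <- length(x)
  L <- length(lo)
  pad <- L - 1L
  left <- x[pmin(pad:1, n)]
  right <- x[pmax(n - (1:pad) + 1L, 1L)]
  xe <- c(left, x, right)
  out_len <- (n + L - 1L) %/% 2L
  # full convolution y[k] = sum_m h[m] * xe[k + L - m], even k kept
  conv_ds <- function(h) {
    y <- numeric(out_len)
    for (m in seq_len(L)) {
      # even output positions of the full convolution: k = 2, 4, ...
      idx <- 2L * seq_len(out_len) + L - m
      y <- y + h[m] * xe[idx]
    }
    y
  }
  list(a = conv_ds(lo), d = conv_ds(hi))
}

#' Level-L discrete wavelet decomposition of a segment
#'
#' Cascade of convolve-and-downsample-by-two analysis steps with the db2
#' filter bank. The detail coefficients of every level and the approximation
#' of the last level are returned, finest detail first.
#'
#' @param x An [eeg_segment] or a numeric vector of samples.
#' @param spec A [wavelet_spec()].
#' @return An object of class `"dwt_decomposition"`: a list with `details`
#'   (list of numeric vectors `D1` ... `DL`, finest to coarsest),
#'   `approximation` (`AL`), `level`, `mode`, and `n` (input length).
#' @details With periodization and an input length divisible by
#'   \eqn{2^L}, the transform is orthonormal: the coefficient count equals
#'   the signal length and total coefficient energy equals signal energy.
#' @seealso [dwt_reconstruct()] for the inverse, [band_statistics()] and
#'   [extract_features()] for the feature pipeline built on top.
#' @export
dwt_decompose <- function(x, spec = wavelet_spec()) {
  if (inherits(x, "eeg_segment")) x <- x$samples
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop_dmelm("signal contains non-finite samples")
  L <- spec$level
  min_len <- 2^L
  if (length(x) < min_len) {
    stop_dmelm("signal too short: length %d < 2^%d = %d samples required",
               length(x), L, min_len)
  }
  f <- db2_filters()
  details <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    step <- if (spec$mode == "periodization") {
      if (length(a) %% 2L == 1L) a <- c(a, a[length(a)])
      dwt_step_per(a, f$lo_d, f$hi_d)
    } else {
      dwt_step_sym(a, f$lo_d, f$hi_d)
    }
    details[[l]] <- step$d
    a <- step$a
  }
  names(details) <- paste0("D", seq_len(L))
  structure(list(details = details, approximation = a, level = L,
                 mode = spec$mode, n = length(x)),
            class = "dwt_decomposition")
}

#' @export
print.dwt_decomposition <- function(x, ...) {
  lens <- c(vapply(x$details, length, integer(1)), A = length(x$approximation))
  cat(sprintf("Level-%d db2 decomposition (%s mode) of %d samples\n",
              x$level, x$mode, x$n))
  cat("  coefficient lengths: ",
      paste(sprintf("%s:%d", c(names(x$details), paste0("A", x$level)), lens),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

# One periodized synthesis step: the exact inverse (transpose) of
# dwt_step_per for even-length outputs.
idwt_step_per <- function(a, d, lo, hi, n_out) {
  L <- length(lo)
  x <- numeric(n_out)
  half <- length(a)
  for (m in seq_len(L)) {
    idx <- ((2L * (seq_len(half) - 1L) + m - 1L) %% n_out) + 1L
    contrib <- lo[m] * a + hi[m] * d
    # accumulate with possible repeated indices (n_out < 2*half never occurs)
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Inverse discrete wavelet transform
#'
#' Reconstructs a signal from a [dwt_decompose()] result. Only the
#' periodization mode admits an exact inverse here; for signal lengths
#' divisible by \eqn{2^L} the round trip `dwt_reconstruct(dwt_decompose(x))`
#' reproduces `x` to floating-point accuracy.
#'
#' @param decomposition A `"dwt_decomposition"` object (periodization mode).
#' @param length Output signal length; defaults to the recorded input length.
#' @return Numeric vector of reconstructed samples.
#' @export
dwt_reconstruct <- function(decomposition, length = decomposition$n) {
  if (!inherits(decomposition, "dwt_decomposition")) {
    stop_dmelm("expected a 'dwt_decomposition' object")
  }
  if (decomposition$mode != "periodization") {
    stop_dmelm("reconstruction is only supported for periodization mode")
  }
  f <- db2_filters()
  L <- decomposition$level
  a <- decomposition$approximation
  for (l in rev(seq_len(L))) {
    d <- decomposition$details[[l]]
    if (length(d) != length(a)) {
      stop_dmelm("inconsistent coefficient lengths at level %d (A:%d, D:%d)",
                 l, length(a), length(d))
    }
    a <- idwt_step_per(a, d, f$lo_d, f$hi_d, 2L * length(a))
  }
  if (length > length(a)) {
    stop_dmelm("requested length %d exceeds reconstructed length %d",
               length, base::length(a))
  }
  a[seq_len(length)]
}

#' Per-sub-band statistical features
#'
#' The six statistics computed on each wavelet sub-band: mean absolute
#' value, average power (mean of squares), population standard deviation,
#' population skewness, population excess kurtosis, and the Shannon entropy
#' (in nats) of the normalized squared coefficients
#' \eqn{p_k = c_k^2 / \sum c^2}. Skewness and kurtosis are defined as 0 for
#' zero-variance bands, and the entropy as 0 for an all-zero band.
#'
#' @param coeffs Numeric vector of sub-band coefficients (length >= 1).
#' @return Named numeric vector of length 6:
#'   `mav`, `power`, `sd`, `skewness`, `kurtosis`, `entropy`.
#' @examples
#' band_statistics(c(1, -1, 1, -1))  # mav 1, power 1, sd 1, kurt -2, ent ln 4
#' @export
band_statistics <- function(coeffs) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) == 0L) stop_dmelm("empty coefficient sequence")
  n <- length(coeffs)
  mu <- mean(coeffs)
  m2 <- mean((coeffs - mu)^2)
  s <- sqrt(m2)
  if (s > 0) {
    skew <- mean((coeffs - mu)^3) / s^3
    kurt <- mean((coeffs - mu)^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  e2 <- sum(coeffs^2)
  if (e2 > 0) {
    p <- coeffs^2 / e2
    p <- p[p > 0]
    ent <- -sum(p * log(p))
  } else {
    ent <- 0
  }
  c(mav = mean(abs(coeffs)), power = mean(coeffs^2), sd = s,
    skewness = skew, kurtosis = kurt, entropy = ent)
}

band_stat_names <- function(level) {
  bands <- c(paste0("D", seq_len(level)), paste0("A", level))
  stats <- c("mav", "power", "sd", "skewness", "kurtosis", "entropy")
  as.vector(t(outer(bands, stats, paste, sep = ":")))
}

#' Wavelet feature vector of one EEG segment
#'
#' Decomposes the segment with [dwt_decompose()] and concatenates the
#' [band_statistics()] of the sub-bands in the fixed order
#' D1, D2, ..., DL, AL. For the default level-4 decomposition and six
#' statistics this is a 30-dimensional vector.
#'
#' @param x An [eeg_segment] or numeric vector.
#' @param spec A [wavelet_spec()].
#' @return Named numeric vector (`"D1:mav"`, ..., `"A4:entropy"`).
#' @export
extract_features <- function(x, spec = wavelet_spec()) {
  dec <- dwt_decompose(x, spec)
  bands <- c(dec$details, list(dec$approximation))
  v <- unlist(lapply(bands, band_statistics), use.names = FALSE)
  names(v) <- band_stat_names(dec$level)
  v
}

#' Build the sample-by-feature table of a dataset
#'
#' Applies [extract_features()] to every segment of an [eeg_dataset] and
#' stacks the rows, preserving dataset order; the class label is kept as the
#' last column.
#'
#' @param dataset An [eeg_dataset].
#' @param spec A [wavelet_spec()].
#' @return A `data.frame` of class `"feature_table"` with one numeric column
#'   per feature and a final factor column `label` (levels in the dataset's
#'   class order).
#' @export
build_feature_table <- function(dataset, spec = wavelet_spec()) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  rows <- lapply(dataset$segments, extract_features, spec = spec)
  mat <- do.call(rbind, rows)
  df <- as.data.frame(mat)
  names(df) <- colnames(mat)
  df$label <- factor(vapply(dataset$segments, `[[`, "", "label"),
                     levels = dataset$class_names)
  rownames(df) <- vapply(dataset$segments, `[[`, "", "segment_id")
  class(df) <- c("feature_table", "data.frame")
  df
}

# Split a feature table into the numeric matrix X and the label factor y.
feature_matrix <- function(table) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  y <- table[["label"]]
  if (!is.factor(y)) y <- factor(y)
  x <- as.matrix(table[, setdiff(names(table), "label"), drop = FALSE])
  storage.mode(x) <- "double"
  list(x = x, y = y)
}
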