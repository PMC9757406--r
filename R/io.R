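#' Construct an EEG segment
#'
#' A single-channel EEG recording segment: an ordered amplitude vector with
#' its sampling rate, an identifier and an optional class label.
#'
#' @param samples Numeric vector of amplitudes (conventionally microvolts).
#' @param sampling_rate Sampling rate in Hz. The default 173.61 Hz is the
#'   documented rate of the public Bonn epileptology distribution; it is
#'   metadata only — no computation in this package depends on it.
#' @param segment_id Identifier string.
#' @param label Class label, or `NA` until the segment is assembled into a
#'   dataset.
#' @return An object of class `"eeg_segment"`.
#' @export
eeg_segment <- function(samples, sampling_rate = 173.61,
                        segment_id = "segment", label = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop_dmelm("segment needs at least 2 samples")
  if (any(!is.finite(samples))) stop_dmelm("segment contains non-finite samples")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop_dmelm("sampling_rate must be positive")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 segment_id = as.character(segment_id),
                 label = as.character(label)),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("EEG segment '%s': %d samples @ %.2f Hz (%.1f s), label %s\n",
              x$segment_id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate,
              if (is.na(x$label)) "<unset>" else x$label))
  invisible(x)
}

#' Read one Bonn-style ASCII segment file
#'
#' Bonn-style files hold one amplitude sample per line in plain ASCII.
#'
#' @param path Path to the file.
#' @param sampling_rate Sampling rate to record on the segment (Hz).
#' @return An [eeg_segment] with `segment_id` derived from the file name and
#'   no label.
#' @export
read_eeg_segment <- function(path, sampling_rate = 173.61) {
  if (!file.exists(path)) stop_dmelm("cannot read EEG file '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  vals <- suppressWarnings(as.numeric(lines[keep]))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1]]
    stop_dmelm("non-numeric value at line %d of '%s'", bad, path)
  }
  if (length(vals) < 2L) {
    stop_dmelm("'%s' contains fewer than 2 samples", path)
  }
  eeg_segment(vals, sampling_rate = sampling_rate,
              segment_id = tools::file_path_sans_ext(basename(path)))
}

#' Construct an EEG dataset
#'
#' @param segments List of [eeg_segment] objects, all labelled and sharing
#'   one sampling rate.
#' @param class_names Ordered unique class names; defaults to the order of
#'   first appearance among the segment labels.
#' @param set_name Dataset name (e.g. `"SET1"` or `"custom"`).
#' @return An object of class `"eeg_dataset"`.
#' @export
eeg_dataset <- function(segments, class_names = NULL, set_name = "custom") {
  stopifnot(is.list(segments), length(segments) >= 1L)
  labels <- vapply(segments, `[[`, "", "label")
  if (anyNA(labels)) stop_dmelm("all segments must be labelled")
  if (is.null(class_names)) class_names <- unique(labels)
  if (anyDuplicated(class_names)) stop_dmelm("class_names must be unique")
  if (!all(labels %in% class_names)) {
    stop_dmelm("segment labels outside class_names: %s",
               paste(setdiff(labels, class_names), collapse = ", "))
  }
  rates <- unique(vapply(segments, `[[`, 0, "sampling_rate"))
  if (length(rates) != 1L) stop_dmelm("segments have differing sampling rates")
  structure(list(segments = segments, class_names = class_names,
                 set_name = set_name, sampling_rate = rates),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  labels <- vapply(x$segments, `[[`, "", "label")
  counts <- table(factor(labels, levels = x$class_names))
  cat(sprintf("EEG dataset '%s': %d segments @ %.2f Hz\n",
              x$set_name, length(x$segments), x$sampling_rate))
  print(counts)
  invisible(x)
}

# The three dataset compositions used throughout: each combines one
# healthy/baseline set with the interictal (D) and ictal (E) sets.
set_compositions <- list(SET1 = c("A", "D", "E"),
                         SET2 = c("B", "D", "E"),
                         SET3 = c("C", "D", "E"))

#' Assemble a labelled dataset from Bonn-style directories
#'
#' Builds one of the three standard three-class datasets: SET1 combines the
#' source sets A, D and E; SET2 combines B, D and E; SET3 combines C, D and
#' E. Each source set becomes one class, labelled with its letter; segments
#' are read in lexicographically sorted file order, so assembly is
#' deterministic.
#'
#' @param set_name `"SET1"`, `"SET2"` or `"SET3"`.
#' @param roots Named character vector or list mapping set letters (at least
#'   those the composition needs) to directories of ASCII segment files.
#' @param pattern Optional file-name regular expression passed to
#'   [list.files()]; by default every file in the directory is read, which
#'   tolerates the Bonn naming variants (Z/O/N/F/S prefixes).
#' @param sampling_rate Sampling rate recorded on every segment (Hz).
#' @return An [eeg_dataset] with one class per source letter.
#' @export
assemble_eeg_set <- function(set_name = c("SET1", "SET2", "SET3"), roots,
                             pattern = NULL, sampling_rate = 173.61) {
  set_name <- match.arg(set_name)
  letters_needed <- set_compositions[[set_name]]
  roots <- as.list(roots)
  segments <- list()
  for (letter in letters_needed) {
    dir <- roots[[letter]]
    if (is.null(dir) || !dir.exists(dir)) {
      stop_dmelm("no directory configured or found for set letter '%s'", letter)
    }
    files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
    files <- files[!dir.exists(files)]
    if (length(files) == 0L) {
      stop_dmelm("directory for set letter '%s' contains no segment files",
                 letter)
    }
    segs <- lapply(files, function(f) {
      s <- read_eeg_segment(f, sampling_rate = sampling_rate)
      s$label <- letter
      s
    })
    segments <- c(segments, segs)
  }
  eeg_dataset(segments, class_names = letters_needed, set_name = set_name)
}

#' Write and read CSV feature tables
#'
#' Feature tables are stored as plain CSV with a header row; the label is
#' the last column. `read_feature_table(write_feature_table(t))` reproduces
#' the table up to floating-point text round-trip (values are written with
#' 17 significant digits, so the round trip is exact for doubles).
#'
#' @param table A `"feature_table"` data frame (numeric feature columns plus
#'   a final `label` column).
#' @param path File path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `"feature_table"` data frame.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  if (anyDuplicated(names(table))) stop_dmelm("column names must be unique")
  cols <- c(setdiff(names(table), "label"), "label")
  df <- table[, cols, drop = FALSE]
  for (j in seq_len(ncol(df) - 1L)) {
    df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df$label <- as.character(df$label)
  utils::write.table(df, path, sep = ",", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_dmelm("cannot read feature table '%s'", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) {
    stop_dmelm("'%s' has no 'label' column", path)
  }
  feat_cols <- setdiff(names(df), "label")
  for (j in feat_cols) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      vv <- suppressWarnings(as.numeric(v))
      if (anyNA(vv) && !anyNA(v)) {
        stop_dmelm("non-numeric feature values in column '%s' of '%s'", j, path)
      }
      df[[j]] <- vv
    }
  }
  df <- df[, c(feat_cols, "label")]
  df$label <- factor(df$label)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Write an EEG dataset as a Bonn-style ASCII tree
#'
#' Writes one subdirectory per class, each containing one ASCII file per
#' segment (one sample per line), so the tree can be read back with
#' [assemble_eeg_set()] or segment by segment with [read_eeg_segment()].
#'
#' @param dataset An [eeg_dataset].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eeg_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  for (cls in dataset$class_names) {
    dir.create(file.path(dir, cls), recursive = TRUE, showWarnings = FALSE)
  }
  for (seg in dataset$segments) {
    f <- file.path(dir, seg$label, paste0(seg$segment_id, ".txt"))
    writeLines(sprintf("%.10g", seg$samples), f)
  }
  invisible(dir)
}
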