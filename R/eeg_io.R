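# Containers and on-disk formats: multi-channel EEG records (ASCII column
# files), seizure/artefact annotations (plain-text sidecar), and instance
# feature tables (CSV, or RDS for bit-exact round-trips).

#' Multi-channel EEG record
#'
#' Container for a fixed-rate multi-channel EEG signal. Samples are stored as
#' a numeric matrix with one column per channel (rows are time points).
#'
#' @param samples Numeric matrix, time points x channels. A vector is treated
#'   as a single channel.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Optional channel names; defaults to `ch1..chK`.
#' @param t0 Time of the first sample in seconds (default 0).
#'
#' @return An object of class `eeg_record` with fields `samples`, `fs`,
#'   `channel_names`, `t0`.
#' @export
eeg_record <- function(samples, fs, channel_names = NULL, t0 = 0) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  assert_that(is.numeric(fs) && length(fs) == 1 && fs > 0, "fs must be > 0")
  assert_that(!anyNA(samples), "samples contain missing values")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(samples)))
  assert_that(length(channel_names) == ncol(samples),
              "channel_names length must match channel count")
  colnames(samples) <- channel_names
  structure(list(samples = samples, fs = fs,
                 channel_names = as.character(channel_names), t0 = t0),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs, record_duration(x)))
  invisible(x)
}

#' Record duration in seconds
#' @param record An `eeg_record`.
#' @return Duration in seconds (samples / fs).
#' @export
record_duration <- function(record) nrow(record$samples) / record$fs

#' Seizure and artefact annotations
#'
#' Intervals are in seconds from record start, 0-based, half-open
#' `[start, end)`. Seizure intervals must be non-overlapping and ordered
#' `onset < offset`.
#'
#' @param seizures Seizure intervals: a 2-column matrix/data.frame of
#'   (onset_s, offset_s), or NULL.
#' @param artefacts Artefact intervals in the same form.
#'
#' @return An object of class `annotation_set` with interval matrices
#'   `seizures` and `artefacts`.
#' @export
annotation_set <- function(seizures = NULL, artefacts = NULL) {
  seiz <- as_interval_matrix(seizures)
  arte <- as_interval_matrix(artefacts)
  for (m in list(seiz, arte))
    if (nrow(m) > 0)
      assert_that(all(m[, 1] < m[, 2]),
                  "annotation intervals need start < end")
  if (nrow(seiz) > 1) {
    o <- order(seiz[, 1])
    seiz <- seiz[o, , drop = FALSE]
    assert_that(all(seiz[-1, 1] >= seiz[-nrow(seiz), 2]),
                "seizure intervals must not overlap")
  }
  structure(list(seizures = seiz, artefacts = arte), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d seizure(s), %d artefact interval(s)\n",
              nrow(x$seizures), nrow(x$artefacts)))
  invisible(x)
}

#' Read an ASCII EEG file
#'
#' Reads a whitespace- or comma-delimited numeric column file, one column per
#' channel and one sample per line (the layout used for released intracranial
#' EEG recordings). Parsing uses dot-decimal numbers regardless of locale.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz of the stored signal.
#' @param channel_names Optional channel names; defaults to `ch1..chK`.
#'
#' @return An [eeg_record].
#' @export
read_eeg_ascii <- function(path, fs, channel_names = NULL) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  nf <- count.fields(path, sep = "", comment.char = "")
  nf <- nf[!is.na(nf)]
  assert_that(length(nf) > 0, "empty EEG file", "asppr_format_error")
  ncol_exp <- nf[1]
  bad <- which(nf != ncol_exp)
  if (length(bad) > 0)
    stop_asppr(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                       path, bad[1], nf[bad[1]], ncol_exp),
               "asppr_format_error")
  vals <- tryCatch(
    scan(path, what = double(), sep = "", quiet = TRUE, dec = "."),
    error = function(e) stop_asppr(
      sprintf("non-numeric token in %s: %s", path, conditionMessage(e)),
      "asppr_format_error"))
  mat <- matrix(vals, ncol = ncol_exp, byrow = TRUE)
  eeg_record(mat, fs = fs, channel_names = channel_names)
}

#' Write an ASCII EEG file
#'
#' Inverse of [read_eeg_ascii]: one line per sample, space-delimited channel
#' columns, full double precision.
#'
#' @param record An [eeg_record].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eeg_ascii <- function(record, path) {
  lines <- apply(record$samples, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read an annotation sidecar file
#'
#' Plain-text key-value format, one interval per line, times in seconds:
#' \preformatted{
#' seizure 1800 1980
#' artefact 100 110
#' }
#' Blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return An [annotation_set].
#' @export
read_annotations <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  seiz <- list(); arte <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
    assert_that(length(tok) == 3,
                sprintf("annotation line %d: expected 'kind start end'", i),
                "asppr_format_error")
    iv <- suppressWarnings(as.numeric(tok[2:3]))
    assert_that(!anyNA(iv),
                sprintf("annotation line %d: non-numeric interval", i),
                "asppr_format_error")
    if (tok[1] == "seizure") seiz[[length(seiz) + 1]] <- iv
    else if (tok[1] == "artefact") arte[[length(arte) + 1]] <- iv
    else stop_asppr(sprintf("annotation line %d: unknown kind '%s'", i, tok[1]),
                    "asppr_format_error")
  }
  annotation_set(seizures = do.call(rbind, seiz),
                 artefacts = do.call(rbind, arte))
}

#' Write an annotation sidecar file
#' @param annotations An [annotation_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  fmt <- function(kind, m)
    if (nrow(m) > 0) sprintf("%s %.10g %.10g", kind, m[, 1], m[, 2]) else character(0)
  writeLines(c("# asppr annotations (seconds, half-open intervals)",
               fmt("seizure", annotations$seizures),
               fmt("artefact", annotations$artefacts)), path)
  invisible(path)
}

#' Instance feature table
#'
#' One row per 5-second instance tick: feature values, the timestamp of the
#' window end, and the 4-state label.
#'
#' @param values Numeric matrix, instances x features, with canonical
#'   `<channel>__<code>` column names.
#' @param timestamps Instance times in seconds, strictly increasing.
#' @param labels Labels from [asppr_labels()].
#'
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, timestamps, labels) {
  values <- as.matrix(values)
  assert_that(nrow(values) == length(timestamps) &&
                nrow(values) == length(labels),
              "values, timestamps and labels must agree in length")
  assert_that(all(diff(timestamps) > 0), "timestamps must be increasing")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), ASPPR_LABELS)
  assert_that(length(bad) == 0,
              sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
              "asppr_format_error")
  assert_that(!anyNA(values), "feature values contain missing values")
  structure(list(values = values, timestamps = as.numeric(timestamps),
                 labels = factor(labels, levels = ASPPR_LABELS)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d instances x %d features\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$labels))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Write / read an instance feature table
#'
#' CSV carries timestamps, labels and values with 15 significant digits
#' (portable); `format = "rds"` is a bit-exact binary round-trip.
#'
#' @param matrix A [feature_matrix].
#' @param path Output path.
#' @param format `"csv"` or `"rds"`.
#' @return `path`, invisibly (writer); a [feature_matrix] (reader).
#' @export
write_feature_dataset <- function(matrix, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(matrix, path)
  } else {
    df <- data.frame(timestamp = matrix$timestamps,
                     label = as.character(matrix$labels),
                     matrix$values, check.names = FALSE)
    write.csv(format(df, digits = 15, trim = TRUE, scientific = NA),
              path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_feature_dataset
#' @export
read_feature_dataset <- function(path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    fm <- readRDS(path)
    assert_that(inherits(fm, "feature_matrix"), "not a feature_matrix RDS",
                "asppr_format_error")
    return(fm)
  }
  df <- read.csv(path, check.names = FALSE)
  assert_that(all(c("timestamp", "label") %in% names(df)),
              "feature CSV must have timestamp and label columns",
              "asppr_format_error")
  vals <- as.matrix(df[, setdiff(names(df), c("timestamp", "label")),
                       drop = FALSE])
  feature_matrix(vals, df$timestamp, df$label)
}
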