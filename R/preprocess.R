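# Artefact handling: expert-annotated artefact intervals are either excised
# (removing samples and shifting later annotations) or replaced by linear
# interpolation (preserving the wall-clock instance grid). Interpolation is
# the default because the 5-s instance clock downstream is aligned to wall
# time, which excision would break.

#' Remove annotated artefact intervals from a record
#'
#' @param record An [eeg_record].
#' @param annotations An [annotation_set]; overlapping artefact intervals are
#'   merged before removal. An artefact overlapping a seizure interval is an
#'   error: ictal ground truth must not be removed.
#' @param policy `"interpolate"` (default): samples inside each merged
#'   artefact interval are replaced, per channel, by linear interpolation
#'   between the interval's boundary samples; duration and annotation times
#'   are preserved. `"excise"`: samples are deleted and all downstream
#'   annotation times are shifted left by the removed duration.
#'
#' @return A list with the cleaned `record` and the (possibly time-shifted)
#'   `annotations` whose artefact list is emptied.
#' @export
remove_artefacts <- function(record, annotations,
                             policy = c("interpolate", "excise")) {
  policy <- match.arg(policy)
  arte <- merge_intervals(annotations$artefacts)
  dur <- record_duration(record)
  if (nrow(arte) > 0) {
    assert_that(all(arte[, 1] >= 0) && all(arte[, 2] <= dur + 1e-9),
                "artefact interval outside record")
    assert_that(!intervals_overlap(arte, annotations$seizures),
                "artefact interval overlaps a seizure interval",
                "asppr_config_error")
  }
  if (nrow(arte) == 0)
    return(list(record = record,
                annotations = annotation_set(seizures = annotations$seizures)))

  fs <- record$fs
  n <- nrow(record$samples)
  # sample index ranges (1-based, half-open in time -> inclusive index span)
  i_lo <- pmax(1L, floor(arte[, 1] * fs) + 1L)
  i_hi <- pmin(n, ceiling(arte[, 2] * fs))

  if (policy == "interpolate") {
    samples <- record$samples
    for (k in seq_len(nrow(arte))) {
      lo <- i_lo[k]; hi <- i_hi[k]
      a <- max(1L, lo - 1L); b <- min(n, hi + 1L)
      for (ch in seq_len(ncol(samples))) {
        ya <- samples[a, ch]; yb <- samples[b, ch]
        samples[lo:hi, ch] <- ya + (yb - ya) *
          (seq(lo, hi) - a) / max(1L, (b - a))
      }
    }
    rec <- eeg_record(samples, fs = fs, channel_names = record$channel_names,
                      t0 = record$t0)
    return(list(record = rec,
                annotations = annotation_set(seizures = annotations$seizures)))
  }

  # excise: drop samples, shift annotation times by removed measure before them
  keep <- rep(TRUE, n)
  for (k in seq_len(nrow(arte))) keep[i_lo[k]:i_hi[k]] <- FALSE
  rec <- eeg_record(record$samples[keep, , drop = FALSE], fs = fs,
                    channel_names = record$channel_names, t0 = record$t0)
  shift_time <- function(t)
    t - vapply(t, function(ti)
      sum(pmin(pmax(ti - arte[, 1], 0), arte[, 2] - arte[, 1])), numeric(1))
  seiz <- annotations$seizures
  if (nrow(seiz) > 0) {
    seiz <- cbind(shift_time(seiz[, 1]), shift_time(seiz[, 2]))
  }
  list(record = rec, annotations = annotation_set(seizures = seiz))
}
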