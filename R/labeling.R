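# Instance labeling and horizon relabeling. Labels live on the 5-s instance
# clock; windows are anchored on seizure onset with the convention that the
# instance whose window ends exactly at onset is the last pre-ictal instance
# (half-open (lo, hi] windows). For a canonical one-hour file with a 180-s
# seizure this yields exactly 60 pre-ictal, 36 ictal, 60 post-ictal and 564
# inter-ictal instances.

#' Label instances by peri-ictal state
#'
#' An instance at time t is `ictal` if t is in `(onset, offset]`, `pre-ictal`
#' if in `(onset - 300, onset]`, `post-ictal` if in `(offset, offset + 300]`,
#' otherwise `inter-ictal`. Precedence for overlapping windows of different
#' seizures is ictal > pre-ictal > post-ictal > inter-ictal. A seizure closer
#' than 300 s to the file start truncates the pre-ictal window with a
#' warning.
#'
#' @param timestamps Instance times in seconds (5-s clock).
#' @param seizures Seizure intervals: 2-column matrix of (onset, offset), or
#'   an [annotation_set].
#' @return Character vector of labels from [asppr_labels()].
#' @export
label_instances <- function(timestamps, seizures) {
  if (inherits(seizures, "annotation_set")) seizures <- seizures$seizures
  seiz <- as_interval_matrix(seizures)
  labels <- rep(ASPPR_LABELS[1], length(timestamps))
  if (nrow(seiz) == 0) return(labels)
  pre <- post <- ictal <- rep(FALSE, length(timestamps))
  for (i in seq_len(nrow(seiz))) {
    onset <- seiz[i, 1]; offset <- seiz[i, 2]
    if (onset < 300 && onset > 0)
      warning(sprintf(
        "seizure at %g s is closer than 300 s to file start; pre-ictal window truncated",
        onset))
    ictal <- ictal | in_lo_hi(timestamps, onset, offset)
    pre <- pre | in_lo_hi(timestamps, onset - 300, onset)
    post <- post | in_lo_hi(timestamps, offset, offset + 300)
  }
  labels[post] <- "post-ictal"
  labels[pre] <- "pre-ictal"
  labels[ictal] <- "ictal"
  labels
}

#' Class frequencies of a label vector
#'
#' @param labels Labels from [asppr_labels()] (character or factor).
#' @return Named numeric vector of the four class frequencies in canonical
#'   order, summing to 1.
#' @export
class_frequencies <- function(labels) {
  tab <- table(factor(as.character(labels), levels = ASPPR_LABELS))
  setNames(as.numeric(tab) / length(labels), ASPPR_LABELS)
}

# infer per-seizure onset boundaries (the last instance tick at or before
# onset) from the label sequence: ictal runs mark the seizures
infer_onset_boundaries <- function(fm) {
  ict <- fm$labels == "ictal"
  if (!any(ict)) return(numeric(0))
  starts <- which(ict & !c(FALSE, ict[-length(ict)]))
  fm$timestamps[starts] - diff_tick(fm)
}

diff_tick <- function(fm) {
  if (length(fm$timestamps) > 1) min(diff(fm$timestamps)) else 5
}

#' Relabel a t = 0 dataset for an advance-prediction horizon
#'
#' Builds the dataset for the horizon-N model (predicting onset N to N+5
#' minutes ahead) from a t = 0 labeled dataset by, per seizure: (i) removing
#' the instances in the window `(onset - 60N, onset]` and (ii) labeling
#' `pre-ictal` the instances in `(onset - 60(N+5), onset - 60N]`, where only
#' formerly inter-ictal instances count as relabeled (instances already
#' pre-ictal at t = 0 that remain in the window keep their label). Ictal and
#' post-ictal instances are retained unchanged.
#'
#' @param dataset A t = 0 [feature_matrix].
#' @param N Horizon in whole minutes, 0 to 20.
#' @param seizures Optional seizure intervals (matrix or [annotation_set]);
#'   when absent, onset boundaries are inferred from the ictal label runs.
#' @return An object of class `horizon_dataset`: list with the relabeled
#'   `base` feature matrix, `horizon_min`, `removed_count` and
#'   `relabeled_count`.
#' @export
relabel_for_horizon <- function(dataset, N, seizures = NULL) {
  assert_that(length(N) == 1 && !is.na(N) && N == round(N) && N >= 0 &&
                N <= 20, "N must be a whole number of minutes in 0..20")
  N <- as.integer(N)
  if (N == 0L)   # identity transform by construction
    return(structure(list(base = dataset, horizon_min = 0L,
                          removed_count = 0L, relabeled_count = 0L),
                     class = "horizon_dataset"))
  tt <- dataset$timestamps
  labels <- as.character(dataset$labels)

  if (is.null(seizures)) {
    bounds <- infer_onset_boundaries(dataset)
  } else {
    if (inherits(seizures, "annotation_set")) seizures <- seizures$seizures
    bounds <- as_interval_matrix(seizures)[, 1]
  }

  remove <- rep(FALSE, length(tt))
  relabel <- rep(FALSE, length(tt))
  for (onset in bounds) {
    if (N > 0) remove <- remove | in_lo_hi(tt, onset - 60 * N, onset)
    win <- in_lo_hi(tt, onset - 60 * (N + 5), onset - 60 * N)
    relabel <- relabel | (win & labels == "inter-ictal")
  }
  relabel <- relabel & !remove
  removed_count <- sum(remove)
  relabeled_count <- sum(relabel)
  labels[relabel] <- "pre-ictal"

  keep <- !remove
  fm <- feature_matrix(dataset$values[keep, , drop = FALSE], tt[keep],
                       labels[keep])
  structure(list(base = fm, horizon_min = N,
                 removed_count = removed_count,
                 relabeled_count = relabeled_count),
            class = "horizon_dataset")
}

#' @export
print.horizon_dataset <- function(x, ...) {
  cat(sprintf("<horizon_dataset> t = %d min: %d instances (%d removed, %d relabeled)\n",
              x$horizon_min, nrow(x$base$values), x$removed_count,
              x$relabeled_count))
  invisible(x)
}
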