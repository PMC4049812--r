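# Synthetic annotated EEG: one-hour "ictal files" with a single seizure,
# 5-minute pre-/post-ictal neighbourhoods, and a controllable pre-ictal
# spectral/amplitude shift. The generator emulates the statistical structure
# the downstream pipeline assumes (stationary coloured background, shared
# latent source across channels, band-limited oscillation, high-amplitude
# rhythmic seizure), not physiologically realistic EEG.

#' Configuration for the synthetic EEG generator
#'
#' @param duration_s Record length in seconds (default 3600, one ictal file).
#' @param fs Sampling rate in Hz (default 256).
#' @param n_channels Number of channels (default 6, the released-record
#'   layout: 3 focal + 3 extra-focal).
#' @param seizure_onset_s,seizure_offset_s Seizure interval in seconds
#'   (default 1800/1980, a 180-s seizure centred in the hour).
#' @param preictal_effect Dimensionless magnitude (>= 0) of the graded
#'   pre-ictal shift applied over the 5 minutes before onset: a multiplicative
#'   gain on the alpha-band oscillation plus a mean shift. 0 makes pre-ictal
#'   windows statistically indistinguishable from inter-ictal ones.
#' @param noise_sd Background signal scale (arbitrary amplitude units).
#' @param artefact_intervals Optional list/matrix of (start_s, end_s) square
#'   high-amplitude transients.
#' @param seed Integer seed; identical configs generate bit-identical records.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 3600, fs = 256, n_channels = 6,
                         seizure_onset_s = 1800, seizure_offset_s = 1980,
                         preictal_effect = 0, noise_sd = 10,
                         artefact_intervals = NULL, seed = 1L) {
  assert_that(fs > 0, "fs must be > 0")
  assert_that(n_channels >= 1, "n_channels must be >= 1")
  assert_that(preictal_effect >= 0, "preictal_effect must be >= 0")
  assert_that(seizure_onset_s >= 0 && seizure_onset_s < seizure_offset_s &&
                seizure_offset_s <= duration_s,
              "need 0 <= onset < offset <= duration_s",
              "asppr_config_error")
  arte <- as_interval_matrix(artefact_intervals)
  if (nrow(arte) > 0)
    assert_that(all(arte[, 1] < arte[, 2]) && all(arte[, 1] >= 0) &&
                  all(arte[, 2] <= duration_s),
                "artefact intervals must lie within the record",
                "asppr_config_error")
  structure(list(duration_s = duration_s, fs = fs, n_channels = n_channels,
                 seizure_onset_s = seizure_onset_s,
                 seizure_offset_s = seizure_offset_s,
                 preictal_effect = preictal_effect, noise_sd = noise_sd,
                 artefact_intervals = arte, seed = as.integer(seed)),
            class = "synth_config")
}

# order-2 autoregressive background, scaled to unit sd
ar2_noise <- function(n, coef = c(1.2, -0.36)) {
  x <- stats::filter(rnorm(n), filter = coef, method = "recursive")
  as.numeric(x) / sd(x)
}

#' Generate one annotated synthetic EEG record
#'
#' Background per channel is a shared latent AR(2) source plus independent
#' AR(2) noise and a 10 Hz alpha-band oscillation. During the seizure the
#' signal amplitude rises about 4x and a large 3 Hz rhythmic component is
#' added. When `preictal_effect > 0`, the 5 minutes before onset carry a
#' linearly graded alpha-gain and mean shift of that magnitude. Optional
#' artefacts are high-amplitude square transients.
#'
#' @param config A [synth_config].
#' @return A list with elements `record` ([eeg_record]) and `annotations`
#'   ([annotation_set]).
#' @export
generate_record <- function(config) {
  assert_that(inherits(config, "synth_config"), "config must be a synth_config")
  fs <- config$fs
  n <- round(config$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  onset <- config$seizure_onset_s
  offset <- config$seizure_offset_s
  sdv <- config$noise_sd

  pre_lo <- max(0, onset - 300)
  pre_ramp <- numeric(n)
  in_pre <- tt >= pre_lo & tt < onset
  if (onset > pre_lo)
    pre_ramp[in_pre] <- (tt[in_pre] - pre_lo) / (onset - pre_lo)
  in_ictal <- tt >= onset & tt < offset

  samples <- withr::with_seed(config$seed, {
    latent <- ar2_noise(n)
    ictal_osc <- 3 * sdv * sin(2 * pi * 3 * tt)
    out <- matrix(0, nrow = n, ncol = config$n_channels)
    for (ch in seq_len(config$n_channels)) {
      idio <- ar2_noise(n)
      phase <- runif(1, 0, 2 * pi)
      base <- sdv * (0.6 * latent + 0.8 * idio)
      osc <- sdv * sin(2 * pi * 10 * tt + phase)
      gain_alpha <- 1 + config$preictal_effect * pre_ramp
      x <- base + osc * gain_alpha +
        0.5 * sdv * config$preictal_effect * pre_ramp
      x[in_ictal] <- 4 * x[in_ictal] + ictal_osc[in_ictal]
      out[, ch] <- x
    }
    arte <- config$artefact_intervals
    if (nrow(arte) > 0) {
      for (i in seq_len(nrow(arte))) {
        sel <- tt >= arte[i, 1] & tt < arte[i, 2]
        out[sel, ] <- out[sel, ] + 25 * sdv
      }
    }
    out
  })

  list(record = eeg_record(samples, fs = fs),
       annotations = annotation_set(
         seizures = matrix(c(onset, offset), ncol = 2),
         artefacts = config$artefact_intervals))
}

#' Generate a synthetic patient (several ictal files)
#'
#' Produces `n_files` independent records sharing one configuration; per-file
#' sub-seeds are derived deterministically from `seed`, so the same master
#' seed reproduces the same patient.
#'
#' @param config A [synth_config] (its `seed` field is ignored here).
#' @param n_files Number of one-seizure files (>= 1).
#' @param seed Master integer seed.
#' @return List of `n_files` elements, each a list(record, annotations).
#' @export
generate_patient <- function(config, n_files, seed) {
  assert_that(n_files >= 1, "n_files must be >= 1")
  seeds <- derive_seeds(seed, n_files)
  lapply(seq_len(n_files), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    generate_record(cfg)
  })
}

#' Write a synthetic record to disk
#'
#' Writes the ASCII signal file, the annotation sidecar, and a JSON sidecar
#' echoing the generator configuration and seed for provenance.
#'
#' @param x A list(record, annotations) as returned by [generate_record].
#' @param config The [synth_config] used.
#' @param basename Output path prefix; writes `<basename>.asc`,
#'   `<basename>.ann` and `<basename>.json`.
#' @return `basename`, invisibly.
#' @export
write_synth_record <- function(x, config, basename) {
  write_eeg_ascii(x$record, paste0(basename, ".asc"))
  write_annotations(x$annotations, paste0(basename, ".ann"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- unclass(config)
    cfg$artefact_intervals <- apply(cfg$artefact_intervals, 1, identity,
                                    simplify = FALSE)
    jsonlite::write_json(cfg, paste0(basename, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(basename)
}
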