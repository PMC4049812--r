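# Feature engineering: 34 features per channel on the 5-second instance
# clock, 204 columns for the canonical 6-channel record. Window lengths
# follow the 256 Hz sampling convention: signal energy over 5 s (w = 1280),
# short-term (STE) 9 s (w = 2304) and long-term (LTE) 180 s (w = 46080)
# windows, all ending at the instance timestamp. Ticks earlier than a full
# window use a growing window over all samples available (warm-up), so the
# matrix has no missing values from t = 5 s onward.

#' Per-channel feature codes in canonical order
#'
#' The 34 codes, grouped as: windowed signal energies (`se`, `ste`, `lte`),
#' accumulated energy (`ae`), wavelet sub-band energies over STE and LTE
#' windows (`dwt1..dwt4`, nominal bands 0-12.5 / 12.5-25 / 25-50 / 50-100 Hz
#' mapped onto the level-4 dyadic sub-bands), largest Lyapunov exponent
#' (`lyap`), correlation dimension (`cdim`), first/third/fourth moments over
#' STE and LTE windows, spectral band power in the five bands 0.5-4, 4-8,
#' 8-13, 13-30 and 30-48 Hz (`sbp1..sbp5`) over STE and LTE, and spectral
#' edge frequencies SEF-50 and SEF-90 over STE and LTE.
#'
#' @return Character vector of length 34.
#' @export
feature_codes <- function() {
  c("se", "ste", "lte", "ae",
    paste0("dwt", 1:4, "_ste"), paste0("dwt", 1:4, "_lte"),
    "lyap", "cdim",
    "mean_ste", "skew_ste", "kurt_ste",
    "mean_lte", "skew_lte", "kurt_lte",
    paste0("sbp", 1:5, "_ste"), paste0("sbp", 1:5, "_lte"),
    "sef50_ste", "sef90_ste", "sef50_lte", "sef90_lte")
}

SBP_BANDS <- matrix(c(0.5, 4, 4, 8, 8, 13, 13, 30, 30, 48),
                    ncol = 2, byrow = TRUE,
                    dimnames = list(paste0("sbp", 1:5), c("lo", "hi")))

#' Feature-extraction configuration
#'
#' @param se_s,ste_s,lte_s Window lengths in seconds for signal energy (5),
#'   short-term (9) and long-term (180) windows; converted to samples with
#'   the record's sampling rate (1280/2304/46080 at 256 Hz).
#' @param tick_s Instance clock step in seconds (default 5).
#' @param wavelet Daubechies wavelet for the sub-band energies (default db4).
#' @param dwt_levels Decomposition depth (default 4).
#' @param embed_dim,delay,theiler Delay-embedding parameters for the
#'   nonlinear features (dimension 10, delay 4 samples, Theiler window 20).
#' @param lyap_fit_steps Steps of the divergence curve used for the Lyapunov
#'   slope fit.
#' @param nl_max_points Cap on embedded reference points for the nonlinear
#'   features (uniform-stride subsampling of the O(n^2) searches).
#' @param n_radii Number of log-spaced correlation-integral radii over
#'   `[sd/100, sd]`.
#' @param sef_percent SEF percentages (50 and 90).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(se_s = 5, ste_s = 9, lte_s = 180, tick_s = 5,
                           wavelet = "db4", dwt_levels = 4,
                           embed_dim = 10, delay = 4, theiler = 20,
                           lyap_fit_steps = 8, nl_max_points = 400,
                           n_radii = 12, sef_percent = c(50, 90)) {
  structure(list(se_s = se_s, ste_s = ste_s, lte_s = lte_s, tick_s = tick_s,
                 wavelet = wavelet, dwt_levels = dwt_levels,
                 embed_dim = embed_dim, delay = delay, theiler = theiler,
                 lyap_fit_steps = lyap_fit_steps,
                 nl_max_points = nl_max_points, n_radii = n_radii,
                 sef_percent = sef_percent),
            class = "feature_config")
}

#' Mean signal energy over a window
#'
#' Mean of squared amplitudes of the `w` samples in `x`.
#'
#' @param x Numeric window with exactly `w` samples.
#' @param w Window length in samples (defaults to `length(x)`).
#' @return Scalar energy value.
#' @export
signal_energy <- function(x, w = length(x)) {
  assert_that(length(x) == w && w > 0,
              sprintf("window has %d samples, expected w = %d", length(x), w),
              "asppr_window_error")
  mean(x^2)
}

#' Accumulated energy series
#'
#' Running sum of successive signal-energy values plus a per-file offset
#' constant (the offset stands in for energy accumulated before the file
#' start, unknown for a patient's chronologically first seizure).
#'
#' @param energy_series Non-negative signal-energy values.
#' @param offset Additive constant (default 0).
#' @return Series of the same length; element q is `offset + sum(E[1..q])`.
#' @export
accumulated_energy <- function(energy_series, offset = 0) {
  assert_that(all(energy_series >= 0), "energies must be non-negative")
  offset + cumsum(energy_series)
}

# map level-4 sub-band signals (a4, d4, d3, d2, d1) onto the four nominal
# band labels: the two lowest dyadic sub-bands merge into the first band.
dwt_band_signals <- function(x, levels = 4, wavelet = "db4") {
  sb <- dwt_subband_signals(x, levels, wavelet)
  out <- cbind(sb[, 1] + sb[, 2], sb[, 3], sb[, 4], sb[, 5])
  colnames(out) <- paste0("band", 1:4)
  out
}

#' Wavelet sub-band energies of a window
#'
#' Decomposes the window with a Daubechies wavelet at level 4, reconstructs
#' the per-sub-band signals, and applies the mean-square energy over the last
#' `min(w, length(x))` samples, where `w` is the STE (9 s) or LTE (180 s)
#' window. The four returned energies carry the nominal band labels
#' 0-12.5, 12.5-25, 25-50 and 50-100 Hz; at 256 Hz they are realised by the
#' dyadic sub-bands 0-16 (approximation + coarsest detail), 16-32, 32-64 and
#' 64-128 Hz.
#'
#' @param x Numeric window.
#' @param fs Sampling rate in Hz.
#' @param window `"STE"` or `"LTE"`.
#' @param config A [feature_config] for window lengths and wavelet choice.
#' @return Named numeric vector of 4 band energies.
#' @export
dwt_band_energies <- function(x, fs = 256, window = c("STE", "LTE"),
                              config = feature_config()) {
  window <- match.arg(window)
  w <- round(fs * if (window == "STE") config$ste_s else config$lte_s)
  bands <- dwt_band_signals(x, config$dwt_levels, config$wavelet)
  wi <- min(w, nrow(bands))
  seg <- bands[seq(nrow(bands) - wi + 1, nrow(bands)), , drop = FALSE]
  en <- colMeans(seg^2)
  names(en) <- c("0-12.5Hz", "12.5-25Hz", "25-50Hz", "50-100Hz")
  en
}

# Hann-tapered one-sided periodogram; power integrates to roughly the signal
# variance. Returns frequency grid and spectral density.
periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  X <- fft(x * w)
  nh <- floor(n / 2)
  psd <- (Mod(X[seq_len(nh + 1)])^2) / (fs * sum(w^2))
  psd[2:(nh + 1)] <- 2 * psd[2:(nh + 1)]
  if (n %% 2 == 0) psd[nh + 1] <- psd[nh + 1] / 2
  list(freq = seq(0, nh) * fs / n, psd = psd, df = fs / n)
}

#' Spectral band power
#'
#' Integrated power spectral density over `[f_lo, f_hi)` from a Hann-tapered
#' periodogram of the window.
#'
#' @param x Numeric window.
#' @param fs Sampling rate in Hz.
#' @param band Length-2 numeric `(f_lo, f_hi)` with
#'   `0 <= f_lo < f_hi <= fs/2`.
#' @return Scalar power value.
#' @export
spectral_band_power <- function(x, fs, band) {
  assert_that(length(band) == 2 && band[1] >= 0 && band[1] < band[2] &&
                band[2] <= fs / 2, "band must lie inside [0, fs/2]")
  pg <- periodogram(x, fs)
  sel <- pg$freq >= band[1] & pg$freq < band[2]
  sum(pg$psd[sel]) * pg$df
}

#' Spectral edge frequency
#'
#' The lowest frequency F such that X% of the spectral power between 0.5 Hz
#' and the Nyquist frequency lies in 0.5 Hz - F Hz.
#'
#' @param x Numeric window.
#' @param fs Sampling rate in Hz.
#' @param X Percentage of spectral power (typically 50 or 90).
#' @return Frequency in Hz. A window with zero spectral power returns 0.5
#'   with attribute `degenerate = TRUE`.
#' @export
spectral_edge_frequency <- function(x, fs, X = 90) {
  assert_that(X > 0 && X < 100, "X must be a percentage in (0, 100)")
  pg <- periodogram(x, fs)
  sel <- pg$freq >= 0.5
  f <- pg$freq[sel]; p <- pg$psd[sel]
  tot <- sum(p)
  if (tot <= 0)
    return(structure(0.5, degenerate = TRUE))
  cum <- cumsum(p)
  f[which(cum >= X / 100 * tot)[1]]
}

#' First, third and fourth standardized moments of a window
#'
#' @param x Non-empty numeric window.
#' @return Named vector `(mean, skewness, kurtosis)`; kurtosis is the raw
#'   (non-excess) standardized fourth moment. A zero-variance window returns
#'   skewness and kurtosis 0 with attribute `degenerate = TRUE`.
#' @export
signal_moments <- function(x) {
  assert_that(length(x) > 0, "empty window", "asppr_window_error")
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0)
    return(structure(c(mean = m, skewness = 0, kurtosis = 0),
                     degenerate = TRUE))
  c(mean = m,
    skewness = mean((x - m)^3) / v^1.5,
    kurtosis = mean((x - m)^4) / v^2)
}

#' Largest Lyapunov exponent of a window
#'
#' Rosenstein-style estimate: nearest-neighbour pairs (outside a Theiler
#' exclusion window) in the delay-embedded phase space are tracked forward
#' and the exponent is the least-squares slope of the mean log separation
#' over the first `fit_steps` steps, in nats per sample.
#'
#' @param x Numeric window.
#' @param embed_dim Embedding dimension (default 10).
#' @param delay Embedding delay in samples (default 4).
#' @param theiler Theiler exclusion window in samples (default 20).
#' @param fit_steps Divergence-curve steps used in the slope fit.
#' @param max_points Cap on reference points (uniform-stride subsampling);
#'   0 disables subsampling.
#' @return Scalar exponent estimate.
#' @export
max_lyapunov <- function(x, embed_dim = 10, delay = 4, theiler = 20,
                         fit_steps = 8, max_points = 400) {
  need <- (embed_dim - 1) * delay + theiler + 10 + fit_steps
  assert_that(length(x) >= need,
              sprintf("window too short for embedding (need >= %d)", need),
              "asppr_window_error")
  if (sd(x) == 0) return(structure(0, degenerate = TRUE))
  cpp_max_lyapunov(as.numeric(x), as.integer(embed_dim), as.integer(delay),
                   as.integer(theiler), as.integer(fit_steps),
                   as.integer(max_points))
}

#' Correlation dimension of a window
#'
#' Grassberger-Procaccia estimate: the slope of the log correlation integral
#' against log radius, fitted over the scaling region (radii with at least 10
#' admissible pairs and unsaturated counts) of log-spaced radii spanning the
#' embedded-point distance scale (`~ sd(x) * sqrt(2 * embed_dim)`).
#'
#' @inheritParams max_lyapunov
#' @param radii Optional explicit radii vector.
#' @param n_radii Number of log-spaced radii when `radii` is NULL.
#' @return Scalar dimension estimate. A constant window returns 0 with
#'   attribute `degenerate = TRUE`.
#' @export
correlation_dimension <- function(x, embed_dim = 10, delay = 4, theiler = 20,
                                  radii = NULL, n_radii = 12,
                                  max_points = 400) {
  s <- sd(x)
  if (is.na(s) || s == 0) return(structure(0, degenerate = TRUE))
  need <- (embed_dim - 1) * delay + theiler + 10
  assert_that(length(x) >= need,
              sprintf("window too short for embedding (need >= %d)", need),
              "asppr_window_error")
  if (is.null(radii)) {
    # span the scale of embedded-point distances (~ sd * sqrt(2 * dim))
    r_hi <- 2 * s * sqrt(2 * embed_dim)
    radii <- exp(seq(log(r_hi / 300), log(r_hi), length.out = n_radii))
  }
  cnt <- cpp_corr_counts(as.numeric(x), as.integer(embed_dim),
                         as.integer(delay), as.integer(theiler),
                         as.numeric(radii), as.integer(max_points))
  npairs <- attr(cnt, "npairs")
  if (is.null(npairs) || npairs <= 0) return(structure(0, degenerate = TRUE))
  ok <- cnt >= 10 & cnt < npairs
  if (sum(ok) < 2) return(structure(0, degenerate = TRUE))
  C <- cnt[ok] / npairs
  unname(coef(lm(log(C) ~ log(radii[ok])))[2])
}

# windowed mean of f(x) from a cumulative sum, with growing-window warm-up:
# value at sample index i over the last min(w, i) samples
cum_window_mean <- function(cs, idx, w) {
  wi <- pmin(w, idx)
  (cs[idx] - ifelse(idx - wi >= 1, cs[idx - wi], 0)) / wi
}

#' Extract the full feature matrix from a record
#'
#' One instance per `tick_s` seconds starting at `t = tick_s`, each holding
#' the per-channel features listed by [feature_codes()] computed over windows
#' ending at the instance timestamp, with growing-window warm-up before a
#' full window has elapsed. Wavelet sub-band signals are reconstructed once
#' per channel over the whole file and then windowed, so band energies and
#' broadband energies share the same windowing convention. Instances are
#' labeled by [label_instances()] from the seizure annotations.
#'
#' @param record A preprocessed (artefact-free) [eeg_record] with 6 channels.
#' @param annotations An [annotation_set] with the seizure interval(s).
#' @param config A [feature_config].
#' @param features Subset of [feature_codes()] to compute (default all 34;
#'   a reduced set is useful for quick label bookkeeping or cheap models).
#' @param ae_seed Integer seed for the per-file accumulated-energy offset,
#'   drawn uniformly from `[0, 10 x median signal energy]`.
#' @param allow_channel_mismatch Set TRUE to permit a channel count other
#'   than 6 (the canonical layout); otherwise a configuration error.
#'
#' @return A [feature_matrix] with `length(features) x n_channels` columns
#'   named `<channel>__<code>`.
#' @export
extract_feature_matrix <- function(record, annotations,
                                   config = feature_config(),
                                   features = feature_codes(),
                                   ae_seed = 1L,
                                   allow_channel_mismatch = FALSE) {
  assert_that(all(features %in% feature_codes()),
              "unknown feature code(s)")
  nch <- ncol(record$samples)
  if (nch != 6 && !allow_channel_mismatch)
    stop_asppr(sprintf(
      "record has %d channels; the canonical layout has 6 (set allow_channel_mismatch = TRUE to override)",
      nch), "asppr_config_error")

  fs <- record$fs
  n <- nrow(record$samples)
  tick <- config$tick_s
  K <- floor(n / (tick * fs))
  assert_that(K >= 1, "record shorter than one instance tick",
              "asppr_window_error")
  timestamps <- tick * seq_len(K)
  idx <- round(timestamps * fs)          # window-end sample indices

  w_se <- round(config$se_s * fs)
  w_ste <- round(config$ste_s * fs)
  w_lte <- round(config$lte_s * fs)

  want <- function(codes) any(codes %in% features)
  code_order <- feature_codes()
  features <- code_order[code_order %in% features]

  # per-file AE offset, shared across channels
  ae_offset <- NULL

  chan_block <- function(ch) {
    x <- record$samples[, ch]
    out <- matrix(NA_real_, nrow = K, ncol = length(features),
                  dimnames = list(NULL, features))
    cs2 <- cumsum(x^2)

    if (want(c("se", "ae"))) {
      se <- cum_window_mean(cs2, idx, w_se)
      if ("se" %in% features) out[, "se"] <- se
      if ("ae" %in% features) {
        if (is.null(ae_offset))
          ae_offset <<- withr::with_seed(as.integer(ae_seed),
                                         runif(1, 0, 10 * median(se)))
        out[, "ae"] <- accumulated_energy(se, ae_offset)
      }
    }
    if ("ste" %in% features) out[, "ste"] <- cum_window_mean(cs2, idx, w_ste)
    if ("lte" %in% features) out[, "lte"] <- cum_window_mean(cs2, idx, w_lte)

    if (want(c(paste0("dwt", 1:4, "_ste"), paste0("dwt", 1:4, "_lte")))) {
      bands <- dwt_band_signals(x, config$dwt_levels, config$wavelet)
      for (b in 1:4) {
        csb <- cumsum(bands[, b]^2)
        nm_s <- paste0("dwt", b, "_ste"); nm_l <- paste0("dwt", b, "_lte")
        if (nm_s %in% features) out[, nm_s] <- cum_window_mean(csb, idx, w_ste)
        if (nm_l %in% features) out[, nm_l] <- cum_window_mean(csb, idx, w_lte)
      }
    }

    if (want(c("mean_ste", "skew_ste", "kurt_ste",
               "mean_lte", "skew_lte", "kurt_lte"))) {
      cs1 <- cumsum(x); cs3 <- cumsum(x^3); cs4 <- cumsum(x^4)
      for (role in c("ste", "lte")) {
        w <- if (role == "ste") w_ste else w_lte
        m1 <- cum_window_mean(cs1, idx, w)
        m2r <- cum_window_mean(cs2, idx, w)
        m3r <- cum_window_mean(cs3, idx, w)
        m4r <- cum_window_mean(cs4, idx, w)
        v <- pmax(m2r - m1^2, 0)
        m3 <- m3r - 3 * m1 * m2r + 2 * m1^3
        m4 <- m4r - 4 * m1 * m3r + 6 * m1^2 * m2r - 3 * m1^4
        degen <- v <= .Machine$double.eps * pmax(m2r, 1)
        sk <- ifelse(degen, 0, m3 / v^1.5)
        ku <- ifelse(degen, 0, m4 / v^2)
        nm <- paste0(c("mean_", "skew_", "kurt_"), role)
        if (nm[1] %in% features) out[, nm[1]] <- m1
        if (nm[2] %in% features) out[, nm[2]] <- sk
        if (nm[3] %in% features) out[, nm[3]] <- ku
      }
    }

    sbp_codes <- c(outer(paste0("sbp", 1:5, "_"), c("ste", "lte"), paste0))
    sef_codes <- c("sef50_ste", "sef90_ste", "sef50_lte", "sef90_lte")
    if (want(c(sbp_codes, sef_codes))) {
      for (role in c("ste", "lte")) {
        w <- if (role == "ste") w_ste else w_lte
        need_sbp <- paste0("sbp", 1:5, "_", role) %in% features
        need_sef <- paste0("sef", c(50, 90), "_", role) %in% features
        if (!any(need_sbp) && !any(need_sef)) next
        for (k in seq_len(K)) {
          i <- idx[k]; wi <- min(w, i)
          pg <- periodogram(x[(i - wi + 1):i], fs)
          if (any(need_sbp)) {
            for (b in 1:5) {
              if (!need_sbp[b]) next
              sel <- pg$freq >= SBP_BANDS[b, 1] & pg$freq < SBP_BANDS[b, 2]
              out[k, paste0("sbp", b, "_", role)] <- sum(pg$psd[sel]) * pg$df
            }
          }
          if (any(need_sef)) {
            sel <- pg$freq >= 0.5
            p <- pg$psd[sel]; f <- pg$freq[sel]
            tot <- sum(p)
            cum <- if (tot > 0) cumsum(p) / tot else rep(1, length(p))
            for (X in c(50, 90)) {
              nm <- paste0("sef", X, "_", role)
              if (!(nm %in% features)) next
              out[k, nm] <- if (tot > 0) f[which(cum >= X / 100)[1]] else 0.5
            }
          }
        }
      }
    }

    if (want(c("lyap", "cdim"))) {
      for (k in seq_len(K)) {
        i <- idx[k]; wi <- min(w_se, i)
        seg <- x[(i - wi + 1):i]
        need <- (config$embed_dim - 1) * config$delay + config$theiler +
          10 + config$lyap_fit_steps
        if ("lyap" %in% features)
          out[k, "lyap"] <- if (wi >= need)
            as.numeric(max_lyapunov(seg, config$embed_dim, config$delay,
                                    config$theiler, config$lyap_fit_steps,
                                    config$nl_max_points)) else 0
        if ("cdim" %in% features)
          out[k, "cdim"] <- if (wi >= need)
            as.numeric(correlation_dimension(seg, config$embed_dim,
                                             config$delay, config$theiler,
                                             n_radii = config$n_radii,
                                             max_points = config$nl_max_points))
          else 0
      }
    }
    out
  }

  blocks <- lapply(seq_len(nch), chan_block)
  values <- do.call(cbind, blocks)
  colnames(values) <- as.vector(t(outer(record$channel_names, features,
                                        function(a, b) paste0(a, "__", b))))
  values[is.na(values)] <- 0

  labels <- label_instances(timestamps, annotations$seizures)
  feature_matrix(values, timestamps, labels)
}
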