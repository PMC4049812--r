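test_that("signal energy matches hand arithmetic", {
  expect_equal(signal_energy(rep(2, 7)), 4)
  expect_equal(signal_energy(c(1, 2, 3), w = 3), 14 / 3)
  expect_equal(signal_energy(numeric(5) , w = 5), 0)
  expect_error(signal_energy(1:4, w = 10), class = "asppr_window_error")
})

test_that("accumulated energy is a cumulative sum plus offset", {
  expect_equal(accumulated_energy(c(1, 1, 1)), c(1, 2, 3))
  expect_equal(accumulated_energy(c(2, 3, 5)), cumsum(c(2, 3, 5)))
  expect_equal(accumulated_energy(c(1, 1), offset = 10), c(11, 12))
  expect_error(accumulated_energy(c(1, -1)), "non-negative")
  # non-decreasing under fixed offset
  e <- withr::with_seed(1, runif(50))
  expect_true(all(diff(accumulated_energy(e, offset = 3)) >= 0))
})

test_that("wavelet sub-bands reconstruct perfectly and localize frequency", {
  x <- withr::with_seed(3, rnorm(4096))
  sb <- dwt_subband_signals(x)
  expect_lt(max(abs(rowSums(sb) - x)) / sd(x), 1e-9)

  # DC lies entirely in the approximation band
  en_dc <- dwt_band_energies(rep(5, 2304), window = "STE")
  expect_lt(sum(en_dc[2:4]), 1e-9 * en_dc[1])
  expect_gt(en_dc[[1]], 0)

  # a 20 Hz sinusoid at 256 Hz falls in the 16-32 Hz dyadic band (second
  # nominal band) with at least 80% of the summed band energies
  t <- (0:2303) / 256
  en <- dwt_band_energies(sin(2 * pi * 20 * t), fs = 256, window = "STE")
  expect_gt(en[[2]] / sum(en), 0.80)
})

test_that("band-pass oracle agrees with the wavelet band split", {
  skip_if_not_installed("signal")
  # oracle: a bank of butterworth band-passes at the dyadic edges decides
  # which band should dominate for each test tone; the wavelet split must
  # agree and concentrate the energy there
  t <- (0:4095) / 256
  edges <- rbind(c(0.5, 16), c(16, 32), c(32, 64), c(64, 127))
  butter_band <- function(x) {
    e <- apply(edges, 1, function(b) {
      bf <- signal::butter(4, b / 128, type = "pass")
      mean(signal::filtfilt(bf, x)^2)
    })
    which.max(e)
  }
  for (f0 in c(6, 24, 45, 90)) {
    x <- sin(2 * pi * f0 * t)
    en <- dwt_band_energies(x, fs = 256, window = "STE")
    expect_equal(which.max(en), butter_band(x), ignore_attr = TRUE)
    expect_gt(max(en) / sum(en), 0.6)
  }
})

test_that("spectral band power matches line spectra and flat spectra", {
  fs <- 256
  t <- (0:2303) / fs
  x <- sin(2 * pi * 10 * t)
  p_alpha <- spectral_band_power(x, fs, c(8, 13))
  p_tot <- spectral_band_power(x, fs, c(0.5, 128))
  expect_gt(p_alpha / p_tot, 0.95)
  expect_equal(spectral_band_power(numeric(512), fs, c(4, 8)), 0)
  expect_error(spectral_band_power(x, fs, c(100, 200)), "fs/2")

  # white noise: band power ratio equals bandwidth ratio (4-8 vs 8-13 Hz)
  ratios <- withr::with_seed(8, vapply(1:100, function(i) {
    xn <- rnorm(2304)
    spectral_band_power(xn, fs, c(4, 8)) /
      spectral_band_power(xn, fs, c(8, 13))
  }, numeric(1)))
  expect_equal(mean(ratios), 4 / 5, tolerance = 0.1)
})

test_that("spectral edge frequency follows the cumulative-power definition", {
  fs <- 256
  t <- (0:46079) / fs
  expect_equal(spectral_edge_frequency(sin(2 * pi * 10 * t), fs, X = 50),
               10, tolerance = 0.1)

  # flat spectrum closed form: SEF-90 = 0.5 + 0.9 * (128 - 0.5)
  sef <- withr::with_seed(9, vapply(1:100, function(i)
    spectral_edge_frequency(rnorm(2304), fs, X = 90), numeric(1)))
  expect_equal(mean(sef), 115.25, tolerance = 2 / 115.25)

  # equal-power tones at 5 and 15 Hz put the median frequency between them
  x2 <- sin(2 * pi * 5 * t) + sin(2 * pi * 15 * t)
  sef50 <- spectral_edge_frequency(x2, fs, X = 50)
  expect_gte(sef50, 5)
  expect_lte(sef50, 15)

  z <- spectral_edge_frequency(numeric(1024), fs, X = 90)
  expect_equal(as.numeric(z), 0.5)
  expect_true(attr(z, "degenerate"))
})

test_that("moments are standardized with a degenerate zero-variance path", {
  expect_equal(signal_moments(c(1, 2, 3))[["mean"]], 2)
  m <- withr::with_seed(10, signal_moments(rnorm(46080)))
  expect_lt(abs(m[["skewness"]]), 0.05)
  expect_equal(m[["kurtosis"]], 3, tolerance = 0.05)
  const <- signal_moments(rep(7, 100))
  expect_equal(unname(const), c(7, 0, 0), ignore_attr = TRUE)
  expect_true(attr(const, "degenerate"))
})

test_that("Lyapunov estimate recovers ln 2 on the chaotic logistic map", {
  x <- logistic_orbit(1280)
  # independent oracle: lambda = mean log |f'(x)| along the orbit
  oracle <- mean(log(abs(4 - 8 * x)))
  expect_equal(oracle, log(2), tolerance = 0.02)
  est <- max_lyapunov(x, embed_dim = 2, delay = 1, theiler = 10,
                      fit_steps = 5, max_points = 0)
  expect_lt(abs(est - log(2)), 0.15)

  # non-chaotic sinusoid stays near zero; white noise exceeds it
  t <- (0:1279) / 256
  lyap_sin <- max_lyapunov(sin(2 * pi * 5 * t))
  expect_lte(lyap_sin, 0.05)
  for (s in 1:20) {
    xn <- withr::with_seed(100 + s, rnorm(1280))
    expect_gt(max_lyapunov(xn), lyap_sin)
  }
})

test_that("correlation dimension matches a brute-force pair-count oracle", {
  t <- (0:2559) / 256
  x <- sin(2 * pi * 5 * t)
  m <- 5L; tau <- 8L; theiler <- 20L
  s <- sd(x)
  r_hi <- 2 * s * sqrt(2 * m)
  radii <- exp(seq(log(r_hi / 300), log(r_hi), length.out = 12))

  # oracle: explicit embedding + dist() pair counts
  n_emb <- length(x) - (m - 1) * tau
  emb <- sapply(0:(m - 1), function(k) x[(1:n_emb) + k * tau])
  D <- as.matrix(dist(emb))
  keep <- abs(outer(1:n_emb, 1:n_emb, "-")) > theiler & upper.tri(D)
  oracle_counts <- vapply(radii, function(r) sum(D[keep] < r), numeric(1))

  cnt <- asppr:::cpp_corr_counts(x, m, tau, theiler, radii, 0L)
  expect_equal(as.numeric(cnt), oracle_counts)
  expect_equal(attr(cnt, "npairs"), sum(keep))

  # 1-D manifold (sinusoid) and 2-torus dimensions
  expect_equal(correlation_dimension(x, m, tau, theiler, max_points = 600),
               1, tolerance = 0.3)
  x2 <- sin(2 * pi * 5 * t) + sin(2 * pi * 5 * sqrt(2) * t)
  expect_equal(correlation_dimension(x2, embed_dim = 5, delay = 12,
                                     theiler = 30, max_points = 600),
               2, tolerance = 0.2)
  const <- correlation_dimension(rep(1, 2000))
  expect_equal(as.numeric(const), 0)
  expect_true(attr(const, "degenerate"))
})

test_that("extraction yields the canonical instance grid and column set", {
  g <- quick_record(duration_s = 200, onset = 100, offset = 120, seed = 21)
  fm <- extract_feature_matrix(g$record, g$annotations)
  expect_equal(dim(fm), c(40, 204))
  expect_equal(fm$timestamps, seq(5, 200, 5))
  expect_true(all(is.finite(fm$values)))
  expect_equal(colnames(fm$values)[1:2], c("ch1__se", "ch1__ste"))
  expect_equal(length(unique(sub("__.*", "", colnames(fm$values)))), 6)
  expect_equal(length(unique(sub(".*__", "", colnames(fm$values)))), 34)

  # accumulated-energy columns are non-decreasing within the file
  ae <- fm$values[, grep("__ae$", colnames(fm$values))]
  expect_true(all(apply(ae, 2, function(v) all(diff(v) >= 0))))

  # a 10-s record gives ticks at 5 and 10 s
  short <- eeg_record(matrix(rnorm(10 * 256 * 6), ncol = 6), fs = 256)
  fm2 <- extract_feature_matrix(short, annotation_set(),
                                features = c("se", "mean_ste"))
  expect_equal(nrow(fm2$values), 2)

  # 5-channel records need the explicit override
  rec5 <- eeg_record(matrix(rnorm(20 * 256 * 5), ncol = 5), fs = 256)
  expect_error(extract_feature_matrix(rec5, annotation_set()),
               class = "asppr_config_error")
  fm5 <- extract_feature_matrix(rec5, annotation_set(), features = "se",
                                allow_channel_mismatch = TRUE)
  expect_equal(ncol(fm5$values), 5)
})

test_that("windowed features ignore samples outside their windows", {
  fs <- 256
  n <- 200 * fs
  base <- withr::with_seed(33, rnorm(n))
  pert <- base
  sel <- (150 * fs + 1):(170 * fs)
  pert[sel] <- pert[sel] + withr::with_seed(34, rnorm(length(sel), sd = 5))
  ann <- annotation_set()
  mk <- function(x) eeg_record(matrix(rep(x, 6), ncol = 6), fs = fs)
  codes <- setdiff(feature_codes(), "ae")   # ae is cumulative by design
  fa <- extract_feature_matrix(mk(base), ann, features = codes)
  fb <- extract_feature_matrix(mk(pert), ann, features = codes)
  early <- fa$timestamps <= 145
  expect_equal(fb$values[early, ], fa$values[early, ], tolerance = 1e-9)
  # and features over the perturbed span do change
  late <- fa$timestamps >= 160 & fa$timestamps <= 170
  expect_gt(max(abs(fb$values[late, ] - fa$values[late, ])), 1)
})
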