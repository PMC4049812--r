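test_that("generator is deterministic and produces the configured layout", {
  cfg <- synth_config(duration_s = 300, seizure_onset_s = 120,
                      seizure_offset_s = 150, seed = 42)
  a <- generate_record(cfg)
  b <- generate_record(cfg)
  expect_identical(a$record$samples, b$record$samples)
  expect_equal(dim(a$record$samples), c(300 * 256, 6))
  expect_equal(a$annotations$seizures[1, ], c(start = 120, end = 150))

  # a one-hour file has duration_s x fs samples per channel
  h <- generate_record(synth_config(seed = 1))
  expect_equal(nrow(h$record$samples), 3600 * 256)
})

test_that("invalid seizure interval ordering is a configuration error", {
  expect_error(synth_config(seizure_onset_s = 2000, seizure_offset_s = 1800),
               class = "asppr_config_error")
  expect_error(synth_config(duration_s = 100, seizure_onset_s = 50,
                            seizure_offset_s = 150),
               class = "asppr_config_error")
})

test_that("canonical labeled durations follow the default layout", {
  labs <- label_instances(canonical_ticks(), canonical_seizure())
  dur <- table(labs) * 5
  expect_equal(unname(dur[["ictal"]]), 180)
  expect_equal(unname(dur[["pre-ictal"]]), 300)
  expect_equal(unname(dur[["post-ictal"]]), 300)
  expect_equal(unname(dur[["inter-ictal"]]), 2820)
})

test_that("a patient is a reproducible set of single-seizure files", {
  cfg <- synth_config(duration_s = 200, seizure_onset_s = 80,
                      seizure_offset_s = 110)
  p1 <- generate_patient(cfg, n_files = 5, seed = 9)
  p2 <- generate_patient(cfg, n_files = 5, seed = 9)
  expect_length(p1, 5)
  for (i in 1:5) {
    expect_equal(nrow(p1[[i]]$annotations$seizures), 1)
    expect_identical(p1[[i]]$record$samples, p2[[i]]$record$samples)
  }
  # distinct sub-seeds give distinct signals
  expect_false(identical(p1[[1]]$record$samples, p1[[2]]$record$samples))
})

test_that("zero pre-ictal effect leaves pre-ictal windows indistinguishable", {
  g <- quick_record(duration_s = 1200, onset = 600, offset = 630,
                    effect = 0, seed = 5)
  x <- g$record$samples[, 1]
  fs <- g$record$fs
  band_power_at <- function(t_end) {
    seg <- x[(round((t_end - 5) * fs) + 1):round(t_end * fs)]
    spectral_band_power(seg, fs, c(8, 13))
  }
  pre_t <- seq(305, 550, by = 5)[1:50]   # windows inside the pre-ictal span
  int_t <- seq(5, 250, by = 5)[1:50]     # inter-ictal windows
  bp_pre <- vapply(pre_t, band_power_at, numeric(1))
  bp_int <- vapply(int_t, band_power_at, numeric(1))
  p <- wilcox.test(bp_pre, bp_int)$p.value
  expect_gt(p, 0.01)
})

test_that("a large pre-ictal effect shifts alpha-band power before onset", {
  g <- quick_record(duration_s = 900, onset = 600, offset = 630,
                    effect = 4, seed = 5)
  x <- g$record$samples[, 1]
  fs <- g$record$fs
  bp <- function(t_end) {
    seg <- x[(round((t_end - 5) * fs) + 1):round(t_end * fs)]
    spectral_band_power(seg, fs, c(8, 13))
  }
  bp_pre <- vapply(seq(450, 595, 5), bp, numeric(1))  # deep in the ramp
  bp_int <- vapply(seq(5, 150, 5), bp, numeric(1))
  expect_lt(wilcox.test(bp_pre, bp_int)$p.value, 1e-6)
})

test_that("artefact transients land where configured", {
  g <- generate_record(synth_config(duration_s = 60, seizure_onset_s = 40,
                                    seizure_offset_s = 50,
                                    artefact_intervals = rbind(c(10, 12)),
                                    noise_sd = 10, seed = 3))
  x <- g$record$samples[, 1]
  fs <- g$record$fs
  inside <- mean(x[(10 * fs + 1):(12 * fs)])
  outside <- mean(x[1:(10 * fs)])
  expect_gt(inside - outside, 100)       # 25 x noise_sd square pulse
  expect_equal(nrow(g$annotations$artefacts), 1)
})
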