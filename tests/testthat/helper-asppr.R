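# Shared fixtures, built in code.

canonical_ticks <- function() seq(5, 3600, by = 5)
canonical_seizure <- function() matrix(c(1800, 1980), ncol = 2)

# a labeled feature matrix on the canonical one-hour clock with a handful of
# random feature columns -- enough for label/relabel bookkeeping
canonical_label_fm <- function(n_feat = 3, seed = 1) {
  tt <- canonical_ticks()
  labs <- label_instances(tt, canonical_seizure())
  vals <- withr::with_seed(seed, matrix(rnorm(length(tt) * n_feat),
                                        ncol = n_feat))
  colnames(vals) <- paste0("ch1__f", seq_len(n_feat))
  feature_matrix(vals, tt, labs)
}

# small synthetic annotated record for feature/pipeline tests
quick_record <- function(duration_s = 600, onset = 300, offset = 330,
                         effect = 0, seed = 11, ...) {
  generate_record(synth_config(duration_s = duration_s, seizure_onset_s = onset,
                               seizure_offset_s = offset,
                               preictal_effect = effect, seed = seed, ...))
}

# brute-force multi-class ReliefF oracle (exhaustive loops; small n only)
relieff_oracle <- function(X, y, k, samp) {
  X <- as.matrix(X)
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  y <- factor(as.character(y))
  priors <- as.numeric(table(y)) / length(y)
  names(priors) <- levels(y)
  W <- numeric(ncol(Xs))
  m <- length(samp)
  for (r in samp) {
    d <- rowSums(abs(sweep(Xs, 2, Xs[r, ])))
    for (cl in levels(y)) {
      cand <- setdiff(which(y == cl), r)
      if (length(cand) == 0) next
      ord <- cand[order(d[cand], cand)]
      kk <- min(k, length(ord))
      nb <- ord[seq_len(kk)]
      coef <- if (cl == as.character(y[r])) -1 / (m * kk)
      else priors[[cl]] / (1 - priors[[as.character(y[r])]]) / (m * kk)
      for (j in nb) W <- W + coef * abs(Xs[r, ] - Xs[j, ])
    }
  }
  setNames(W, colnames(X))
}

# logistic-map orbit (fully chaotic r = 4)
logistic_orbit <- function(n, x0 = 0.4123) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}
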