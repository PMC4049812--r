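# Multi-class ReliefF feature weighting (Robnik-Sikonja & Kononenko update:
# miss contributions weighted by the miss class's prior over 1 - prior of the
# sampled instance's class), with min-max feature scaling and Manhattan
# neighbour distances. Ranking averages weights over independent runs.

#' ReliefF feature weights (one run)
#'
#' Samples `m` instances; for each, finds the `k` nearest hits and, per other
#' class, `k` nearest misses (Manhattan distance on min-max scaled features,
#' distance ties broken by lower row index) and updates the weights. A class
#' with fewer than `k` available neighbours contributes its available
#' neighbours with a warning.
#'
#' @param X Numeric matrix, instances x features (a [feature_matrix] is also
#'   accepted).
#' @param y Class labels (>= 2 classes present).
#' @param k Neighbours per class (default 10).
#' @param m Sampled instances (default `min(n, 1000)`).
#' @param seed Integer seed controlling the instance sampling.
#' @return Named numeric vector of per-feature weights.
#' @export
relieff_weights <- function(X, y, k = 10, m = NULL, seed = 1L) {
  if (inherits(X, "feature_matrix")) {
    if (missing(y) || is.null(y)) y <- X$labels
    X <- X$values
  }
  X <- as.matrix(X)
  y <- factor(as.character(y))
  assert_that(nlevels(y) >= 2, "need at least 2 classes")
  assert_that(k >= 1, "k must be >= 1")
  n <- nrow(X)
  if (is.null(m)) m <- min(n, 1000L)
  assert_that(m >= 1, "m must be >= 1")

  counts <- table(y)
  small <- names(counts)[counts < k + 1]
  if (length(small) > 0)
    warning(sprintf("class(es) with fewer than k+1 = %d instances (%s); using available neighbours",
                    k + 1, paste(small, collapse = ", ")))

  # min-max scale so |x1 - x2| is the normalized diff() directly
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")

  priors <- as.numeric(counts) / n
  samp <- withr::with_seed(as.integer(seed),
                           if (m >= n) seq_len(n) else sample.int(n, m))
  w <- cpp_relieff(Xs, as.integer(y) - 1L, priors, as.integer(k),
                   as.integer(samp) - 1L)
  setNames(as.numeric(w), colnames(X))
}

#' Rank features from repeated ReliefF runs and select the top subset
#'
#' Averages the per-run weights, ranks features by descending mean weight
#' (exact ties broken in favour of the lower column index) and selects the
#' top `n_select`.
#'
#' @param weight_runs Matrix of weights, runs x features (a single run vector
#'   is also accepted).
#' @param n_select How many features to select (default 14).
#' @return An object of class `feature_ranking`: list with `weights_per_run`,
#'   `mean_weights`, `rank_order` and `selected` (column indices).
#' @export
rank_and_select <- function(weight_runs, n_select = 14) {
  if (is.null(dim(weight_runs))) weight_runs <- matrix(weight_runs, nrow = 1)
  nf <- ncol(weight_runs)
  assert_that(n_select >= 1 && n_select <= nf,
              sprintf("n_select must be in 1..%d", nf))
  mean_w <- colMeans(weight_runs)
  rank_order <- order(-mean_w, seq_len(nf))
  structure(list(weights_per_run = weight_runs, mean_weights = mean_w,
                 rank_order = rank_order,
                 selected = rank_order[seq_len(n_select)]),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  nm <- names(x$mean_weights)
  top <- x$selected
  lab <- if (!is.null(nm)) nm[top] else paste0("f", top)
  cat(sprintf("<feature_ranking> %d run(s) over %d features; top %d:\n",
              nrow(x$weights_per_run), length(x$mean_weights), length(top)))
  print(setNames(round(x$mean_weights[top], 4), lab))
  invisible(x)
}

#' Repeated-run ReliefF ranking
#'
#' Runs [relieff_weights()] `runs` times with independent sub-seeds derived
#' from `seed` and ranks by the mean weights.
#'
#' @inheritParams relieff_weights
#' @param runs Number of independent repetitions (default 10).
#' @param n_select Number of features to select (default 14).
#' @return A `feature_ranking` (see [rank_and_select()]).
#' @export
relieff_rank <- function(X, y = NULL, runs = 10, n_select = 14, k = 10,
                         m = NULL, seed = 1L) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$labels
    X <- X$values
  }
  seeds <- derive_seeds(seed, runs)
  W <- t(vapply(seeds, function(s) relieff_weights(X, y, k = k, m = m,
                                                   seed = s),
                numeric(ncol(X))))
  colnames(W) <- colnames(X)
  rank_and_select(W, n_select)
}
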