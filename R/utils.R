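# Internal helpers: interval arithmetic on half-open [start, end) second
# intervals, seed derivation, and small validation utilities.

stop_asppr <- function(msg, class) {
  stop(structure(class = c(class, "asppr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(ok, msg, class = "asppr_validation_error") {
  if (!isTRUE(ok)) stop_asppr(msg, class)
  invisible(TRUE)
}

# intervals: 2-column matrix (start, end), possibly 0 rows
as_interval_matrix <- function(x) {
  if (is.null(x) || length(x) == 0) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.null(dim(x))) x <- matrix(x, ncol = 2, byrow = TRUE)
  m <- matrix(as.numeric(x), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  m
}

# union of half-open intervals, returned sorted and disjoint
merge_intervals <- function(intervals) {
  m <- as_interval_matrix(intervals)
  if (nrow(m) == 0) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      last <- nrow(out)
      if (m[i, 1] <= out[last, 2]) {
        out[last, 2] <- max(out[last, 2], m[i, 2])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

interval_measure <- function(intervals) {
  m <- merge_intervals(intervals)
  if (nrow(m) == 0) return(0)
  sum(m[, 2] - m[, 1])
}

intervals_overlap <- function(a, b) {
  # any overlap between two half-open interval sets
  a <- as_interval_matrix(a); b <- as_interval_matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(FALSE)
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      if (a[i, 1] < b[j, 2] && b[j, 1] < a[i, 2]) return(TRUE)
  FALSE
}

# in_interval for half-open (lo, hi] windows anchored on onsets: the labeling
# convention counts the instance whose window ends exactly at the boundary.
in_lo_hi <- function(t, lo, hi) t > lo & t <= hi

# Deterministic sub-seed derivation: spreads a master seed into k child seeds
# below 2^31 without consuming the global RNG stream.
derive_seeds <- function(seed, k) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, k))
}
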