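# Evaluation: 4-state confusion tables, Accuracy / Sensitivity / Specificity
# / S1 under two conventions, and closed-form expected metrics for baseline
# and random predictors. The printed-equation convention ("paper") conditions
# Sensitivity and Specificity on the *predicted* class (the fraction of
# pre-ictal predictions that are truly pre-ictal, and of non-pre-ictal
# predictions that are truly non-pre-ictal); the "truth" convention is the
# standard TP/(TP+FN), TN/(TN+FP) pair. Both are needed to reproduce all the
# published reference values.

#' Confusion table of 4-state predictions
#'
#' @param y_true,y_pred Equal-length label vectors from [asppr_labels()].
#' @return 4x4 integer matrix `N(true -> predicted)` in canonical class
#'   order, class `confusion_table`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  assert_that(length(y_true) == length(y_pred),
              "y_true and y_pred must have equal length")
  bad <- setdiff(unique(c(y_true, y_pred)), ASPPR_LABELS)
  assert_that(length(bad) == 0,
              sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  tab <- table(factor(y_true, levels = ASPPR_LABELS),
               factor(y_pred, levels = ASPPR_LABELS))
  m <- matrix(as.integer(tab), 4, 4,
              dimnames = list(true = ASPPR_LABELS, predicted = ASPPR_LABELS))
  class(m) <- c("confusion_table", class(m))
  m
}

s1_harmonic <- function(ss, sp) {
  if (ss + sp <= 0) return(0)
  2 * ss * sp / (ss + sp)
}

#' Accuracy, Sensitivity, Specificity and S1 from a confusion table
#'
#' Accuracy is the percentage of correct 4-state classifications. Under the
#' default `"paper"` convention, Sensitivity is the percentage of pre-ictal
#' *predictions* that are truly pre-ictal and Specificity the percentage of
#' non-pre-ictal predictions that are truly non-pre-ictal; under `"truth"`
#' they are the standard truth-conditioned rates. S1 is the harmonic mean of
#' Sensitivity and Specificity. A zero denominator yields 0 for that measure
#' with a `degenerate` flag.
#'
#' @param table A [confusion] table.
#' @param convention `"paper"` (prediction-conditioned, default) or
#'   `"truth"`.
#' @return List with `accuracy`, `sensitivity`, `specificity`, `s1`
#'   (percentages) and `degenerate` (logical).
#' @export
classification_metrics <- function(table, convention = c("paper", "truth")) {
  convention <- match.arg(convention)
  total <- sum(table)
  assert_that(total > 0, "empty confusion table")
  acc <- 100 * sum(diag(table)) / total
  pre <- "pre-ictal"
  nonpre <- setdiff(ASPPR_LABELS, pre)
  degenerate <- FALSE
  rate <- function(num, den) {
    if (den <= 0) { degenerate <<- TRUE; 0 } else 100 * num / den
  }
  if (convention == "paper") {
    ss <- rate(table[pre, pre], sum(table[, pre]))
    sp <- rate(sum(table[nonpre, nonpre]), sum(table[, nonpre]))
  } else {
    ss <- rate(table[pre, pre], sum(table[pre, ]))
    sp <- rate(sum(table[nonpre, nonpre]), sum(table[nonpre, ]))
  }
  list(accuracy = acc, sensitivity = ss, specificity = sp,
       s1 = s1_harmonic(ss, sp), degenerate = degenerate)
}

#' Class-frequency vector
#'
#' @param p_inter,p_pre,p_ictal,p_post Non-negative class probabilities
#'   summing to 1 (within 1e-9).
#' @return Named numeric vector in canonical order, class
#'   `class_frequencies`.
#' @export
frequency_vector <- function(p_inter = 0.7833, p_pre = 0.08333,
                             p_ictal = 0.05, p_post = 0.08333) {
  p <- c("inter-ictal" = p_inter, "pre-ictal" = p_pre, "ictal" = p_ictal,
         "post-ictal" = p_post)
  assert_that(all(p >= 0), "frequencies must be non-negative")
  assert_that(abs(sum(p) - 1) <= 1e-3,
              sprintf("frequencies sum to %.5f, expected 1", sum(p)))
  class(p) <- "class_frequencies"
  p
}

#' Expected metrics of baseline and random predictors
#'
#' Closed-form expected Accuracy, Sensitivity, Specificity and S1 for simple
#' reference predictors against labels drawn at the given class frequencies,
#' with predictions independent of the truth:
#' \describe{
#'   \item{`always_pre`}{always predicts pre-ictal.}
#'   \item{`never_pre`}{never predicts pre-ictal (predicts the other classes
#'     at their relative frequencies, for the accuracy figure).}
#'   \item{`informed_random`}{predicts each of the four classes at its true
#'     frequency; its expected accuracy is `sum(p_c^2)`.}
#'   \item{`random_p`}{predicts pre-ictal with probability `p`, otherwise a
#'     non-pre-ictal class at relative frequency.}
#' }
#' Prediction-conditioned ("paper") Sensitivity equals the pre-ictal
#' frequency and Specificity its complement for any such independent
#' predictor; the truth-conditioned convention instead returns the emission
#' probability `p` and `1 - p`.
#'
#' @param freqs A [frequency_vector()] of class frequencies.
#' @param predictor One of `"always_pre"`, `"never_pre"`,
#'   `"informed_random"`, `"random_p"`.
#' @param p Emission probability for `random_p` (in `[0, 1]`).
#' @param convention `"paper"` (prediction-conditioned) or `"truth"`.
#' @return List with `accuracy`, `sensitivity`, `specificity`, `s1`
#'   (percentages) and `degenerate`.
#' @export
baseline_expected_metrics <- function(freqs = frequency_vector(),
                                      predictor = c("informed_random",
                                                    "always_pre", "never_pre",
                                                    "random_p"),
                                      p = NULL,
                                      convention = c("paper", "truth")) {
  predictor <- match.arg(predictor)
  convention <- match.arg(convention)
  pr <- as.numeric(freqs)
  names(pr) <- names(unclass(freqs))
  p_pre <- pr[["pre-ictal"]]
  nonpre <- setdiff(names(pr), "pre-ictal")

  # per-class emission probabilities q_c of the predictor
  q <- switch(predictor,
    always_pre = c("pre-ictal" = 1,
                   setNames(rep(0, 3), nonpre)),
    never_pre = c("pre-ictal" = 0,
                  setNames(pr[nonpre] / sum(pr[nonpre]), nonpre)),
    informed_random = pr,
    random_p = {
      assert_that(!is.null(p) && p >= 0 && p <= 1, "p must lie in [0, 1]")
      c("pre-ictal" = p, setNames((1 - p) * pr[nonpre] / sum(pr[nonpre]),
                                  nonpre))
    })
  q <- q[names(pr)]

  acc <- 100 * sum(pr * q)
  degenerate <- FALSE
  if (convention == "paper") {
    ss <- if (q[["pre-ictal"]] > 0) 100 * p_pre else { degenerate <- TRUE; 0 }
    sp <- if (q[["pre-ictal"]] < 1) 100 * (1 - p_pre) else { degenerate <- TRUE; 0 }
  } else {
    ss <- 100 * q[["pre-ictal"]]
    sp <- 100 * (1 - q[["pre-ictal"]])
  }
  list(accuracy = unname(acc), sensitivity = unname(ss),
       specificity = unname(sp), s1 = s1_harmonic(ss, sp),
       degenerate = degenerate)
}

#' Truncate a percentage toward zero at one decimal
#'
#' Reference S1 values are reported truncated (15.27... prints as 15.2).
#'
#' @param x Numeric.
#' @param digits Decimal places kept (default 1).
#' @return Truncated value.
#' @export
truncate_percent <- function(x, digits = 1) {
  trunc(x * 10^digits) / 10^digits
}
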