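test_that("confusion tables cross-tabulate exactly", {
  y <- c("pre-ictal", "inter-ictal", "ictal", "post-ictal")
  tab <- confusion(y, y)
  expect_equal(sum(diag(tab)), 4)
  expect_equal(sum(tab), 4)

  tab2 <- confusion(c("pre-ictal", "inter-ictal"),
                    c("inter-ictal", "inter-ictal"))
  expect_equal(tab2["pre-ictal", "inter-ictal"], 1, ignore_attr = TRUE)
  expect_equal(tab2["inter-ictal", "inter-ictal"], 1, ignore_attr = TRUE)

  expect_error(confusion(c("pre-ictal"), c("mystery")), "mystery")
})

test_that("metrics reproduce the published reference arithmetic", {
  y <- rep(asppr_labels(), each = 5)
  perfect <- classification_metrics(confusion(y, y))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                "s1")]),
               c(accuracy = 100, sensitivity = 100, specificity = 100,
                 s1 = 100))

  # harmonic mean of 8.33 / 91.67 truncates to the printed 15.2
  s1 <- 2 * 8.333 * 91.667 / (8.333 + 91.667)
  expect_equal(truncate_percent(s1), 15.2)

  # hand table: 3 correct pre-ictal predictions, 1 inter-ictal leaking in
  tab <- confusion(c(rep("pre-ictal", 3), "inter-ictal", rep("ictal", 2)),
                   c(rep("pre-ictal", 4), rep("ictal", 2)))
  m <- classification_metrics(tab)
  expect_equal(m$sensitivity, 75)

  # degenerate: no pre-ictal predictions at all
  m0 <- classification_metrics(
    confusion(c("pre-ictal", "inter-ictal"), rep("inter-ictal", 2)))
  expect_true(m0$degenerate)
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$s1, 0)
})

test_that("S1 never exceeds the arithmetic mean of its parts", {
  set.seed(3)
  for (i in 1:50) {
    ss <- runif(1, 0, 100); sp <- runif(1, 0, 100)
    s1 <- 2 * ss * sp / (ss + sp)
    expect_lte(s1, mean(c(ss, sp)) + 1e-12)
  }
  expect_equal(2 * 80 * 80 / 160, 80)   # equality iff equal
})

test_that("baseline predictors reproduce the printed reference values", {
  fr <- frequency_vector()
  ir <- baseline_expected_metrics(fr, "informed_random")
  expect_equal(round(ir$sensitivity, 2), 8.33)
  expect_equal(round(ir$specificity, 2), 91.67)
  expect_equal(round(ir$accuracy, 1), 63.0)
  expect_equal(truncate_percent(ir$s1), 15.2)

  p5 <- baseline_expected_metrics(fr, "random_p", p = 0.5,
                                  convention = "truth")
  expect_equal(unlist(p5[c("sensitivity", "specificity", "s1")]),
               c(sensitivity = 50, specificity = 50, s1 = 50))

  ap <- baseline_expected_metrics(fr, "always_pre", convention = "truth")
  expect_equal(ap$sensitivity, 100)
  expect_equal(ap$specificity, 0)
  expect_equal(ap$s1, 0)

  np <- baseline_expected_metrics(fr, "never_pre", convention = "truth")
  expect_equal(np$sensitivity, 0)
  expect_equal(np$specificity, 100)

  expect_error(baseline_expected_metrics(fr, "random_p", p = 1.5), "0, 1")
})

test_that("Monte-Carlo baseline simulation matches the closed forms", {
  fr <- frequency_vector()
  n <- 1e5
  labs <- withr::with_seed(41, sample(names(fr), n, replace = TRUE,
                                      prob = as.numeric(fr)))
  sim <- function(pred_fun, convention) {
    preds <- pred_fun(n)
    classification_metrics(confusion(labs, preds), convention)
  }
  # informed random, prediction-conditioned
  emp <- withr::with_seed(42, sim(function(n)
    sample(names(fr), n, replace = TRUE, prob = as.numeric(fr)), "paper"))
  thr <- baseline_expected_metrics(fr, "informed_random")
  for (f in c("accuracy", "sensitivity", "specificity", "s1"))
    expect_lt(abs(emp[[f]] - thr[[f]]), 0.5)

  # p = 0.5 random predictor, truth-conditioned
  emp2 <- withr::with_seed(43, sim(function(n)
    ifelse(runif(n) < 0.5, "pre-ictal",
           sample(setdiff(names(fr), "pre-ictal"), n, replace = TRUE)),
    "truth"))
  thr2 <- baseline_expected_metrics(fr, "random_p", p = 0.5,
                                    convention = "truth")
  for (f in c("sensitivity", "specificity", "s1"))
    expect_lt(abs(emp2[[f]] - thr2[[f]]), 0.5)
})
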