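toy_4class <- function(n_per = 12, sd = 0.2, seed = 5) {
  withr::with_seed(seed, {
    centers <- rbind(c(0, 0), c(3, 0), c(0, 3), c(3, 3))
    X <- do.call(rbind, lapply(1:4, function(i)
      cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
    y <- rep(asppr_labels(), each = n_per)
    list(X = X, y = y)
  })
}

test_that("class weights follow the inter-ictal frequency ratios", {
  labs <- c(rep("inter-ictal", 564), rep("pre-ictal", 60),
            rep("ictal", 36), rep("post-ictal", 60))
  w <- compute_class_weights(labs)
  expect_equal(unname(w),
               c(1, 564 / 60, 564 / 36, 564 / 60))
  expect_equal(round(w[["ictal"]], 4), 15.6667)

  eq <- compute_class_weights(rep(asppr_labels(), each = 10))
  expect_true(all(eq == 1))

  expect_error(compute_class_weights(c("inter-ictal", "ictal", "post-ictal")),
               "pre-ictal", class = "asppr_training_error")
})

test_that("the default grid spans 18 combinations and ties prefer small C", {
  g <- default_svm_grid()
  expect_equal(nrow(g), 18)
  expect_setequal(unique(g$C), 2^c(8, 12, 16))
  expect_setequal(unique(g$gamma), 2^seq(0, 10, 2))

  toy <- toy_4class()
  gs <- grid_search(toy$X, toy$y,
                    grid = data.frame(C = c(2^8, 2^16), gamma = 1),
                    folds = 3, seed = 1)
  expect_equal(nrow(gs$cv_accuracy), 2)
  # a cleanly separable problem scores identically -> smaller C wins
  expect_equal(gs$cv_accuracy$accuracy[1], gs$cv_accuracy$accuracy[2])
  expect_equal(gs$C, 2^8)

  one <- grid_search(toy$X, toy$y, grid = data.frame(C = 4, gamma = 0.5),
                     folds = 3, seed = 1)
  expect_equal(one$C, 4)
  expect_equal(one$gamma, 0.5)
})

test_that("one-vs-one training builds a binary model per class pair", {
  toy <- toy_4class()
  model <- svm_train(toy$X, toy$y, C = 256, gamma = 1,
                     class_weights = compute_class_weights(toy$y))
  expect_length(model$binary_models, 6)
  pred <- predict(model, toy$X)
  expect_equal(as.character(pred), toy$y)
  # votes always sum to m(m-1)/2
  votes <- predict(model, toy$X, vote_matrix = TRUE)
  expect_true(all(rowSums(votes) == 6))

  # 2-class separable toy problem reaches 100% training accuracy
  X2 <- rbind(c(0, 0), c(0, 1), c(5, 5), c(5, 6))
  y2 <- c("inter-ictal", "inter-ictal", "pre-ictal", "pre-ictal")
  m2 <- svm_train(X2, y2, C = 100, gamma = 0.5)
  expect_length(m2$binary_models, 1)
  expect_equal(as.character(predict(m2, X2)), y2)

  expect_error(svm_train(cbind(c(1, NA), c(1, 2)), c("a", "b"), 1, 1),
               class = "asppr_training_error")
})

test_that("vote ties break toward the most frequent training class", {
  votes <- rbind(c(2, 2, 1, 1),
                 c(2, 2, 1, 1),
                 c(0, 3, 2, 1))
  # frequencies: inter-ictal most frequent
  freqs <- c(0.78, 0.08, 0.05, 0.08)
  pick <- asppr:::resolve_votes(votes, freqs)
  expect_equal(pick, c(1, 1, 2))
  # reversed frequencies flip the tie
  pick2 <- asppr:::resolve_votes(votes[1, , drop = FALSE],
                                 c(0.08, 0.78, 0.09, 0.05))
  expect_equal(pick2, 2)
  # frequency tie falls back to class order
  pick3 <- asppr:::resolve_votes(votes[1, , drop = FALSE],
                                 c(0.25, 0.25, 0.25, 0.25))
  expect_equal(pick3, 1)
})

test_that("doubling class weights is equivalent to doubling C", {
  toy <- toy_4class(sd = 0.8)
  w <- compute_class_weights(toy$y)
  grid_pts <- as.matrix(expand.grid(seq(-1, 4, 0.5), seq(-1, 4, 0.5)))
  m1 <- svm_train(toy$X, toy$y, C = 10, gamma = 0.5, class_weights = 2 * w)
  m2 <- svm_train(toy$X, toy$y, C = 20, gamma = 0.5, class_weights = w)
  expect_equal(as.character(predict(m1, grid_pts)),
               as.character(predict(m2, grid_pts)))
})

test_that("training and tuning are deterministic under a fixed seed", {
  toy <- toy_4class(sd = 1.2)
  run <- function() {
    gs <- grid_search(toy$X, toy$y,
                      grid = data.frame(C = c(4, 64), gamma = c(0.1, 1)),
                      folds = 4, seed = 7)
    model <- svm_train(toy$X, toy$y, gs$C, gs$gamma)
    list(gs = gs, pred = predict(model, toy$X))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$gs[c("C", "gamma")], r2$gs[c("C", "gamma")])
  expect_identical(r1$pred, r2$pred)
})

test_that("feature-count mismatches are refused at prediction", {
  toy <- toy_4class()
  model <- svm_train(toy$X, toy$y, C = 10, gamma = 1)
  expect_error(predict(model, matrix(0, 2, 3)),
               class = "asppr_prediction_error")
})
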