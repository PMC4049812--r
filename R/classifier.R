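# Class-weighted one-against-one soft-margin RBF SVM. The binary
# quadratic-program solves are delegated to e1071/libsvm; the one-vs-one
# construction, per-class penalty weighting (cost C x weight(class)), the
# voting rule and the training-frequency tie-break are implemented here.

#' Class weights for unbalanced peri-ictal data
#'
#' Weight 1 for `inter-ictal` and `count(inter-ictal)/count(c)` for each
#' other class, so every class has the same total penalty influence.
#'
#' @param labels Training labels; all four classes must be present.
#' @return Named numeric vector of per-class weights in canonical order.
#' @export
compute_class_weights <- function(labels) {
  counts <- table(factor(as.character(labels), levels = ASPPR_LABELS))
  missing_cls <- names(counts)[counts == 0]
  if (length(missing_cls) > 0)
    stop_asppr(sprintf("class(es) absent from training data: %s",
                       paste(missing_cls, collapse = ", ")),
               "asppr_training_error")
  w <- as.numeric(counts["inter-ictal"]) / as.numeric(counts)
  setNames(w, ASPPR_LABELS)
}

#' Default hyperparameter grid
#'
#' C over 2^8, 2^12, 2^16 and the RBF width gamma over 2^0, 2^2, ..., 2^10:
#' 18 combinations.
#'
#' @return Data frame with columns `C` and `gamma`.
#' @export
default_svm_grid <- function() {
  expand.grid(C = 2^c(8, 12, 16), gamma = 2^seq(0, 10, by = 2))
}

# majority vote with ties broken by higher training-set class frequency,
# then by class position; returns column indices into the vote matrix
resolve_votes <- function(votes, freqs) {
  apply(votes, 1, function(v) {
    top <- which(v == max(v))
    top[order(-freqs[top], top)[1]]
  })
}

# stratified fold assignment: round-robin within each class after a seeded
# shuffle, so every fold gets near-equal class composition
stratified_folds <- function(y, folds, seed) {
  y <- factor(as.character(y))
  assign <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Grid search for (C, gamma) by stratified cross-validated accuracy
#'
#' Evaluates every grid combination by k-fold cross-validation accuracy of
#' the one-vs-one weighted SVM on the training data; ties are broken by
#' smaller C, then smaller gamma. If the rarest class has fewer instances
#' than `folds`, the fold count is reduced with a warning so every fold keeps
#' all classes represented.
#'
#' @param X Numeric training matrix (already feature-selected and scaled).
#' @param y Training labels.
#' @param grid Data frame of `C`, `gamma` combinations
#'   (default [default_svm_grid()]).
#' @param folds Cross-validation folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param class_weights Per-class penalty multipliers (default computed from
#'   `y` when all four classes are present, else uniform).
#' @return List with the selected `C`, `gamma`, and the per-combination
#'   `cv_accuracy`.
#' @export
grid_search <- function(X, y, grid = default_svm_grid(), folds = 10,
                        seed = 1L, class_weights = NULL) {
  assert_that(nrow(grid) >= 1, "grid must be non-empty")
  assert_that(folds >= 2, "folds must be >= 2")
  X <- as.matrix(X)
  y <- factor(as.character(y))
  if (is.null(class_weights))
    class_weights <- tryCatch(compute_class_weights(y),
                              error = function(e)
                                setNames(rep(1, nlevels(y)), levels(y)))
  min_count <- min(table(y))
  if (min_count < folds) {
    folds <- max(2L, as.integer(min_count))
    warning(sprintf("rarest class has %d instances; reducing to %d folds",
                    min_count, folds))
  }
  assign <- stratified_folds(y, folds, seed)

  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- assign != f
      model <- svm_train(X[tr, , drop = FALSE], y[tr], C = grid$C[g],
                         gamma = grid$gamma[g], class_weights = class_weights)
      pred <- predict(model, X[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    acc[g] <- correct / length(y)
  }
  best <- order(-acc, grid$C, grid$gamma)[1]
  list(C = grid$C[best], gamma = grid$gamma[best],
       cv_accuracy = cbind(grid, accuracy = acc))
}

#' Train the one-against-one weighted RBF SVM
#'
#' Fits one soft-margin RBF SVM per unordered pair of classes present in the
#' training data (6 models for 4 classes), with per-class error penalty
#' `C x class_weight`. The model records training-set class frequencies for
#' vote tie-breaking.
#'
#' @param X Numeric training matrix (feature-selected and scaled by the
#'   caller).
#' @param y Training labels (>= 2 classes).
#' @param C Regularisation parameter.
#' @param gamma RBF kernel width.
#' @param class_weights Named per-class penalty multipliers (default 1).
#' @param tolerance Solver termination tolerance (default 1e-3).
#' @return An object of class `trained_model`.
#' @export
svm_train <- function(X, y, C, gamma, class_weights = NULL,
                      tolerance = 1e-3) {
  X <- as.matrix(X)
  assert_that(all(is.finite(X)), "non-finite feature values",
              "asppr_training_error")
  y <- factor(as.character(y))
  y <- droplevels(y)
  classes <- levels(y)
  assert_that(length(classes) >= 2, "need at least 2 classes",
              "asppr_training_error")
  if (is.null(class_weights))
    class_weights <- setNames(rep(1, length(classes)), classes)

  pairs <- utils::combn(classes, 2, simplify = FALSE)
  binary <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    y2 <- factor(as.character(y[sel]), levels = pr)
    e1071::svm(x = X[sel, , drop = FALSE], y = y2, type = "C-classification",
               kernel = "radial", cost = C, gamma = gamma,
               class.weights = class_weights[pr], scale = FALSE,
               tolerance = tolerance)
  })
  freqs <- table(y) / length(y)
  structure(list(binary_models = binary, pairs = pairs, classes = classes,
                 C = C, gamma = gamma, class_weights = class_weights,
                 class_frequencies = freqs, n_features = ncol(X)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %d binary SVM(s) over classes {%s}; C = %g, gamma = %g\n",
              length(x$binary_models), paste(x$classes, collapse = ", "),
              x$C, x$gamma))
  invisible(x)
}

#' Predict with the one-against-one model
#'
#' Each binary model casts one vote; the predicted class has the most votes,
#' with ties broken in favour of the class with the highest training-set
#' frequency (then canonical class order).
#'
#' @param object A `trained_model`.
#' @param newdata Numeric matrix with the model's feature columns, scaled as
#'   in training.
#' @param vote_matrix Return the per-class vote counts instead of labels.
#' @param ... Unused.
#' @return Factor of predicted labels (or an integer vote matrix).
#' @export
predict.trained_model <- function(object, newdata, vote_matrix = FALSE, ...) {
  newdata <- as.matrix(newdata)
  assert_that(ncol(newdata) == object$n_features,
              sprintf("expected %d features, got %d", object$n_features,
                      ncol(newdata)),
              "asppr_prediction_error")
  n <- nrow(newdata)
  votes <- matrix(0L, nrow = n, ncol = length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (b in seq_along(object$binary_models)) {
    p <- as.character(predict(object$binary_models[[b]], newdata))
    for (cl in object$pairs[[b]])
      votes[, cl] <- votes[, cl] + (p == cl)
  }
  if (vote_matrix) return(votes)
  pick <- resolve_votes(votes,
                        as.numeric(object$class_frequencies[object$classes]))
  lev <- if (all(object$classes %in% ASPPR_LABELS))
    intersect(ASPPR_LABELS, object$classes) else object$classes
  factor(object$classes[pick], levels = lev)
}
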