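#' Split a feature table into training and test sets
#'
#' Seeded, stratified 80:20 split. With `unit = "subject"` (the default) all
#' trials of a subject land in the same partition, preventing within-subject
#' leakage across the two trials; `unit = "trial"` splits trials
#' independently. Stratification guarantees both classes are present in
#' both partitions.
#'
#' @param features Tibble from [extract_features()] (needs `subject_id` and
#'   `label` columns).
#' @param train_frac Training fraction (default 0.8).
#' @param unit `"subject"` or `"trial"`.
#' @param seed Integer seed (required).
#' @return List with tibbles `train` and `test`.
#' @export
split_dataset <- function(features, train_frac = 0.8,
                          unit = c("subject", "trial"), seed) {
  unit <- match.arg(unit)
  if (missing(seed)) stop("`seed` is required for a reproducible split.", call. = FALSE)
  if (nrow(features) < 10) stop("Need at least 10 rows to split.", call. = FALSE)
  labs <- unique(features$label)
  if (length(labs) != 2) stop("Need exactly two classes.", call. = FALSE)

  withr::with_seed(seed, {
    if (unit == "subject") {
      units <- features |>
        dplyr::distinct(.data$subject_id, .data$label)
      if (any(duplicated(units$subject_id))) {
        stop("A subject carries two different labels.", call. = FALSE)
      }
      pick <- unlist(lapply(labs, function(l) {
        ids <- sample(units$subject_id[units$label == l])
        ids[seq_len(max(1, floor(train_frac * length(ids))))]
      }))
      train <- features[features$subject_id %in% pick, ]
      test <- features[!features$subject_id %in% pick, ]
    } else {
      idx <- unlist(lapply(labs, function(l) {
        rows <- sample(which(features$label == l))
        rows[seq_len(max(1, floor(train_frac * length(rows))))]
      }))
      train <- features[sort(idx), ]
      test <- features[-sort(idx), ]
    }
  })
  if (length(unique(train$label)) < 2 || length(unique(test$label)) < 2) {
    stop("A class is missing from one partition; enlarge the dataset.", call. = FALSE)
  }
  list(train = train, test = test)
}

feature_columns <- function(features) {
  setdiff(names(features), c("subject_id", "trial", "label", "gender", "synthetic"))
}

default_grids <- function() {
  list(
    svm = expand.grid(cost = c(0.1, 1, 10), gamma = c(0.01, 0.1, 1)),
    tree = expand.grid(maxdepth = c(2, 4, 8), cp = c(0.001, 0.01)),
    forest = expand.grid(ntree = c(100, 300), mtry_frac = c(0.3, 0.6)),
    lda = data.frame(dummy = 1),
    knn = expand.grid(k = c(1, 3, 5, 7, 9))
  )
}

fit_family <- function(family, X, y, par) {
  y <- factor(y, levels = c(0, 1))
  switch(family,
    svm = e1071::svm(X, y, cost = par$cost, gamma = par$gamma, kernel = "radial"),
    tree = rpart::rpart(label ~ .,
      data = data.frame(X, label = y),
      method = "class",
      control = rpart::rpart.control(maxdepth = par$maxdepth, cp = par$cp, minsplit = 5)
    ),
    forest = randomForest::randomForest(X, y,
      ntree = par$ntree,
      mtry = max(1, floor(par$mtry_frac * ncol(X)))
    ),
    lda = MASS::lda(X, grouping = y),
    knn = list(train = X, y = y, k = par$k), # lazy learner
    stop(sprintf("Unknown classifier family '%s'.", family), call. = FALSE)
  )
}

predict_family <- function(family, model, X) {
  out <- switch(family,
    svm = stats::predict(model, X),
    tree = stats::predict(model, data.frame(X), type = "class"),
    forest = stats::predict(model, X),
    lda = stats::predict(model, X)$class,
    knn = class::knn(model$train, X, model$y, k = model$k)
  )
  as.integer(as.character(out))
}

#' Grid-search cross-validated training of a classifier family
#'
#' Exhaustive grid search scored by mean 10-fold cross-validation accuracy
#' on the training set, then a refit of the best configuration on the full
#' training set. Ties go to the first grid row. Families: `"svm"`
#' (max-margin, RBF), `"tree"` (decision tree), `"forest"` (random forest),
#' `"lda"` (linear discriminant), `"knn"` (nearest neighbor).
#'
#' @param train Training tibble (from [split_dataset()]; `label` must be
#'   0/1 with 1 = positive/ICPP).
#' @param family One of `"svm"`, `"tree"`, `"forest"`, `"lda"`, `"knn"`.
#' @param grid Data frame of hyperparameter combinations; defaults per
#'   family from `default_grids()`.
#' @param n_folds Cross-validation folds (default 10; reduced with a
#'   warning when the training set is smaller).
#' @param seed Integer seed for fold assignment and stochastic learners.
#' @return Object of class `nirs_classifier`: `model`, `family`,
#'   `best_params`, `cv_results` (tibble), `feature_cols`.
#' @export
tune_and_train <- function(train, family = c("svm", "tree", "forest", "lda", "knn"),
                           grid = NULL, n_folds = 10, seed = 1) {
  family <- match.arg(family)
  grid <- grid %||% default_grids()[[family]]
  if (is.null(grid) || nrow(grid) == 0) stop("Hyperparameter grid is empty.", call. = FALSE)
  cols <- feature_columns(train)
  X <- as.matrix(train[, cols])
  y <- train$label
  n <- nrow(X)
  if (n < n_folds) {
    n_folds <- max(2, n %/% 2)
    warning(sprintf("Training set smaller than fold count; using %d folds.", n_folds),
      call. = FALSE
    )
  }
  withr::with_seed(seed, {
    folds <- sample(rep(seq_len(n_folds), length.out = n))
    cv <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
      par <- grid[g, , drop = FALSE]
      accs <- vapply(seq_len(n_folds), function(f) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2) return(NA_real_)
        m <- fit_family(family, X[tr, , drop = FALSE], y[tr], par)
        pred <- predict_family(family, m, X[!tr, , drop = FALSE])
        mean(pred == y[!tr])
      }, 0)
      dplyr::bind_cols(tibble::as_tibble(par), tibble::tibble(
        cv_accuracy = mean(accs, na.rm = TRUE)
      ))
    })
    best <- which.max(cv$cv_accuracy) # ties -> first grid row
    model <- fit_family(family, X, y, grid[best, , drop = FALSE])
  })
  structure(
    list(
      model = model, family = family,
      best_params = grid[best, , drop = FALSE],
      cv_results = cv, feature_cols = cols
    ),
    class = "nirs_classifier"
  )
}

#' @export
print.nirs_classifier <- function(x, ...) {
  cat(sprintf(
    "<nirs_classifier> %s; best CV accuracy %.3f; params: %s\n",
    x$family, max(x$cv_results$cv_accuracy),
    paste(names(x$best_params), unlist(x$best_params), sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' @export
predict.nirs_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_cols])
  predict_family(object$family, object$model, X)
}

#' Classification metrics from a confusion matrix
#'
#' Computes the evaluation panel from the four confusion counts, with ICPP
#' (label 1) as the positive class: accuracy, specificity
#' `TN / (TN + FP)`, and precision, recall and F1 averaged per class with
#' weights equal to the true class counts. All metrics are percentages.
#'
#' @param tp,tn,fp,fn Confusion counts.
#' @return Tibble with `accuracy`, `precision`, `recall`, `f1`,
#'   `specificity` (percent) and the four counts.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  if (n == 0) stop("Empty confusion matrix.", call. = FALSE)
  n_pos <- tp + fn # true ICPP
  n_neg <- tn + fp # true normal
  if (n_neg == 0) stop("Specificity undefined: no true-negative-class cases.", call. = FALSE)
  if (n_pos == 0) stop("Recall undefined for the positive class: no positive cases.", call. = FALSE)
  prec_pos <- if (tp + fp > 0) tp / (tp + fp) else 0
  prec_neg <- if (tn + fn > 0) tn / (tn + fn) else 0
  rec_pos <- tp / n_pos
  rec_neg <- tn / n_neg
  f1_of <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0
  w <- c(n_neg, n_pos) / n
  tibble::tibble(
    accuracy = (tp + tn) / n * 100,
    precision = sum(w * c(prec_neg, prec_pos)) * 100,
    recall = sum(w * c(rec_neg, rec_pos)) * 100,
    f1 = sum(w * c(f1_of(prec_neg, rec_neg), f1_of(prec_pos, rec_pos))) * 100,
    specificity = rec_neg * 100,
    tp = tp, tn = tn, fp = fp, fn = fn
  )
}

#' Evaluate a fitted classifier on a test set
#'
#' @param classifier A `nirs_classifier`.
#' @param test Test tibble with true `label` (1 = ICPP positive class).
#' @return An `eval_report` tibble: the [confusion_metrics()] panel plus
#'   `family` and `n_test`.
#' @export
evaluate <- function(classifier, test) {
  truth <- test$label
  if (length(unique(truth)) < 2) {
    stop("Test set contains a single class; metrics undefined.", call. = FALSE)
  }
  pred <- stats::predict(classifier, test)
  m <- confusion_metrics(
    tp = sum(pred == 1 & truth == 1), tn = sum(pred == 0 & truth == 0),
    fp = sum(pred == 1 & truth == 0), fn = sum(pred == 0 & truth == 1)
  )
  out <- dplyr::mutate(m, family = classifier$family, n_test = length(truth))
  class(out) <- c("eval_report", class(out))
  out
}
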