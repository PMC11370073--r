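# Random-forest window classifier: 500 trees on the 25-feature contract,
# with leave-one-subject-out validation and class-to-intensity mapping.

check_feature_contract <- function(data, feature_names) {
  missing <- setdiff(feature_names, names(data))
  if (length(missing) > 0) {
    abort_arg(paste0(
      "feature contract mismatch; missing: ", paste(missing, collapse = ", ")
    ))
  }
  X <- data[feature_names]
  if (any(!purrr::map_lgl(X, is.numeric))) abort_arg("features must be numeric.")
  if (any(!is.finite(as.matrix(X)))) abort_arg("features contain missing or non-finite values.")
  X
}

#' Train the activity-class random forest
#'
#' Fits a 500-tree random forest mapping the 25 window features to the five
#' activity classes. `mtry` is `floor(sqrt(25)) = 5` and trees are grown to
#' purity; vote ties are broken deterministically in the fixed class order
#' SED < L_ACT_G < MV_ACT_G < WALK < RUN.
#'
#' @param corpus Data frame of labelled windows: the 25 feature columns (see
#'   [feature_names()]) plus a `label` column.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed; training is fully deterministic given the seed.
#' @param label Name of the label column.
#'
#' @return Object of class `activity_model` holding the fitted forest, the
#'   ordered feature-name contract, the class labels and the seed.
#' @export
train_activity_model <- function(corpus, n_trees = 500, seed = 1, label = "label") {
  if (!label %in% names(corpus)) abort_arg("corpus must contain a `label` column.")
  y <- activity_factor(corpus[[label]])
  if (anyNA(y)) abort_arg("labels outside the five-class set.")
  if (length(unique(y)) < 2) abort_arg("corpus must contain at least 2 classes.")
  X <- check_feature_contract(corpus, FEATURE_NAMES)
  d <- dplyr::bind_cols(X, tibble::tibble(.label = droplevels(y)))
  fit <- ranger::ranger(
    dependent.variable.name = ".label",
    data = as.data.frame(d),
    num.trees = n_trees,
    mtry = floor(sqrt(length(FEATURE_NAMES))),
    seed = seed,
    num.threads = 1,
    probability = FALSE,
    respect.unordered.factors = "order"
  )
  structure(
    list(
      forest = fit,
      feature_names = FEATURE_NAMES,
      classes = ACTIVITY_CLASSES,
      n_trees = n_trees,
      seed = seed
    ),
    class = "activity_model"
  )
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf(
    "<activity_model> %d trees, %d features, OOB error %.3f\n",
    x$n_trees, length(x$feature_names), x$forest$prediction.error
  ))
  invisible(x)
}

#' Predict activity classes for windows
#'
#' @param object An [train_activity_model()] fit.
#' @param new_data Data frame containing the 25 feature columns.
#' @param ... Unused.
#'
#' @return Factor of predicted classes over the five-class set, one per row
#'   of `new_data`.
#' @export
predict.activity_model <- function(object, new_data, ...) {
  if (nrow(new_data) == 0) {
    return(factor(character(), levels = object$classes))
  }
  X <- check_feature_contract(new_data, object$feature_names)
  pred <- predict(object$forest,
    data = as.data.frame(X),
    num.threads = 1, seed = object$seed
  )$predictions
  factor(as.character(pred), levels = object$classes)
}

#' Classification metrics from truth and predictions
#'
#' Builds the confusion matrix (rows = truth, columns = predicted) and the
#' per-class recall (recognition accuracy), precision and F-score, plus the
#' macro-averaged F-score over classes with support.
#'
#' @param truth,predicted Vectors of class labels.
#'
#' @return Object of class `class_metrics`: list with `confusion` (matrix),
#'   `per_class` (tibble), `macro_f`, `accuracy`, `n`.
#' @export
classification_metrics <- function(truth, predicted) {
  truth <- activity_factor(truth)
  predicted <- activity_factor(predicted)
  if (length(truth) != length(predicted)) abort_arg("length mismatch.")
  cm <- table(truth = truth, predicted = predicted)
  support <- rowSums(cm)
  pred_tot <- colSums(cm)
  diagv <- diag(cm)
  recall <- ifelse(support > 0, diagv / support, NA_real_)
  precision <- ifelse(pred_tot > 0, diagv / pred_tot, NA_real_)
  f <- ifelse(
    !is.na(recall) & !is.na(precision) & (precision + recall) > 0,
    2 * precision * recall / (precision + recall),
    ifelse(is.na(recall), NA_real_, 0)
  )
  per_class <- tibble::tibble(
    class = rownames(cm),
    support = as.integer(support),
    recall = as.numeric(recall),
    precision = as.numeric(precision),
    f_score = as.numeric(f)
  )
  structure(
    list(
      confusion = unclass(cm),
      per_class = per_class,
      macro_f = mean(f[support > 0]),
      accuracy = sum(diagv) / sum(cm),
      n = length(truth)
    ),
    class = "class_metrics"
  )
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf(
    "<class_metrics> n = %d, accuracy %.3f, macro F %.3f\n",
    x$n, x$accuracy, x$macro_f
  ))
  print(x$per_class)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.class_metrics <- function(x, ...) x$per_class

#' @exportS3Method generics::glance
glance.class_metrics <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy, macro_f = x$macro_f)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject, trains the forest on all other subjects and predicts
#' the held-out subject's windows; predictions are pooled over all held-out
#' subjects into one confusion matrix, so every window is scored exactly
#' once.
#'
#' @param corpus Labelled windows with `subject_id`, `label` and the 25
#'   feature columns (e.g. from [simulate_annotated_corpus()]).
#' @param n_trees Trees per fold (default 500).
#' @param seed Integer seed used for every fold.
#'
#' @return A `class_metrics` object with an additional `predictions` element
#'   (tibble `subject_id`, `truth`, `predicted`).
#' @export
loso_cv <- function(corpus, n_trees = 500, seed = 1) {
  if (!all(c("subject_id", "label") %in% names(corpus))) {
    abort_arg("corpus needs subject_id and label columns.")
  }
  subjects <- unique(corpus$subject_id)
  if (length(subjects) < 2) abort_arg("leave-one-subject-out needs >= 2 subjects.")
  preds <- purrr::map_dfr(subjects, function(s) {
    train <- corpus[corpus$subject_id != s, ]
    test <- corpus[corpus$subject_id == s, ]
    model <- train_activity_model(train, n_trees = n_trees, seed = seed)
    tibble::tibble(
      subject_id = test$subject_id,
      truth = activity_factor(test$label),
      predicted = predict(model, test)
    )
  })
  out <- classification_metrics(preds$truth, preds$predicted)
  out$predictions <- preds
  out
}

#' Map activity classes to intensity categories
#'
#' SED is sedentary; L_ACT_G is light-intensity physical activity (LPA);
#' MV_ACT_G, WALK and RUN together are energetic play (MVPA).
#'
#' @param label Vector of activity class labels.
#'
#' @return Factor over `SEDENTARY`, `LPA`, `MVPA`.
#' @export
#'
#' @examples
#' map_to_intensity(c("SED", "WALK", "L_ACT_G"))
map_to_intensity <- function(label) {
  label <- as.character(label)
  bad <- setdiff(unique(label), ACTIVITY_CLASSES)
  if (length(bad) > 0) {
    abort_arg(paste0("unknown class labels: ", paste(bad, collapse = ", ")))
  }
  out <- ifelse(label == "SED", "SEDENTARY",
    ifelse(label == "L_ACT_G", "LPA", "MVPA")
  )
  factor(out, levels = INTENSITY_LEVELS)
}
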