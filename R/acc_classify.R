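# Ensemble behaviour classification: random-forest training on
# summary-statistic features, stratified splits, and segment-length
# evaluation by pooled F-measure.

.feature_columns <- function(features) {
  setdiff(names(features),
          c("bird_id", "burst_start", "segment", "behaviour",
            "segment_length"))
}

#' Stratified train/test split
#'
#' Splits indices into a training and a held-out set, stratified by class so
#' rare classes (begging) keep their share on both sides.
#'
#' @param labels Character or factor vector of class labels.
#' @param train_frac Fraction of each class assigned to training
#'   (default 0.7).
#' @param seed RNG seed.
#' @return A list of integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  set.seed(seed)
  idx <- seq_along(labels)
  train <- unlist(lapply(split(idx, labels), function(ii) {
    n_tr <- max(1L, floor(length(ii) * train_frac))
    sample(ii, n_tr)
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(idx, train)))
}

#' Train the behaviour classifier
#'
#' Fits a random-forest ensemble (via \pkg{ranger}) on a feature table from
#' [featurize_segments()]. Class weights inversely proportional to class
#' frequency counter the strong imbalance of field training sets, where
#' begging is by far the rarest class.
#'
#' @param features Feature tibble including a `behaviour` column.
#' @param num_trees Number of trees (default 500).
#' @param class_weights `"balanced"` (inverse-frequency, the default),
#'   `"none"`, or a named numeric vector.
#' @param seed RNG seed; the fit is fully reproducible.
#' @return An object of class `behaviour_classifier` supporting
#'   [predict()][predict.behaviour_classifier()] (labels or class
#'   probabilities) and [feature_importance()].
#' @export
train_classifier <- function(features, num_trees = 500,
                             class_weights = "balanced", seed = 1L) {
  stopifnot(is.data.frame(features), "behaviour" %in% names(features))
  y <- factor(features$behaviour)
  tab <- table(y)
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(tab < 5)) {
    stop("each class needs >= 5 training segments; short of that: ",
         paste(names(tab)[tab < 5], collapse = ", "), call. = FALSE)
  }
  cols <- .feature_columns(features)
  dat <- as.data.frame(features[cols])
  dat$.behaviour <- y
  wts <- if (identical(class_weights, "balanced")) {
    w <- 1 / as.numeric(tab[y]); w / mean(w)
  } else if (identical(class_weights, "none")) {
    NULL
  } else {
    stopifnot(is.numeric(class_weights), !is.null(names(class_weights)))
    as.numeric(class_weights[as.character(y)])
  }
  fit <- ranger::ranger(
    dependent.variable.name = ".behaviour", data = dat,
    num.trees = num_trees, probability = TRUE,
    importance = "impurity", seed = seed,
    case.weights = wts, num.threads = 1
  )
  structure(list(fit = fit, classes = levels(y), feature_cols = cols,
                 num_trees = num_trees, seed = seed),
            class = "behaviour_classifier")
}

#' Predict behaviour classes or probabilities
#'
#' @param object A `behaviour_classifier`.
#' @param features Feature tibble with the columns the model was trained on.
#' @param type `"class"` (default) for labels, `"prob"` for the class
#'   probability matrix.
#' @param ... Unused.
#' @return Character vector of labels, or a numeric matrix of class
#'   probabilities.
#' @export
predict.behaviour_classifier <- function(object, features,
                                         type = c("class", "prob"), ...) {
  type <- match.arg(type)
  dat <- as.data.frame(features[object$feature_cols])
  pr <- stats::predict(object$fit, data = dat, num.threads = 1)$predictions
  if (type == "prob") return(pr)
  object$classes[max.col(pr, ties.method = "first")]
}

#' Feature importances of a trained classifier
#'
#' @param object A `behaviour_classifier`.
#' @return Named numeric vector (impurity importance), decreasing.
#' @export
feature_importance <- function(object) {
  stopifnot(inherits(object, "behaviour_classifier"))
  sort(ranger::importance(object$fit), decreasing = TRUE)
}

#' @export
print.behaviour_classifier <- function(x, ...) {
  cat("<behaviour_classifier>", x$num_trees, "trees,",
      length(x$classes), "classes:",
      paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Train and score the classifier across segment lengths
#'
#' For each segment length, cuts the labelled bursts, featurizes, splits
#' stratified 70/30 at the burst level (all segments of one burst stay on
#' one side, so held-out scores are not inflated by within-burst leakage),
#' trains, and scores held-out predictions with [f_measure()] under the
#' standard pooling (forage, rest, fly, walk, beg).
#'
#' @param bursts Labelled burst tibble (e.g. from
#'   [simulate_training_bursts()]).
#' @param segment_lengths Lengths to evaluate (default all of 0.4, 0.8,
#'   1.6 s).
#' @param train_frac Training fraction (default 0.7).
#' @param seed RNG seed used for the split and the forest.
#' @param acc_rate Sampling rate in Hz.
#' @param pooling Pooling map for scoring (default [behaviour_pooling()]).
#' @return A list with `scores` (tibble: segment_length, class, F) and
#'   `models` (one `behaviour_classifier` per length, named by length).
#' @export
evaluate_segment_lengths <- function(bursts,
                                     segment_lengths = c(0.4, 0.8, 1.6),
                                     train_frac = 0.7, seed = 1L,
                                     acc_rate = 20,
                                     pooling = behaviour_pooling()) {
  stopifnot(is.data.frame(bursts), "behaviour" %in% names(bursts))
  split <- stratified_split(bursts$behaviour, train_frac, seed)
  scores <- list(); models <- list()
  for (len in segment_lengths) {
    tr <- featurize_segments(segment_bursts(bursts[split$train, ], len,
                                            acc_rate), acc_rate)
    te <- featurize_segments(segment_bursts(bursts[split$test, ], len,
                                            acc_rate), acc_rate)
    model <- train_classifier(tr, seed = seed)
    pred <- predict(model, te)
    f <- f_measure(pred, te$behaviour, pooling)
    scores[[as.character(len)]] <- tibble::tibble(
      segment_length = len, class = names(f), F = unname(f)
    )
    models[[as.character(len)]] <- model
  }
  list(scores = do.call(rbind, scores), models = models)
}
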