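# Sequential floating forward selection (SFFS) with a randomized-tree
# ensemble evaluator scored by subject-grouped inner-CV mean F1.

#' Extremely-randomized-trees evaluator for feature selection
#'
#' Returns a train-and-predict closure around an extremely randomized tree
#' ensemble (random split points, here via ranger's `extratrees` split rule)
#' with case weights. The ensemble is deliberately light - feature selection
#' only needs a stable *ranking* of candidate subsets, not a polished
#' classifier.
#'
#' @param num_trees Trees per ensemble (default 50).
#' @param sample_fraction Per-tree subsample fraction (default 0.632).
#' @param min_node_size Minimal node size (default 10).
#' @return Function `(x_train, y_train, w_train, x_new, seed)` returning
#'   predicted labels for `x_new`.
#' @export
extratrees_evaluator <- function(num_trees = 50, sample_fraction = 0.632,
                                 min_node_size = 10) {
  force(num_trees); force(sample_fraction); force(min_node_size)
  function(x_train, y_train, w_train, x_new, seed = 1L) {
    fit <- ranger::ranger(
      x = x_train, y = y_train, case.weights = w_train,
      num.trees = num_trees, splitrule = "extratrees", num.random.splits = 1,
      sample.fraction = sample_fraction, min.node.size = min_node_size,
      num.threads = 1, seed = seed, oob.error = FALSE, verbose = FALSE
    )
    stats::predict(fit, data = x_new, num.threads = 1)$predictions
  }
}

# Mean F1 over the inner folds for one candidate column subset.
inner_cv_f1 <- function(X, y, subjects, cols, inner_folds, evaluator,
                        fold_seeds, positive = NULL) {
  scores <- vapply(seq_along(inner_folds), function(i) {
    f <- inner_folds[[i]]
    tr <- subjects %in% f$train_subjects
    va <- subjects %in% f$val_subjects
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < 2L || !any(va)) return(NA_real_)
    w <- class_weights(ytr)$obs
    pred <- evaluator(X[tr, cols, drop = FALSE], ytr, w,
                      X[va, cols, drop = FALSE], seed = fold_seeds[i])
    m <- evaluate_metrics(y[va], pred, classes = levels(y))
    if (!is.null(positive)) m$per_class$f1[m$per_class$class == positive]
    else m$macro$f1
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

#' Sequential floating forward feature selection
#'
#' Classic SFFS: at every iteration the feature whose addition maximises the
#' subject-grouped inner-CV mean F1 of the evaluator is added; after each
#' addition, any feature whose removal *strictly* improves the criterion is
#' floated out again (repeatedly). Selection stops when no addition improves
#' the criterion by more than `min_improve` or when `max_features` is
#' reached. The result is never empty: at minimum the single best feature is
#' returned. Subset scores are memoised, and the whole procedure is
#' deterministic given `seed`.
#'
#' @param features Numeric feature matrix or data frame (imputed; no NAs).
#' @param labels Class labels (factor or character).
#' @param groups Subject id per row (inner folds respect this grouping).
#' @param evaluator A train-and-predict closure, see [extratrees_evaluator()].
#' @param inner_k Inner folds (default 5).
#' @param max_features Selection cap (default 20).
#' @param min_improve Minimal criterion gain to accept an addition
#'   (default 0.002); the floating removals still require strict improvement.
#' @param positive For binary problems, the class whose F1 is the criterion;
#'   `NULL` uses the class-average F1.
#' @param seed Integer seed.
#' @return Character vector of selected feature names, with attributes
#'   `"score"` (criterion of the returned subset) and `"trace"` (data frame of
#'   the accepted steps).
#' @export
sffs_select <- function(features, labels, groups, evaluator = extratrees_evaluator(),
                        inner_k = 5L, max_features = 20L, min_improve = 0.002,
                        positive = NULL, seed = 1L) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("features must be imputed before selection", call. = FALSE)
  if (ncol(X) < 2L) stop("need at least 2 candidate features", call. = FALSE)
  y <- droplevels(as.factor(labels))
  subjects <- as.character(groups)
  plan <- grouped_kfold(subjects, k = min(inner_k, length(unique(subjects))),
                        seed = seed, inner_k = 0L)
  inner_folds <- plan$folds
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max, length(inner_folds))

  cache <- new.env(parent = emptyenv())
  score_of <- function(cols) {
    key <- paste(sort(cols), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- inner_cv_f1(X, y, subjects, cols, inner_folds, evaluator, fold_seeds, positive)
    cache[[key]] <- s
    s
  }

  all_cols <- colnames(X)
  selected <- character()
  best_score <- -Inf
  trace <- list()

  repeat {
    remaining <- setdiff(all_cols, selected)
    if (!length(remaining) || length(selected) >= max_features) break
    add_scores <- vapply(remaining, function(f) score_of(c(selected, f)), numeric(1))
    best_add <- remaining[which.max(add_scores)]
    gain <- max(add_scores) - best_score
    required <- if (length(selected) == 0L) -Inf else min_improve # never empty
    if (gain <= required) break
    selected <- c(selected, best_add)
    best_score <- max(add_scores)
    trace[[length(trace) + 1L]] <- data.frame(
      action = "add", feature = best_add, score = best_score, size = length(selected)
    )
    # floating backward removals
    while (length(selected) > 2L) {
      drop_scores <- vapply(selected, function(f) score_of(setdiff(selected, f)),
                            numeric(1))
      if (max(drop_scores) <= best_score) break
      worst <- selected[which.max(drop_scores)]
      selected <- setdiff(selected, worst)
      best_score <- max(drop_scores)
      trace[[length(trace) + 1L]] <- data.frame(
        action = "remove", feature = worst, score = best_score, size = length(selected)
      )
    }
  }
  structure(selected, score = best_score,
            trace = do.call(rbind, trace))
}
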