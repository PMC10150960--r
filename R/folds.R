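# Subject-grouped cross-validation plans, class weighting, and the
# imbalance-aware evaluation metrics.

balance_subjects <- function(counts, k) {
  # Greedy episode-count balancing: largest subjects first, each into the
  # currently lightest fold. `counts` is a named vector (subject -> episodes)
  # in the (already shuffled) tie-break order.
  ord <- order(-counts)
  fold_of <- integer(length(counts))
  names(fold_of) <- names(counts)
  totals <- numeric(k)
  for (i in ord) {
    j <- which.min(totals)
    fold_of[i] <- j
    totals[j] <- totals[j] + counts[i]
  }
  fold_of
}

#' Subject-grouped k-fold plan with nested inner folds
#'
#' Partitions subjects into `k` validation groups of near-equal episode
#' counts, so that no subject's observations can appear on both sides of a
#' fold. Each outer training set gets its own nested `inner_k`-fold plan built
#' the same way (used by the feature-selection wrapper).
#'
#' @param subjects Subject id per observation.
#' @param k Number of outer folds; must not exceed the number of subjects.
#' @param seed Integer seed (shuffles the tie-break order).
#' @param inner_k Number of nested folds per outer training set (0 = none);
#'   reduced to the training-subject count when necessary.
#' @return Object of class `fold_plan`: list with `k`, `seed` and `folds`,
#'   each fold holding `train_subjects`, `val_subjects` and `inner` (a list of
#'   nested folds with the same two components).
#' @export
grouped_kfold <- function(subjects, k, seed = 1L, inner_k = 5L) {
  subjects <- as.character(subjects)
  uniq <- unique(subjects)
  if (k > length(uniq)) {
    stop(sprintf("k = %d exceeds the number of subjects (%d)", k, length(uniq)),
         call. = FALSE)
  }
  set.seed(seed)
  build <- function(sub_ids, kk) {
    counts <- table(factor(subjects[subjects %in% sub_ids], levels = sub_ids))
    counts <- counts[sample(length(counts))] # seeded tie-break order
    fold_of <- balance_subjects(as.numeric(counts), kk)
    names(fold_of) <- names(counts)
    lapply(seq_len(kk), function(j) {
      val <- names(fold_of)[fold_of == j]
      list(train_subjects = setdiff(sub_ids, val), val_subjects = val)
    })
  }
  outer <- build(uniq, k)
  folds <- lapply(outer, function(f) {
    inner <- list()
    if (inner_k > 0L) {
      kk <- min(inner_k, length(f$train_subjects))
      inner <- build(f$train_subjects, kk)
    }
    c(f, list(inner = inner))
  })
  structure(list(k = k, seed = seed, folds = folds), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d outer folds (seed %d), %d nested folds each\n",
              x$k, x$seed, length(x$folds[[1]]$inner)))
  invisible(x)
}

#' Inverse-frequency class weights
#'
#' Weight for an observation of class i is `N_obs / (N_cl * N_obs_i)`, so the
#' weights sum to `N_obs` over the dataset and are all 1 under perfect
#' balance.
#'
#' @param labels Class label per observation; every class must occur.
#' @return List of class `class_weight_table`: `table` (class, count, weight),
#'   `obs` (per-observation weights), `n_obs`, `n_classes`.
#' @export
class_weights <- function(labels) {
  counts <- table(labels) # factor input keeps (and checks) declared levels
  if (any(counts == 0)) stop("every class must occur at least once", call. = FALSE)
  labels <- as.character(labels)
  n <- length(labels)
  ncl <- length(counts)
  w <- n / (ncl * as.numeric(counts))
  names(w) <- names(counts)
  structure(list(
    table = data.frame(class = names(counts), count = as.integer(counts),
                       weight = w, row.names = NULL, stringsAsFactors = FALSE),
    obs = unname(w[labels]), n_obs = n, n_classes = ncl
  ), class = "class_weight_table")
}

binary_mcc <- function(tp, fp, fn, tn) {
  d <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(d == 0)) return(0)
  (tp * tn - fp * fn) / sqrt(prod(d))
}

#' Classification metrics for imbalanced data
#'
#' Per-class precision, recall, F1 (harmonic mean of the two) and one-vs-rest
#' Matthews correlation coefficient, plus their class averages and the
#' multiclass MCC computed from the full confusion matrix. Zero-denominator
#' conventions: precision/recall/F1 are 0 when undefined, MCC is 0 when any
#' marginal is zero.
#'
#' @param y_true,y_pred Aligned label vectors.
#' @param classes Class set (default: observed union, sorted).
#' @return List of class `metric_set`: `per_class` (data frame), `macro`
#'   (class-average precision/recall/F1 and mean per-class MCC), `mcc`
#'   (multiclass MCC; equals the per-class value for binary problems),
#'   `confusion`.
#' @export
evaluate_metrics <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  cm <- table(factor(y_true, classes), factor(y_pred, classes))
  n <- length(y_true)

  per <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    tn <- n - tp - fp - fn
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    data.frame(class = cl, precision = precision, recall = recall, f1 = f1,
               mcc = binary_mcc(tp, fp, fn, tn), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)

  # multiclass MCC from the confusion matrix (reduces to the binary MCC when
  # there are two classes)
  s <- n
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  mcc_multi <- if (den == 0) 0 else (c_ * s - sum(p_k * t_k)) / den

  structure(list(
    per_class = per,
    macro = list(precision = mean(per$precision), recall = mean(per$recall),
                 f1 = mean(per$f1), mcc = mean(per$mcc)),
    mcc = mcc_multi,
    confusion = cm
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  print(x$per_class, ...)
  cat(sprintf("macro F1 %.3f | multiclass MCC %.3f\n", x$macro$f1, x$mcc))
  invisible(x)
}
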