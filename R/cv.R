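# The classification experiments: subject-grouped outer k-fold CV with nested
# SFFS, optional PCA feature space, class-weighted neural classifiers, and
# fold-level metric reporting.

#' PCA transform fitted on a training design
#'
#' Principal components of an (imputed, standardised) training matrix,
#' ordered by explained variance. The returned `transform` applies the
#' training-fold centering and rotation unchanged to new data.
#'
#' @param x Numeric training matrix (>= 2 rows, no NAs).
#' @return List of class `pca_transform`: `rotation`, `center`, `sdev`, and
#'   `transform(newdata)`.
#' @export
pca_transform <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 rows", call. = FALSE)
  if (anyNA(x)) stop("impute before PCA", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  structure(list(
    rotation = pc$rotation, center = pc$center, sdev = pc$sdev,
    transform = function(newdata) {
      scale(as.matrix(newdata), center = pc$center, scale = FALSE) %*% pc$rotation
    }
  ), class = "pca_transform")
}

# Train-fold preprocessing: mean imputation, then standardisation; constant
# columns are dropped. All statistics come from the training rows only.
fit_preprocessor <- function(Xtr) {
  mu <- colMeans(Xtr, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  impute <- function(X) {
    for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
    X
  }
  Xi <- impute(Xtr)
  sds <- apply(Xi, 2, stats::sd)
  keep <- which(sds > 1e-12)
  center <- colMeans(Xi)[keep]
  scale_ <- sds[keep]
  list(apply = function(X) {
    X <- impute(as.matrix(X))[, keep, drop = FALSE]
    scale(X, center = center, scale = scale_)
  }, kept = names(keep))
}

candidate_feature_columns <- function(features) {
  reg <- feature_registry()
  setdiff(intersect(reg$name, names(features)), reg$name[reg$group == "advisor"])
}

fit_fold_model <- function(features, labels, subjects, fold, space, objective,
                           positive_class = NULL, sffs_control = list(),
                           nn_control = list(), fold_seed = 1L) {
  tr <- subjects %in% fold$train_subjects
  va <- subjects %in% fold$val_subjects
  ytr <- droplevels(as.factor(labels[tr]))
  if (nlevels(ytr) < 2L) return(NULL)

  pre <- fit_preprocessor(as.matrix(features[tr, , drop = FALSE]))
  Xtr <- pre$apply(features[tr, , drop = FALSE])
  Xva <- pre$apply(features[va, , drop = FALSE])
  if (space == "pca") {
    pca <- pca_transform(Xtr)
    Str <- pca$transform(Xtr)
    Sva <- pca$transform(Xva)
    colnames(Str) <- colnames(Sva) <- paste0("PC", seq_len(ncol(Str)))
    keep <- which(pca$sdev > 1e-8)
    pre2 <- fit_preprocessor(Str[, keep, drop = FALSE])
    Xtr <- pre2$apply(Str[, keep, drop = FALSE])
    Xva <- pre2$apply(Sva[, keep, drop = FALSE])
  }

  sffs_args <- utils::modifyList(list(
    features = Xtr, labels = ytr, groups = subjects[tr],
    positive = positive_class, seed = fold_seed
  ), sffs_control)
  selected <- do.call(sffs_select, sffs_args)

  spec <- do.call(nn_spec, utils::modifyList(list(objective = objective), nn_control))
  w <- class_weights(ytr)$obs
  model <- fit_nn_classifier(Xtr[, selected, drop = FALSE], ytr, weights = w,
                             spec = spec, seed = fold_seed)
  pred <- predict(model, Xva[, selected, drop = FALSE])
  list(model = model, selected = selected, pred = pred,
       y_val = labels[va], val_subjects = fold$val_subjects)
}

#' Run a cross-validated classification experiment
#'
#' The full experimental protocol for one scenario: subject-grouped outer
#' `k`-fold CV; within each outer training sample, SFFS (on the raw features
#' or on training-fold principal components) with an extremely-randomized-tree
#' evaluator in a nested subject-grouped 5-fold CV; then a class-weighted
#' neural classifier (hidden width = selected subset size) trained per
#' objective and evaluated on the fold's validation sample. Bolus-advisor
#' features are excluded from the candidate set to maximise the usable sample.
#'
#' @param features Feature table from [featurize_cohort()] (must contain
#'   `subject_id` and `category`).
#' @param scenario `"ovr"` (binary one-vs-rest, separately per class) or
#'   `"multiclass"` (exclusive 3-class).
#' @param space `"raw"` or `"pca"`.
#' @param objective `"f1"`, `"recall"` or `"precision"`.
#' @param k Outer folds (default 10).
#' @param seed Integer seed controlling the fold plan and every downstream
#'   seeded step.
#' @param classes Classes analysed (default the three cause categories).
#' @param sffs_control Named overrides for [sffs_select()] (e.g.
#'   `max_features`, `inner_k`, `evaluator`).
#' @param nn_control Named overrides for [nn_spec()].
#' @param return_models Keep the per-fold fitted models (default FALSE).
#' @return Object of class `cv_report`: `folds` (fold-level metric rows),
#'   `summary` (mean and population SD per metric), `selected` (feature
#'   subsets per fold), `skipped` (folds without all classes in training),
#'   and optionally `models`.
#' @export
run_cv_experiment <- function(features, scenario = c("ovr", "multiclass"),
                              space = c("raw", "pca"),
                              objective = c("f1", "recall", "precision"),
                              k = 10L, seed = 1L,
                              classes = analysis_categories(),
                              sffs_control = list(), nn_control = list(),
                              return_models = FALSE) {
  scenario <- match.arg(scenario)
  space <- match.arg(space)
  objective <- match.arg(objective)
  stopifnot(all(c("subject_id", "category") %in% names(features)))

  subjects <- as.character(features$subject_id)
  labels <- as.character(features$category)
  X <- features[candidate_feature_columns(features)]
  plan <- grouped_kfold(subjects, k = k, seed = seed, inner_k = 0L)
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max, k)

  arms <- if (scenario == "ovr") classes else "multiclass"
  fold_rows <- list(); selected <- list(); models <- list(); skipped <- list()

  for (arm in arms) {
    if (scenario == "ovr") {
      y_arm <- factor(ifelse(labels == arm, arm, "rest"), levels = c("rest", arm))
      positive <- arm
    } else {
      y_arm <- factor(labels, levels = classes)
      positive <- NULL
    }
    for (i in seq_len(k)) {
      fold <- plan$folds[[i]]
      res <- fit_fold_model(X, y_arm, subjects, fold, space, objective,
                            positive_class = positive,
                            sffs_control = sffs_control, nn_control = nn_control,
                            fold_seed = fold_seeds[i])
      if (is.null(res)) {
        skipped[[length(skipped) + 1L]] <- data.frame(arm = arm, fold = i)
        warning(sprintf("fold %d (%s): a class is missing from training; skipped",
                        i, arm), call. = FALSE)
        next
      }
      m <- evaluate_metrics(res$y_val, res$pred, classes = levels(y_arm))
      rows <- if (scenario == "ovr") {
        pc <- m$per_class[m$per_class$class == arm, , drop = FALSE]
        data.frame(scenario = scenario, space = space, objective = objective,
                   class = arm, fold = i, f1 = pc$f1, recall = pc$recall,
                   precision = pc$precision, mcc = m$mcc,
                   n_val = length(res$y_val), stringsAsFactors = FALSE)
      } else {
        pc <- m$per_class
        rbind(
          data.frame(scenario = scenario, space = space, objective = objective,
                     class = pc$class, fold = i, f1 = pc$f1, recall = pc$recall,
                     precision = pc$precision, mcc = pc$mcc,
                     n_val = length(res$y_val), stringsAsFactors = FALSE),
          data.frame(scenario = scenario, space = space, objective = objective,
                     class = "class_average", fold = i, f1 = m$macro$f1,
                     recall = m$macro$recall, precision = m$macro$precision,
                     mcc = m$mcc, n_val = length(res$y_val),
                     stringsAsFactors = FALSE)
        )
      }
      fold_rows[[length(fold_rows) + 1L]] <- rows
      selected[[sprintf("%s_fold%02d", arm, i)]] <- res$selected
      if (return_models) models[[sprintf("%s_fold%02d", arm, i)]] <- res
    }
  }
  folds_df <- do.call(rbind, fold_rows)
  summary_df <- NULL
  if (!is.null(folds_df)) {
    agg <- function(metric) {
      stats::aggregate(folds_df[[metric]],
                       by = folds_df[c("scenario", "space", "objective", "class")],
                       FUN = function(v) c(mean = mean(v), sd = population_sd(v)))
    }
    parts <- lapply(c("f1", "recall", "precision", "mcc"), function(metric) {
      a <- agg(metric)
      data.frame(a[c("scenario", "space", "objective", "class")],
                 metric = metric, mean = a$x[, "mean"], sd = a$x[, "sd"],
                 stringsAsFactors = FALSE)
    })
    summary_df <- do.call(rbind, parts)
    rownames(summary_df) <- NULL
  }
  out <- list(folds = folds_df, summary = summary_df, selected = selected,
              skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
              plan = plan, scenario = scenario, space = space,
              objective = objective, seed = seed)
  if (return_models) out$models <- models
  structure(out, class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s / %s / objective %s, %d folds\n",
              x$scenario, x$space, x$objective, x$plan$k))
  if (!is.null(x$summary)) {
    s <- x$summary
    s$value <- sprintf("%.2f ± %.2f", s$mean, s$sd)
    print(utils::head(s[c("class", "metric", "value")], 20), row.names = FALSE)
  }
  invisible(x)
}
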