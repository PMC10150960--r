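# Small dense neural classifier used for the final per-fold models: three
# fully connected hidden layers (width = number of input features), ReLU,
# inverted dropout, observation-weighted cross-entropy, full-batch Adam.
# Checkpoint (and, for binary models, the decision threshold) are selected on
# an internal class-stratified 20% split to maximise the configured objective
# (F1, recall or precision).

#' Neural classifier specification
#'
#' @param objective Model-selection objective on the internal split: `"f1"`,
#'   `"recall"` or `"precision"`. For multiclass models the class-average of
#'   the metric is used; for binary models the positive-class metric.
#' @param hidden_layers Number of hidden layers (default 3).
#' @param dropout Dropout rate on hidden activations (default 0.6).
#' @param epochs Maximum training epochs (default 300).
#' @param patience Early-stopping patience on the internal objective
#'   (default 30 epochs).
#' @param learning_rate Adam step size (default 0.01).
#' @param batch_size Minibatch size (default 32); dropout masks are redrawn
#'   per batch.
#' @param val_fraction Internal model-selection split fraction (default 0.2).
#' @return List of class `nn_spec`.
#' @export
nn_spec <- function(objective = c("f1", "recall", "precision"),
                    hidden_layers = 3L, dropout = 0.6, epochs = 300L,
                    patience = 30L, learning_rate = 0.01, batch_size = 32L,
                    val_fraction = 0.2) {
  objective <- match.arg(objective)
  stopifnot(dropout >= 0, dropout < 1, hidden_layers >= 1, batch_size >= 1)
  structure(list(objective = objective, hidden_layers = hidden_layers,
                 dropout = dropout, epochs = epochs, patience = patience,
                 learning_rate = learning_rate, batch_size = batch_size,
                 val_fraction = val_fraction),
            class = "nn_spec")
}

relu <- function(x) x * (x > 0)

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

nn_forward <- function(params, X, dropout = 0, multiclass = FALSE) {
  H <- X
  keep <- 1 - dropout
  for (l in seq_along(params$W)[-length(params$W)]) {
    H <- relu(sweep(H %*% params$W[[l]], 2, params$b[[l]], `+`))
    if (dropout > 0) {
      mask <- matrix(stats::rbinom(ncol(H), 1, keep) / keep, nrow(H), ncol(H),
                     byrow = TRUE)
      H <- H * mask
    }
  }
  L <- length(params$W)
  Z <- sweep(H %*% params$W[[L]], 2, params$b[[L]], `+`)
  if (multiclass) softmax_rows(Z) else stats::plogis(Z)
}

objective_score <- function(objective, y_true, y_pred, classes, positive) {
  m <- evaluate_metrics(y_true, y_pred, classes = classes)
  if (!is.null(positive)) {
    m$per_class[[objective]][m$per_class$class == positive]
  } else {
    m$macro[[objective]]
  }
}

#' Train the neural classifier
#'
#' @param x Numeric matrix of (imputed, standardised) features; the hidden
#'   width equals `ncol(x)`.
#' @param y Factor of class labels. Binary models take the *last* level as the
#'   positive class; multiclass models use a softmax output over all levels.
#' @param weights Observation weights (e.g. [class_weights()]`$obs`);
#'   default inverse-frequency weights of `y`.
#' @param spec An [nn_spec()].
#' @param seed Integer seed (initialisation, dropout masks, internal split).
#' @return Object of class `nn_classifier` with the checkpointed parameters,
#'   the selected decision threshold (binary), class levels, and the training
#'   trace.
#' @export
fit_nn_classifier <- function(x, y, weights = NULL, spec = nn_spec(), seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("training data contain a single class", call. = FALSE)
  if (anyNA(x)) stop("features must be imputed before training", call. = FALSE)
  if (is.null(weights)) weights <- class_weights(y)$obs
  stopifnot(length(weights) == nrow(x), length(y) == nrow(x))

  multiclass <- nlevels(y) > 2L
  positive <- if (multiclass) NULL else levels(y)[2L]
  classes <- levels(y)
  set.seed(seed)

  # internal stratified split for checkpoint/threshold selection
  val_idx <- unlist(lapply(classes, function(cl) {
    idx <- which(y == cl)
    take <- max(1L, round(length(idx) * spec$val_fraction))
    sample(idx, min(take, length(idx) - 1L))
  }))
  tr_idx <- setdiff(seq_len(nrow(x)), val_idx)
  if (length(unique(y[tr_idx])) < 2L) stop("internal split left a single class", call. = FALSE)

  d <- ncol(x)
  width <- max(1L, d)
  out_dim <- if (multiclass) nlevels(y) else 1L
  dims <- c(d, rep(width, spec$hidden_layers), out_dim)
  init <- function(fan_in, fan_out) {
    matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
  }
  params <- list(
    W = lapply(seq_len(length(dims) - 1L), function(l) init(dims[l], dims[l + 1L])),
    b = lapply(seq_len(length(dims) - 1L), function(l) rep(0, dims[l + 1L]))
  )
  mom <- list(mW = lapply(params$W, function(w) w * 0),
              vW = lapply(params$W, function(w) w * 0),
              mb = lapply(params$b, function(b) b * 0),
              vb = lapply(params$b, function(b) b * 0))

  Xtr <- x[tr_idx, , drop = FALSE]
  wtr <- weights[tr_idx]
  wtr <- wtr / sum(wtr)
  Y <- if (multiclass) {
    stats::model.matrix(~ 0 + y[tr_idx])
  } else {
    matrix(as.numeric(y[tr_idx] == positive), ncol = 1)
  }
  Xva <- x[val_idx, , drop = FALSE]
  yva <- y[val_idx]

  predict_labels <- function(P) {
    if (multiclass) classes[max.col(P, ties.method = "first")]
    else ifelse(P[, 1] >= 0.5, classes[2L], classes[1L])
  }

  L <- length(params$W)
  keep <- 1 - spec$dropout
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(score = -Inf, params = params, epoch = 0L)
  since_best <- 0L
  trace <- numeric(0)
  step <- 0L
  n_tr <- nrow(Xtr)

  for (epoch in seq_len(spec$epochs)) {
    batches <- split(sample(n_tr), ceiling(seq_len(n_tr) / spec$batch_size))
    for (idx in batches) {
      Xb <- Xtr[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      wb <- wtr[idx] / sum(wtr[idx])
      # forward with per-batch dropout masks kept for backprop
      A <- vector("list", L + 1L)
      M <- vector("list", L)
      A[[1L]] <- Xb
      for (l in seq_len(L - 1L)) {
        H <- relu(sweep(A[[l]] %*% params$W[[l]], 2, params$b[[l]], `+`))
        if (spec$dropout > 0) {
          mask <- matrix(stats::rbinom(length(H), 1, keep) / keep, nrow(H), ncol(H))
          H <- H * mask
          M[[l]] <- mask
        }
        A[[l + 1L]] <- H
      }
      Z <- sweep(A[[L]] %*% params$W[[L]], 2, params$b[[L]], `+`)
      P <- if (multiclass) softmax_rows(Z) else stats::plogis(Z)

      dZ <- (P - Yb) * wb # weighted cross-entropy gradient (batch weights sum to 1)
      grads_W <- vector("list", L)
      grads_b <- vector("list", L)
      delta <- dZ
      for (l in rev(seq_len(L))) {
        grads_W[[l]] <- crossprod(A[[l]], delta)
        grads_b[[l]] <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(params$W[[l]])
          if (spec$dropout > 0) delta <- delta * M[[l - 1L]]
          delta <- delta * (A[[l]] > 0)
        }
      }
      step <- step + 1L
      lr_t <- spec$learning_rate * sqrt(1 - b2^step) / (1 - b1^step)
      for (l in seq_len(L)) {
        mom$mW[[l]] <- b1 * mom$mW[[l]] + (1 - b1) * grads_W[[l]]
        mom$vW[[l]] <- b2 * mom$vW[[l]] + (1 - b2) * grads_W[[l]]^2
        params$W[[l]] <- params$W[[l]] - lr_t * mom$mW[[l]] / (sqrt(mom$vW[[l]]) + eps)
        mom$mb[[l]] <- b1 * mom$mb[[l]] + (1 - b1) * grads_b[[l]]
        mom$vb[[l]] <- b2 * mom$vb[[l]] + (1 - b2) * grads_b[[l]]^2
        params$b[[l]] <- params$b[[l]] - lr_t * mom$mb[[l]] / (sqrt(mom$vb[[l]]) + eps)
      }
    }

    Pva <- nn_forward(params, Xva, dropout = 0, multiclass = multiclass)
    score <- objective_score(spec$objective, yva, predict_labels(Pva), classes, positive)
    trace[epoch] <- score
    if (score > best$score) {
      best <- list(score = score, params = params, epoch = epoch)
      since_best <- 0L
    } else {
      # on score ties keep the later checkpoint: the internal objective
      # saturates quickly on easy splits while training still improves
      if (score == best$score) best <- list(score = score, params = params,
                                            epoch = epoch)
      since_best <- since_best + 1L
      if (since_best >= spec$patience) break
    }
  }

  threshold <- 0.5
  if (!multiclass) {
    Pva <- nn_forward(best$params, Xva, dropout = 0, multiclass = FALSE)[, 1]
    grid <- seq(0.05, 0.95, by = 0.05)
    scores <- vapply(grid, function(th) {
      pred <- ifelse(Pva >= th, classes[2L], classes[1L])
      objective_score(spec$objective, yva, pred, classes, positive)
    }, numeric(1))
    threshold <- grid[which.max(scores)]
  }
  structure(list(params = best$params, classes = classes, positive = positive,
                 multiclass = multiclass, threshold = threshold, spec = spec,
                 width = width, best_epoch = best$epoch,
                 internal_score = best$score, trace = trace),
            class = "nn_classifier")
}

#' Predict from a fitted neural classifier
#'
#' @param object An `nn_classifier`.
#' @param newdata Feature matrix on the training standardisation scale.
#' @param type `"class"` for labels, `"prob"` for class probabilities.
#' @param ... Unused.
#' @return Character vector of labels or a probability matrix.
#' @export
predict.nn_classifier <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  P <- nn_forward(object$params, as.matrix(newdata), dropout = 0,
                  multiclass = object$multiclass)
  if (type == "prob") {
    colnames(P) <- if (object$multiclass) object$classes else object$positive
    return(P)
  }
  if (object$multiclass) {
    object$classes[max.col(P, ties.method = "first")]
  } else {
    ifelse(P[, 1] >= object$threshold, object$classes[2L], object$classes[1L])
  }
}

#' @export
print.nn_classifier <- function(x, ...) {
  cat(sprintf(
    "<nn_classifier> %s, %d hidden layers x %d units, dropout %.0f%%, best epoch %d (internal %s %.3f)\n",
    if (x$multiclass) sprintf("%d-class softmax", length(x$classes)) else "binary",
    x$spec$hidden_layers, x$width, 100 * x$spec$dropout, x$best_epoch,
    x$spec$objective, x$internal_score
  ))
  invisible(x)
}
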