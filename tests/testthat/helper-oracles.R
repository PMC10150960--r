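# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: loops and textbook formulas only.

# Confusion-matrix metrics by explicit counting.
oracle_metrics <- function(y_true, y_pred, positive) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(y_true)) {
    if (y_pred[i] == positive && y_true[i] == positive) tp <- tp + 1
    else if (y_pred[i] == positive) fp <- fp + 1
    else if (y_true[i] == positive) fn <- fn + 1
    else tn <- tn + 1
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  list(precision = precision, recall = recall, f1 = f1, mcc = mcc)
}

# Biased-moment skewness and excess kurtosis, written out longhand.
oracle_skewness <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m3 / m2^(3 / 2)
}
oracle_kurtosis <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m4 <- sum((x - m)^4) / n
  m4 / m2^2 - 3
}

# Plain logistic regression by hand-rolled IRLS (Newton-Raphson on the
# log-likelihood); independent of glm/glmer.
oracle_irls_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    grad <- t(X) %*% (y - p)
    H <- t(X) %*% (X * W)
    step <- solve(H, grad)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# A tiny deterministic diary around a known episode time, for feature tests.
# All record times are given as offsets in hours from the episode.
make_test_diary <- function(t_event = as.POSIXct("2024-03-06 14:00:00", tz = "UTC"),
                            glucose_offsets = numeric(), glucose_values = numeric(),
                            qa = NULL, basal = NULL, carbs = NULL,
                            advisor = NULL, quiz = NULL,
                            profile = subject_profile("T01", 45, "female", 20)) {
  at <- function(off) t_event + off * 3600
  d <- diary(
    profile = profile,
    glucose = data.frame(timestamp = at(glucose_offsets), value = glucose_values),
    qa_doses = if (is.null(qa)) data.frame(timestamp = at(numeric()), units = numeric())
               else data.frame(timestamp = at(qa$off), units = qa$units),
    basal_doses = if (is.null(basal)) data.frame(timestamp = at(numeric()), units = numeric())
                  else data.frame(timestamp = at(basal$off), units = basal$units),
    carbs = if (is.null(carbs)) data.frame(timestamp = at(numeric()), grams = numeric())
            else data.frame(timestamp = at(carbs$off), grams = carbs$grams),
    advisor = if (is.null(advisor)) hypocause:::empty_frame("advisor") else advisor,
    quiz = if (is.null(quiz)) hypocause:::empty_frame("quiz") else quiz
  )
  attr(d, "t_event") <- t_event
  d
}

# Simulate grouped binary data from the random-intercept logit model.
simulate_mixed_logit <- function(n_subjects, events_per_subject, beta0, beta1,
                                 sigma_b, seed) {
  set.seed(seed)
  g <- rep(seq_len(n_subjects), each = events_per_subject)
  b <- rnorm(n_subjects, 0, sigma_b)
  x <- rnorm(length(g))
  eta <- beta0 + beta1 * x + b[g]
  y <- rbinom(length(g), 1, 1 / (1 + exp(-eta)))
  list(x = x, y = y, groups = paste0("S", g))
}
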