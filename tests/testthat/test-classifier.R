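test_that("grouped k-fold plans partition subjects and balance episode counts", {
  set.seed(1)
  subjects <- rep(sprintf("S%02d", 1:54), times = sample(5:25, 54, replace = TRUE))
  plan <- grouped_kfold(subjects, k = 10, seed = 4, inner_k = 5)
  val_sets <- lapply(plan$folds, `[[`, "val_subjects")
  # every subject in exactly one outer validation set
  expect_setequal(unlist(val_sets), unique(subjects))
  expect_equal(sum(lengths(val_sets)), 54L)
  for (f in plan$folds) {
    expect_length(intersect(f$train_subjects, f$val_subjects), 0L)
    for (inner in f$inner) {
      expect_length(intersect(inner$train_subjects, inner$val_subjects), 0L)
      expect_true(all(c(inner$train_subjects, inner$val_subjects)
                      %in% f$train_subjects))
    }
  }
  # near-equal validation episode counts
  counts <- vapply(val_sets, function(s) sum(subjects %in% s), numeric(1))
  expect_lt(max(counts) - min(counts), max(table(subjects)) + 1)
  # determinism and error behaviour
  plan2 <- grouped_kfold(subjects, k = 10, seed = 4, inner_k = 5)
  expect_identical(plan, plan2)
  expect_error(grouped_kfold(c("a", "b"), k = 3), "exceeds")
})

test_that("class weights follow the inverse-frequency formula exactly", {
  w <- class_weights(rep(c("a", "b", "c"), each = 30))
  expect_true(all(w$table$weight == 1))
  w2 <- class_weights(rep(c("a", "b"), times = c(60, 30)))
  expect_equal(w2$table$weight, c(0.75, 1.5))
  expect_equal(sum(w2$obs), 90)
  expect_error(class_weights(factor(c("a", "a"), levels = c("a", "b"))), "class")
})

test_that("metrics match the confusion-matrix oracle", {
  # worked confusion matrix: TP 45, FP 15, FN 5, TN 35
  y_true <- rep(c("pos", "pos", "neg", "neg"), times = c(45, 5, 15, 35))
  y_pred <- rep(c("pos", "neg", "pos", "neg"), times = c(45, 5, 15, 35))
  m <- evaluate_metrics(y_true, y_pred)
  pc <- m$per_class[m$per_class$class == "pos", ]
  expect_equal(pc$precision, 0.75)
  expect_equal(pc$recall, 0.9)
  expect_equal(pc$f1, 2 * 0.75 * 0.9 / 1.65, tolerance = 1e-12)
  expect_equal(pc$mcc, (45 * 35 - 15 * 5) / sqrt(60 * 50 * 50 * 40),
               tolerance = 1e-12)
  # perfect predictions
  mp <- evaluate_metrics(y_true, y_true)
  expect_true(all(unlist(mp$per_class[-1]) == 1))
  expect_equal(mp$mcc, 1)
  # constant predictor: MCC 0 by convention
  mc <- evaluate_metrics(y_true, rep("pos", 100))
  expect_equal(mc$per_class$mcc, c(0, 0))
  expect_equal(mc$mcc, 0)
  expect_error(evaluate_metrics(y_true, y_pred[-1]), "length")
})

test_that("metrics agree with the oracle on random multiclass labels", {
  set.seed(14)
  classes <- c("A", "F", "M")
  for (i in 1:200) {
    n <- sample(10:60, 1)
    yt <- sample(classes, n, replace = TRUE)
    yp <- sample(classes, n, replace = TRUE)
    m <- evaluate_metrics(yt, yp, classes = classes)
    for (cl in classes) {
      o <- oracle_metrics(yt, yp, cl)
      row <- m$per_class[m$per_class$class == cl, ]
      expect_equal(row$precision, o$precision, tolerance = 1e-12)
      expect_equal(row$recall, o$recall, tolerance = 1e-12)
      expect_equal(row$f1, o$f1, tolerance = 1e-12)
      expect_equal(row$mcc, o$mcc, tolerance = 1e-12)
    }
  }
})

test_that("SFFS finds a separating feature immediately and never returns empty", {
  set.seed(6)
  n <- 240
  g <- rep(sprintf("S%02d", 1:12), each = 20)
  y <- factor(rep(c("rest", "pos"), length.out = n), levels = c("rest", "pos"))
  X <- matrix(rnorm(n * 12), n, dimnames = list(NULL, paste0("noise", 1:12)))
  X <- cbind(X, perfect = ifelse(y == "pos", 1, -1) + rnorm(n, 0, 0.05))
  sel <- sffs_select(X, y, g, positive = "pos", max_features = 4, seed = 2)
  expect_equal(attr(sel, "trace")$feature[1], "perfect")
  expect_true("perfect" %in% sel)

  # all-noise candidates: still returns the single best feature
  Xn <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("n", 1:6)))
  seln <- sffs_select(Xn, y, g, positive = "pos", max_features = 4, seed = 2)
  expect_gte(length(seln), 1L)
})

test_that("the floating step removes a redundant noisy proxy", {
  set.seed(9)
  n <- 420
  g <- rep(sprintf("S%02d", 1:14), each = 30)
  a <- rnorm(n); b <- rnorm(n)
  y <- factor(ifelse(a + b > 0, "pos", "rest"), levels = c("rest", "pos"))
  # noisy proxy of a+b: best single feature, redundant once a and b are in
  proxy <- a + b + rnorm(n, 0, 0.8)
  X <- cbind(a = a, b = b, proxy = proxy, n1 = rnorm(n), n2 = rnorm(n))
  sel <- sffs_select(X, y, g, positive = "pos", max_features = 4,
                     min_improve = 0.002, seed = 10)
  trace <- attr(sel, "trace")
  expect_equal(trace$feature[1], "proxy") # strongest alone
  expect_true(all(c("a", "b") %in% sel))
  expect_true("remove" %in% trace$action)
  expect_false("proxy" %in% sel) # floated out once a and b cover it
})

test_that("PCA transform conserves variance and yields orthogonal scores", {
  set.seed(12)
  X <- scale(matrix(rnorm(120 * 6), 120))
  X <- cbind(X, X[, 1]) # duplicated column -> rank deficiency
  p <- pca_transform(X)
  S <- p$transform(X)
  expect_equal(sum(apply(S, 2, var)), sum(apply(X, 2, var)), tolerance = 1e-9)
  cp <- crossprod(scale(S, center = TRUE, scale = FALSE))
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-6)
  expect_lt(min(p$sdev), 1e-9) # at least one zero-variance component
  expect_error(pca_transform(X[1, , drop = FALSE]), "2 rows")
})

test_that("the neural classifier fits separable data and honours its contract", {
  set.seed(18)
  X <- matrix(rnorm(400 * 7), 400)
  colnames(X) <- paste0("f", 1:7)
  X <- X[abs(X[, 1] + X[, 2]) > 0.3, ][1:300, ] # separable with a margin
  n <- nrow(X)
  y <- factor(ifelse(X[, 1] + X[, 2] > 0, "pos", "rest"), levels = c("rest", "pos"))
  X <- scale(X)
  model <- fit_nn_classifier(X, y, spec = nn_spec("f1"), seed = 4)
  expect_equal(model$width, 7L) # hidden width equals feature count
  expect_length(model$params$W, 4L) # 3 hidden + output
  expect_equal(dim(model$params$W[[2]]), c(7L, 7L))
  pred <- predict(model, X)
  m <- evaluate_metrics(y, pred, classes = levels(y))
  expect_gte(m$per_class$f1[m$per_class$class == "pos"], 0.99)

  # multiclass head is a 3-way softmax with rows summing to one
  y3 <- factor(sample(c("A", "F", "M"), n, replace = TRUE))
  m3 <- fit_nn_classifier(X, y3, spec = nn_spec("f1", epochs = 30), seed = 4)
  P <- predict(m3, X, type = "prob")
  expect_equal(ncol(P), 3L)
  expect_equal(rowSums(P), rep(1, n), tolerance = 1e-9)

  expect_error(fit_nn_classifier(X, factor(rep("pos", n))), "single class")
})

test_that("cross-validated experiments are deterministic and leak-free", {
  cfg <- cohort_config(n_subjects = 12, days = 100, episodes_per_subject = 8,
                       seed = 23)
  res <- generate_cohort(cfg)
  ft <- featurize_cohort(res$diaries)
  ctrl <- list(max_features = 3, evaluator = extratrees_evaluator(num_trees = 25))
  nnc <- list(epochs = 60, patience = 15)

  r1 <- run_cv_experiment(ft, "ovr", "raw", "f1", k = 3, seed = 5,
                          classes = "ACTIVITY", sffs_control = ctrl,
                          nn_control = nnc, return_models = TRUE)
  r2 <- run_cv_experiment(ft, "ovr", "raw", "f1", k = 3, seed = 5,
                          classes = "ACTIVITY", sffs_control = ctrl,
                          nn_control = nnc)
  expect_equal(r1$folds, r2$folds)
  expect_equal(r1$selected, r2$selected)

  # poisoning a validation subject must not change that fold's trained model
  poison_subj <- r1$plan$folds[[1]]$val_subjects[1]
  ft_poison <- ft
  feat_cols <- setdiff(names(ft), c("episode_id", "subject_id", "category"))
  ft_poison[ft_poison$subject_id == poison_subj, feat_cols] <- 999
  r3 <- run_cv_experiment(ft_poison, "ovr", "raw", "f1", k = 3, seed = 5,
                          classes = "ACTIVITY", sffs_control = ctrl,
                          nn_control = nnc, return_models = TRUE)
  key <- "ACTIVITY_fold01"
  expect_equal(r1$models[[key]]$model$params, r3$models[[key]]$model$params)
  expect_equal(r1$models[[key]]$selected, r3$models[[key]]$selected)

  # PCA space runs end to end on the same folds
  rp <- run_cv_experiment(ft, "ovr", "pca", "f1", k = 3, seed = 5,
                          classes = "ACTIVITY", sffs_control = ctrl,
                          nn_control = nnc)
  expect_true(all(grepl("^PC", unlist(rp$selected))))
})
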