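test_that("mixed logit with sigma_b fixed at zero equals plain logistic", {
  dat <- simulate_mixed_logit(40, 20, beta0 = -0.4, beta1 = 0.9, sigma_b = 0, seed = 101)
  fit0 <- fit_mixed_logit(mixed_logit_spec(dat$y, cbind(x = dat$x), dat$groups),
                          fix_sigma = 0)
  oracle <- oracle_irls_logistic(dat$x, dat$y)
  expect_lt(max(abs(fit0$beta - oracle)), 1e-3)
  expect_equal(fit0$sigma_b, 0)

  # the estimated-variance fit lands close by on zero-variance data
  fit <- fit_mixed_logit(mixed_logit_spec(dat$y, cbind(x = dat$x), dat$groups))
  expect_lt(fit$sigma_b, 0.35)
  expect_lt(max(abs(fit$beta - oracle)), 0.05)
  # invariants of the fit object
  expect_equal(fit$z, fit$beta / fit$se)
  expect_true(is.finite(fit$bic))
  ll_df <- 3 # beta0, beta1, sigma_b
  expect_equal(fit$bic, ll_df * log(fit$n_used) - 2 * fit$loglik)
})

test_that("mixed logit recovers nonzero random-intercept structure", {
  dat <- simulate_mixed_logit(120, 15, beta0 = 0.5, beta1 = -0.7, sigma_b = 1, seed = 7)
  fit <- fit_mixed_logit(mixed_logit_spec(dat$y, cbind(x = dat$x), dat$groups))
  expect_lt(abs(fit$beta[["x"]] - (-0.7)), 0.15)
  expect_lt(abs(fit$sigma_b - 1), 0.35)
})

test_that("degenerate model inputs are rejected", {
  dat <- simulate_mixed_logit(10, 10, 0, 0.5, 1, seed = 3)
  expect_error(
    fit_mixed_logit(mixed_logit_spec(rep(1, 100), cbind(x = dat$x), dat$groups)),
    "constant"
  )
  expect_error(mixed_logit_spec(c(dat$y[-1], NA), cbind(x = dat$x), dat$groups),
               "complete cases")
  expect_error(
    fit_mixed_logit(mixed_logit_spec(dat$y, cbind(x = dat$x), rep("A", 100))),
    "2 subjects"
  )
})

test_that("significance stars follow the conventional thresholds", {
  expect_equal(significance_stars(c(0.04, 0.004, 0.0004, 0.2)),
               c("*", "**", "***", ""))
  expect_equal(significance_stars(0.05), "") # boundary is exclusive
})

test_that("single-variable scan uses per-feature complete cases", {
  set.seed(11)
  n <- 400
  g <- paste0("S", rep(1:20, each = 20))
  b <- rnorm(20, 0, 0.8)[rep(1:20, each = 20)]
  strong <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 1.2 * strong + b))
  labels <- ifelse(y == 1, "ACTIVITY", "FOOD")
  feats <- data.frame(
    strong = strong,
    noise = rnorm(n),
    holey = ifelse(seq_len(n) %% 3 == 0, NA, rnorm(n)),
    tiny = c(rnorm(10), rep(NA, n - 10))
  )
  scan <- single_variable_scan(feats, labels, g, "ACTIVITY")
  expect_equal(scan$stars[scan$feature == "strong"], "***")
  expect_equal(scan$n[scan$feature == "holey"], sum(!is.na(feats$holey)))
  tiny_row <- scan[scan$feature == "tiny", ]
  expect_true(tiny_row$skipped)
  expect_match(tiny_row$skip_reason, "complete rows")
  # a pure-noise feature should rarely reach a star; at minimum its |z| here
  # is modest compared to the planted predictor
  expect_lt(abs(scan$z[scan$feature == "noise"]),
            abs(scan$z[scan$feature == "strong"]))
})

test_that("BIC ranking prefers informative features and respects tie order", {
  set.seed(21)
  n <- 600
  g <- paste0("S", rep(1:30, each = 20))
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.0 * x))
  labels <- ifelse(y == 1, "FOOD", "ACTIVITY")
  feats <- data.frame(noise1 = rnorm(n), info = x, noise2 = rnorm(n),
                      info_dup = x)
  ranked <- bic_rank_features(feats, labels, g, "FOOD")
  expect_equal(ranked[1], "info") # duplicated feature ties; input order decides
  expect_equal(ranked[2], "info_dup")
  scan <- attr(ranked, "scan")
  expect_equal(scan$bic[scan$feature == "info"],
               scan$bic[scan$feature == "info_dup"], tolerance = 1e-6)
  # informative single-feature model beats the noise models by BIC
  expect_lt(scan$bic[scan$feature == "info"],
            min(scan$bic[grep("noise", scan$feature)]))
})

test_that("VIF filter drops collinear columns and spares orthogonal designs", {
  # exactly orthogonal columns -> all VIFs 1, nothing dropped
  X <- qr.Q(qr(matrix(rnorm(200 * 4), 200)))
  colnames(X) <- paste0("q", 1:4)
  kept <- vif_filter(X)
  expect_setequal(as.character(kept), colnames(X))
  expect_true(all(abs(attr(kept, "vif") - 1) < 1e-3))

  # exact linear dependence: one of the three is dropped, remainder clean
  set.seed(5)
  x1 <- rnorm(300); x2 <- rnorm(300)
  X2 <- cbind(a = x1, b = x2, c = x1 + x2, d = rnorm(300))
  kept2 <- vif_filter(X2)
  expect_length(kept2, 3L)
  expect_true(all(attr(kept2, "vif") < 10))
  expect_length(attr(kept2, "dropped"), 1L)

  # the keep-priority protects the preferred column among exact ties
  kept3 <- vif_filter(X2[, c("a", "b", "c")], priority = c(3, 2, 1))
  expect_true("c" %in% kept3)
  expect_false("a" %in% kept3)

  # independent Gaussian columns at large n: no-op
  X3 <- matrix(rnorm(10000 * 5), 10000)
  colnames(X3) <- paste0("g", 1:5)
  expect_length(vif_filter(X3), 5L)
})

test_that("correlation pairs use an inclusive threshold", {
  set.seed(8)
  n <- 500
  base <- scale(rnorm(n))[, 1]
  ortho <- scale(residuals(lm(rnorm(n) ~ base)))[, 1]
  exact07 <- 0.7 * base + sqrt(1 - 0.49) * ortho # correlation exactly 0.7
  X <- data.frame(base = base, exact07 = exact07, dup = base,
                  indep = rnorm(n), const = rep(1, n))
  rep_ <- correlation_pairs(X)
  pair_key <- paste(rep_$pairs$feature_a, rep_$pairs$feature_b)
  expect_true("base dup" %in% pair_key || "dup base" %in% pair_key)
  expect_true(any(grepl("exact07", pair_key))) # rho = 0.7 is included
  expect_equal(rep_$undefined, "const")
  expect_false("indep" %in% rep_$features)
  # independent columns only -> empty report
  X0 <- data.frame(a = rnorm(n), b = rnorm(n))
  expect_equal(nrow(correlation_pairs(X0)$pairs), 0L)
})

test_that("adding an informative predictor never hurts the log-likelihood", {
  set.seed(31)
  n <- 500
  g <- paste0("S", rep(1:25, each = 20))
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.6 * x1 + 0.8 * x2))
  f1 <- fit_mixed_logit(mixed_logit_spec(y, cbind(x1 = x1), g))
  f2 <- fit_mixed_logit(mixed_logit_spec(y, cbind(x1 = x1, x2 = x2), g))
  expect_gte(f2$loglik, f1$loglik)
})

test_that("multiple regression excludes advisor features and reports stars", {
  cfg <- cohort_config(n_subjects = 16, days = 120, episodes_per_subject = 10,
                       seed = 19)
  res <- generate_cohort(cfg)
  ft <- featurize_cohort(res$diaries)
  rep_ <- multiple_regression_report(ft, ft$category, ft$subject_id,
                                     association_config(top_k = 12),
                                     categories = "ACTIVITY")
  expect_false(any(grepl("^ba_", rep_$table$feature)))
  expect_false("tod" %in% rep_$table$feature)
  expect_false("cos_tod" %in% rep_$table$feature)
  expect_true(all(rep_$table$stars == significance_stars(rep_$table$p)))
  expect_true(all(rep_$table$n == rep_$fits$ACTIVITY$n_used))
})
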