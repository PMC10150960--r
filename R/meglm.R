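# Mixed-effects logistic association analysis: random-intercept logit models
# per cause category, single-variable scans, BIC screening, VIF and
# correlation filtering, and the multiple-regression report.

#' Specify a random-intercept logistic model
#'
#' @param y Binary outcome vector (0/1), one element per event.
#' @param X Numeric design matrix or data frame of predictors (no intercept
#'   column; one is always added).
#' @param groups Subject identifier per event (the random-intercept grouping).
#' @param offset Optional linear-predictor offset (default 0).
#' @return List of class `mixed_logit_spec` with complete-case-validated,
#'   aligned components.
#' @export
mixed_logit_spec <- function(y, X, groups, offset = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y)
  stopifnot(nrow(X) == n, length(groups) == n)
  if (is.null(offset)) offset <- rep(0, n)
  stopifnot(length(offset) == n)
  if (anyNA(y) || anyNA(X) || anyNA(groups)) {
    stop("mixed_logit_spec requires complete cases (drop missing rows first)",
         call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(y = as.numeric(y), X = X, groups = as.factor(groups),
                 offset = as.numeric(offset)), class = "mixed_logit_spec")
}

#' Fit a random-intercept logistic model
#'
#' Maximises the marginal likelihood of a logit model with a per-subject
#' random intercept by adaptive Gauss-Hermite quadrature (lme4 backend,
#' `nAGQ` nodes, default 15). Wald standard errors, z statistics and two-sided
#' p-values are reported for the fixed effects, together with the
#' random-intercept SD, the maximised marginal log-likelihood and
#' BIC = k ln(n) - 2 lnL.
#'
#' @param spec A [mixed_logit_spec()].
#' @param nAGQ Number of quadrature nodes (>= 1; 1 = Laplace).
#' @param fix_sigma Optionally fix the random-intercept SD. The only
#'   supported fixed value is 0, under which the model degenerates exactly to
#'   plain logistic regression (fitted by IRLS); `NULL` (default) estimates
#'   `sigma_b` by maximum likelihood.
#' @return Object of class `mixed_logit_fit`: `beta`, `se`, `z`, `p`
#'   (named, intercept first), `sigma_b`, `loglik`, `bic`, `n_used`,
#'   `converged`, `messages`, and `deviance_residuals`.
#' @export
fit_mixed_logit <- function(spec, nAGQ = 15, fix_sigma = NULL) {
  stopifnot(inherits(spec, "mixed_logit_spec"))
  n <- length(spec$y)
  f <- ncol(spec$X)
  if (n < f + 2) stop("need n >= f + 2 observations", call. = FALSE)
  if (nlevels(droplevels(spec$groups)) < 2) stop("need >= 2 subjects", call. = FALSE)
  if (length(unique(spec$y)) < 2) stop("outcome is constant", call. = FALSE)

  if (!is.null(fix_sigma)) {
    if (!identical(as.numeric(fix_sigma), 0)) {
      stop("only fix_sigma = 0 (plain logistic submodel) is supported", call. = FALSE)
    }
    g <- stats::glm.fit(cbind("(Intercept)" = 1, spec$X), spec$y,
                        family = stats::binomial(), offset = spec$offset)
    beta <- g$coefficients
    # observed information from the IRLS working weights at the optimum
    W <- g$weights
    Xd <- cbind(1, spec$X)
    se <- sqrt(diag(solve(crossprod(Xd, Xd * W))))
    names(se) <- names(beta)
    z <- beta / se
    ll <- -g$deviance / 2
    k <- f + 1
    return(structure(list(
      beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
      sigma_b = 0, loglik = ll, bic = k * log(n) - 2 * ll,
      n_used = n, n_groups = nlevels(droplevels(spec$groups)),
      converged = g$converged, messages = character(),
      deviance_residuals = summary(sign(spec$y - g$fitted.values) *
                                     sqrt(stats::binomial()$dev.resids(
                                       spec$y, g$fitted.values, 1)))
    ), class = "mixed_logit_fit"))
  }

  # fit on unit-SD columns for numerical stability (PIRLS is fragile with
  # widely different predictor scales); coefficients are mapped back below
  col_sd <- apply(spec$X, 2, stats::sd)
  col_sd[col_sd == 0 | !is.finite(col_sd)] <- 1
  Xs <- sweep(spec$X, 2, col_sd, `/`)
  dat <- data.frame(.y = spec$y, Xs, .g = droplevels(spec$groups),
                    .off = spec$offset, check.names = FALSE)
  xn <- colnames(spec$X)
  fml <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", xn), collapse = " + "), "+ (1 | .g)"
  ))
  msgs <- character()
  run_glmer <- function(nodes) {
    withCallingHandlers(
      lme4::glmer(fml, data = dat, family = stats::binomial(), nAGQ = nodes,
                  offset = dat$.off,
                  control = lme4::glmerControl(optimizer = "bobyqa",
                                               calc.derivs = FALSE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      }
    )
  }
  fit <- tryCatch(run_glmer(nAGQ), error = function(e) e)
  if (inherits(fit, "error") && nAGQ > 1) {
    # quadrature fits occasionally fail on hard designs; fall back to Laplace
    msgs <- c(msgs, paste("nAGQ fit failed, refit with Laplace:",
                          conditionMessage(fit)))
    fit <- tryCatch(run_glmer(1), error = function(e) e)
  }
  if (inherits(fit, "error")) stop(conditionMessage(fit), call. = FALSE)
  scale_back <- c(1, col_sd) # intercept unscaled
  se_unit <- sqrt(diag(as.matrix(stats::vcov(fit)))) # on the unit-SD scale
  if (any(!is.finite(se_unit)) || any(se_unit > 100)) {
    stop("apparent complete separation: some Wald SEs are unbounded", call. = FALSE)
  }
  beta <- lme4::fixef(fit) / scale_back
  se <- se_unit / scale_back
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  converged <- length(msgs) == 0 &&
    isTRUE(fit@optinfo$conv$opt == 0) &&
    length(fit@optinfo$conv$lme4) == 0
  structure(list(
    beta = beta, se = se, z = z, p = p,
    sigma_b = sqrt(unname(lme4::VarCorr(fit)[[".g"]][1, 1])),
    loglik = as.numeric(ll), bic = k * log(n) - 2 * as.numeric(ll),
    n_used = n, n_groups = nlevels(dat$.g),
    converged = converged, messages = msgs,
    deviance_residuals = summary(stats::residuals(fit, type = "deviance"))
  ), class = "mixed_logit_fit")
}

#' @export
print.mixed_logit_fit <- function(x, ...) {
  cat(sprintf("<mixed_logit_fit> n = %d, %d subjects, sigma_b = %.3f, BIC = %.1f%s\n",
              x$n_used, x$n_groups, x$sigma_b, x$bic,
              if (x$converged) "" else " [not converged]"))
  tab <- data.frame(beta = x$beta, se = x$se, z = x$z, p = signif(x$p, 3),
                    stars = significance_stars(x$p))
  print(tab, ...)
  invisible(x)
}

#' Significance stars at the conventional thresholds
#'
#' `"*"` for p < 0.05, `"**"` for p < 0.01, `"***"` for p < 0.001.
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Single-variable mixed-logit scan
#'
#' Fits one random-intercept logit model per feature for the one-vs-rest
#' outcome of `category`, using each feature's own complete cases (so features
#' with different missingness use as much data as available). Features are
#' centred (not scaled) on their complete cases before fitting. Features with
#' fewer than `min_rows` complete rows, zero variance, or a failing fit are
#' skipped with a recorded reason.
#'
#' @param features Data frame of numeric feature columns.
#' @param labels Episode category labels (character), aligned with rows.
#' @param groups Subject ids, aligned with rows.
#' @param category Target category (one-vs-rest outcome).
#' @param min_rows Minimum complete rows to fit a feature (default 20).
#' @param nAGQ Quadrature nodes for [fit_mixed_logit()].
#' @return Data frame of class `association_scan`: one row per feature with
#'   `feature`, `category`, `beta`, `se`, `z`, `p`, `stars`, `n`, `bic`,
#'   `converged`, `skipped`, `skip_reason`.
#' @export
single_variable_scan <- function(features, labels, groups, category,
                                 min_rows = 20, nAGQ = 15) {
  stopifnot(nrow(features) == length(labels), length(labels) == length(groups))
  y_all <- as.numeric(labels == category)
  rows <- lapply(names(features), function(fn) {
    x <- features[[fn]]
    ok <- !is.na(x)
    row <- data.frame(feature = fn, category = category, beta = NA_real_,
                      se = NA_real_, z = NA_real_, p = NA_real_, stars = "",
                      n = sum(ok), bic = NA_real_, converged = NA,
                      skipped = TRUE, skip_reason = "", stringsAsFactors = FALSE)
    if (sum(ok) < min_rows) {
      row$skip_reason <- sprintf("only %d complete rows", sum(ok))
      return(row)
    }
    xs <- x[ok] - mean(x[ok])
    if (stats::var(xs) == 0) {
      row$skip_reason <- "constant on complete rows"
      return(row)
    }
    if (length(unique(y_all[ok])) < 2) {
      row$skip_reason <- "outcome constant on complete rows"
      return(row)
    }
    fit <- tryCatch(
      fit_mixed_logit(mixed_logit_spec(y_all[ok], matrix(xs, dimnames = list(NULL, fn)),
                                       groups[ok]), nAGQ = nAGQ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      row$skip_reason <- conditionMessage(fit)
      return(row)
    }
    row$beta <- unname(fit$beta[2L]); row$se <- unname(fit$se[2L])
    row$z <- unname(fit$z[2L]); row$p <- unname(fit$p[2L])
    row$stars <- significance_stars(row$p)
    row$bic <- fit$bic; row$converged <- fit$converged; row$skipped <- FALSE
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("association_scan", class(out))
  out
}

#' Rank features by single-feature-model BIC
#'
#' Features sorted ascending by the BIC of their single-feature
#' random-intercept logit model for `category`; ties are broken by the input
#' column order. Skipped features rank last.
#'
#' @inheritParams single_variable_scan
#' @param scan Optional precomputed [single_variable_scan()] result (avoids
#'   refitting).
#' @return Character vector of feature names, best fit first, with the scan
#'   attached as attribute `"scan"`.
#' @export
bic_rank_features <- function(features, labels, groups, category,
                              scan = NULL, min_rows = 20, nAGQ = 15) {
  if (is.null(scan)) {
    scan <- single_variable_scan(features, labels, groups, category,
                                 min_rows = min_rows, nAGQ = nAGQ)
  }
  ord <- order(is.na(scan$bic), scan$bic, seq_len(nrow(scan)))
  ranked <- scan$feature[ord][!is.na(scan$bic[ord])]
  attr(ranked, "scan") <- scan
  ranked
}

# VIF of each column of a complete-case design (intercept always included in
# the auxiliary regressions). Infinite for exactly collinear or constant cols.
compute_vifs <- function(X) {
  p <- ncol(X)
  vapply(seq_len(p), function(j) {
    yj <- X[, j]
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(Inf)
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, yj)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative variance-inflation-factor filter
#'
#' Repeatedly drops the column with the largest VIF while any VIF is at or
#' above `threshold`. Exactly collinear columns have infinite VIF and are
#' dropped first. Ties (several columns sharing the maximal, possibly
#' infinite, VIF) are broken by `priority`: the column with the *largest*
#' priority value is dropped, so callers can protect informative features
#' (e.g. by passing BIC ranks).
#'
#' @param X Numeric complete-case design matrix or data frame (>= 2 columns).
#' @param threshold VIF threshold (default 10, inclusive: VIF >= 10 drops).
#' @param priority Numeric vector aligned with columns; lower = keep
#'   preferentially. Default is the column order.
#' @return Character vector of retained column names, with the final VIFs
#'   attached as attribute `"vif"` and the dropped columns as `"dropped"`.
#' @export
vif_filter <- function(X, threshold = 10, priority = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot(ncol(X) >= 2, nrow(X) > ncol(X), !anyNA(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(priority)) priority <- seq_len(ncol(X))
  stopifnot(length(priority) == ncol(X))
  names(priority) <- colnames(X)

  keep <- colnames(X)
  dropped <- character()
  repeat {
    if (length(keep) < 2L) break
    v <- compute_vifs(X[, keep, drop = FALSE])
    names(v) <- keep
    if (max(v) < threshold) break
    worst <- which(v == max(v))
    drop_j <- worst[which.max(priority[keep][worst])]
    dropped <- c(dropped, keep[drop_j])
    keep <- keep[-drop_j]
  }
  final_vif <- if (length(keep) >= 2L) {
    stats::setNames(compute_vifs(X[, keep, drop = FALSE]), keep)
  } else stats::setNames(rep(1, length(keep)), keep)
  structure(keep, vif = final_vif, dropped = dropped)
}

#' Report highly correlated feature pairs
#'
#' Lists all unordered pairs of (by default non-binary) features whose
#' pairwise-complete Pearson correlation is at or above `rho_threshold` in
#' absolute value, together with the correlation submatrix of the implicated
#' features. Constant columns have undefined correlations and are reported
#' separately.
#'
#' @param X Data frame or matrix of numeric features.
#' @param rho_threshold Inclusive absolute-correlation threshold (default 0.7).
#' @param drop_binary Exclude columns with at most two distinct observed
#'   values (default TRUE).
#' @return List with `pairs` (data frame `feature_a`, `feature_b`, `rho`),
#'   `features` (implicated names), `cor_matrix` (their submatrix), and
#'   `undefined` (constant columns).
#' @export
correlation_pairs <- function(X, rho_threshold = 0.7, drop_binary = TRUE) {
  X <- as.data.frame(X)
  nuniq <- vapply(X, function(x) length(unique(x[!is.na(x)])), integer(1))
  undefined <- names(X)[nuniq <= 1L]
  use <- if (drop_binary) names(X)[nuniq > 2L] else setdiff(names(X), undefined)
  if (length(use) < 2L) {
    return(list(pairs = data.frame(feature_a = character(), feature_b = character(),
                                   rho = numeric()),
                features = character(), cor_matrix = NULL, undefined = undefined))
  }
  cm <- suppressWarnings(stats::cor(as.matrix(X[use]), use = "pairwise.complete.obs"))
  hits <- which(abs(cm) >= rho_threshold & upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(
    feature_a = rownames(cm)[hits[, 1]],
    feature_b = colnames(cm)[hits[, 2]],
    rho = cm[hits], stringsAsFactors = FALSE
  )
  pairs <- pairs[!is.na(pairs$rho), , drop = FALSE]
  feats <- sort(unique(c(pairs$feature_a, pairs$feature_b)))
  list(pairs = pairs, features = feats,
       cor_matrix = if (length(feats)) cm[feats, feats, drop = FALSE] else NULL,
       undefined = undefined)
}

#' Association configuration
#'
#' @param top_k Number of best-BIC features entering multiple regression.
#' @param vif_threshold VIF filter threshold.
#' @param rho_threshold Correlation-report threshold.
#' @param min_complete Minimum fraction of non-missing rows a feature needs to
#'   enter the multiple regression (keeps the shared complete-case set from
#'   collapsing).
#' @param min_rows Minimum complete rows per single-variable fit.
#' @param nAGQ Quadrature nodes.
#' @param epv Optional events-per-variable cap: when set, the number of
#'   multiple-regression predictors is additionally capped at (minority
#'   outcome count) / `epv`. Default `NULL`: instead of a hard cap, the
#'   design is reduced (worst-BIC features first) only when it is actually
#'   separable/unidentifiable.
#' @return List of class `association_config`.
#' @export
association_config <- function(top_k = 40, vif_threshold = 10, rho_threshold = 0.7,
                               min_complete = 0.8, min_rows = 20, nAGQ = 15,
                               epv = NULL) {
  structure(list(top_k = top_k, vif_threshold = vif_threshold,
                 rho_threshold = rho_threshold, min_complete = min_complete,
                 min_rows = min_rows, nAGQ = nAGQ, epv = epv),
            class = "association_config")
}

#' Multiple-regression association report
#'
#' For each analysed cause category: excludes the bolus-advisor features and
#' the raw time-of-day, drops features with completeness below
#' `min_complete`, screens the remainder to the `top_k` best single-feature
#' BICs, restricts to the shared complete-case rows, centres (but does not
#' scale) the design, applies the VIF filter (ties broken in favour of
#' better-BIC features), and fits one multi-predictor random-intercept logit
#' model.
#'
#' @param features Feature table as from [featurize_cohort()] (the canonical
#'   and auxiliary columns; id columns are ignored).
#' @param labels Category labels aligned with rows.
#' @param groups Subject ids aligned with rows.
#' @param config An [association_config()].
#' @param categories Categories to analyse (default the three cause classes).
#' @return List of class `association_report`: `table` (combined rows
#'   `feature`, `category`, `beta`, `se`, `z`, `p`, `stars`, `n`), `fits`
#'   (per-category `mixed_logit_fit`), `selected` (features per category),
#'   `scans` (per-category single-variable scans of the candidate set).
#' @export
multiple_regression_report <- function(features, labels, groups,
                                       config = association_config(),
                                       categories = analysis_categories()) {
  reg <- feature_registry()
  # cos_tod is the exact affine complement of sin_tod (their sum is 12 hours
  # by construction), so only sin_tod enters the multi-predictor design; its
  # coefficient carries the whole time-of-day effect.
  candidates <- setdiff(intersect(reg$name, names(features)),
                        c(reg$name[reg$group == "advisor"], "cos_tod"))
  Xall <- features[candidates]

  completeness <- vapply(Xall, function(x) mean(!is.na(x)), numeric(1))
  eligible <- names(completeness)[completeness >= config$min_complete]

  tables <- list(); fits <- list(); selected <- list(); scans <- list()
  for (cat in categories) {
    scan <- single_variable_scan(Xall[eligible], labels, groups, cat,
                                 min_rows = config$min_rows, nAGQ = config$nAGQ)
    scans[[cat]] <- scan
    ranked <- bic_rank_features(Xall[eligible], labels, groups, cat, scan = scan)
    screened <- utils::head(ranked, config$top_k)

    cc <- stats::complete.cases(Xall[screened])
    if (!is.null(config$epv)) {
      y_cc <- as.numeric(labels[cc] == cat)
      minority <- min(sum(y_cc), sum(1 - y_cc))
      cap <- max(2L, floor(minority / config$epv))
      if (length(screened) > cap) {
        screened <- screened[seq_len(cap)]
        cc <- stats::complete.cases(Xall[screened])
      }
    }
    Xcc <- as.matrix(Xall[cc, screened, drop = FALSE])
    keep_var <- apply(Xcc, 2, function(x) stats::var(x) > 0)
    Xcc <- Xcc[, keep_var, drop = FALSE]
    Xcc <- scale(Xcc, center = TRUE, scale = FALSE)

    vkeep <- vif_filter(Xcc, threshold = config$vif_threshold,
                        priority = match(colnames(Xcc), screened))
    Xfit <- Xcc[, vkeep, drop = FALSE]
    if (qr(Xfit)$rank < ncol(Xfit)) {
      stop("rank-deficient design after VIF filtering; offending columns among: ",
           paste(colnames(Xfit), collapse = ", "), call. = FALSE)
    }
    y <- as.numeric(labels[cc] == cat)

    # Identifiability backoff: an over-rich screened set can make the classes
    # (quasi-)separable, leaving the Wald information unbounded. Features are
    # shed worst-BIC-first, with a cheap plain-logit separation pre-check,
    # until the mixed model is estimable.
    rank_of <- stats::setNames(match(colnames(Xfit), screened), colnames(Xfit))
    shed <- function(X) { # drop the single worst-BIC column: reduce only as
      # far as identifiability requires
      ord <- order(rank_of[colnames(X)])
      X[, ord[seq_len(ncol(X) - 1L)], drop = FALSE]
    }
    glm_separable <- function(X) {
      Z <- sweep(X, 2, pmax(apply(X, 2, stats::sd), 1e-12), `/`)
      g <- suppressWarnings(stats::glm.fit(cbind(1, Z), y,
                                           family = stats::binomial()))
      any(abs(g$coefficients[-1]) > 15, na.rm = TRUE) ||
        all(abs(g$fitted.values - y) < 1e-6)
    }
    while (ncol(Xfit) > 2L && glm_separable(Xfit)) Xfit <- shed(Xfit)
    fit <- NULL
    repeat {
      fit <- tryCatch(
        fit_mixed_logit(mixed_logit_spec(y, Xfit, groups[cc]), nAGQ = config$nAGQ),
        error = function(e) e
      )
      if (!inherits(fit, "error") || ncol(Xfit) <= 2L) break
      # separation and PIRLS non-convergence are the same pathology here: the
      # design is too rich for the outcome; shed and retry
      if (!grepl("separation|pwrss|PIRLS|step-halvings", conditionMessage(fit))) {
        stop(fit)
      }
      Xfit <- shed(Xfit)
    }
    if (inherits(fit, "error")) stop(fit)
    fits[[cat]] <- fit
    selected[[cat]] <- colnames(Xfit)
    idx <- seq_along(fit$beta)[-1L]
    tables[[cat]] <- data.frame(
      feature = names(fit$beta)[idx], category = cat,
      beta = unname(fit$beta[idx]), se = unname(fit$se[idx]),
      z = unname(fit$z[idx]), p = unname(fit$p[idx]),
      stars = significance_stars(unname(fit$p[idx])),
      n = fit$n_used, stringsAsFactors = FALSE
    )
  }
  structure(list(table = do.call(rbind, c(tables, list(make.row.names = FALSE))),
                 fits = fits, selected = selected, scans = scans,
                 config = config),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat("<association_report>\n")
  for (cat_k in names(x$fits)) {
    f <- x$fits[[cat_k]]
    cat(sprintf("  %s: %d predictors, n = %d%s\n", cat_k, length(x$selected[[cat_k]]),
                f$n_used, if (f$converged) "" else " [not converged]"))
  }
  invisible(x)
}
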