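# End-to-end orchestration: simulate -> featurize -> associate -> classify,
# persisting every intermediate with a seed manifest, plus the human-readable
# report rendering.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()].
#' @param window A [window_config()].
#' @param association An [association_config()].
#' @param experiments List of experiment descriptors, each a list with
#'   `scenario`, `space`, `objective` (see [run_cv_experiment()]).
#' @param k Outer CV folds.
#' @param analysis_seed Seed for the fold plans and classifiers (the cohort
#'   has its own seed inside `cohort`); all randomness is controlled by these
#'   two explicit seeds.
#' @param sffs_control,nn_control Overrides passed through to
#'   [run_cv_experiment()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), window = window_config(),
                            association = association_config(),
                            experiments = list(
                              list(scenario = "ovr", space = "raw", objective = "f1")
                            ),
                            k = 10L, analysis_seed = 1L,
                            sffs_control = list(), nn_control = list()) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(window, "window_config"),
            inherits(association, "association_config"))
  structure(list(cohort = cohort, window = window, association = association,
                 experiments = experiments, k = as.integer(k),
                 analysis_seed = as.integer(analysis_seed),
                 sffs_control = sffs_control, nn_control = nn_control),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> featurize -> associate -> classify, persisting every
#' intermediate artifact under `out_dir`: `diaries/` (CSV tables plus
#' `ground_truth.csv`), `features.csv` and `features_schema.json`,
#' `assoc/single_scan.csv` and `assoc/multiple_regression.csv`, `report/`
#' (fold-level and summary CV tables, selected features, rendered text
#' summaries) and `manifest.json` recording the seeds. A rerun with the same
#' configuration reproduces the same artifacts; a stage failure aborts with a
#' stage-scoped message, retaining the artifacts already written.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- stage("simulate", {
    res <- generate_cohort(config$cohort)
    dd <- file.path(out_dir, "diaries")
    write_diary_tables(res$diaries, dd)
    tr <- res$truth
    tr$timestamp <- format_diary_time(tr$timestamp)
    utils::write.csv(tr, file.path(dd, "ground_truth.csv"), row.names = FALSE, na = "")
    res
  })

  features <- stage("featurize", {
    ft <- featurize_cohort(sim$diaries, config$window)
    utils::write.csv(ft, file.path(out_dir, "features.csv"), row.names = FALSE, na = "")
    jsonlite::write_json(feature_registry(), file.path(out_dir, "features_schema.json"),
                         dataframe = "rows", pretty = TRUE)
    ft
  })

  assoc <- stage("associate", {
    dir.create(file.path(out_dir, "assoc"), showWarnings = FALSE)
    feat_cols <- c(feature_registry()$name, extra_feature_names())
    Xall <- features[intersect(feat_cols, names(features))]
    scans <- lapply(analysis_categories(), function(cat_k) {
      single_variable_scan(Xall, features$category, features$subject_id, cat_k,
                           min_rows = config$association$min_rows,
                           nAGQ = config$association$nAGQ)
    })
    single <- do.call(rbind, scans)
    utils::write.csv(single, file.path(out_dir, "assoc", "single_scan.csv"),
                     row.names = FALSE, na = "")
    multi <- multiple_regression_report(features, features$category,
                                        features$subject_id, config$association)
    utils::write.csv(multi$table, file.path(out_dir, "assoc", "multiple_regression.csv"),
                     row.names = FALSE, na = "")
    list(single = single, multiple = multi)
  })

  cv_reports <- stage("classify", {
    dir.create(file.path(out_dir, "report"), showWarnings = FALSE)
    reports <- lapply(config$experiments, function(ex) {
      run_cv_experiment(features, scenario = ex$scenario, space = ex$space,
                        objective = ex$objective, k = config$k,
                        seed = config$analysis_seed,
                        sffs_control = config$sffs_control,
                        nn_control = config$nn_control)
    })
    folds <- do.call(rbind, lapply(reports, `[[`, "folds"))
    summaries <- do.call(rbind, lapply(reports, `[[`, "summary"))
    utils::write.csv(folds, file.path(out_dir, "report", "cv_report.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(summaries, file.path(out_dir, "report", "cv_summary.csv"),
                     row.names = FALSE, na = "")
    jsonlite::write_json(lapply(reports, `[[`, "selected"),
                         file.path(out_dir, "report", "selected_features.json"),
                         pretty = TRUE)
    reports
  })

  stage("report", {
    write_report(assoc = assoc, cv = cv_reports, dir = file.path(out_dir, "report"))
  })

  manifest <- list(
    package = "hypocause",
    version = as.character(utils::packageVersion("hypocause")),
    cohort_seed = config$cohort$seed,
    analysis_seed = config$analysis_seed,
    n_subjects = config$cohort$n_subjects,
    days = config$cohort$days,
    k = config$k,
    experiments = config$experiments,
    n_episodes = nrow(features)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Format one association-table cell
#'
#' `beta` with significance stars and the Wald z statistic in parentheses,
#' e.g. `"0.5* (2.1)"`.
#' @param beta,z,p Coefficient, z statistic, p-value.
#' @return Character vector.
#' @export
format_association_cell <- function(beta, z, p) {
  sprintf("%.3g%s (%.3g)", beta, significance_stars(p), z)
}

#' Format fold metrics as mean plus/minus SD
#'
#' Population (n-denominator) SD across folds, e.g. `"0.65 ± 0.05"`.
#' @param values Numeric vector of fold-level values.
#' @return Character scalar.
#' @export
format_mean_sd <- function(values) {
  sprintf("%.2f ± %.2f", mean(values), population_sd(values))
}

#' Render human-readable association and classification summaries
#'
#' Writes `association_summary.txt` (features x categories, each cell as
#' [format_association_cell()]) and `classification_summary.txt` (metric mean
#' plus/minus SD by scenario/space/objective and class). Empty inputs produce
#' an explicit "no results" stub.
#'
#' @param assoc `NULL` or list with `single` (scan data frame) and `multiple`
#'   (an `association_report`).
#' @param cv `NULL` or list of `cv_report` objects.
#' @param dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(assoc = NULL, cv = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  render_assoc <- function(tab) {
    tab <- tab[!is.na(tab$beta), , drop = FALSE]
    if (!nrow(tab)) return("no results")
    tab$cell <- format_association_cell(tab$beta, tab$z, tab$p)
    wide <- stats::reshape(tab[c("feature", "category", "cell")],
                           idvar = "feature", timevar = "category",
                           direction = "wide")
    names(wide) <- sub("^cell\\.", "", names(wide))
    paste(utils::capture.output(print(wide, row.names = FALSE)), collapse = "\n")
  }
  f_assoc <- file.path(dir, "association_summary.txt")
  if (is.null(assoc) || (is.null(assoc$single) && is.null(assoc$multiple))) {
    writeLines("no results", f_assoc)
  } else {
    sections <- character()
    if (!is.null(assoc$single)) {
      sections <- c(sections, "== Single-variable mixed-logit scan ==",
                    render_assoc(assoc$single), "")
    }
    if (!is.null(assoc$multiple)) {
      sections <- c(sections, "== Multiple regression (BIC screen + VIF filter) ==",
                    render_assoc(assoc$multiple$table), "")
    }
    writeLines(sections, f_assoc)
  }
  paths <- c(paths, f_assoc)

  f_cv <- file.path(dir, "classification_summary.txt")
  if (is.null(cv) || !length(cv)) {
    writeLines("no results", f_cv)
  } else {
    lines <- character()
    for (rep_i in cv) {
      if (is.null(rep_i$folds)) next
      lines <- c(lines, sprintf("== %s / %s features / objective %s ==",
                                rep_i$scenario, rep_i$space, rep_i$objective))
      for (cl in unique(rep_i$folds$class)) {
        sub <- rep_i$folds[rep_i$folds$class == cl, , drop = FALSE]
        lines <- c(lines, sprintf(
          "  %-14s F1 %s | recall %s | precision %s | MCC %s",
          cl, format_mean_sd(sub$f1), format_mean_sd(sub$recall),
          format_mean_sd(sub$precision), format_mean_sd(sub$mcc)
        ))
      }
      lines <- c(lines, "")
    }
    if (!length(lines)) lines <- "no results"
    writeLines(lines, f_cv)
  }
  paths <- c(paths, f_cv)
  invisible(paths)
}
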