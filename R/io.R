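# CSV interchange for diary cohorts. One file per record kind, comma-separated
# with a header row, ISO-8601 timestamps, missing values as empty fields:
#   subjects.csv(subject_id,age,gender,years_with_diabetes)
#   glucose.csv(subject_id,timestamp,value_mmol_l)
#   insulin.csv(subject_id,timestamp,units,kind)          kind in {QA, BASAL}
#   carbs.csv(subject_id,timestamp,grams)
#   advisor.csv(subject_id,timestamp,food_ins,corr_ins,total_ins,logged_intake,
#               iob,allowed_bgv,carb_cu,meal_rise,exercise_tag)
#   quiz.csv(subject_id,timestamp,points,session_id)
#   episodes.csv(subject_id,timestamp,smbg_value,raw_reason,confidence)

diary_csv_files <- function() {
  c("subjects.csv", "glucose.csv", "insulin.csv", "carbs.csv",
    "advisor.csv", "quiz.csv", "episodes.csv")
}

diary_csv_schema <- function() {
  list(
    subjects.csv = c("subject_id", "age", "gender", "years_with_diabetes"),
    glucose.csv  = c("subject_id", "timestamp", "value_mmol_l"),
    insulin.csv  = c("subject_id", "timestamp", "units", "kind"),
    carbs.csv    = c("subject_id", "timestamp", "grams"),
    advisor.csv  = c("subject_id", "timestamp", "food_ins", "corr_ins", "total_ins",
                     "logged_intake", "iob", "allowed_bgv", "carb_cu", "meal_rise",
                     "exercise_tag"),
    quiz.csv     = c("subject_id", "timestamp", "points", "session_id"),
    episodes.csv = c("subject_id", "timestamp", "smbg_value", "raw_reason", "confidence")
  )
}

read_schema_csv <- function(path, required) {
  if (!file.exists(path)) stop("missing diary table: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", na.strings = "",
                        check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(basename(path), ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

parse_num_col <- function(df, col, file) {
  x <- df[[col]]
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("%s: column '%s' is not numeric at row %d (value %s)",
                 file, col, bad[1L], sQuote(x[bad[1L]])), call. = FALSE)
  }
  out
}

#' Read a diary cohort from CSV tables
#'
#' Reads the seven-file CSV interchange format (see [write_diary_tables()]) and
#' assembles one [diary()] per subject listed in `subjects.csv`. Files are
#' validated against the schemas; unparseable values and duplicated subject ids
#' are errors, never silently skipped. Episode categories are derived from the
#' raw reason labels via `mapping`.
#'
#' @param dir Directory containing the CSV files.
#' @param mapping Reason-to-category mapping, see [map_reason_to_category()].
#' @param default_category Optional fallback category for unmapped labels.
#' @return A named list of diaries (class `t1d_cohort`), keyed by subject id.
#' @export
read_diary_tables <- function(dir, mapping = default_reason_mapping(),
                              default_category = NULL) {
  schema <- diary_csv_schema()
  tabs <- lapply(names(schema), function(f) {
    read_schema_csv(file.path(dir, f), schema[[f]])
  })
  names(tabs) <- names(schema)

  subj <- tabs$subjects.csv
  if (anyDuplicated(subj$subject_id)) {
    stop("subjects.csv: duplicated subject_id ",
         sQuote(subj$subject_id[duplicated(subj$subject_id)][1L]), call. = FALSE)
  }
  for (col in c("age", "gender", "years_with_diabetes")) {
    subj[[col]] <- parse_num_col(subj, col, "subjects.csv")
  }
  num_cols <- list(
    glucose.csv = "value_mmol_l", insulin.csv = "units", carbs.csv = "grams",
    advisor.csv = c("food_ins", "corr_ins", "total_ins", "logged_intake", "iob",
                    "allowed_bgv", "carb_cu", "meal_rise", "exercise_tag"),
    quiz.csv = "points", episodes.csv = c("smbg_value", "confidence")
  )
  for (f in names(num_cols)) {
    for (col in num_cols[[f]]) tabs[[f]][[col]] <- parse_num_col(tabs[[f]], col, f)
    tabs[[f]]$timestamp <- parse_diary_time(tabs[[f]]$timestamp)
  }
  ins <- tabs$insulin.csv
  if (nrow(ins) && any(!ins$kind %in% c("QA", "BASAL"))) {
    stop("insulin.csv: kind must be 'QA' or 'BASAL'", call. = FALSE)
  }

  pick <- function(df, id, cols) {
    out <- df[df$subject_id == id, cols, drop = FALSE]
    rownames(out) <- NULL
    out
  }
  diaries <- lapply(seq_len(nrow(subj)), function(i) {
    id <- subj$subject_id[i]
    adv <- pick(tabs$advisor.csv, id, schema$advisor.csv[-1])
    adv$exercise_tag <- as.logical(adv$exercise_tag)
    ep <- pick(tabs$episodes.csv, id, c("timestamp", "smbg_value", "raw_reason", "confidence"))
    ep$confidence <- as.integer(ep$confidence)
    ep$category <- if (nrow(ep)) {
      map_reason_to_category(ep$raw_reason, mapping, default_category)
    } else character()
    g <- pick(tabs$glucose.csv, id, c("timestamp", "value_mmol_l"))
    names(g)[2] <- "value"
    qz <- pick(tabs$quiz.csv, id, c("timestamp", "points", "session_id"))
    qz$points <- as.integer(qz$points)
    diary(
      profile = subject_profile(id, subj$age[i], subj$gender[i], subj$years_with_diabetes[i]),
      glucose = g,
      qa_doses = pick(ins[ins$kind == "QA", ], id, c("timestamp", "units")),
      basal_doses = pick(ins[ins$kind == "BASAL", ], id, c("timestamp", "units")),
      carbs = pick(tabs$carbs.csv, id, c("timestamp", "grams")),
      advisor = adv,
      quiz = qz,
      episodes = ep
    )
  })
  names(diaries) <- subj$subject_id
  structure(diaries, class = "t1d_cohort")
}

#' Write a diary cohort to CSV tables
#'
#' Inverse of [read_diary_tables()]: emits the seven-file CSV interchange
#' format with stable column order; an empty cohort yields headers-only files.
#'
#' @param diaries A list of diaries (e.g. a `t1d_cohort`).
#' @param dir Output directory, created if necessary.
#' @return The directory path, invisibly.
#' @export
write_diary_tables <- function(diaries, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir, call. = FALSE)

  gather <- function(extract) {
    parts <- lapply(diaries, extract)
    do.call(rbind, parts)
  }
  with_id <- function(d, df, drop = NULL) {
    df <- df[, setdiff(names(df), drop), drop = FALSE]
    if (nrow(df) == 0L) {
      return(cbind(data.frame(subject_id = character(), stringsAsFactors = FALSE), df))
    }
    cbind(data.frame(subject_id = d$profile$subject_id, stringsAsFactors = FALSE), df)
  }
  fmt <- function(df) {
    if (inherits(df$timestamp, "POSIXct")) df$timestamp <- format_diary_time(df$timestamp)
    if ("exercise_tag" %in% names(df)) df$exercise_tag <- as.integer(df$exercise_tag)
    df
  }
  out <- list(
    subjects.csv = do.call(rbind, lapply(diaries, function(d) d$profile)),
    glucose.csv = gather(function(d) {
      g <- d$glucose
      names(g)[names(g) == "value"] <- "value_mmol_l"
      with_id(d, g)
    }),
    insulin.csv = gather(function(d) {
      qa <- with_id(d, d$qa_doses)
      qa$kind <- rep("QA", nrow(qa))
      ba <- with_id(d, d$basal_doses)
      ba$kind <- rep("BASAL", nrow(ba))
      rbind(qa, ba)
    }),
    carbs.csv = gather(function(d) with_id(d, d$carbs)),
    advisor.csv = gather(function(d) with_id(d, d$advisor)),
    quiz.csv = gather(function(d) with_id(d, d$quiz)),
    episodes.csv = gather(function(d) with_id(d, d$episodes, drop = c("episode_id", "category")))
  )
  schema <- diary_csv_schema()
  for (f in names(schema)) {
    df <- out[[f]]
    if (is.null(df)) df <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(schema[[f]]))), schema[[f]]
    )
    df <- fmt(df[, schema[[f]], drop = FALSE])
    utils::write.csv(df, file.path(dir, f), row.names = FALSE, na = "")
  }
  invisible(dir)
}
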