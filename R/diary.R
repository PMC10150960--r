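#' Hypoglycemia cause categories
#'
#' The three analysed cause categories (physical activity, mistakes in food
#' intake, mistakes in medication dosage) plus the two buckets excluded from
#' analysis.
#'
#' @return Character vector of category codes.
#' @export
hypo_categories <- function() c("ACTIVITY", "FOOD", "MEDICATION", "OTHER", "UNKNOWN")

analysis_categories <- function() c("ACTIVITY", "FOOD", "MEDICATION")

#' Subject demographic profile
#'
#' @param subject_id Opaque subject identifier (character scalar).
#' @param age Age in years, > 0.
#' @param gender `"female"`/`"male"` or the numeric code (female = 0, male = 1).
#'   The coding is a package convention; flip it upstream if another convention
#'   is required.
#' @param years_with_diabetes Diabetes duration in years, in `[0, age]`.
#'
#' @return One-row data frame with columns `subject_id`, `age`, `gender`,
#'   `years_with_diabetes`.
#' @export
subject_profile <- function(subject_id, age, gender, years_with_diabetes) {
  if (is.character(gender)) {
    gender <- match.arg(tolower(gender), c("female", "male"))
    gender <- if (gender == "male") 1 else 0
  }
  stopifnot(length(subject_id) == 1L, length(age) == 1L, length(gender) == 1L)
  if (!isTRUE(age > 0)) stop("age must be > 0", call. = FALSE)
  if (!gender %in% c(0, 1)) stop("gender code must be 0 (female) or 1 (male)", call. = FALSE)
  if (!isTRUE(years_with_diabetes >= 0 && years_with_diabetes <= age)) {
    stop("years_with_diabetes must lie in [0, age]", call. = FALSE)
  }
  data.frame(
    subject_id = as.character(subject_id), age = as.numeric(age),
    gender = as.numeric(gender), years_with_diabetes = as.numeric(years_with_diabetes),
    stringsAsFactors = FALSE
  )
}

empty_frame <- function(kind) {
  switch(kind,
    glucose  = data.frame(timestamp = parse_diary_time(character()), value = numeric()),
    dose     = data.frame(timestamp = parse_diary_time(character()), units = numeric()),
    carbs    = data.frame(timestamp = parse_diary_time(character()), grams = numeric()),
    advisor  = data.frame(
      timestamp = parse_diary_time(character()), food_ins = numeric(),
      corr_ins = numeric(), total_ins = numeric(), logged_intake = numeric(),
      iob = numeric(), allowed_bgv = numeric(), carb_cu = numeric(),
      meal_rise = numeric(), exercise_tag = logical()
    ),
    quiz     = data.frame(
      timestamp = parse_diary_time(character()), points = integer(),
      session_id = character(), stringsAsFactors = FALSE
    ),
    episodes = data.frame(
      episode_id = character(), timestamp = parse_diary_time(character()),
      smbg_value = numeric(), raw_reason = character(), confidence = integer(),
      category = character(), stringsAsFactors = FALSE
    ),
    stop("unknown frame kind: ", kind)
  )
}

sort_by_time <- function(df) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct a subject diary
#'
#' A diary bundles one subject's demographics with their time-ordered self-care
#' record: self-monitored blood glucose (SMBG) readings, quick-acting (QA) and
#' basal insulin doses, carbohydrate intakes, bolus-advisor records, quiz
#' answers, and labelled hypoglycemia episodes. All component tables are sorted
#' by timestamp on construction and validated against the domain invariants
#' (positive glucose, nonnegative doses and grams, episode SMBG < 4 mmol/L,
#' confidence in 1..5).
#'
#' @param profile A [subject_profile()] row.
#' @param glucose Data frame `timestamp`, `value` (mmol/L).
#' @param qa_doses,basal_doses Data frames `timestamp`, `units`.
#' @param carbs Data frame `timestamp`, `grams`.
#' @param advisor Data frame with the bolus-advisor columns (`food_ins`,
#'   `corr_ins`, `total_ins`, `logged_intake`, `iob`, `allowed_bgv`, `carb_cu`,
#'   `meal_rise`, `exercise_tag`); any field may be `NA`.
#' @param quiz Data frame `timestamp`, `points`, `session_id`.
#' @param episodes Data frame `timestamp`, `smbg_value`, `raw_reason`,
#'   `confidence`, `category` (and optionally `episode_id`).
#'
#' @return An object of class `t1d_diary`.
#' @export
diary <- function(profile,
                  glucose = empty_frame("glucose"),
                  qa_doses = empty_frame("dose"),
                  basal_doses = empty_frame("dose"),
                  carbs = empty_frame("carbs"),
                  advisor = empty_frame("advisor"),
                  quiz = empty_frame("quiz"),
                  episodes = empty_frame("episodes")) {
  episodes <- as.data.frame(episodes)
  if (is.null(episodes$episode_id)) {
    episodes$episode_id <- character(nrow(episodes))
    ord <- order(episodes$timestamp)
    episodes$episode_id[ord] <- sprintf("%s_E%03d", profile$subject_id,
                                        seq_len(nrow(episodes)))
  }
  canon <- c("episode_id", "timestamp", "smbg_value", "raw_reason", "confidence", "category")
  if (all(canon %in% names(episodes))) episodes <- episodes[canon]
  d <- structure(list(
    profile = profile,
    glucose = sort_by_time(as.data.frame(glucose)),
    qa_doses = sort_by_time(as.data.frame(qa_doses)),
    basal_doses = sort_by_time(as.data.frame(basal_doses)),
    carbs = sort_by_time(as.data.frame(carbs)),
    advisor = sort_by_time(as.data.frame(advisor)),
    quiz = sort_by_time(as.data.frame(quiz)),
    episodes = sort_by_time(episodes)
  ), class = "t1d_diary")
  validate_diary(d)
  d
}

#' Validate a diary against the domain invariants
#'
#' @param d A `t1d_diary`.
#' @return `d`, invisibly; errors on any violated invariant.
#' @export
validate_diary <- function(d) {
  stopifnot(inherits(d, "t1d_diary"))
  p <- d$profile
  if (nrow(p) != 1L || !all(c("subject_id", "age", "gender", "years_with_diabetes") %in% names(p))) {
    stop("profile must be a single subject_profile() row", call. = FALSE)
  }
  if (nrow(d$glucose) && any(d$glucose$value <= 0, na.rm = TRUE)) {
    stop("glucose values must be > 0", call. = FALSE)
  }
  for (k in c("qa_doses", "basal_doses")) {
    if (nrow(d[[k]]) && any(d[[k]]$units < 0, na.rm = TRUE)) {
      stop(k, ": insulin units must be >= 0", call. = FALSE)
    }
  }
  if (nrow(d$carbs) && any(d$carbs$grams < 0, na.rm = TRUE)) {
    stop("carbohydrate grams must be >= 0", call. = FALSE)
  }
  ep <- d$episodes
  if (nrow(ep)) {
    if (any(ep$smbg_value >= 4.0, na.rm = TRUE)) {
      stop("episode smbg_value must be < 4.0 mmol/L", call. = FALSE)
    }
    if (any(!ep$confidence %in% 1:5)) {
      stop("episode confidence must be an integer in 1..5", call. = FALSE)
    }
    if (any(!ep$category %in% hypo_categories())) {
      stop("unknown episode category", call. = FALSE)
    }
  }
  for (k in c("glucose", "qa_doses", "basal_doses", "carbs", "advisor", "quiz", "episodes")) {
    ts <- d[[k]]$timestamp
    if (length(ts) > 1L && is.unsorted(ts)) stop(k, " is not time-sorted", call. = FALSE)
  }
  invisible(d)
}

#' @export
print.t1d_diary <- function(x, ...) {
  cat(sprintf(
    "<t1d_diary> subject %s: %d SMBG, %d QA doses, %d basal, %d carbs, %d advisor, %d quiz, %d episodes\n",
    x$profile$subject_id, nrow(x$glucose), nrow(x$qa_doses), nrow(x$basal_doses),
    nrow(x$carbs), nrow(x$advisor), nrow(x$quiz), nrow(x$episodes)
  ))
  invisible(x)
}

#' @export
print.t1d_cohort <- function(x, ...) {
  n_ep <- sum(vapply(x, function(d) nrow(d$episodes), integer(1)))
  cat(sprintf("<t1d_cohort> %d subjects, %d labelled episodes\n", length(x), n_ep))
  invisible(x)
}

#' Filter labelled episodes for analysis
#'
#' Keeps exactly the episodes labelled with high confidence (default >= 4) whose
#' cause category is one of the three analysed classes; episodes labelled
#' "Other" or "Don't know" are excluded regardless of confidence. Row order is
#' preserved and the operation is idempotent.
#'
#' @param episodes Episode data frame (as in a diary's `episodes` component).
#' @param min_confidence Minimum confidence level retained, default 4.
#' @return The filtered episode data frame (possibly zero rows).
#' @export
filter_label_episodes <- function(episodes, min_confidence = 4) {
  stopifnot(all(c("confidence", "category") %in% names(episodes)))
  keep <- episodes$confidence >= min_confidence &
    !episodes$category %in% c("OTHER", "UNKNOWN")
  out <- episodes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
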