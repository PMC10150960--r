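#' Cohort simulation configuration
#'
#' Bundles the parameters of the synthetic diary generator. The defaults mirror
#' the acquisition setting the package targets: 54 subjects, a 6-month diary
#' horizon, roughly 15 labelled episodes per subject, a 48/36/16 percent cause
#' mix over (activity, food, medication), bolus-advisor context available for
#' about 40 percent of episodes, and label confidence mostly at levels 4-5.
#'
#' @param n_subjects Number of subjects.
#' @param days Diary horizon in days; must be >= 90 so that the 3-month
#'   self-care window features are meaningful.
#' @param episodes_per_subject Mean number of labelled episodes per subject
#'   (Poisson, with log-normal inter-subject rate dispersion).
#' @param class_mix Probability triple over (ACTIVITY, FOOD, MEDICATION);
#'   must sum to 1.
#' @param advisor_availability Probability that an episode carries a
#'   bolus-advisor record.
#' @param effect_profile Named list of per-category injection mechanisms, see
#'   [default_effect_profile()].
#' @param confidence_probs Probabilities of confidence levels 1..5 for episode
#'   labels.
#' @param rate_dispersion SD of the per-subject log episode rate (inter-subject
#'   variability of episode counts).
#' @param start Calendar start date of every diary (ISO date string).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 54, days = 180, episodes_per_subject = 15,
                          class_mix = c(ACTIVITY = 0.48, FOOD = 0.36, MEDICATION = 0.16),
                          advisor_availability = 0.40,
                          effect_profile = default_effect_profile(),
                          confidence_probs = c(0, 0, 0.1, 0.3, 0.6),
                          rate_dispersion = 0.3,
                          start = "2024-01-01",
                          seed = 1L) {
  stopifnot(n_subjects >= 1)
  if (days < 90) stop("days must be >= 90 (3-month window features)", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1", call. = FALSE)
  if (any(class_mix < 0) || any(class_mix > 1)) stop("class_mix entries must be in [0,1]", call. = FALSE)
  if (advisor_availability < 0 || advisor_availability > 1) {
    stop("advisor_availability must be in [0,1]", call. = FALSE)
  }
  stopifnot(length(confidence_probs) == 5, abs(sum(confidence_probs) - 1) < 1e-9)
  names(class_mix) <- analysis_categories()
  structure(list(
    n_subjects = as.integer(n_subjects), days = as.integer(days),
    episodes_per_subject = episodes_per_subject, class_mix = class_mix,
    advisor_availability = advisor_availability, effect_profile = effect_profile,
    confidence_probs = confidence_probs, rate_dispersion = rate_dispersion,
    start = start, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default cause-conditional injection mechanisms
#'
#' Each analysed cause category gets a mechanism list controlling how an
#' injected episode perturbs the surrounding diary. Only the *directions* of
#' the encoded effects are treated as established; the magnitudes are free
#' parameters of the generator:
#'
#' * `ACTIVITY` - daytime-concentrated episode times, an exercise tag in the
#'   preceding advisor record with high probability, preceding quick-acting
#'   dose at or below the subject's mean.
#' * `FOOD` - morning/evening-skewed times, preceding quick-acting dose above
#'   the subject's mean (carbohydrate overestimate), a prompt corrective
#'   carbohydrate intake after the episode.
#' * `MEDICATION` - business-day-skewed, a longer gap since the last
#'   carbohydrate intake, and an elevated basal dose on the episode day.
#'
#' Mechanism fields: `tod_kind` (`"uniform"`, `"normal"`, `"bimodal"`) with
#' `tod_mean`/`tod_sd` or `tod_modes`; `bday_prob` (`NA` = natural calendar);
#' `exercise_tag_prob`; `qa_shift` (units relative to the subject mean dose);
#' `next_carb_gap` (hours, `NA` = none); `carb_clear_hours`; `basal_shift`
#' (units).
#'
#' @return Named list with entries `ACTIVITY`, `FOOD`, `MEDICATION`.
#' @export
default_effect_profile <- function() {
  list(
    ACTIVITY = list(tod_kind = "normal", tod_mean = 14, tod_sd = 2.5,
                    bday_prob = NA_real_, exercise_tag_prob = 0.85,
                    qa_shift = -1.5, next_carb_gap = 1.2,
                    carb_clear_hours = 0, carb_clear_prob = 0, basal_shift = 0),
    FOOD = list(tod_kind = "bimodal", tod_modes = c(8.5, 19.5), tod_sd = 1.5,
                bday_prob = NA_real_, exercise_tag_prob = 0.05,
                qa_shift = 2.5, next_carb_gap = 0.3,
                carb_clear_hours = 0, carb_clear_prob = 0, basal_shift = 0),
    MEDICATION = list(tod_kind = "uniform",
                      bday_prob = 0.85, exercise_tag_prob = 0.05,
                      qa_shift = 0, next_carb_gap = 1.2,
                      carb_clear_hours = 4, carb_clear_prob = 0.7, basal_shift = 3)
  )
}

#' Null injection profile (no cause-conditional structure)
#'
#' All categories share uniform episode times, the natural business-day rate,
#' the baseline exercise-tag rate, and zero dose/carb perturbations. Used for
#' null calibration of the downstream analyses.
#' @return Named list like [default_effect_profile()].
#' @export
zero_effect_profile <- function() {
  null_mech <- list(tod_kind = "uniform", bday_prob = NA_real_,
                    exercise_tag_prob = 0.05, qa_shift = 0,
                    next_carb_gap = 0.8, carb_clear_hours = 0,
                    carb_clear_prob = 0, basal_shift = 0)
  list(ACTIVITY = null_mech, FOOD = null_mech, MEDICATION = null_mech)
}

rnorm_clip <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

# Subject-level latent self-care parameters.
draw_subject_latents <- function() {
  list(
    wake = rnorm_clip(1, 7, 0.75, 5, 9.5),            # usual wake time, h
    bg_mu = stats::runif(1, 6, 10),                    # mmol/L
    bg_sigma = stats::runif(1, 0.15, 0.30),            # log-scale SD
    carb_ratio = stats::runif(1, 8, 12),               # g per unit QA insulin
    basal_units = stats::runif(1, 18, 30),
    meal_gram_mean = stats::runif(1, 40, 60)
  )
}

#' Simulate one subject's diary (without labelled episodes)
#'
#' Generates `days` days of self-care records: 3-6 SMBG readings per day with
#' the first shortly after a subject-specific wake time, 2-4 meals per day with
#' a carbohydrate record and a quick-acting dose near grams / carb ratio, one
#' basal dose per day, and sporadic quiz sessions. Glucose values follow a
#' log-normal process around a subject-specific mean in 6-10 mmol/L.
#'
#' @param profile A [subject_profile()] row.
#' @param days Horizon in days, >= 90.
#' @param seed Optional integer seed (otherwise the current RNG stream is used).
#' @param start ISO start date.
#' @return A `t1d_diary` with empty `episodes`; subject latent parameters are
#'   attached as attribute `"latent"`.
#' @export
simulate_subject_diary <- function(profile, days, seed = NULL, start = "2024-01-01") {
  if (days < 90) stop("days must be >= 90", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lat <- draw_subject_latents()
  t0 <- as.POSIXct(paste0(start, "T00:00:00"), format = DIARY_TIME_FORMAT, tz = DIARY_TZ)

  gl_t <- list(); gl_v <- list()
  qa_t <- list(); qa_u <- list()
  ca_t <- list(); ca_g <- list()
  ba_t <- numeric(days); ba_u <- numeric(days)
  qz <- list()
  session_counter <- 0L
  meal_anchors <- c(8, 12.5, 18, 21)

  for (day in seq_len(days)) {
    day0 <- t0 + (day - 1) * 86400

    n_meals <- sample(2:4, 1L)
    mt <- sort(rnorm_clip(n_meals, sort(sample(meal_anchors, n_meals)), 0.5, 6, 22.5))
    grams <- pmax(10, stats::rnorm(n_meals, lat$meal_gram_mean, 15))
    doses <- pmax(0.5, grams / lat$carb_ratio + stats::rnorm(n_meals, 0, 0.8))
    ca_t[[day]] <- day0 + mt * 3600
    ca_g[[day]] <- round(grams)
    qa_t[[day]] <- day0 + (mt + stats::runif(n_meals, -0.1, 0.1)) * 3600
    qa_u[[day]] <- round(doses, 1)

    n_bg <- sample(3:6, 1L)
    first <- max(4.6, stats::rnorm(1, lat$wake, 0.3))
    rest <- stats::runif(n_bg - 1L, min(first + 0.5, 23), 23)
    bg_tod <- c(first, sort(rest))
    vals <- exp(stats::rnorm(n_bg, log(lat$bg_mu) - lat$bg_sigma^2 / 2, lat$bg_sigma))
    gl_t[[day]] <- day0 + bg_tod * 3600
    gl_v[[day]] <- pmax(1.5, round(vals, 1))

    ba_t[day] <- as.numeric(day0) + rnorm_clip(1, 22, 0.25, 21, 23) * 3600
    ba_u[day] <- max(1, round(lat$basal_units + stats::rnorm(1, 0, 1), 1))

    if (stats::runif(1) < 0.15) {
      session_counter <- session_counter + 1L
      n_ans <- sample(3:8, 1L)
      start_s <- day0 + stats::runif(1, 9, 21) * 3600
      qz[[length(qz) + 1L]] <- data.frame(
        timestamp = start_s + (seq_len(n_ans) - 1L) * 90,
        points = stats::rpois(n_ans, 3),
        session_id = sprintf("%s_Q%03d", profile$subject_id, session_counter),
        stringsAsFactors = FALSE
      )
    }
  }

  cat_time <- function(lst) as.POSIXct(unlist(lapply(lst, as.numeric)),
                                       origin = "1970-01-01", tz = DIARY_TZ)
  quiz <- if (length(qz)) do.call(rbind, qz) else empty_frame("quiz")
  quiz$timestamp <- trunc_minute(quiz$timestamp)
  d <- diary(
    profile = profile,
    glucose = data.frame(timestamp = trunc_minute(cat_time(gl_t)), value = unlist(gl_v)),
    qa_doses = data.frame(timestamp = trunc_minute(cat_time(qa_t)), units = unlist(qa_u)),
    basal_doses = data.frame(
      timestamp = trunc_minute(as.POSIXct(ba_t, origin = "1970-01-01", tz = DIARY_TZ)),
      units = ba_u
    ),
    carbs = data.frame(timestamp = trunc_minute(cat_time(ca_t)), grams = unlist(ca_g)),
    quiz = quiz
  )
  attr(d, "latent") <- lat
  attr(d, "horizon") <- list(start = t0, days = days)
  d
}

draw_episode_tod <- function(mech) {
  tod <- switch(mech$tod_kind,
    uniform = stats::runif(1, 6.5, 22.5),
    normal = rnorm_clip(1, mech$tod_mean, mech$tod_sd, 6.5, 22.5),
    bimodal = rnorm_clip(1, sample(mech$tod_modes, 1L), mech$tod_sd, 6.5, 22.5),
    stop("unknown tod_kind: ", mech$tod_kind)
  )
  tod
}

#' Inject one cause-labelled hypoglycemia episode into a diary
#'
#' Inserts an SMBG reading below 4 mmol/L at a category-conditional episode
#' time and perturbs the surrounding records according to the category's
#' mechanism (see [default_effect_profile()]). An advisor record is attached
#' with probability `advisor_availability`, and the label confidence is drawn
#' from `confidence_probs` (mostly 4-5 by default).
#'
#' @param d A `t1d_diary`.
#' @param category One of `"ACTIVITY"`, `"FOOD"`, `"MEDICATION"`.
#' @param effect_profile Mechanism list, see [default_effect_profile()].
#' @param advisor_availability Probability of an attached advisor record.
#' @param confidence_probs Probabilities of confidence 1..5.
#' @param day Episode day index (1-based from the diary start); default draws
#'   uniformly from the admissible range (after the feature history window).
#' @param seed Optional integer seed.
#' @return List with elements `diary` (modified), `episode` (one-row data
#'   frame) and `truth` (one-row data frame of the injected mechanism values).
#' @export
inject_cause_episode <- function(d, category, effect_profile = default_effect_profile(),
                                 advisor_availability = 0.40,
                                 confidence_probs = c(0, 0, 0.1, 0.3, 0.6),
                                 day = NULL, seed = NULL) {
  if (!category %in% analysis_categories()) {
    stop("category must be one of ", paste(analysis_categories(), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mech <- effect_profile[[category]]
  if (is.null(mech)) stop("effect_profile has no entry for ", category, call. = FALSE)
  hor <- attr(d, "horizon")
  if (is.null(hor)) {
    span <- as.numeric(diff(range(diary_date(d$glucose$timestamp)))) + 1
    hor <- list(start = as.POSIXct(paste(min(diary_date(d$glucose$timestamp)), "00:00:00"),
                                   tz = DIARY_TZ), days = span)
  }
  first_day <- min(90, floor(hor$days / 2)) + 1L
  admissible <- seq.int(first_day, hor$days)

  if (is.null(day)) {
    if (!is.na(mech$bday_prob)) {
      want_bday <- stats::runif(1) < mech$bday_prob
      day_dates <- as.Date(hor$start) + admissible - 1L
      pool <- admissible[is_business_day(as.POSIXct(paste(day_dates, "12:00:00"), tz = DIARY_TZ)) == want_bday]
      if (!length(pool)) pool <- admissible
      day <- if (length(pool) == 1L) pool else sample(pool, 1L)
    } else {
      day <- if (length(admissible) == 1L) admissible else sample(admissible, 1L)
    }
  }
  day0 <- hor$start + (day - 1) * 86400
  tod <- draw_episode_tod(mech)
  t_ev <- day0 + round(tod * 60) * 60 # minute resolution
  smbg <- round(stats::runif(1, 2.5, 3.9), 1)

  d$glucose <- sort_by_time(rbind(d$glucose, data.frame(timestamp = t_ev, value = smbg)))

  # Preceding QA dose relative to the subject mean (carb overestimate /
  # activity-adjusted dose mechanisms).
  qa_mean <- mean(d$qa_doses$units)
  pre_idx <- which(d$qa_doses$timestamp < t_ev &
                     hours_between(d$qa_doses$timestamp, t_ev) <= 3)
  inserted_dose <- FALSE
  applied_shift <- mech$qa_shift
  if (length(pre_idx)) {
    i <- pre_idx[length(pre_idx)]
    d$qa_doses$units[i] <- max(0, d$qa_doses$units[i] + mech$qa_shift +
                                 stats::rnorm(1, 0, 0.3))
  } else if (stats::runif(1) < 0.9) {
    t_dose <- trunc_minute(t_ev - stats::runif(1, 0.75, 2.5) * 3600)
    units <- max(0.5, qa_mean + mech$qa_shift + stats::rnorm(1, 0, 0.5))
    d$qa_doses <- sort_by_time(rbind(d$qa_doses,
                                     data.frame(timestamp = t_dose, units = round(units, 1))))
    inserted_dose <- TRUE
  } else {
    applied_shift <- 0
  }

  carb_cleared <- FALSE
  if (mech$carb_clear_hours > 0 && stats::runif(1) < mech$carb_clear_prob) {
    gap_lo <- t_ev - mech$carb_clear_hours * 3600
    drop <- d$carbs$timestamp >= gap_lo & d$carbs$timestamp < t_ev
    d$carbs <- d$carbs[!drop, , drop = FALSE]
    carb_cleared <- TRUE
  }
  if (!is.na(mech$next_carb_gap)) {
    # corrective carbohydrate intake after the episode; gap log-normally
    # dispersed around the category's typical delay
    gap <- mech$next_carb_gap * exp(stats::rnorm(1, 0, 0.4))
    t_c <- trunc_minute(t_ev + gap * 3600)
    d$carbs <- sort_by_time(rbind(d$carbs,
                                  data.frame(timestamp = t_c, grams = round(stats::runif(1, 15, 25)))))
  }
  if (mech$basal_shift != 0) {
    same_day <- diary_date(d$basal_doses$timestamp) == diary_date(t_ev)
    if (any(same_day)) {
      j <- which(same_day)[1L]
      d$basal_doses$units[j] <- max(0, d$basal_doses$units[j] + mech$basal_shift)
    }
  }

  advisor_attached <- stats::runif(1) < advisor_availability
  has_tag <- FALSE
  if (advisor_attached) {
    has_tag <- stats::runif(1) < mech$exercise_tag_prob
    food_ins <- max(0.5, qa_mean + stats::rnorm(1, 0, 1))
    corr_ins <- round(stats::runif(1, 0, 2), 1)
    total <- food_ins + corr_ins
    rec <- data.frame(
      timestamp = trunc_minute(t_ev - stats::runif(1, 0.5, 2.5) * 3600),
      food_ins = round(food_ins, 1), corr_ins = corr_ins,
      total_ins = round(total, 1),
      logged_intake = round(max(0, total + stats::rnorm(1, 0, 0.7)), 1),
      iob = round(stats::runif(1, 0, 3), 1),
      allowed_bgv = round(stats::runif(1, 4.5, 7.5), 1),
      carb_cu = round(stats::runif(1, 0.8, 1.2), 2),
      meal_rise = round(stats::runif(1, 1, 3), 1),
      exercise_tag = has_tag
    )
    d$advisor <- sort_by_time(rbind(d$advisor, rec))
  }

  conf <- sample(1:5, 1L, prob = confidence_probs)
  reasons <- names(default_reason_mapping())[default_reason_mapping() == category]
  episode <- data.frame(
    timestamp = t_ev, smbg_value = smbg,
    raw_reason = sample(reasons, 1L), confidence = conf, category = category,
    stringsAsFactors = FALSE
  )
  d$episodes <- sort_by_time(rbind(d$episodes[, names(episode), drop = FALSE], episode))
  validate_diary(d)

  truth <- data.frame(
    subject_id = d$profile$subject_id, timestamp = t_ev, category = category,
    tod_hours = tod, business_day = is_business_day(t_ev),
    qa_shift = applied_shift, dose_inserted = inserted_dose,
    carb_cleared = carb_cleared,
    next_carb_gap = mech$next_carb_gap, basal_shift = mech$basal_shift,
    advisor_attached = advisor_attached, exercise_tag = has_tag,
    confidence = conf, stringsAsFactors = FALSE
  )
  list(diary = d, episode = episode, truth = truth)
}

#' Generate a synthetic cohort of diaries with labelled episodes
#'
#' Draws subject demographics, simulates each subject's background diary, and
#' injects cause-labelled hypoglycemia episodes according to the configured
#' class mix and effect profile. Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List with `diaries` (a `t1d_cohort`) and `truth` (one data frame row
#'   per injected episode: category and the mechanism values actually applied).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  diaries <- vector("list", config$n_subjects)
  truths <- list()
  ids <- sprintf("S%02d", seq_len(config$n_subjects))

  for (i in seq_len(config$n_subjects)) {
    age <- rnorm_clip(1, 46.8, 15.2, 18, 85)
    gender <- as.numeric(stats::runif(1) < 1 / 3) # cohort skews female
    ywd <- min(age - 1, max(0.5, stats::runif(1, 2, age - 15)))
    prof <- subject_profile(ids[i], age, gender, ywd)
    d <- simulate_subject_diary(prof, config$days, start = config$start)

    n_epi <- stats::rpois(1, config$episodes_per_subject *
                            exp(stats::rnorm(1, 0, config$rate_dispersion) -
                                  config$rate_dispersion^2 / 2))
    if (n_epi > 0L) {
      cats <- sample(analysis_categories(), n_epi, replace = TRUE,
                     prob = config$class_mix)
      for (j in seq_len(n_epi)) {
        # day selection is left to the injector: the business-day skew of the
        # medication mechanism lives there
        res <- inject_cause_episode(
          d, cats[j], config$effect_profile,
          advisor_availability = config$advisor_availability,
          confidence_probs = config$confidence_probs
        )
        d <- res$diary
        truths[[length(truths) + 1L]] <- res$truth
      }
    }
    # assign stable episode ids in time order
    if (nrow(d$episodes)) {
      d$episodes$episode_id <- sprintf("%s_E%03d", ids[i], seq_len(nrow(d$episodes)))
      d$episodes <- d$episodes[, c("episode_id", "timestamp", "smbg_value",
                                   "raw_reason", "confidence", "category")]
    }
    diaries[[i]] <- d
  }
  names(diaries) <- ids
  truth <- if (length(truths)) do.call(rbind, truths) else NULL
  if (!is.null(truth)) {
    # join episode ids by (subject, timestamp)
    all_ep <- do.call(rbind, lapply(diaries, function(d) {
      cbind(subject_id = rep(d$profile$subject_id, nrow(d$episodes)),
            d$episodes[, c("episode_id", "timestamp"), drop = FALSE])
    }))
    key_t <- paste(truth$subject_id, as.numeric(truth$timestamp))
    key_e <- paste(all_ep$subject_id, as.numeric(all_ep$timestamp))
    truth$episode_id <- all_ep$episode_id[match(key_t, key_e)]
    truth <- truth[, c("episode_id", setdiff(names(truth), "episode_id"))]
    rownames(truth) <- NULL
  }
  list(diaries = structure(diaries, class = "t1d_cohort"), truth = truth)
}
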