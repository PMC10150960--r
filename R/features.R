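# Event representation: one labelled hypoglycemia episode -> the canonical
# 83-slot feature vector (plus the auxiliary columns). All offsets are decimal
# hours and nonnegative; missingness is explicit NA, never silent NaN.

#' Subject baselines for episode-relative centering
#'
#' Computes the subject's 3-month means of quick-acting insulin dose, basal
#' dose and carbohydrate amount, and the median time-of-day of each day's
#' first glucose reading at or after 04:30, strictly from data before
#' `t_event` within the preceding `window_days`.
#'
#' @param d A `t1d_diary`.
#' @param t_event Episode timestamp.
#' @param window_days History window length in days (default 90).
#' @return List with `qa_mean`, `basal_mean`, `carb_mean`, `wake_median`
#'   (hours), any of which may be `NA` when no data are available.
#' @export
subject_baselines <- function(d, t_event, window_days = 90) {
  lo <- t_event - window_days * 86400
  in_win <- function(ts) ts >= lo & ts < t_event
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

  g <- d$glucose[in_win(d$glucose$timestamp), , drop = FALSE]
  wake_median <- NA_real_
  if (nrow(g)) {
    tod <- time_of_day_hours(g$timestamp)
    ok <- tod >= 4.5
    if (any(ok)) {
      firsts <- tapply(tod[ok], diary_date(g$timestamp[ok]), min)
      wake_median <- stats::median(as.numeric(firsts))
    }
  }
  list(
    qa_mean = mean_or_na(d$qa_doses$units[in_win(d$qa_doses$timestamp)]),
    basal_mean = mean_or_na(d$basal_doses$units[in_win(d$basal_doses$timestamp)]),
    carb_mean = mean_or_na(d$carbs$grams[in_win(d$carbs$timestamp)]),
    wake_median = wake_median
  )
}

#' Temporal context of an episode
#'
#' Five values describing when the episode happened: `tod` (fraction of day in
#' `[0,1]`, auxiliary), `cos_tod` = absolute hour offset from noon, `sin_tod` =
#' absolute hour offset from midnight (i.e. `min(t, 24 - t)`), both in
#' `[0, 12]`; `wake_up_offset` = episode-day first-reading time-of-day minus
#' the subject's usual (90-day median) first-reading time-of-day, in hours; and
#' `is_bday` (1 on Monday-Friday). `wake_up_offset` is missing when the episode
#' day has no reading before the episode.
#'
#' @param t_event Episode timestamp.
#' @param d A `t1d_diary`.
#' @param baselines Output of [subject_baselines()] at `t_event`.
#' @return Named list of 5 numeric values.
#' @export
temporal_features <- function(t_event, d, baselines) {
  t_h <- time_of_day_hours(t_event)
  same_day <- diary_date(d$glucose$timestamp) == diary_date(t_event) &
    d$glucose$timestamp < t_event
  tod_day <- time_of_day_hours(d$glucose$timestamp[same_day])
  tod_day <- tod_day[tod_day >= 4.5]
  wake_off <- if (length(tod_day) && !is.na(baselines$wake_median)) {
    min(tod_day) - baselines$wake_median
  } else NA_real_
  list(
    tod = t_h / 24,
    cos_tod = abs(t_h - 12),
    sin_tod = min(t_h, 24 - t_h),
    wake_up_offset = wake_off,
    is_bday = as.numeric(is_business_day(t_event))
  )
}

# Monotone piecewise-cubic interpolation through (x, y); handles the 1- and
# 2-knot degenerate cases. x strictly increasing.
pchip_eval <- function(x, y, xout) {
  if (length(x) == 1L) return(rep(y, length(xout)))
  if (length(x) == 2L) return(stats::approx(x, y, xout)$y)
  pracma::pchip(x, y, xout)
}

#' Interpolated glucose-curve summaries around an episode
#'
#' SMBG readings within `interp_half_window` hours of the episode (the episode
#' reading included) are interpolated with a monotonicity-preserving piecewise
#' cubic Hermite polynomial (PCHIP), resampled on a uniform grid
#' (`resample_step_min` minutes) spanning the first to last reading, and
#' summarised: mean, population SD, range, min, max, least-squares slope
#' (mmol/L per hour), sample skewness and excess kurtosis of the resampled
#' curve. Readings at duplicated times are averaged before interpolation.
#' With two readings the interpolant is linear; with one it is constant
#' (SD = range = slope = 0, skewness/kurtosis missing); with none all eight
#' values are missing.
#'
#' @param d A `t1d_diary`.
#' @param t_event Episode timestamp.
#' @param config A [window_config()].
#' @return Named list `bgi_mean`, `bgi_std`, `bgi_range`, `bgi_min`,
#'   `bgi_max`, `bgi_slope`, `bgi_skew`, `bgi_kurt`.
#' @export
interp_bg_features <- function(d, t_event, config = window_config()) {
  hw <- config$interp_half_window * 3600
  sel <- d$glucose$timestamp >= t_event - hw & d$glucose$timestamp <= t_event + hw
  g <- d$glucose[sel, , drop = FALSE]
  out <- list(bgi_mean = NA_real_, bgi_std = NA_real_, bgi_range = NA_real_,
              bgi_min = NA_real_, bgi_max = NA_real_, bgi_slope = NA_real_,
              bgi_skew = NA_real_, bgi_kurt = NA_real_)
  if (nrow(g) == 0L) return(out)

  th <- hours_between(t_event, g$timestamp) # knot times relative to episode, h
  yk <- as.numeric(tapply(g$value, th, mean))
  xk <- sort(unique(th))

  if (length(xk) == 1L) {
    v <- yk[1L]
    return(list(bgi_mean = v, bgi_std = 0, bgi_range = 0, bgi_min = v, bgi_max = v,
                bgi_slope = 0, bgi_skew = NA_real_, bgi_kurt = NA_real_))
  }
  step <- config$resample_step_min / 60
  grid <- seq(xk[1L], xk[length(xk)], by = step)
  if (grid[length(grid)] < xk[length(xk)]) grid <- c(grid, xk[length(xk)])
  yv <- pchip_eval(xk, yk, grid)

  slope <- if (stats::var(grid) > 0) {
    sum((grid - mean(grid)) * (yv - mean(yv))) / sum((grid - mean(grid))^2)
  } else 0
  list(
    bgi_mean = mean(yv), bgi_std = population_sd(yv),
    bgi_range = max(yv) - min(yv), bgi_min = min(yv), bgi_max = max(yv),
    bgi_slope = slope, bgi_skew = sample_skewness(yv), bgi_kurt = excess_kurtosis(yv)
  )
}

#' Neighbouring SMBG readings around an episode
#'
#' Value and hour offsets of the nearest readings strictly before and strictly
#' after the episode (the episode reading itself excluded), plus the hour
#' offsets of the nearest preceding/following hyperglycemia (> hyper
#' threshold), hypoglycemia (< hypo threshold) and in-target readings (within
#' the target band, inclusive). Offsets are nonnegative; an absent antecedent
#' or consequent is missing.
#'
#' @inheritParams interp_bg_features
#' @return Named list of 10 values (`pre_g_val`, `pre_g_offset`,
#'   `pre_H_offset`, `pre_h_offset`, `pre_t_offset` and `post_*` analogues).
#' @export
neighbor_bg_features <- function(d, t_event, config = window_config()) {
  g <- d$glucose[d$glucose$timestamp != t_event, , drop = FALSE]
  pre <- g[g$timestamp < t_event, , drop = FALSE]
  post <- g[g$timestamp > t_event, , drop = FALSE]

  last_off <- function(df, keep) {
    idx <- which(keep)
    if (!length(idx)) return(NA_real_)
    hours_between(df$timestamp[idx[length(idx)]], t_event)
  }
  first_off <- function(df, keep) {
    idx <- which(keep)
    if (!length(idx)) return(NA_real_)
    hours_between(t_event, df$timestamp[idx[1L]])
  }
  band <- config$target_band
  list(
    pre_g_val = if (nrow(pre)) pre$value[nrow(pre)] else NA_real_,
    pre_g_offset = last_off(pre, rep(TRUE, nrow(pre))),
    pre_H_offset = last_off(pre, pre$value > config$hyper_threshold),
    pre_h_offset = last_off(pre, pre$value < config$hypo_threshold),
    pre_t_offset = last_off(pre, pre$value >= band[1] & pre$value <= band[2]),
    post_g_val = if (nrow(post)) post$value[1L] else NA_real_,
    post_g_offset = first_off(post, rep(TRUE, nrow(post))),
    post_H_offset = first_off(post, post$value > config$hyper_threshold),
    post_h_offset = first_off(post, post$value < config$hypo_threshold),
    post_t_offset = first_off(post, post$value >= band[1] & post$value <= band[2])
  )
}

#' Neighbouring intakes (insulin and carbohydrate) around an episode
#'
#' For each of quick-acting insulin, basal insulin and carbohydrate intake:
#' the amount of the record nearest before and nearest after the episode,
#' centred on the subject's 3-month mean of that signal, plus the hour offsets
#' to/from the episode. An absent record makes both the amount and the offset
#' missing.
#'
#' @param d A `t1d_diary`.
#' @param t_event Episode timestamp.
#' @param baselines Output of [subject_baselines()] at `t_event`.
#' @return Named list of 12 values.
#' @export
intake_context_features <- function(d, t_event, baselines) {
  ctx <- function(df, valcol, center) {
    pre <- df[df$timestamp < t_event, , drop = FALSE]
    post <- df[df$timestamp > t_event, , drop = FALSE]
    list(
      pre_val = if (nrow(pre)) pre[[valcol]][nrow(pre)] - center else NA_real_,
      pre_off = if (nrow(pre)) hours_between(pre$timestamp[nrow(pre)], t_event) else NA_real_,
      post_val = if (nrow(post)) post[[valcol]][1L] - center else NA_real_,
      post_off = if (nrow(post)) hours_between(t_event, post$timestamp[1L]) else NA_real_
    )
  }
  qa <- ctx(d$qa_doses, "units", baselines$qa_mean)
  ba <- ctx(d$basal_doses, "units", baselines$basal_mean)
  ca <- ctx(d$carbs, "grams", baselines$carb_mean)
  list(
    pre_ins_dosage = qa$pre_val, pre_ins_offset = qa$pre_off,
    post_ins_dosage = qa$post_val, post_ins_offset = qa$post_off,
    pre_bas_dosage = ba$pre_val, pre_bas_offset = ba$pre_off,
    post_bas_dosage = ba$post_val, post_bas_offset = ba$post_off,
    pre_car_dosage = ca$pre_val, pre_car_offset = ca$pre_off,
    post_car_dosage = ca$post_val, post_car_offset = ca$post_off
  )
}

#' Bolus-advisor context before an episode
#'
#' Reads the most recent advisor record within the lookback window before the
#' episode. `ba_diff` is the total advised insulin minus the logged intake;
#' `ba_has_excercise` is 1 iff any record in the lookback carries the exercise
#' tag. Without any record in the lookback all nine values are missing.
#'
#' @inheritParams interp_bg_features
#' @return Named list of 9 values: the six canonical advisor features plus the
#'   auxiliary `ba_iob`, `ba_allowed_bgv`, `ba_carb_cu`.
#' @export
advisor_features <- function(d, t_event, config = window_config()) {
  lo <- t_event - config$advisor_lookback * 3600
  sel <- d$advisor$timestamp >= lo & d$advisor$timestamp < t_event
  rec <- d$advisor[sel, , drop = FALSE]
  if (nrow(rec) == 0L) {
    nm <- c("ba_food_ins", "ba_corr_ins", "ba_total_ins", "ba_diff", "ba_meal_rise",
            "ba_has_excercise", "ba_iob", "ba_allowed_bgv", "ba_carb_cu")
    return(stats::setNames(as.list(rep(NA_real_, 9L)), nm))
  }
  r <- rec[nrow(rec), , drop = FALSE]
  list(
    ba_food_ins = r$food_ins, ba_corr_ins = r$corr_ins, ba_total_ins = r$total_ins,
    ba_diff = r$total_ins - r$logged_intake, ba_meal_rise = r$meal_rise,
    ba_has_excercise = as.numeric(any(rec$exercise_tag, na.rm = TRUE)),
    ba_iob = r$iob, ba_allowed_bgv = r$allowed_bgv, ba_carb_cu = r$carb_cu
  )
}

#' Long-horizon summary statistics of a self-care signal
#'
#' Summarises one signal over the window `[t_event - window, t_event)`:
#' mean, SD (sample, n-1), range, max, min, rate of mean-value crossing
#' (number of sign changes of consecutive deviations from the mean, divided by
#' the number of samples), sample skewness and excess kurtosis. For the
#' glucose signal additionally the means of negative and positive slopes
#' between consecutive readings no more than 6 hours apart (mmol/L per hour).
#' With fewer than 2 samples the SD/range/crossing/skewness/kurtosis are
#' missing; an empty window makes everything missing.
#'
#' @param times Timestamps of the signal's records.
#' @param values Record values aligned with `times`.
#' @param t_event Episode timestamp.
#' @param window_days Window length in days (default 90).
#' @param slopes Compute the signed slope means (glucose only).
#' @return Named list of 8 statistics (`mean`, `std`, `range`, `max`, `min`,
#'   `mean_x`, `skew`, `kurt`), plus `neg_slopes_mean`/`pos_slopes_mean` when
#'   `slopes = TRUE`.
#' @export
longterm_signal_stats <- function(times, values, t_event, window_days = 90,
                                  slopes = FALSE) {
  lo <- t_event - window_days * 86400
  sel <- times >= lo & times < t_event
  x <- values[sel]
  ts <- times[sel]
  n <- length(x)
  out <- list(
    mean = if (n >= 1L) mean(x) else NA_real_,
    std = if (n >= 2L) stats::sd(x) else NA_real_,
    range = if (n >= 2L) max(x) - min(x) else NA_real_,
    max = if (n >= 1L) max(x) else NA_real_,
    min = if (n >= 1L) min(x) else NA_real_,
    mean_x = if (n >= 2L) mean_crossing_rate(x) else NA_real_,
    skew = if (n >= 2L) sample_skewness(x) else NA_real_,
    kurt = if (n >= 2L) excess_kurtosis(x) else NA_real_
  )
  if (slopes) {
    neg <- NA_real_; pos <- NA_real_
    if (n >= 2L) {
      ord <- order(ts)
      dt <- diff(as.numeric(ts[ord])) / 3600
      dv <- diff(x[ord])
      ok <- dt > 0 & dt <= 6 # skip overnight/sparse gaps
      sl <- dv[ok] / dt[ok]
      if (any(sl < 0)) neg <- mean(sl[sl < 0])
      if (any(sl > 0)) pos <- mean(sl[sl > 0])
    }
    out$neg_slopes_mean <- neg
    out$pos_slopes_mean <- pos
  }
  out
}

#' Quiz engagement statistics over the history window
#'
#' @param quiz Quiz-answer data frame (`timestamp`, `points`, `session_id`).
#' @param t_event Episode timestamp.
#' @param window_days Window length in days (default 90).
#' @return Named list: number of answers, number of distinct days with
#'   answers, mean/SD of points, mean/SD of per-session answer counts. With no
#'   activity the counts are 0 and the means/SDs missing.
#' @export
quiz_engagement_features <- function(quiz, t_event, window_days = 90) {
  lo <- t_event - window_days * 86400
  q <- quiz[quiz$timestamp >= lo & quiz$timestamp < t_event, , drop = FALSE]
  if (nrow(q) == 0L) {
    return(list(cnc_ansnum = 0, cnc_daysnum = 0, cnc_points_avg = NA_real_,
                cnc_points_std = NA_real_, cnc_dist_avg = NA_real_,
                cnc_dist_std = NA_real_))
  }
  per_session <- as.numeric(table(q$session_id))
  list(
    cnc_ansnum = nrow(q),
    cnc_daysnum = length(unique(diary_date(q$timestamp))),
    cnc_points_avg = mean(q$points),
    cnc_points_std = if (nrow(q) >= 2L) stats::sd(q$points) else NA_real_,
    cnc_dist_avg = mean(per_session),
    cnc_dist_std = if (length(per_session) >= 2L) stats::sd(per_session) else NA_real_
  )
}

#' Represent one episode as the canonical feature vector
#'
#' Assembles all feature groups into the registry order. The result always has
#' exactly the 83 canonical slots (plus the auxiliary columns) with explicit
#' `NA` for unavailable values, and is deterministic for fixed inputs.
#'
#' @param episode One-row episode data frame (from a diary's `episodes`).
#' @param d The episode's `t1d_diary`.
#' @param config A [window_config()].
#' @return One-row data frame: `episode_id`, `subject_id`, `category`, the 83
#'   registry columns, then [extra_feature_names()].
#' @export
represent_event <- function(episode, d, config = window_config()) {
  stopifnot(nrow(episode) == 1L)
  t_ev <- episode$timestamp
  bl <- subject_baselines(d, t_ev, config$long_window_days)

  tmp <- temporal_features(t_ev, d, bl)
  bgi <- interp_bg_features(d, t_ev, config)
  nbr <- neighbor_bg_features(d, t_ev, config)
  ink <- intake_context_features(d, t_ev, bl)
  adv <- advisor_features(d, t_ev, config)
  lt_g <- longterm_signal_stats(d$glucose$timestamp, d$glucose$value, t_ev,
                                config$long_window_days, slopes = TRUE)
  lt_i <- longterm_signal_stats(d$qa_doses$timestamp, d$qa_doses$units, t_ev,
                                config$long_window_days)
  lt_b <- longterm_signal_stats(d$basal_doses$timestamp, d$basal_doses$units, t_ev,
                                config$long_window_days)
  lt_c <- longterm_signal_stats(d$carbs$timestamp, d$carbs$grams, t_ev,
                                config$long_window_days)
  qz <- quiz_engagement_features(d$quiz, t_ev, config$long_window_days)

  pick_lt <- function(stats, prefix) {
    nm <- c("mean", "std", "range", "max", "min", "mean_x", "skew", "kurt")
    stats::setNames(stats[nm], paste0(prefix, "_", nm))
  }
  vals <- c(
    list(age = d$profile$age, gender = d$profile$gender,
         y_w_diab = d$profile$years_with_diabetes),
    tmp[c("cos_tod", "sin_tod", "wake_up_offset", "is_bday")],
    bgi, nbr, ink,
    adv[c("ba_food_ins", "ba_corr_ins", "ba_total_ins", "ba_diff",
          "ba_meal_rise", "ba_has_excercise")],
    pick_lt(lt_g, "glu"),
    lt_g[c("neg_slopes_mean", "pos_slopes_mean")],
    pick_lt(lt_i, "ins"), pick_lt(lt_b, "bas"), pick_lt(lt_c, "car"),
    qz
  )
  reg <- feature_registry()
  if (!identical(sort(names(vals)), sort(reg$name))) {
    stop("internal error: assembled features do not match the registry", call. = FALSE)
  }
  vals <- vals[reg$name]
  extras <- c(tmp["tod"], adv[c("ba_iob", "ba_allowed_bgv", "ba_carb_cu")])

  out <- data.frame(
    episode_id = episode$episode_id %||% NA_character_,
    subject_id = d$profile$subject_id,
    category = episode$category,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(lapply(c(vals, extras), as.numeric)))
}

#' Build the feature table of a cohort
#'
#' Filters each diary's episodes ([filter_label_episodes()]) and represents
#' every retained episode ([represent_event()]).
#'
#' @param diaries A `t1d_cohort` (list of diaries).
#' @param config A [window_config()].
#' @param min_confidence Confidence filter threshold (default 4).
#' @return Data frame with one row per retained episode: `episode_id`,
#'   `subject_id`, `category`, the 83 registry columns, then the auxiliary
#'   columns.
#' @export
featurize_cohort <- function(diaries, config = window_config(), min_confidence = 4) {
  rows <- list()
  for (d in diaries) {
    eps <- filter_label_episodes(d$episodes, min_confidence)
    for (i in seq_len(nrow(eps))) {
      rows[[length(rows) + 1L]] <- represent_event(eps[i, , drop = FALSE], d, config)
    }
  }
  if (!length(rows)) {
    stop("no episodes passed the confidence/category filter", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
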